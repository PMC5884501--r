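#' Local-velocity-direction (LVD) configuration
#'
#' Parameters of the direction-histogram baseline matcher: gaze
#' displacement directions are binned into `n_bins` equal arcs per sliding
#' window, windows are modelled by a diagonal-covariance GMM universal
#' background model, and subject models are derived by mean-only MAP
#' adaptation with relevance factor `relevance_r`. Defaults follow the
#' published configuration of this baseline: 27 bins, 16 Gaussians,
#' relevance 16.
#'
#' @param n_bins number of direction histogram bins.
#' @param n_gaussians GMM components.
#' @param relevance_r MAP relevance factor (>= 0).
#' @param window_len_samples,window_hop sliding-window extent and hop.
#' @return An `lvd_config` list.
#' @export
lvd_config <- function(n_bins = 27, n_gaussians = 16, relevance_r = 16,
                       window_len_samples = 300, window_hop = 30) {
  stopifnot(n_bins >= 2, n_gaussians >= 1, relevance_r >= 0,
            window_len_samples >= 2, window_hop >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 n_gaussians = as.integer(n_gaussians),
                 relevance_r = relevance_r,
                 window_len_samples = as.integer(window_len_samples),
                 window_hop = as.integer(window_hop)),
            class = "lvd_config")
}

#' Local velocity direction histograms of a recording
#'
#' Over sliding windows of `window_len_samples` valid samples (hop
#' `window_hop`), computes the `atan2` direction of every sample-to-sample
#' displacement, bins directions into `n_bins` equal arcs over `[0, 2*pi)`
#' and normalizes each histogram to sum 1. Zero displacements carry no
#' direction and are skipped; a window with only zero displacements is
#' dropped with a warning.
#'
#' @param rec a [gaze_recording()].
#' @param cfg an [lvd_config()].
#' @return Matrix with one row per window and `n_bins` columns.
#' @export
lvd_histograms <- function(rec, cfg = lvd_config()) {
  stopifnot(inherits(rec, "gaze_recording"), inherits(cfg, "lvd_config"))
  s <- rec$samples[rec$samples$valid, , drop = FALSE]
  n <- nrow(s)
  if (cfg$window_len_samples > n)
    stop("window length exceeds the number of valid samples")
  dx <- diff(s$x); dy <- diff(s$y)
  dir <- atan2(dy, dx) %% (2 * pi)
  nonzero <- dx != 0 | dy != 0
  bin <- pmin(floor(dir / (2 * pi / cfg$n_bins)) + 1L, cfg$n_bins)
  starts <- seq(1, n - cfg$window_len_samples + 1, by = cfg$window_hop)
  rows <- list(); dropped <- 0L
  for (st in starts) {
    idx <- st:(st + cfg$window_len_samples - 2)  # displacement indices
    use <- idx[nonzero[idx]]
    if (length(use) == 0) { dropped <- dropped + 1L; next }
    h <- tabulate(bin[use], nbins = cfg$n_bins)
    rows[[length(rows) + 1L]] <- h / sum(h)
  }
  if (dropped > 0)
    warning(sprintf("dropped %d window(s) with only zero displacements", dropped))
  if (length(rows) == 0) stop("no usable windows in recording")
  do.call(rbind, rows)
}

gmm_log_dens <- function(model, X) {
  # n x G matrix of log(w_g) + log N(x | m_g, diag v_g)
  n <- nrow(X); G <- nrow(model$means)
  out <- matrix(0, n, G)
  for (g in seq_len(G)) {
    lv <- log(model$vars[g, ])
    out[, g] <- log(model$weights[g]) -
      0.5 * sum(lv) - 0.5 * ncol(X) * log(2 * pi) -
      0.5 * colSums((t(X) - model$means[g, ])^2 / model$vars[g, ])
  }
  out
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Fit a diagonal-covariance GMM universal background model
#'
#' Expectation-maximization with k-means initialization (seeded, hence
#' deterministic per seed) and a variance floor. The per-iteration
#' log-likelihood trace is stored; EM guarantees it is non-decreasing.
#'
#' @param histograms numeric matrix, one observation per row (needs at
#'   least `10 * n_gaussians` rows).
#' @param cfg an [lvd_config()].
#' @param seed integer seed.
#' @param max_iter,tol EM stopping rule.
#' @param var_floor lower bound on component variances.
#' @return A `gmm_model`: `weights`, `means` (G x d), `vars` (G x d),
#'   `loglik` trace.
#' @export
train_ubm <- function(histograms, cfg = lvd_config(), seed = 1L,
                      max_iter = 200, tol = 1e-8, var_floor = 1e-8) {
  X <- as.matrix(histograms)
  G <- cfg$n_gaussians
  if (nrow(X) < 10 * G)
    stop(sprintf("need at least %d rows to fit %d Gaussians", 10 * G, G))
  d <- ncol(X)
  uniq <- unique(X)
  means <- with_seed(seed, {
    if (nrow(uniq) >= G) {
      km <- suppressWarnings(kmeans(X, centers = G, nstart = 3,
                                    iter.max = 50))
      km$centers
    } else {
      uniq[sample.int(nrow(uniq), G, replace = TRUE), , drop = FALSE]
    }
  })
  vars <- matrix(pmax(rep(apply(X, 2, stats::var), each = G), var_floor), G, d)
  model <- list(weights = rep(1 / G, G), means = means, vars = vars)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ld <- gmm_log_dens(model, X)
    lse <- logsumexp_rows(ld)
    ll <- sum(lse)
    resp <- exp(ld - lse)
    nk <- colSums(resp)
    model$weights <- pmax(nk, 1e-12) / sum(pmax(nk, 1e-12))
    for (g in seq_len(G)) {
      if (nk[g] < 1e-12) next
      mu <- colSums(resp[, g] * X) / nk[g]
      model$means[g, ] <- mu
      model$vars[g, ] <- pmax(colSums(resp[, g] * (X - rep(mu, each = nrow(X)))^2) /
                                nk[g], var_floor)
    }
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && ll - ll_trace[it - 1] < tol * abs(ll_trace[it - 1]) + tol)
      break
  }
  structure(c(model, list(loglik = ll_trace)), class = "gmm_model")
}

#' MAP-adapt a UBM to a subject's data (mean-only)
#'
#' Classic relevance-MAP update of the component means:
#' `m_hat_g = (n_g * xbar_g + r * m_g) / (n_g + r)` where `n_g` are the
#' soft counts and `xbar_g` the responsibility-weighted data means under
#' the UBM. `r = 0` returns the data's soft means, `r -> Inf` returns the
#' UBM means; weights and variances are kept.
#'
#' @param ubm a [train_ubm()] model.
#' @param subject_histograms matrix of the subject's observations.
#' @param relevance_r relevance factor (>= 0).
#' @return The adapted `gmm_model`.
#' @export
map_adapt <- function(ubm, subject_histograms, relevance_r = 16) {
  stopifnot(inherits(ubm, "gmm_model"), relevance_r >= 0)
  X <- as.matrix(subject_histograms)
  ld <- gmm_log_dens(ubm, X)
  resp <- exp(ld - logsumexp_rows(ld))
  nk <- colSums(resp)
  adapted <- ubm
  for (g in seq_len(nrow(ubm$means))) {
    xbar <- if (nk[g] > 0) colSums(resp[, g] * X) / nk[g] else ubm$means[g, ]
    adapted$means[g, ] <- (nk[g] * xbar + relevance_r * ubm$means[g, ]) /
      (nk[g] + relevance_r)
  }
  adapted
}

#' Average log-likelihood-ratio score of probe histograms
#'
#' The standard GMM-UBM verification score: the mean over probe rows of
#' `log p(x | subject model) - log p(x | UBM)`. Positive scores support
#' the claimed subject; the score is invariant to row order.
#'
#' @param subject_model,ubm `gmm_model`s sharing dimensionality.
#' @param probe_histograms matrix of probe observations.
#' @return Scalar score.
#' @export
lvd_score <- function(subject_model, ubm, probe_histograms) {
  stopifnot(inherits(subject_model, "gmm_model"), inherits(ubm, "gmm_model"))
  if (ncol(subject_model$means) != ncol(ubm$means))
    stop("models have different dimensionality")
  X <- as.matrix(probe_histograms)
  if (ncol(X) != ncol(ubm$means))
    stop("probe dimensionality does not match the models")
  mean(logsumexp_rows(gmm_log_dens(subject_model, X)) -
         logsumexp_rows(gmm_log_dens(ubm, X)))
}
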