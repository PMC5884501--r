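#' Detection error tradeoff curve and equal error rate
#'
#' Sweeps a decision threshold over the pooled score set. At threshold `t`,
#' `FPR(t)` is the fraction of impostor scores `>= t` (an impostor
#' incorrectly accepted) and `FNR(t)` the fraction of genuine scores `< t`
#' (a genuine subject incorrectly rejected). The EER is the common value of
#' FPR and FNR at their crossing, obtained by linear interpolation between
#' the two bracketing thresholds where `FPR - FNR` changes sign.
#'
#' @param x a [score_matrix()], or a numeric vector of genuine scores.
#' @param impostor numeric vector of impostor scores when `x` is a vector.
#' @return A `det_curve`: data frame `points` (`threshold`, `fpr`, `fnr`)
#'   and scalar `eer` in `[0, 1]`.
#' @export
compute_det <- function(x, impostor = NULL) {
  if (inherits(x, "score_matrix")) {
    sp <- split_scores(x); genuine <- sp$genuine; impostor <- sp$impostor
  } else genuine <- x
  if (length(genuine) == 0 || length(impostor) == 0)
    stop("need at least one genuine and one impostor score")
  thr <- c(-Inf, sort(unique(c(genuine, impostor))), Inf)
  fpr <- vapply(thr, function(t) mean(impostor >= t), numeric(1))
  fnr <- vapply(thr, function(t) mean(genuine < t), numeric(1))
  d <- fpr - fnr
  i <- which(d[-length(d)] >= 0 & d[-1] < 0)[1]
  eer <- if (is.na(i)) {           # degenerate: crossing at an endpoint
    fpr[which.min(abs(d))]
  } else if (d[i] == 0) {
    fpr[i]
  } else {
    a <- d[i] / (d[i] - d[i + 1])
    fpr[i] + a * (fpr[i + 1] - fpr[i])
  }
  structure(list(points = data.frame(threshold = thr, fpr = fpr, fnr = fnr),
                 eer = eer),
            class = "det_curve")
}

#' @export
print.det_curve <- function(x, ...) {
  cat(sprintf("<det_curve> EER = %.2f%% over %d thresholds\n",
              100 * x$eer, nrow(x$points)))
  invisible(x)
}

#' Cumulative match characteristic curve
#'
#' For every probe row the genuine subject's rank is computed among all
#' gallery scores; rank-k identification rate is the fraction of rows with
#' rank `<= k`. The default tie policy is optimistic (rank = 1 + number of
#' strictly greater scores); `ties = "pessimistic"` counts ties against
#' the genuine subject.
#'
#' @param sm a [score_matrix()] (closed set).
#' @param ties `"optimistic"` (default) or `"pessimistic"`.
#' @return A `cmc_curve`: numeric `ir` (rank-k identification rates for
#'   `k = 1..K`), plus the per-row `ranks`.
#' @export
compute_cmc <- function(sm, ties = c("optimistic", "pessimistic")) {
  stopifnot(inherits(sm, "score_matrix"))
  ties <- match.arg(ties)
  g <- sm$scores[genuine_index(sm)]
  cmp <- if (ties == "optimistic") sm$scores > g else sm$scores >= g
  cmp[genuine_index(sm)] <- FALSE
  ranks <- 1 + rowSums(cmp)
  K <- ncol(sm$scores)
  ir <- vapply(seq_len(K), function(k) mean(ranks <= k), numeric(1))
  structure(list(ir = ir, ranks = ranks, ties = ties), class = "cmc_curve")
}

#' @export
print.cmc_curve <- function(x, ...) {
  cat(sprintf("<cmc_curve> Rank-1 IR = %.2f%% (K = %d)\n",
              100 * x$ir[1], length(x$ir)))
  invisible(x)
}

#' Tanh score normalization
#'
#' Maps a raw match score `s` to `s' = tanh(0.01 * (s - mu) / sigma) + 1`,
#' a robust standardization onto the open interval (0, 2) used before
#' sum-rule fusion of heterogeneous matchers. `s = mu` maps to exactly 1;
#' the map is strictly increasing, so single-matcher EER and CMC are
#' invariant under it.
#'
#' @param s raw score(s).
#' @param mu,sigma location and scale of the raw score distribution
#'   (`sigma > 0`), typically estimated from training-phase scores.
#' @param c inner coefficient (fixed at 0.01 in the standard recipe).
#' @return Normalized score(s) in (0, 2).
#' @export
tanh_normalize <- function(s, mu, sigma, c = 0.01) {
  if (sigma <= 0) stop("sigma must be > 0")
  tanh(c * (s - mu) / sigma) + 1
}

#' Tanh-normalize every entry of a score matrix
#'
#' When `mu`/`sigma` are omitted they are estimated from the matrix's own
#' pooled genuine + impostor scores; for leakage-free fusion, pass
#' statistics estimated from training-phase scores.
#'
#' @param sm a [score_matrix()].
#' @param mu,sigma normalization parameters (defaults: pooled mean/sd).
#' @param c inner coefficient.
#' @return The normalized [score_matrix()].
#' @export
normalize_scores <- function(sm, mu = NULL, sigma = NULL, c = 0.01) {
  stopifnot(inherits(sm, "score_matrix"))
  if (is.null(mu)) mu <- mean(sm$scores)
  if (is.null(sigma)) sigma <- sd(as.numeric(sm$scores))
  out <- sm
  out$scores <- tanh_normalize(sm$scores, mu, sigma, c)
  out
}

#' Sum-rule fusion of normalized score matrices
#'
#' Entrywise sum of two or more aligned score matrices (same shape,
#' gallery and probe labels); the genuine mask is preserved. Matrices are
#' expected to be tanh-normalized first so each matcher contributes on a
#' commensurate scale.
#'
#' @param sms list of [score_matrix()] objects.
#' @return The fused [score_matrix()].
#' @export
fuse_sum <- function(sms) {
  stopifnot(length(sms) >= 1, all(vapply(sms, inherits, TRUE, "score_matrix")))
  ref <- sms[[1]]
  for (m in sms[-1]) {
    if (!identical(dim(m$scores), dim(ref$scores)) ||
        !identical(m$gallery, ref$gallery) ||
        !identical(m$probe_subject, ref$probe_subject))
      stop("score matrices are not aligned (shape, gallery or probe labels differ)")
  }
  out <- ref
  out$scores <- Reduce(`+`, lapply(sms, `[[`, "scores"))
  out
}

#' Relative change between two result columns, in percent
#'
#' `type = "increase"` reports `100 * (comparison - baseline) / baseline`
#' (e.g. how much an error rate grew); `type = "loss"` reports
#' `100 * (baseline - comparison) / baseline` (e.g. how much an
#' identification rate dropped). Results are rounded to two decimals; a
#' zero baseline yields `NA`.
#'
#' @param baseline,comparison numeric vectors (aligned).
#' @param type `"increase"` or `"loss"`.
#' @return Numeric vector of percentages.
#' @export
relative_change <- function(baseline, comparison,
                            type = c("increase", "loss")) {
  type <- match.arg(type)
  stopifnot(length(baseline) == length(comparison))
  num <- if (type == "increase") comparison - baseline else
    baseline - comparison
  out <- ifelse(baseline == 0, NA_real_, 100 * num / baseline)
  round(out, 2)
}
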