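#' Assemble probes by averaging feature vectors
#'
#' A probe is the arithmetic mean of `NoET` feature vectors of one subject,
#' the unit of matching. Within each probe the `NoET` vectors are sampled
#' without replacement (fresh shuffle per probe, so different probes of the
#' same subject may overlap when `n_probes * NoET` exceeds the pool).
#' Averaging shrinks the within-subject feature variance roughly like
#' `1/NoET`, which is why larger probes match better.
#'
#' @param features numeric matrix, one feature vector per row.
#' @param subjects subject label per row.
#' @param NoET number of vectors averaged per probe (>= 1).
#' @param n_probes probes per subject.
#' @param seed integer seed.
#' @return A `probe_set`: list with `vectors` (matrix, one probe per row),
#'   `subject` (label per probe), `NoET` and `member_ids` (list of source
#'   row indices per probe).
#' @export
assemble_probes <- function(features, subjects, NoET, n_probes, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(subjects), NoET >= 1, n_probes >= 1)
  subjects <- as.character(subjects)
  pools <- split(seq_along(subjects), subjects)
  short <- names(pools)[vapply(pools, length, 1L) < NoET]
  if (length(short) > 0)
    stop("insufficient data: subject(s) with fewer than NoET vectors: ",
         paste(short, collapse = ", "))
  with_seed(seed, {
    vecs <- list(); labs <- character(0); members <- list()
    for (s in names(pools)) {
      pool <- pools[[s]]
      for (p in seq_len(n_probes)) {
        idx <- sample(pool, NoET)
        vecs[[length(vecs) + 1L]] <- colMeans(features[idx, , drop = FALSE])
        labs <- c(labs, s)
        members[[length(members) + 1L]] <- idx
      }
    }
    structure(list(vectors = do.call(rbind, vecs), subject = labs,
                   NoET = as.integer(NoET), member_ids = members),
              class = "probe_set")
  })
}

#' Maximum-likelihood intrinsic dimension estimate
#'
#' The Levina-Bickel nearest-neighbour maximum-likelihood estimator with
#' the standard small-k bias correction: for each point,
#' `m_k(x) = [ (1/(k-2)) * sum_{j<k} log(T_k(x)/T_j(x)) ]^-1` with `T_j`
#' the distance to the j-th neighbour (the `k-2` denominator removes the
#' `(k-1)/(k-2)` bias of the raw estimator); estimates are averaged over
#' points and over neighbourhood sizes `k_min..k_max`. The estimator is
#' scale invariant. Duplicate points (zero distances) are jittered by a
#' tiny epsilon with a warning.
#'
#' @param X numeric matrix (rows = points; needs more than `k_max` rows).
#' @param k_min,k_max neighbourhood-size range (defaults 6 and 12).
#' @return Scalar estimated intrinsic dimension.
#' @export
estimate_intrinsic_dim <- function(X, k_min = 6, k_max = 12) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k_min >= 3, k_max >= k_min, n >= k_max + 1)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  if (any(D[upper.tri(D)] == 0)) {
    warning("duplicate points; adding jitter of 1e-8 * mean distance")
    eps <- 1e-8 * mean(D[is.finite(D)])
    D[D == 0] <- eps
  }
  sorted <- apply(D, 1, function(r) sort(r)[seq_len(k_max)])  # k_max x n
  logT <- log(sorted)
  est_k <- vapply(k_min:k_max, function(k) {
    inv <- (colSums(logT[k, , drop = FALSE][rep(1, k - 1), , drop = FALSE] -
                      logT[seq_len(k - 1), , drop = FALSE]) / (k - 2))^-1
    mean(inv)
  }, numeric(1))
  mean(est_k)
}

#' Fit the dimensionality-reduction model (standardize + LDA)
#'
#' Standardizes features (z-score from the training set), drops constant
#' columns, and fits Fisher linear discriminant analysis by solving the
#' generalized eigenproblem of the between-class versus within-class
#' scatter matrices, projecting to `target_dim` dimensions. The
#' within-class scatter is always shrunk towards the identity
#' (`Sw + lambda * tr(Sw)/p * I` with `lambda = 1e-3`), which keeps the
#' solve well-posed when features are collinear or outnumber the training
#' probes; a warning flags the genuinely singular case. Discriminant
#' columns are normalized to unit within-class variance, so they are
#' orthogonal under the (regularized) within-scatter metric. When
#' `target_dim` is `NULL` it defaults to `min(round(d_hat), n_classes - 1)`
#' with `d_hat` the maximum-likelihood intrinsic dimension of the training
#' features — the projection target is re-estimated per dataset rather
#' than fixed.
#'
#' @param X training feature matrix.
#' @param labels class (subject) label per row (>= 2 samples per class).
#' @param target_dim output dimension, or `NULL` to estimate.
#' @param standardize z-score features first (default TRUE).
#' @param shrinkage within-scatter ridge coefficient (fraction of the
#'   average within-scatter eigenvalue; default 1e-3).
#' @return A `reduction_model` with the centering/scaling, kept columns,
#'   projection matrix `W` (first `target_dim` discriminants), `d_hat` and
#'   the regularized within scatter `Sw_reg`.
#' @export
fit_reduction <- function(X, labels, target_dim = NULL, standardize = TRUE,
                          shrinkage = 1e-3) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  k <- nlevels(labels)
  ctr <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) pmax(apply(X, 2, sd), 1e-12) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  keep <- which(apply(Xs, 2, sd) > 1e-10)
  if (length(keep) == 0) stop("all features are constant")
  Xs <- Xs[, keep, drop = FALSE]
  p <- ncol(Xs)
  d_hat <- if (is.null(target_dim)) {
    dh <- tryCatch(suppressWarnings(estimate_intrinsic_dim(Xs)),
                   error = function(e) k - 1)
    max(1, round(dh))
  } else NA_real_
  m <- if (is.null(target_dim)) min(d_hat, k - 1) else
    min(target_dim, k - 1, p)
  mu <- colMeans(Xs)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (l in levels(labels)) {
    Xi <- Xs[labels == l, , drop = FALSE]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  if (nrow(Xs) < p + k)
    warning("within-class scatter is singular (more features than samples); ",
            "shrinkage regularization applied")
  Sw_reg <- Sw + shrinkage * sum(diag(Sw)) / p * diag(p)
  E <- eigen(solve(Sw_reg, Sb))
  ord <- order(Re(E$values), decreasing = TRUE)[seq_len(m)]
  W <- Re(E$vectors[, ord, drop = FALSE])
  # unit within-class variance per discriminant (Sw-metric orthonormal)
  nrm <- sqrt(diag(t(W) %*% Sw_reg %*% W) / max(1, nrow(Xs) - k))
  W <- sweep(W, 2, pmax(nrm, 1e-300), "/")
  structure(list(center = ctr, scale = scl, keep = keep, W = W,
                 levels = levels(labels), d_hat = d_hat,
                 target_dim = ncol(W), standardize = standardize,
                 Sw_reg = Sw_reg),
            class = "reduction_model")
}

#' Project features with a fitted reduction model
#'
#' @param model a [fit_reduction()] model.
#' @param X feature matrix (same columns as the training features).
#' @return Projected matrix with `target_dim` columns.
#' @export
project_features <- function(model, X) {
  stopifnot(inherits(model, "reduction_model"))
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xs[, model$keep, drop = FALSE] %*% model$W
}

#' Fit the one-against-one SVM matcher
#'
#' Trains `k * (k-1) / 2` pairwise SVM classifiers over the `k` enrolled
#' subjects in the reduced feature space (linear kernel, C = 1 by default:
#' after LDA the classes are low-dimensional and near-linearly separable).
#' Each subject participates in exactly `k - 1` pairwise classifiers;
#' identification aggregates votes over all pairs, verification over the
#' claimed subject's `k - 1` pairs.
#'
#' @param probes a training [assemble_probes()] set (>= 2 subjects, >= 2
#'   probes each).
#' @param reduction a [fit_reduction()] model fitted on the same features.
#' @param kernel,cost SVM kernel and cost passed to [e1071::svm()].
#' @param gamma RBF kernel width (ignored for linear).
#' @return A `matcher_model` with the SVM, the reduction and the enrolled
#'   subject levels; `n_classifiers` records `k * (k-1) / 2`.
#' @export
fit_matchers <- function(probes, reduction, kernel = "linear", cost = 1,
                         gamma = NULL) {
  stopifnot(inherits(probes, "probe_set"), inherits(reduction, "reduction_model"))
  y <- factor(probes$subject)
  if (nlevels(y) < 2) stop("need at least 2 enrolled subjects")
  if (any(table(y) < 2)) stop("every subject needs at least 2 training probes")
  Z <- project_features(reduction, probes$vectors)
  args <- list(x = Z, y = y, kernel = kernel, cost = cost, scale = FALSE,
               probability = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  k <- nlevels(y)
  structure(list(svm = fit, reduction = reduction, subjects = levels(y),
                 k = k, n_classifiers = k * (k - 1) / 2,
                 kernel = kernel, cost = cost),
            class = "matcher_model")
}

# Pairwise decision values for raw feature rows: n x (k(k-1)/2) matrix with
# columns named "A/B" (positive margin favours A).
pairwise_margins <- function(matcher, X) {
  Z <- project_features(matcher$reduction, as.matrix(X))
  pr <- stats::predict(matcher$svm, Z, decision.values = TRUE)
  attr(pr, "decision.values")
}

# Margin of every pairwise classifier involving `subject`, oriented so
# positive supports `subject`. Returns an n x (k-1) matrix.
margins_for_subject <- function(matcher, D, subject) {
  parts <- strsplit(colnames(D), "/", fixed = TRUE)
  first <- vapply(parts, `[`, "", 1)
  second <- vapply(parts, `[`, "", 2)
  cols <- which(first == subject | second == subject)
  signs <- ifelse(first[cols] == subject, 1, -1)
  sweep(D[, cols, drop = FALSE], 2, signs, "*")
}

#' Verification score of a probe against a claimed identity
#'
#' The mean signed decision margin of the `k - 1` pairwise classifiers
#' involving the claimed subject, oriented so larger supports the claim —
#' a continuous generalization of vote counting that gives DET curves
#' fine-grained thresholds. The plain vote fraction is also returned.
#'
#' @param matcher a [fit_matchers()] model.
#' @param probe one probe: a feature vector or single-row matrix (raw
#'   feature space).
#' @param claimed_subject enrolled subject label.
#' @return List with `score` (mean margin) and `vote_fraction`.
#' @export
verify <- function(matcher, probe, claimed_subject) {
  stopifnot(inherits(matcher, "matcher_model"))
  if (!claimed_subject %in% matcher$subjects)
    stop("unknown subject: ", claimed_subject)
  D <- pairwise_margins(matcher, matrix(probe, nrow = 1))
  M <- margins_for_subject(matcher, D, claimed_subject)
  list(score = mean(M[1, ]), vote_fraction = mean(M[1, ] > 0))
}

#' Identify a probe against all enrolled subjects
#'
#' Aggregates the votes of all `k(k-1)/2` pairwise classifiers (each casts
#' exactly one vote); subjects are ranked by votes, ties broken by summed
#' signed margins and then by subject label — a documented, deterministic
#' ordering.
#'
#' @param matcher a [fit_matchers()] model.
#' @param probe one probe in raw feature space.
#' @return Data frame (one row per enrolled subject, best first) with
#'   `subject`, `votes`, `margin_sum`, `rank`.
#' @export
identify <- function(matcher, probe) {
  stopifnot(inherits(matcher, "matcher_model"))
  D <- pairwise_margins(matcher, matrix(probe, nrow = 1))
  votes <- margin_sum <- stats::setNames(numeric(matcher$k), matcher$subjects)
  for (s in matcher$subjects) {
    M <- margins_for_subject(matcher, D, s)
    votes[s] <- sum(M[1, ] > 0)
    margin_sum[s] <- sum(M[1, ])
  }
  ord <- order(-votes, -margin_sum, matcher$subjects)
  data.frame(subject = matcher$subjects[ord], votes = votes[ord],
             margin_sum = margin_sum[ord], rank = seq_len(matcher$k),
             row.names = NULL)
}

#' Score a probe set against every enrolled subject
#'
#' Builds the score matrix feeding DET/EER and CMC evaluation: one row per
#' test probe, one column per enrolled subject, entries the verification
#' score (mean pairwise margin by default, vote fraction with
#' `score = "votes"`). Exactly one entry per row is genuine.
#'
#' @param matcher a [fit_matchers()] model.
#' @param probes a test [assemble_probes()] set.
#' @param score `"margin"` (default): mean signed margin of the claimed
#'   subject's `k - 1` classifiers — the fine-grained verification score;
#'   `"votes"`: the vote fraction of those classifiers; `"ident"`: total
#'   votes over all `k(k-1)/2` classifiers with the summed margin as a
#'   bounded tie-break — the identification score whose ranking matches
#'   [identify()].
#' @return A `score_matrix`: list with `scores`, `gallery` (column
#'   subjects) and `probe_subject` (true label per row).
#' @export
score_probes <- function(matcher, probes,
                         score = c("margin", "votes", "ident")) {
  stopifnot(inherits(matcher, "matcher_model"), inherits(probes, "probe_set"))
  score <- match.arg(score)
  D <- pairwise_margins(matcher, probes$vectors)
  S <- matrix(0, nrow(D), matcher$k,
              dimnames = list(NULL, matcher$subjects))
  for (s in matcher$subjects) {
    M <- margins_for_subject(matcher, D, s)
    S[, s] <- switch(score,
      margin = rowMeans(M),
      votes = rowMeans(M > 0),
      ident = rowSums(M > 0) + stats::plogis(rowSums(M)) * 0.5)
  }
  score_matrix(S, probes$subject)
}

#' Construct a score matrix
#'
#' @param scores numeric matrix, rows = probes, named columns = enrolled
#'   subjects.
#' @param probe_subject true subject per row (must appear in the columns).
#' @return A `score_matrix` object.
#' @export
score_matrix <- function(scores, probe_subject) {
  scores <- as.matrix(scores)
  stopifnot(!is.null(colnames(scores)),
            length(probe_subject) == nrow(scores))
  if (!all(probe_subject %in% colnames(scores)))
    stop("probe subjects must all be enrolled (closed set)")
  structure(list(scores = scores, gallery = colnames(scores),
                 probe_subject = as.character(probe_subject)),
            class = "score_matrix")
}

genuine_index <- function(sm) {
  cbind(seq_len(nrow(sm$scores)), match(sm$probe_subject, sm$gallery))
}

#' Split a score matrix into genuine and impostor scores
#' @param sm a [score_matrix()].
#' @return List with numeric vectors `genuine` and `impostor`.
#' @export
split_scores <- function(sm) {
  stopifnot(inherits(sm, "score_matrix"))
  gi <- genuine_index(sm)
  mask <- matrix(FALSE, nrow(sm$scores), ncol(sm$scores))
  mask[gi] <- TRUE
  list(genuine = sm$scores[mask], impostor = sm$scores[!mask])
}
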