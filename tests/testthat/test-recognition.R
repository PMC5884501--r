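test_that("probe assembly averages distinct vectors per probe", {
  set.seed(1)
  X <- matrix(rnorm(12 * 5), 12, 5)
  ps <- assemble_probes(X, rep("a", 12), NoET = 4, n_probes = 3, seed = 2)
  expect_equal(nrow(ps$vectors), 3)
  for (i in 1:3) {
    expect_length(unique(ps$member_ids[[i]]), 4)
    expect_equal(ps$vectors[i, ],
                 colMeans(X[ps$member_ids[[i]], , drop = FALSE]))
  }
  one <- assemble_probes(X, rep("a", 12), NoET = 1, n_probes = 12, seed = 3)
  expect_true(all(one$vectors %in% X))
  expect_error(assemble_probes(X[1:3, ], rep("a", 3), NoET = 4, n_probes = 1),
               "insufficient")
  expect_identical(assemble_probes(X, rep("a", 12), 4, 3, seed = 9),
                   assemble_probes(X, rep("a", 12), 4, 3, seed = 9))
})

test_that("probe variance scales like 1/NoET", {
  set.seed(4)
  X <- matrix(rnorm(1000), ncol = 1)
  v <- vapply(c(2, 8), function(noet) {
    ps <- assemble_probes(X, rep("a", 1000), noet, n_probes = 600, seed = 5)
    var(ps$vectors[, 1])
  }, numeric(1))
  expect_equal(v[1] / v[2], 4, tolerance = 0.15 * 4)
})

test_that("the ML intrinsic dimension estimator recovers manifold dims", {
  set.seed(7)
  X2 <- cbind(matrix(runif(1000), 500, 2), matrix(0, 500, 8))
  d2 <- estimate_intrinsic_dim(X2)
  expect_gt(d2, 1.6); expect_lt(d2, 2.4)

  X1 <- cbind(seq(0, 1, length.out = 300),
              matrix(rnorm(300 * 4, sd = 1e-4), 300, 4))
  d1 <- estimate_intrinsic_dim(X1)
  expect_gt(d1, 0.8); expect_lt(d1, 1.3)

  expect_equal(estimate_intrinsic_dim(10 * X2), d2, tolerance = 1e-9)
  expect_warning(estimate_intrinsic_dim(rbind(X2, X2[1:20, ])), "duplicate")

  # independent per-point loop oracle (bias-corrected ML estimator)
  naive_mle <- function(X, k_min = 6, k_max = 12) {
    n <- nrow(X)
    ests <- c()
    for (k in k_min:k_max) {
      inv <- numeric(n)
      for (i in 1:n) {
        d <- sort(sqrt(colSums((t(X) - X[i, ])^2)))[-1]
        inv[i] <- 1 / (sum(log(d[k] / d[1:(k - 1)])) / (k - 2))
      }
      ests <- c(ests, mean(inv))
    }
    mean(ests)
  }
  Xs <- X2[1:60, ]
  expect_equal(estimate_intrinsic_dim(Xs), naive_mle(Xs), tolerance = 1e-9)
})

test_that("LDA reduction separates classes and respects rank bounds", {
  set.seed(8)
  tc <- toy_classes(k = 2, n = 20, d = 4, sep = 10)
  red <- fit_reduction(tc$X, tc$y)
  expect_equal(ncol(red$W), 1)   # at most k - 1 dimensions
  Z <- project_features(red, tc$X)
  mus <- tapply(Z[, 1], tc$y, mean)
  pooled <- sqrt(mean(tapply(Z[, 1], tc$y, var)))
  expect_gt(abs(diff(mus)) / pooled, 5)

  # discriminant columns orthogonal under the within-scatter metric
  tc3 <- toy_classes(k = 4, n = 15, d = 6, sep = 5, seed = 2)
  red3 <- fit_reduction(tc3$X, tc3$y, target_dim = 3)
  G <- t(red3$W) %*% red3$Sw_reg %*% red3$W
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-6)

  expect_error(fit_reduction(tc$X[c(1, 21), ], tc$y[c(1, 21)]),
               "at least 2 samples")
})

test_that("shrinkage LDA agrees with a reference LDA when well-posed", {
  skip_if_not_installed("MASS")
  set.seed(9)
  tc <- toy_classes(k = 3, n = 30, d = 5, sep = 4)
  red <- fit_reduction(tc$X, tc$y, target_dim = 2)
  Z <- project_features(red, tc$X)
  ref <- MASS::lda(scale(tc$X), grouping = factor(tc$y))
  Zr <- scale(tc$X) %*% ref$scaling
  for (j in 1:2)
    expect_gt(abs(cor(Z[, j], Zr[, j])), 0.99)
})

test_that("one-against-one matchers count classifiers and separate toys", {
  tc <- toy_classes(k = 3, n = 10, d = 3, sep = 12)
  red <- fit_reduction(tc$X, tc$y, target_dim = 2)
  probes <- structure(list(vectors = tc$X, subject = tc$y, NoET = 1L,
                           member_ids = as.list(seq_along(tc$y))),
                      class = "probe_set")
  m <- fit_matchers(probes, red)
  expect_equal(m$n_classifiers, 3)
  D <- gazetex:::pairwise_margins(m, tc$X)
  expect_equal(ncol(D), 3)   # the SVM really holds k(k-1)/2 classifiers
  # perfect training identification on a separable toy
  top1 <- vapply(seq_len(nrow(tc$X)), function(i)
    identify(m, tc$X[i, ])$subject[1], "")
  expect_equal(top1, tc$y)

  tc4 <- toy_classes(k = 4, n = 8, d = 3, sep = 12, seed = 3)
  red4 <- fit_reduction(tc4$X, tc4$y, target_dim = 3)
  p4 <- structure(list(vectors = tc4$X, subject = tc4$y, NoET = 1L,
                       member_ids = as.list(seq_along(tc4$y))),
                  class = "probe_set")
  m4 <- fit_matchers(p4, red4)
  expect_equal(m4$n_classifiers, 6)
  expect_error(fit_matchers(structure(list(vectors = tc4$X[1:9, ],
                                           subject = c(rep("a", 8), "b"),
                                           NoET = 1L,
                                           member_ids = as.list(1:9)),
                                      class = "probe_set"), red4),
               "at least 2 training probes")
})

test_that("verification and identification match brute-force vote counting", {
  tc <- toy_classes(k = 4, n = 10, d = 4, sep = 8, seed = 5)
  red <- fit_reduction(tc$X, tc$y, target_dim = 3)
  probes <- structure(list(vectors = tc$X, subject = tc$y, NoET = 1L,
                           member_ids = as.list(seq_along(tc$y))),
                      class = "probe_set")
  m <- fit_matchers(probes, red)
  subjects <- m$subjects
  Z <- project_features(red, tc$X)

  # brute force: train each pairwise SVM separately, count votes
  brute_votes <- function(z) {
    votes <- stats::setNames(numeric(4), subjects)
    for (a in 1:3) for (b in (a + 1):4) {
      sel <- tc$y %in% subjects[c(a, b)]
      fit <- e1071::svm(x = Z[sel, ], y = factor(tc$y[sel]),
                        kernel = "linear", cost = 1, scale = FALSE)
      w <- as.character(predict(fit, matrix(z, nrow = 1)))
      votes[w] <- votes[w] + 1
    }
    votes
  }
  set.seed(6)
  for (i in sample(nrow(tc$X), 5)) {
    bv <- brute_votes(Z[i, ])
    idr <- identify(m, tc$X[i, ])
    expect_equal(sum(idr$votes), 6)          # each classifier votes once
    got <- stats::setNames(idr$votes, idr$subject)[subjects]
    expect_equal(unname(got), unname(bv))
    v <- verify(m, tc$X[i, ], tc$y[i])
    expect_equal(v$vote_fraction, 1.0)       # training point, separable toy
    expect_gt(v$score, 0)
  }
  expect_error(verify(m, tc$X[1, ], "nobody"), "unknown subject")
})

test_that("score matrices have one genuine entry per row", {
  tc <- toy_classes(k = 3, n = 10, d = 3, sep = 6, seed = 8)
  red <- fit_reduction(tc$X, tc$y, target_dim = 2)
  probes <- structure(list(vectors = tc$X, subject = tc$y, NoET = 1L,
                           member_ids = as.list(seq_along(tc$y))),
                      class = "probe_set")
  m <- fit_matchers(probes, red)
  sm <- score_probes(m, probes)
  expect_equal(dim(sm$scores), c(30, 3))
  sp <- split_scores(sm)
  expect_length(sp$genuine, 30)
  expect_length(sp$impostor, 60)
  expect_error(score_matrix(sm$scores, rep("zz", 30)), "enrolled")
})
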