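test_that("I-VT segments stillness and steps correctly", {
  geom <- test_geometry()
  still <- make_rec(rep(500, 301), rep(500, 301))
  ev <- ivt_segment(still, 30, geom)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(ev$fixations$centroid_x, 500)
  expect_equal(ev$fixations$duration, 1, tolerance = 1e-9)

  step_px <- degrees_to_pixels(geom, 10)
  r <- make_rec(c(rep(500, 150), rep(500 + step_px, 150)), rep(500, 300))
  ev2 <- ivt_segment(r, 30, geom)
  expect_equal(nrow(ev2$saccades), 1)
  expect_equal(nrow(ev2$fixations), 2)
  expect_equal(ev2$saccades$amplitude_deg, 10, tolerance = 0.2)

  expect_error(ivt_segment(make_rec(1:5, 1:5, valid = rep(FALSE, 5))),
               "valid samples")
})

test_that("I-VT velocities match an independent finite difference", {
  geom <- test_geometry()
  set.seed(4)
  r <- random_rec(100)
  r$samples$valid <- TRUE
  ev <- ivt_segment(r, 30, geom)
  s <- r$samples
  n <- nrow(s)
  vref <- numeric(n)
  for (i in 2:(n - 1)) {
    d <- sqrt((s$x[i + 1] - s$x[i - 1])^2 + (s$y[i + 1] - s$y[i - 1])^2)
    vref[i] <- pixels_to_degrees(geom, d) / (s$t[i + 1] - s$t[i - 1])
  }
  vref[1] <- pixels_to_degrees(geom, sqrt((s$x[2] - s$x[1])^2 +
                                            (s$y[2] - s$y[1])^2)) / (s$t[2] - s$t[1])
  vref[n] <- pixels_to_degrees(geom, sqrt((s$x[n] - s$x[n - 1])^2 +
                                            (s$y[n] - s$y[n - 1])^2)) / (s$t[n] - s$t[n - 1])
  expect_equal(ev$velocity, vref, tolerance = 1e-9)
})

test_that("I-VT events partition the valid samples", {
  geom <- test_geometry()
  sess <- simulate_session(session_plan(2, 1, 1, 2, seed = 5), geom)
  for (r in sess$recordings) {
    ev <- ivt_segment(r, 30, geom)
    expect_equal(length(ev$sample_event), sum(r$samples$valid))
    expect_true(all(ev$sample_event >= 1))
    expect_equal(nrow(ev$fixations) + nrow(ev$saccades),
                 max(ev$sample_event))
    if (nrow(ev$saccades) > 0) {
      expect_true(all(ev$saccades$peak_velocity_deg_s >=
                        ev$saccades$mean_velocity_deg_s))
      expect_true(all(ev$saccades$mean_velocity_deg_s > 0))
    }
    expect_true(all(ev$fixations$end_t > ev$fixations$start_t))
  }
})

test_that("CEM features summarize events and flag empty classes", {
  fx <- data.frame(start_t = c(0, 1), end_t = c(0.2, 1.3),
                   centroid_x = c(1, 2), centroid_y = c(1, 2),
                   duration = c(0.2, 0.3))
  sc <- data.frame(start_t = 0.2, end_t = 0.25, amplitude_deg = 4,
                   mean_velocity_deg_s = 100, peak_velocity_deg_s = 180)
  v <- cem_features(fx, sc)
  expect_length(v, 11)
  expect_equal(v[["fix_duration_mean"]], 0.25)
  expect_equal(v[["fix_duration_sd"]], 0.05)      # population sd
  expect_equal(v[["sacc_amplitude_sd"]], 0)       # single event
  v2 <- cem_features(fx, sc[0, ])
  expect_true(attr(v2, "flags")[["no_saccades"]])
  expect_equal(v2[["sacc_peak_velocity_mean"]], 0)

  # naive per-field recomputation oracle on random event sets
  set.seed(6)
  pop_sd <- function(x) if (length(x) <= 1) 0 else sqrt(mean((x - mean(x))^2))
  for (i in 1:50) {
    nf <- sample(1:6, 1); ns <- sample(0:5, 1)
    fx <- data.frame(start_t = 1:nf, end_t = 1:nf + runif(nf),
                     centroid_x = rnorm(nf), centroid_y = rnorm(nf),
                     duration = runif(nf))
    sc <- data.frame(start_t = seq_len(ns), end_t = seq_len(ns) + runif(ns),
                     amplitude_deg = runif(ns, 0, 20),
                     mean_velocity_deg_s = runif(ns, 10, 200),
                     peak_velocity_deg_s = runif(ns, 200, 500))
    v <- cem_features(fx, sc)
    expect_equal(v[["fixation_count"]], nf)
    expect_equal(v[["fix_duration_mean"]], mean(fx$duration))
    expect_equal(v[["fix_duration_sd"]], pop_sd(fx$duration))
    expect_equal(v[["sacc_amplitude_mean"]],
                 if (ns == 0) 0 else mean(sc$amplitude_deg))
    expect_equal(v[["sacc_duration_sd"]], pop_sd(sc$end_t - sc$start_t))
    expect_equal(v[["sacc_peak_velocity_mean"]],
                 if (ns == 0) 0 else mean(sc$peak_velocity_deg_s))
  }
})

test_that("LVD histograms bin directions and normalize", {
  cfg <- lvd_config(window_len_samples = 50, window_hop = 10)
  right <- make_rec(seq(0, 990, by = 10), rep(500, 100))
  H <- lvd_histograms(right, cfg)
  expect_true(all(abs(rowSums(H) - 1) < 1e-12))
  expect_true(all(H[, 1] == 1))  # direction 0 falls in the first bin

  # dense circular motion: near-uniform histogram
  th <- seq(0, 6 * pi, length.out = 2000)
  circ <- make_rec(960 + 300 * cos(th), 540 + 300 * sin(th))
  Hc <- lvd_histograms(circ, lvd_config(window_len_samples = 2000))
  expect_lt(max(Hc), 2 / 27)

  expect_error(lvd_histograms(right, lvd_config(window_len_samples = 500)),
               "exceeds")
  stillr <- make_rec(rep(5, 60), rep(5, 60))
  expect_warning(expect_error(lvd_histograms(stillr, cfg), "no usable"),
                 "zero displacements")
})

test_that("the GMM UBM fits degenerate and mixture data correctly", {
  cfg2 <- lvd_config(n_gaussians = 2)
  X <- matrix(rep(c(0.3, 0.7), each = 40), ncol = 2)
  m <- train_ubm(X, cfg2, seed = 1)
  expect_equal(unname(m$means[1, ]), c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(unname(m$means[2, ]), c(0.3, 0.7), tolerance = 1e-6)
  expect_true(all(diff(m$loglik) >= -1e-6))

  set.seed(2)
  Y <- rbind(matrix(rnorm(400, 0, 0.05), ncol = 2),
             matrix(rnorm(400, 1, 0.05), ncol = 2))
  m2 <- train_ubm(Y, cfg2, seed = 3)
  mu <- m2$means[order(m2$means[, 1]), ]
  expect_equal(unname(mu[1, ]), c(0, 0), tolerance = 0.05)
  expect_equal(unname(mu[2, ]), c(1, 1), tolerance = 0.05)
  expect_true(all(diff(m2$loglik) >= -1e-6))
  expect_error(train_ubm(Y[1:10, ], lvd_config(), seed = 1), "at least")
})

test_that("MAP adaptation interpolates between UBM and data means", {
  set.seed(3)
  X <- matrix(rnorm(300), ncol = 3)
  ubm <- train_ubm(X, lvd_config(n_gaussians = 4), seed = 1)
  sub <- matrix(rnorm(90, mean = 0.5), ncol = 3)

  far <- map_adapt(ubm, sub, 1e12)
  expect_equal(far$means, ubm$means, tolerance = 1e-6)

  near <- map_adapt(ubm, sub, 0)
  ld <- gazetex:::gmm_log_dens(ubm, sub)
  resp <- exp(ld - gazetex:::logsumexp_rows(ld))
  soft <- t(vapply(seq_len(4), function(g)
    colSums(resp[, g] * sub) / sum(resp[, g]), numeric(3)))
  expect_equal(unname(near$means), unname(soft), tolerance = 1e-9)

  # hand-computed single-component toy: m_hat = (n xbar + r m) / (n + r)
  ubm1 <- structure(list(weights = 1, means = matrix(0.2, 1, 1),
                         vars = matrix(0.1, 1, 1), loglik = 0),
                    class = "gmm_model")
  pts <- matrix(c(1, 2, 3), ncol = 1)
  ad <- map_adapt(ubm1, pts, relevance_r = 2)
  expect_equal(ad$means[1, 1], (3 * 2 + 2 * 0.2) / (3 + 2), tolerance = 1e-12)

  # interpolation: every adapted mean lies between UBM mean and soft mean
  mid <- map_adapt(ubm, sub, 5)
  lo <- pmin(ubm$means, soft); hi <- pmax(ubm$means, soft)
  expect_true(all(mid$means >= lo - 1e-9 & mid$means <= hi + 1e-9))
})

test_that("GMM-UBM scoring behaves like a log-likelihood ratio", {
  set.seed(5)
  X <- matrix(rnorm(400), ncol = 2)
  ubm <- train_ubm(X, lvd_config(n_gaussians = 2), seed = 1)
  expect_equal(lvd_score(ubm, ubm, X[1:50, ]), 0)
  probe <- matrix(rnorm(100, mean = 1), ncol = 2)
  subj <- map_adapt(ubm, matrix(rnorm(200, mean = 1), ncol = 2), 16)
  s <- lvd_score(subj, ubm, probe)
  expect_gt(s, 0)
  expect_equal(lvd_score(subj, ubm, probe[sample(50), ]), s)
  bad <- structure(list(weights = 1, means = matrix(0, 1, 3),
                        vars = matrix(1, 1, 3), loglik = 0),
                   class = "gmm_model")
  expect_error(lvd_score(bad, ubm, probe), "dimensionality")
})

test_that("fixation density maps are normalized duration histograms", {
  geom <- test_geometry()
  fx1 <- data.frame(start_t = 0, end_t = 0.3, centroid_x = 960,
                    centroid_y = 540, duration = 0.3)
  m <- fdm_build(fx1, grid_size = 64, smoothing_sigma = 0, geometry = geom)
  expect_equal(sum(m$weights), 1)
  expect_equal(sum(m$weights > 0), 1)
  expect_equal(max(m$weights), 1)

  fx2 <- rbind(fx1, data.frame(start_t = 1, end_t = 1.3, centroid_x = 100,
                               centroid_y = 100, duration = 0.3))
  m2 <- fdm_build(fx2, 64, 0, geom)
  expect_equal(sort(m2$weights[m2$weights > 0]), c(0.5, 0.5))

  m3 <- fdm_build(fx2, 64, 1.5, geom)
  expect_equal(sum(m3$weights), 1, tolerance = 1e-9)
  expect_true(all(m3$weights >= 0))
  expect_error(fdm_build(fx1[0, ], 64, 0, geom), "at least one")
})

test_that("density-map similarities match their definitions", {
  p <- as_fdm(matrix(c(0.5, 0.5, 0, 0), 2))
  q <- as_fdm(matrix(c(1, 0, 0, 0), 2))
  expect_equal(fdm_similarity(p, p, "SIM"), 1)
  expect_equal(fdm_similarity(p, q, "SIM"), 0.5)
  disjoint <- as_fdm(matrix(c(0, 0, 1, 0), 2))
  expect_equal(fdm_similarity(p, disjoint, "SIM"), 0)
  expect_equal(fdm_similarity(p, q, "SIM"), fdm_similarity(q, p, "SIM"))
  expect_equal(fdm_similarity(p, p, "PCC"), 1)
  expect_equal(fdm_similarity(p, p, "KLD"), 0, tolerance = 1e-9)
  expect_lt(fdm_similarity(p, disjoint, "KLD"), 0)
  big <- as_fdm(matrix(runif(9), 3))
  expect_error(fdm_similarity(p, big), "different grids")
})
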