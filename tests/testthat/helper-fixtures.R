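# Shared fixtures: all test data are generated in code.

test_geometry <- function() screen_geometry()

# A recording following a fixed path, optionally with validity gaps.
make_rec <- function(x, y, valid = rep(TRUE, length(x)), rate_hz = 300,
                     subject = "s1", question = "q1", trial = 1L) {
  gaze_recording(t = (seq_along(x) - 1) / rate_hz, x = x, y = y,
                 valid = valid, rate_hz = rate_hz, subject_id = subject,
                 question_id = question, trial = trial)
}

random_rec <- function(n = 50, rate_hz = 300, subject = "s1",
                       question = "q1", trial = 1L) {
  make_rec(x = round(runif(n, 0, 1919), 4), y = round(runif(n, 0, 1079), 4),
           valid = runif(n) > 0.05, rate_hz = rate_hz, subject = subject,
           question = question, trial = trial)
}

# Bare trajectory image from a pixel matrix (for closed-form pixel tests).
as_traj_image <- function(px) {
  structure(list(pixels = px, size_px = nrow(px), provenance = "synthetic"),
            class = "trajectory_image")
}

# Bare density map from a weight matrix.
as_fdm <- function(w) {
  structure(list(weights = w / sum(w), grid_size = nrow(w),
                 smoothing_sigma = 0), class = "fixation_density_map")
}

# Zero-noise oculomotor profile hitting region centres exactly.
still_profile <- function(subject = "Sx") {
  structure(list(fix_shape = 4, fix_scale = 0.0625, sacc_slope = 2.2,
                 sacc_intercept = 21, drift_sd = 0, tremor_sd = 0,
                 landing_gain = 1, revisit = 0.3,
                 scan_bias = rep(1 / 8, 8), subject_id = subject),
            class = "oculomotor_profile")
}

# Small, fast Gabor bank for pipeline-level tests (kernels stay small).
small_bank <- function() build_bank(gabor_bank_config(n_scales = 6))

# Well-separated Gaussian class clouds for matcher tests.
toy_classes <- function(k = 3, n = 8, d = 3, sep = 10, seed = 1) {
  with_seed <- function(s, e) { set.seed(s); e }
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * sep
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n * d, sd = 1), n, d), 2, centers[i, ], "+")))
  list(X = X, y = rep(sprintf("C%d", seq_len(k)), each = n))
}
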