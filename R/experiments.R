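#' Feature dataset container
#'
#' Per-recording features of one extraction method plus subject/trial
#' labels. Three kinds are supported, matching how the methods score:
#' `"vector"` (a numeric matrix, one row per recording; matched through
#' LDA + one-against-one SVM), `"map"` (a list of fixation density maps;
#' matched by map similarity against per-subject templates) and `"hist"`
#' (a list of direction-histogram matrices; matched by GMM-UBM
#' log-likelihood ratio).
#'
#' @param kind `"vector"`, `"map"` or `"hist"`.
#' @param x the features (matrix or list, one element/row per recording).
#' @param subject,trial labels per recording.
#' @param method method name used in reports.
#' @return A `feature_dataset` object.
#' @export
feature_dataset <- function(kind = c("vector", "map", "hist"), x, subject,
                            trial, method = "features") {
  kind <- match.arg(kind)
  n <- if (kind == "vector") nrow(x) else length(x)
  stopifnot(length(subject) == n, length(trial) == n)
  structure(list(kind = kind, x = x, subject = as.character(subject),
                 trial = as.integer(trial), method = method),
            class = "feature_dataset")
}

rec_labels <- function(recordings) {
  list(subject = vapply(recordings, `[[`, "", "subject_id"),
       trial = vapply(recordings, `[[`, 0L, "trial"))
}

#' Gabor texture features for a set of recordings
#'
#' Renders each recording at `size_px` and extracts the 176-dim texture
#' descriptor (batched so the kernel FFTs are shared).
#'
#' @param recordings list of [gaze_recording()]s.
#' @param geometry a [screen_geometry()].
#' @param size_px trajectory-image side (pixET).
#' @param bank a [build_bank()] Gabor bank.
#' @param increment rendering intensity increment.
#' @return A `"vector"` [feature_dataset()].
#' @export
gwt_dataset <- function(recordings, geometry = screen_geometry(),
                        size_px = 128, bank = build_bank(),
                        increment = 0.25) {
  imgs <- lapply(recordings, render_trajectory, size_px = size_px,
                 geometry = geometry, increment = increment)
  lab <- rec_labels(recordings)
  feature_dataset("vector", extract_features(imgs, bank),
                  lab$subject, lab$trial, "gwt")
}

#' Gray-image control features for a set of recordings
#' @inheritParams gwt_dataset
#' @return A `"vector"` [feature_dataset()] with 2 columns.
#' @export
gi_dataset <- function(recordings, geometry = screen_geometry(),
                       size_px = 128, increment = 0.25) {
  X <- t(vapply(recordings, function(r)
    gi_features(render_trajectory(r, size_px, geometry, increment)),
    numeric(2)))
  lab <- rec_labels(recordings)
  feature_dataset("vector", X, lab$subject, lab$trial, "gi")
}

#' Fixation/saccade (CEM) features for a set of recordings
#'
#' I-VT segmentation followed by [cem_features()]; classified through the
#' same LDA + SVM pipeline as the texture features (a simplified variant
#' of the original weighted-comparison scheme, flagged as such).
#'
#' @inheritParams gwt_dataset
#' @param velocity_threshold_deg_s,min_fixation_s I-VT parameters.
#' @return A `"vector"` [feature_dataset()].
#' @export
cem_dataset <- function(recordings, geometry = screen_geometry(),
                        velocity_threshold_deg_s = 30,
                        min_fixation_s = 0.06) {
  X <- t(vapply(recordings, function(r) {
    ev <- ivt_segment(r, velocity_threshold_deg_s, geometry, min_fixation_s)
    cem_features(ev$fixations, ev$saccades)
  }, numeric(11)))
  lab <- rec_labels(recordings)
  feature_dataset("vector", X, lab$subject, lab$trial, "cem (simplified)")
}

#' Fixation density maps for a set of recordings
#' @inheritParams cem_dataset
#' @param grid_size,smoothing_sigma map resolution and smoothing (cells).
#' @return A `"map"` [feature_dataset()].
#' @export
fdm_dataset <- function(recordings, geometry = screen_geometry(),
                        grid_size = 64, smoothing_sigma = 1,
                        velocity_threshold_deg_s = 30,
                        min_fixation_s = 0.06) {
  maps <- lapply(recordings, function(r) {
    ev <- ivt_segment(r, velocity_threshold_deg_s, geometry, min_fixation_s)
    fdm_build(ev$fixations, grid_size, smoothing_sigma, geometry)
  })
  lab <- rec_labels(recordings)
  feature_dataset("map", maps, lab$subject, lab$trial, "fdm")
}

#' Local-velocity-direction histograms for a set of recordings
#'
#' The window length defaults to one second of samples with a tenth-second
#' hop, capped at each recording's length.
#'
#' @inheritParams gwt_dataset
#' @param cfg an [lvd_config()]; `NULL` derives the window from the rate.
#' @return A `"hist"` [feature_dataset()].
#' @export
lvd_dataset <- function(recordings, cfg = NULL) {
  hists <- lapply(recordings, function(r) {
    c0 <- if (is.null(cfg)) {
      lvd_config(window_len_samples = max(2, round(r$rate_hz)),
                 window_hop = max(1, round(r$rate_hz / 10)))
    } else cfg
    n_ok <- n_valid_samples(r)
    if (c0$window_len_samples > n_ok)
      c0$window_len_samples <- as.integer(n_ok)
    suppressWarnings(lvd_histograms(r, c0))
  })
  lab <- rec_labels(recordings)
  feature_dataset("hist", hists, lab$subject, lab$trial, "lvd")
}

#' Plan probe membership for one train/test partition
#'
#' Splits recordings into training and testing pools — `"ST"` (short
#' term): a seeded 70/30 split of trial-1 recordings per subject;
#' `"LT"` (long term): all of trial 1 trains, all of trial 2 tests — and
#' samples the member recordings of every training and test probe
#' (`NoET` members each, without replacement within a probe). The same
#' plan can be applied to several feature datasets so their score
#' matrices stay probe-aligned for fusion.
#'
#' @param subject,trial per-recording labels.
#' @param NoET probe size.
#' @param split `"ST"` or `"LT"`.
#' @param n_train_probes,n_test_probes probes per subject.
#' @param train_frac training fraction for the ST split.
#' @param seed integer seed.
#' @return A `probe_plan` with member-index lists and probe labels.
#' @export
probe_plan <- function(subject, trial, NoET, split = c("ST", "LT"),
                       n_train_probes = 20, n_test_probes = 6,
                       train_frac = 0.7, seed = 1L) {
  split <- match.arg(split)
  subject <- as.character(subject)
  if (split == "LT" && !any(trial == 2))
    stop("LT split requested but the dataset has no trial-2 recordings")
  with_seed(seed, {
    subjects <- sort(unique(subject))
    train_idx <- list(); test_idx <- list()
    for (s in subjects) {
      if (split == "ST") {
        pool <- which(subject == s & trial == 1)
        n_tr <- round(train_frac * length(pool))
        tr <- sample(pool, n_tr)
        train_idx[[s]] <- tr
        test_idx[[s]] <- setdiff(pool, tr)
      } else {
        train_idx[[s]] <- which(subject == s & trial == 1)
        test_idx[[s]] <- which(subject == s & trial == 2)
      }
      if (length(train_idx[[s]]) < NoET || length(test_idx[[s]]) < NoET)
        stop(sprintf("subject %s has fewer than NoET=%d recordings in a pool",
                     s, NoET))
    }
    draw <- function(pool, n_probes)
      lapply(seq_len(n_probes), function(i) sample(pool, NoET))
    train_members <- list(); test_members <- list()
    train_lab <- character(0); test_lab <- character(0)
    for (s in subjects) {
      train_members <- c(train_members, draw(train_idx[[s]], n_train_probes))
      train_lab <- c(train_lab, rep(s, n_train_probes))
      test_members <- c(test_members, draw(test_idx[[s]], n_test_probes))
      test_lab <- c(test_lab, rep(s, n_test_probes))
    }
    structure(list(split = split, NoET = as.integer(NoET),
                   subjects = subjects,
                   train_pool = train_idx, test_pool = test_idx,
                   train_members = train_members, train_label = train_lab,
                   test_members = test_members, test_label = test_lab,
                   seed = seed),
              class = "probe_plan")
  })
}

probes_from_plan <- function(ds, members, labels) {
  vecs <- t(vapply(members, function(idx)
    colMeans(ds$x[idx, , drop = FALSE]), numeric(ncol(ds$x))))
  structure(list(vectors = vecs, subject = labels,
                 NoET = length(members[[1]]), member_ids = members),
            class = "probe_set")
}

mean_map <- function(maps) {
  w <- Reduce(`+`, lapply(maps, `[[`, "weights")) / length(maps)
  structure(list(weights = w / sum(w), grid_size = maps[[1]]$grid_size,
                 smoothing_sigma = maps[[1]]$smoothing_sigma),
            class = "fixation_density_map")
}

#' Score one feature dataset under a probe plan
#'
#' Runs the method-appropriate matcher and returns probe-aligned score
#' matrices for the test probes and (for normalization) the training
#' probes. Vector datasets go through standardize + LDA + one-against-one
#' SVM; map datasets are scored by [fdm_similarity()] against per-subject
#' mean training maps; histogram datasets by [lvd_score()] with a UBM
#' trained on all training windows and MAP-adapted subject models.
#'
#' @param ds a [feature_dataset()].
#' @param plan a [probe_plan()] built from the same recordings.
#' @param matcher_score `"margin"` or `"votes"` (vector kind).
#' @param kernel,cost SVM options (vector kind).
#' @param fdm_metric map-similarity metric (map kind).
#' @param lvd_cfg an [lvd_config()] for UBM fitting (hist kind).
#' @return List with [score_matrix()]s `test` and `train`.
#' @export
score_dataset <- function(ds, plan, matcher_score = "margin",
                          kernel = "linear", cost = 1, fdm_metric = "SIM",
                          lvd_cfg = lvd_config()) {
  stopifnot(inherits(ds, "feature_dataset"), inherits(plan, "probe_plan"))
  if (ds$kind == "vector") {
    tr <- probes_from_plan(ds, plan$train_members, plan$train_label)
    te <- probes_from_plan(ds, plan$test_members, plan$test_label)
    red <- fit_reduction(tr$vectors, tr$subject)
    mat <- fit_matchers(tr, red, kernel = kernel, cost = cost)
    list(test = score_probes(mat, te, matcher_score),
         train = score_probes(mat, tr, matcher_score),
         test_ident = score_probes(mat, te, "ident"))
  } else if (ds$kind == "map") {
    templates <- lapply(plan$subjects, function(s)
      mean_map(ds$x[plan$train_pool[[s]]]))
    names(templates) <- plan$subjects
    score_maps <- function(members, labels) {
      S <- matrix(0, length(members), length(plan$subjects),
                  dimnames = list(NULL, plan$subjects))
      for (i in seq_along(members)) {
        pm <- mean_map(ds$x[members[[i]]])
        S[i, ] <- vapply(plan$subjects, function(s)
          fdm_similarity(pm, templates[[s]], fdm_metric), numeric(1))
      }
      score_matrix(S, labels)
    }
    list(test = score_maps(plan$test_members, plan$test_label),
         train = score_maps(plan$train_members, plan$train_label))
  } else {
    train_rows <- do.call(rbind, ds$x[unlist(plan$train_pool)])
    ubm <- train_ubm(train_rows, lvd_cfg, seed = plan$seed)
    models <- lapply(plan$subjects, function(s)
      map_adapt(ubm, do.call(rbind, ds$x[plan$train_pool[[s]]]),
                lvd_cfg$relevance_r))
    names(models) <- plan$subjects
    score_hists <- function(members, labels) {
      S <- matrix(0, length(members), length(plan$subjects),
                  dimnames = list(NULL, plan$subjects))
      for (i in seq_along(members)) {
        H <- do.call(rbind, ds$x[members[[i]]])
        S[i, ] <- vapply(plan$subjects, function(s)
          lvd_score(models[[s]], ubm, H), numeric(1))
      }
      score_matrix(S, labels)
    }
    list(test = score_hists(plan$test_members, plan$test_label),
         train = score_hists(plan$train_members, plan$train_label))
  }
}

sm_metrics <- function(sms) {
  if (inherits(sms, "score_matrix")) sms <- list(test = sms)
  ident <- if (!is.null(sms$test_ident)) sms$test_ident else sms$test
  c(eer = compute_det(sms$test)$eer, rank1 = compute_cmc(ident)$ir[1])
}

#' Evaluate a method over random partitions
#'
#' For each of `n_partitions` seeded partitions, plans probes, scores the
#' dataset and computes EER and Rank-1 IR; headline numbers are the means
#' over partitions.
#'
#' @param ds a [feature_dataset()].
#' @param NoET probe size.
#' @param split `"ST"` or `"LT"`.
#' @param n_partitions number of random partitions averaged (default 10).
#' @param seed base seed (partition i uses a derived sub-seed).
#' @param ... matcher options passed to [score_dataset()].
#' @inheritParams probe_plan
#' @return List with mean `eer`, `rank1`, and the per-partition table.
#' @export
evaluate_biometric <- function(ds, NoET, split = "ST", n_partitions = 10,
                               n_train_probes = 20, n_test_probes = 6,
                               train_frac = 0.7, seed = 1L, ...) {
  rows <- lapply(seq_len(n_partitions), function(i) {
    plan <- probe_plan(ds$subject, ds$trial, NoET, split,
                       n_train_probes, n_test_probes, train_frac,
                       seed = derive_seed(seed, paste0("part", i)))
    m <- sm_metrics(score_dataset(ds, plan, ...))
    data.frame(partition = i, eer = m[["eer"]], rank1 = m[["rank1"]])
  })
  tab <- do.call(rbind, rows)
  list(eer = mean(tab$eer), rank1 = mean(tab$rank1), partitions = tab)
}

#' Sweep probe size and report EER / Rank-1 per NoET
#'
#' @inheritParams evaluate_biometric
#' @param NoET_grid probe sizes to evaluate (default 2, 4, 8, 16).
#' @return Data frame with one row per NoET: mean `eer` and `rank1`
#'   (fractions in `[0, 1]`) over partitions.
#' @export
run_noet_sweep <- function(ds, NoET_grid = c(2, 4, 8, 16), split = "ST",
                           n_partitions = 10, seed = 1L, ...) {
  rows <- lapply(NoET_grid, function(noet) {
    r <- evaluate_biometric(ds, noet, split, n_partitions, seed = seed, ...)
    data.frame(NoET = noet, eer = r$eer, rank1 = r$rank1)
  })
  do.call(rbind, rows)
}

#' Template-aging experiment: short-term vs long-term results
#'
#' For every method and probe size, evaluates the short-term split (70/30
#' within trial 1) and the long-term split (trial 1 trains, trial 2
#' tests), averaging over `n_partitions` random partitions, and reports
#' the difference `DIF = LT - ST` for both EER and Rank-1 IR.
#'
#' @param datasets named list of [feature_dataset()]s built from a
#'   two-trial recording set.
#' @inheritParams run_noet_sweep
#' @return Data frame with columns `method`, `NoET`, `eer_st`, `eer_lt`,
#'   `eer_dif`, `rank1_st`, `rank1_lt`, `rank1_dif` (fractions).
#' @export
run_aging_experiment <- function(datasets, NoET_grid = c(2, 4, 8, 16),
                                 n_partitions = 10, seed = 1L, ...) {
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  rows <- list()
  for (m in names(datasets)) {
    ds <- datasets[[m]]
    if (!any(ds$trial == 2))
      stop("aging experiment needs trial-2 recordings in dataset: ", m)
    for (noet in NoET_grid) {
      st <- evaluate_biometric(ds, noet, "ST", n_partitions, seed = seed, ...)
      lt <- evaluate_biometric(ds, noet, "LT", n_partitions, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, NoET = noet,
        eer_st = st$eer, eer_lt = lt$eer, eer_dif = lt$eer - st$eer,
        rank1_st = st$rank1, rank1_lt = lt$rank1,
        rank1_dif = lt$rank1 - st$rank1)
    }
  }
  do.call(rbind, rows)
}

#' Temporal and spatial robustness experiment
#'
#' Re-runs feature extraction and evaluation on degraded copies of the
#' recordings: temporal conditions decimate to each rate in
#' `temporal_grid` (which must divide the source rate); spatial conditions
#' add Gaussian position noise of each magnitude in `spatial_grid_deg`.
#' The identity condition (source rate, 0 deg) reproduces the undegraded
#' result for the same seed.
#'
#' @param recordings list of [gaze_recording()]s at the source rate.
#' @param extractors named list of functions `recordings -> feature_dataset`.
#' @param geometry a [screen_geometry()].
#' @param temporal_grid sampling rates (Hz) to test.
#' @param spatial_grid_deg noise magnitudes (degrees) to test.
#' @param NoET probe size used throughout.
#' @inheritParams run_noet_sweep
#' @return Data frame with `condition`, `value`, `method`, `eer`, `rank1`;
#'   attribute `provenance` records the seed and grids.
#' @export
run_robustness_experiment <- function(recordings, extractors,
                                      geometry = screen_geometry(),
                                      temporal_grid = c(300, 150, 75, 30),
                                      spatial_grid_deg = c(0, 1, 2, 3),
                                      NoET = 8, split = "ST",
                                      n_partitions = 3, seed = 1L, ...) {
  src_rate <- recordings[[1]]$rate_hz
  bad <- temporal_grid[abs(src_rate / temporal_grid -
                             round(src_rate / temporal_grid)) > 1e-9]
  if (length(bad) > 0)
    stop("temporal grid rate(s) not integer divisors of the source rate: ",
         paste(bad, collapse = ", "))
  conditions <- rbind(
    data.frame(condition = "temporal", value = temporal_grid),
    data.frame(condition = "spatial", value = spatial_grid_deg))
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions$condition[ci]; val <- conditions$value[ci]
    recs <- if (cond == "temporal") {
      lapply(recordings, downsample_gaze, target_hz = val)
    } else if (val == 0) recordings else {
      lapply(seq_along(recordings), function(i)
        add_spatial_noise(recordings[[i]], val, geometry,
                          seed = derive_seed(seed, paste0("noise", val, "_", i))))
    }
    for (m in names(extractors)) {
      ds <- extractors[[m]](recs)
      r <- evaluate_biometric(ds, NoET, split, n_partitions, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, value = val, method = m, eer = r$eer,
        rank1 = r$rank1)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- list(seed = seed, source_rate_hz = src_rate,
                                  temporal_grid = temporal_grid,
                                  spatial_grid_deg = spatial_grid_deg,
                                  NoET = NoET, split = split,
                                  n_partitions = n_partitions)
  out
}

#' Score-level fusion experiment
#'
#' For each partition, all methods are scored under one shared probe plan
#' (so their score matrices are probe-aligned), each matrix is
#' tanh-normalized with location/scale estimated from that method's
#' training-phase score pool (avoiding test-set leakage), and the
#' normalized matrices are fused by the sum rule.
#'
#' @param datasets named list of [feature_dataset()]s over the same
#'   recordings.
#' @inheritParams evaluate_biometric
#' @return List with mean `eer` and `rank1` of the fused matcher, the
#'   per-partition table, and per-method means for comparison.
#' @export
run_fusion_experiment <- function(datasets, NoET, split = "ST",
                                  n_partitions = 10, n_train_probes = 20,
                                  n_test_probes = 6, train_frac = 0.7,
                                  seed = 1L, ...) {
  stopifnot(length(datasets) >= 2, !is.null(names(datasets)))
  ref <- datasets[[1]]
  fused_rows <- list(); per_method <- list()
  for (i in seq_len(n_partitions)) {
    plan <- probe_plan(ref$subject, ref$trial, NoET, split,
                       n_train_probes, n_test_probes, train_frac,
                       seed = derive_seed(seed, paste0("part", i)))
    normed <- list()
    for (m in names(datasets)) {
      sms <- score_dataset(datasets[[m]], plan, ...)
      mu <- mean(sms$train$scores)
      sigma <- sd(as.numeric(sms$train$scores))
      normed[[m]] <- normalize_scores(sms$test, mu, sigma)
      pm <- sm_metrics(sms)
      per_method[[length(per_method) + 1L]] <- data.frame(
        partition = i, method = m, eer = pm[["eer"]], rank1 = pm[["rank1"]])
    }
    fm <- sm_metrics(fuse_sum(normed))
    fused_rows[[i]] <- data.frame(partition = i, eer = fm[["eer"]],
                                  rank1 = fm[["rank1"]])
  }
  ftab <- do.call(rbind, fused_rows)
  mtab <- do.call(rbind, per_method)
  list(eer = mean(ftab$eer), rank1 = mean(ftab$rank1), partitions = ftab,
       per_method = stats::aggregate(cbind(eer, rank1) ~ method, mtab, mean))
}
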