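# Pipeline-level tests use a reduced 6-scale Gabor bank and 64 px images
# so kernels stay small and each run takes seconds, not minutes.

sim_small <- function(n_subjects = 5, questions = 12, trials = 1, seed = 21,
                      aging_sd = 0) {
  simulate_session(session_plan(n_subjects, trials, 1, questions,
                                seed = seed),
                   test_geometry(), separation = 1, aging_sd = aging_sd)
}

test_that("probe plans honor split proportions and membership rules", {
  sess <- sim_small(4, 20, trials = 2)
  lab <- gazetex:::rec_labels(sess$recordings)
  plan <- probe_plan(lab$subject, lab$trial, NoET = 4, split = "ST",
                     seed = 3)
  for (s in plan$subjects) {
    expect_equal(length(plan$train_pool[[s]]), 14)  # 70% of 20, exactly
    expect_equal(length(plan$test_pool[[s]]), 6)
    expect_length(intersect(plan$train_pool[[s]], plan$test_pool[[s]]), 0)
  }
  for (mm in plan$train_members) expect_length(unique(mm), 4)
  lt <- probe_plan(lab$subject, lab$trial, 4, "LT", seed = 3)
  expect_true(all(lab$trial[unlist(lt$train_pool)] == 1))
  expect_true(all(lab$trial[unlist(lt$test_pool)] == 2))
  expect_error(probe_plan(lab$subject, rep(1L, length(lab$subject)), 4, "LT"),
               "no trial-2")
  expect_error(probe_plan(lab$subject, lab$trial, NoET = 7, split = "ST"),
               "fewer than NoET")
})

test_that("every feature dataset kind can be scored end to end", {
  geom <- test_geometry()
  sess <- sim_small(4, 14)
  recs <- sess$recordings
  lab <- gazetex:::rec_labels(recs)
  plan <- probe_plan(lab$subject, lab$trial, NoET = 2, split = "ST",
                     n_train_probes = 8, n_test_probes = 3, seed = 5)
  datasets <- list(
    gwt = gwt_dataset(recs, geom, size_px = 64, bank = small_bank()),
    gi = gi_dataset(recs, geom, size_px = 64),
    cem = cem_dataset(recs, geom),
    fdm = fdm_dataset(recs, geom),
    lvd = lvd_dataset(recs))
  for (m in names(datasets)) {
    sms <- score_dataset(datasets[[m]], plan,
                         lvd_cfg = lvd_config(n_gaussians = 4))
    expect_equal(dim(sms$test$scores), c(12, 4))
    expect_equal(dim(sms$train$scores), c(32, 4))
    met <- gazetex:::sm_metrics(sms)
    expect_true(met[["eer"]] >= 0 && met[["eer"]] <= 1)
    expect_true(met[["rank1"]] >= 0 && met[["rank1"]] <= 1)
  }
})

test_that("the NoET sweep and ST/LT aging driver produce sane tables", {
  geom <- test_geometry()
  sess <- sim_small(6, 24, trials = 2, seed = 31, aging_sd = 0)
  ds <- gwt_dataset(sess$recordings, geom, size_px = 64,
                    bank = small_bank())
  tab <- run_noet_sweep(ds, NoET_grid = c(2, 4), split = "ST",
                        n_partitions = 2, seed = 9)
  expect_equal(tab$NoET, c(2, 4))
  expect_true(all(tab$eer >= 0 & tab$eer <= 1))

  aging <- run_aging_experiment(list(gwt = ds), NoET_grid = 4,
                                n_partitions = 4, seed = 9)
  expect_named(aging, c("method", "NoET", "eer_st", "eer_lt", "eer_dif",
                        "rank1_st", "rank1_lt", "rank1_dif"))
  expect_equal(aging$eer_dif, aging$eer_lt - aging$eer_st)
  # with no aging injected, long-term degradation is small
  expect_lt(abs(aging$eer_dif), 0.10)
})

test_that("robustness driver reproduces the identity condition exactly", {
  geom <- test_geometry()
  sess <- sim_small(4, 12, seed = 41)
  extractors <- list(gwt = function(r)
    gwt_dataset(r, geom, size_px = 64, bank = small_bank()))
  run1 <- run_robustness_experiment(sess$recordings, extractors, geom,
                                    temporal_grid = c(300, 150),
                                    spatial_grid_deg = c(0, 1), NoET = 2,
                                    n_partitions = 2, seed = 6)
  run2 <- run_robustness_experiment(sess$recordings, extractors, geom,
                                    temporal_grid = c(300, 150),
                                    spatial_grid_deg = c(0, 1), NoET = 2,
                                    n_partitions = 2, seed = 6)
  expect_identical(run1, run2)
  id_t <- run1[run1$condition == "temporal" & run1$value == 300, ]
  id_s <- run1[run1$condition == "spatial" & run1$value == 0, ]
  # 300 Hz decimation and 0-degree noise are both the identity
  expect_equal(id_t$eer, id_s$eer, tolerance = 1e-12)
  expect_equal(id_t$rank1, id_s$rank1, tolerance = 1e-12)
  expect_named(attr(run1, "provenance"),
               c("seed", "source_rate_hz", "temporal_grid",
                 "spatial_grid_deg", "NoET", "split", "n_partitions"))
  expect_error(run_robustness_experiment(sess$recordings, extractors, geom,
                                         temporal_grid = c(140)),
               "not integer divisors")
})

test_that("score fusion of aligned matchers runs and reports per-method means", {
  geom <- test_geometry()
  sess <- sim_small(4, 14, seed = 51)
  datasets <- list(
    gwt = gwt_dataset(sess$recordings, geom, size_px = 64,
                      bank = small_bank()),
    cem = cem_dataset(sess$recordings, geom))
  fus <- run_fusion_experiment(datasets, NoET = 2, n_partitions = 2,
                               n_train_probes = 8, n_test_probes = 3,
                               seed = 4)
  expect_true(fus$eer >= 0 && fus$eer <= 1)
  expect_equal(sort(fus$per_method$method), c("cem", "gwt"))
  best <- min(fus$per_method$eer)
  expect_lt(fus$eer, best + 0.15)   # fusion should not be far worse
})

test_that("the pipeline runner is reproducible and writes its outputs", {
  cfg <- default_config(seed = 99)
  cfg$synth$n_subjects <- 4
  cfg$synth$questions_per_test <- 12
  cfg$render$size_px <- 64
  cfg$eval$NoET_grid <- c(2, 4)
  cfg$eval$n_partitions <- 2
  cfg$eval$n_train_probes <- 8
  cfg$eval$n_test_probes <- 3
  out1 <- withr::local_tempdir()
  res1 <- run_pipeline(cfg, out_dir = out1)
  res2 <- run_pipeline(cfg)
  expect_identical(res1$results, res2$results)
  expect_setequal(unique(res1$results$method), c("gwt", "gi"))
  expect_true(file.exists(file.path(out1, "results.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "config.yaml")))
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$config_hash, config_hash(cfg))
})

test_that("config files round-trip and hashes track content", {
  cfg <- default_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  h1 <- config_hash(cfg)
  expect_identical(h1, config_hash(cfg))
  cfg2 <- cfg; cfg2$render$size_px <- 256
  expect_false(identical(h1, config_hash(cfg2)))
})
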