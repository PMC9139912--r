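# A minimal configuration that exercises the whole pipeline in seconds.
smoke_config <- function(...) {
  utils::modifyList(list(
    cohort = list(n_per_class = 4, class_labels = c("CN", "AD"),
                  volume_shape = c(8, 8, 6, 10), fingerprint_sd = 2,
                  class_effect_sd = 0, noise_sd = 1, smoothness = 1),
    slices = list(percentile = 80, per_subject = 6),
    prep = list(target_size = 16),
    split = list(n_train_subjects = 3, n_test_subjects = 1, train_fraction = 0.7),
    model = list(architecture = "tinycnn", batch_size = 16,
                 learning_rate = 1e-3, epochs = 1),
    problems = list(c("CN", "AD")),
    seed = 5L
  ), list(...))
}

test_that("untrained (epochs = 0) smoke run emits a complete flagged table", {
  out <- withr::local_tempdir()
  ex <- run_experiment(smoke_config(model = list(architecture = "tinycnn",
                                                 batch_size = 16,
                                                 learning_rate = 1e-3,
                                                 epochs = 0)),
                       outdir = out)
  expect_equal(nrow(ex$results), 2)            # one problem x two modes
  expect_true(all(ex$results$untrained))
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in% names(ex$results)))
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "leakage_report.json")))
  expect_true(file.exists(file.path(out, "results.md")))
  expect_true(file.exists(file.path(out, "slice_manifest.csv")))
  # the audits embedded in the report match the split modes
  expect_false(ex$report$subject_audit$leaky)
  expect_true(ex$report$slice_audit$leaky)
})

test_that("experiments are reproducible given the configuration", {
  e1 <- run_experiment(smoke_config(), outdir = withr::local_tempdir())
  e2 <- run_experiment(smoke_config(), outdir = withr::local_tempdir())
  e1$outdir <- e2$outdir <- NULL
  expect_equal(e1$results, e2$results)
  expect_equal(e1$report$gaps, e2$report$gaps)
})

test_that("slice counts through the pipeline follow the configured arithmetic", {
  ex <- run_experiment(smoke_config(), outdir = withr::local_tempdir())
  # 4 + 4 subjects x 6 slices each; subject mode: 3/1 per class
  expect_equal(ex$results$n_test[ex$results$holdout_mode == "subject"], 2 * 6)
  # slice mode: per class 24 slices -> floor(0.7 * 24) = 16 train, 8 test
  expect_equal(ex$results$n_test[ex$results$holdout_mode == "slice"], 16)
})

test_that("double-null cohort (no fingerprint, no class effect) sits at chance", {
  cfg <- smoke_config(cohort = list(n_per_class = 4,
                                    class_labels = c("CN", "AD"),
                                    volume_shape = c(8, 8, 6, 10),
                                    fingerprint_sd = 0, class_effect_sd = 0,
                                    noise_sd = 1, smoothness = 1),
                      slices = list(percentile = 80, per_subject = 10),
                      seed = 21L)
  ex <- run_experiment(cfg, outdir = withr::local_tempdir())
  for (m in c("subject", "slice")) {
    acc <- ex$results$accuracy[ex$results$holdout_mode == m]
    n <- ex$results$n_test[ex$results$holdout_mode == m]
    ci_half <- 100 * 1.96 * sqrt(0.25 / n)
    expect_lt(abs(acc - 50), ci_half + 1e-9)
  }
})

test_that("strong class effect without fingerprints is learnable in both modes", {
  cfg <- smoke_config(cohort = list(n_per_class = 4,
                                    class_labels = c("CN", "AD"),
                                    volume_shape = c(8, 8, 6, 10),
                                    fingerprint_sd = 0, class_effect_sd = 6,
                                    noise_sd = 0.5, smoothness = 2),
                      slices = list(percentile = 80, per_subject = 10),
                      model = list(architecture = "tinycnn", batch_size = 8,
                                   learning_rate = 2e-3, epochs = 4),
                      seed = 31L)
  ex <- run_experiment(cfg, outdir = withr::local_tempdir())
  expect_true(all(ex$results$accuracy >= 90))
})

test_that("the leakage gap grows with fingerprint strength (monotone trend)", {
  light <- function(fp, sd) list(
    cohort = list(n_per_class = 6, class_labels = c("CN", "AD"),
                  volume_shape = c(16, 16, 10, 12), fingerprint_sd = fp,
                  class_effect_sd = 0, noise_sd = 1, smoothness = 2),
    slices = list(percentile = 90, per_subject = 12),
    prep = list(target_size = 16),
    split = list(n_train_subjects = 4, n_test_subjects = 2, train_fraction = 0.7),
    model = list(architecture = "tinycnn", batch_size = 16,
                 learning_rate = 1e-3, epochs = 3),
    seed = sd)
  levels <- c(0, 1.5, 3)
  mean_gap <- vapply(levels, function(fp) {
    mean(vapply(1:5, function(sd) {
      ex <- run_experiment(light(fp, 400L + sd), outdir = withr::local_tempdir())
      with(ex$results, accuracy[holdout_mode == "slice"] -
                       accuracy[holdout_mode == "subject"])
    }, numeric(1)))
  }, numeric(1))
  # nondecreasing in expectation (small sampling slack), clearly positive trend
  expect_true(all(diff(mean_gap) > -5))
  expect_gt(mean_gap[3] - mean_gap[1], 10)
  expect_gt(stats::coef(stats::lm(mean_gap ~ levels))[2], 0)
})

test_that("YAML configuration round-trips through read_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 99, cohort = list(n_per_class = 3),
                        problems = list(c("CN", "AD"))), path)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$cohort$n_per_class, 3)
  expect_equal(cfg$cohort$noise_sd, 1)          # default preserved
  expect_equal(cfg$problems, list(c("CN", "AD")))
})

test_that("stage failures carry the problem and mode in the error", {
  cfg <- smoke_config(split = list(n_train_subjects = 5, n_test_subjects = 2,
                                   train_fraction = 0.7))
  expect_error(run_experiment(cfg, outdir = withr::local_tempdir()),
               class = "sliceleak_stage_failure")
  expect_error(run_experiment(cfg, outdir = withr::local_tempdir()),
               regexp = "CN vs. AD.*subject")
})
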