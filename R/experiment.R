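#' Default desk-scale experiment configuration
#'
#' The shipped defaults run the full leakage demonstration on a CPU in
#' minutes: two diagnostic groups of 10 subjects, volumes (24, 28, 22, 20),
#' the 90th-percentile mean-signal filter (keeping 44 of 440 slices per
#' subject), 40 slices sampled per subject, a 7/3 subject split versus a
#' 70/30 slice split, and a three-epoch tinycnn. The subject fingerprint is
#' strong relative to noise and the class effect is zero, so any
#' above-chance test performance can only come from identity leakage.
#'
#' @return nested configuration list (see sections: cohort, slices, prep,
#'   split, model, problems, positive_class, seed).
#' @export
default_config <- function() {
  list(
    cohort = list(n_per_class = 10, class_labels = c("CN", "AD"),
                  volume_shape = c(24, 28, 22, 20),
                  fingerprint_sd = 3, class_effect_sd = 0, noise_sd = 1,
                  baseline = 100, scans_per_subject = 1, smoothness = 2),
    slices = list(percentile = 90, per_subject = 40),
    prep = list(target_size = 32),
    split = list(n_train_subjects = 7, n_test_subjects = 3,
                 train_fraction = 0.7),
    model = list(architecture = "tinycnn", dropout = 0.2, batch_size = 32,
                 learning_rate = 1e-3, epochs = 3),
    problems = list(c("CN", "AD")),
    modes = c("subject", "slice"),
    positive_class = "second",
    seed = 1L
  )
}

#' Read an experiment configuration from YAML
#'
#' Missing keys fall back to [default_config()] values.
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.null(user$problems))
    user$problems <- lapply(user$problems, unlist)
  utils::modifyList(default_config(), user)
}

subset_stack <- function(stack, classes) {
  keep <- stack$info$class_label %in% classes
  new_slice_stack(if (is.null(stack$pixels)) NULL else stack$pixels[keep],
                  stack$info[keep, , drop = FALSE], stack$provenance)
}

# cohort -> dedup -> per-subject slice/filter/sample -> one bound stack
build_slice_collection <- function(config, dir) {
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
  cohort <- generate_cohort(spec, file.path(dir, "cohort"))
  cohort <- select_earliest_scan(cohort)
  stacks <- lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    vol <- read_cohort_volume(row$path, row$subject_id, row$class_label,
                              row$scan_date)
    st <- extract_slices(vol)
    st <- filter_top_percentile(st, config$slices$percentile)
    sample_slices(st, n = config$slices$per_subject,
                  seed = derive_seed(config$seed, "sample", row$subject_id))
  })
  bind_stacks(stacks)
}

evaluate_problem_mode <- function(stack_p, problem, mode, config) {
  split_cfg <- config$split
  plan <- if (mode == "subject")
    split_by_subject(stack_p$info, split_cfg$n_train_subjects,
                     split_cfg$n_test_subjects, seed = config$seed)
  else
    split_by_slice(stack_p$info, split_cfg$train_fraction, seed = config$seed)
  sides <- materialize_split(plan, stack_p)
  positive <- if (identical(config$positive_class, "second")) problem[2]
              else config$positive_class
  tr <- prepare_slices(sides$train, positive, config$prep$target_size)
  te <- prepare_slices(sides$test, positive, config$prep$target_size)
  hp <- do.call(hyperparams, c(config$model,
                               list(input_size = config$prep$target_size,
                                    seed = derive_seed(config$seed, "train",
                                                       paste(problem, collapse = "-"),
                                                       mode))))
  model <- build_model(hp)
  model <- train_model(model, tr$x, tr$y, hp)
  pred <- stats::predict(model, te$x, allow_untrained = hp$epochs == 0)
  cm <- confusion(pred$label, te$y, positive_class = 1)
  rec <- metrics(cm, problem = problem, holdout_mode = mode)
  rec$untrained <- hp$epochs == 0
  rec$n_test <- nrow(te$info)
  list(record = rec, audit = audit_leakage(plan), plan = plan,
       model = model, test_info = te$info, test_pred = pred)
}

#' Run the full two-hold-out leakage experiment
#'
#' For each binary problem and each hold-out mode: generate (or reuse) the
#' synthetic cohort, deduplicate to earliest scans, slice along depth and
#' time, filter by the mean-signal percentile, sample per subject, split,
#' train the classifier, and score the held-out slices. Emits a two-panel
#' results table (one row per problem and mode) plus per-mode medians and a
#' leakage report, all deterministic given the configuration.
#'
#' @param config configuration list as from [default_config()] or
#'   [read_config()]; partial lists are completed with defaults.
#' @param outdir output directory for the cohort, results CSV, leakage
#'   report JSON and Markdown summary; a temporary directory by default.
#' @return list with `results` (data.frame), `medians` (per mode),
#'   `report` (a `leakage_report`), `config`, `outdir`.
#' @export
run_experiment <- function(config = list(), outdir = tempfile("sliceleak-")) {
  config <- utils::modifyList(default_config(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  collection <- build_slice_collection(config, outdir)
  write_slice_manifest(collection, file.path(outdir, "slice_manifest.csv"))

  rows <- list()
  audits <- list(subject = NULL, slice = NULL)
  for (problem in config$problems) {
    stack_p <- subset_stack(collection, problem)
    for (mode in config$modes) {
      ev <- tryCatch(
        evaluate_problem_mode(stack_p, problem, mode, config),
        error = function(e) stop_labeled(
          "stage_failure", "problem %s, mode %s: %s",
          paste(problem, collapse = " vs. "), mode, conditionMessage(e)))
      rows[[length(rows) + 1L]] <- ev$record
      audits[[mode]] <- ev$audit
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL

  medians <- lapply(stats::setNames(nm = config$modes), function(m)
    median_metrics(results[results$holdout_mode == m, , drop = FALSE],
                   na.rm = TRUE))
  report <- if (all(c("subject", "slice") %in% config$modes))
    leakage_gap(results[results$holdout_mode == "subject", , drop = FALSE],
                results[results$holdout_mode == "slice", , drop = FALSE],
                subject_audit = audits$subject, slice_audit = audits$slice)
  else NULL

  utils::write.csv(results, file.path(outdir, "results.csv"), row.names = FALSE)
  if (!is.null(report))
    write_leakage_report(report, file.path(outdir, "leakage_report.json"))
  write_results_markdown(results, medians,
                         file.path(outdir, "results.md"))
  list(results = results, medians = medians, report = report,
       config = config, outdir = outdir)
}

#' Write the two-panel Markdown summary table
#'
#' One row per binary problem, the two hold-out modes side by side, plus a
#' median row — the shape in which such results are conventionally reported.
#' @param results results data.frame from [run_experiment()].
#' @param medians per-mode median list.
#' @param path output path.
#' @export
write_results_markdown <- function(results, medians, path) {
  fmt <- function(x) ifelse(is.na(x), "--", sprintf("%.2f", x))
  modes <- intersect(c("subject", "slice"), unique(results$holdout_mode))
  lines <- c(
    paste0("| | ", paste(sprintf("%s hold-out | | |", modes), collapse = "")),
    paste0("| Binary classes | ",
           paste(rep("Accuracy (%) | Sensitivity (%) | Specificity (%) |",
                     length(modes)), collapse = " ")),
    paste0(paste(rep("|---", 1 + 3 * length(modes)), collapse = ""), "|"))
  probs <- unique(results$problem)
  body <- vapply(probs, function(pb) {
    cells <- unlist(lapply(modes, function(m) {
      r <- results[results$problem == pb & results$holdout_mode == m, ]
      c(fmt(r$accuracy), fmt(r$sensitivity), fmt(r$specificity))
    }))
    paste0("| ", pb, " | ", paste(cells, collapse = " | "), " |")
  }, character(1))
  med <- unlist(lapply(modes, function(m)
    c(fmt(medians[[m]]$accuracy), fmt(medians[[m]]$sensitivity),
      fmt(medians[[m]]$specificity))))
  writeLines(c(lines, body,
               paste0("| **Median** | ", paste(med, collapse = " | "), " |")),
             path)
  invisible(path)
}
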