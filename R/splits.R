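#' @section Split plans:
#' A split plan records which slices train and which test, identified by
#' (subject_id, depth_index, time_index), together with the split mode and
#' seed. Two modes are contrasted:
#' \itemize{
#'   \item \strong{subject} — whole subjects are assigned to one side
#'     ("brain hold-out"); the statistically valid strategy.
#'   \item \strong{slice} — individual slices are assigned irrespective of
#'     subject ("slice hold-out"); the leaky strategy, since the model can
#'     recognize training subjects' anatomy in the test set.
#' }
#' Both modes are stratified per class, each class split independently with
#' a sub-seed hashed from (seed, class), so adding a class never perturbs
#' another class's split.
#' @name split-plans
NULL

slice_keys <- function(info)
  paste(info$subject_id, info$depth_index, info$time_index, sep = "|")

new_split_plan <- function(mode, seed, train, test) {
  rownames(train) <- NULL; rownames(test) <- NULL
  if (length(intersect(slice_keys(train), slice_keys(test))) > 0)
    stop_labeled("overlapping_plan", "train and test share slice identifiers")
  structure(list(mode = mode, seed = as.integer(seed),
                 train = train, test = test),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> mode=%s seed=%d: %d train / %d test slices (%d / %d subjects)\n",
              x$mode, x$seed, nrow(x$train), nrow(x$test),
              length(unique(x$train$subject_id)), length(unique(x$test$subject_id))))
  invisible(x)
}

#' Subject-level hold-out split (the valid strategy)
#'
#' Per class, subjects are partitioned uniformly at random into
#' `n_train_subjects` train and `n_test_subjects` test; every slice follows
#' its subject. At the full-scale design (25 subjects per class, 700 slices
#' each, 17/8 split) this yields 11,900 train and 5,600 test slices per
#' diagnosis. Deterministic given `seed`.
#'
#' @param info slice table (the `info` of a bound `slice_stack`, or any
#'   data.frame with subject_id, class_label, depth_index, time_index).
#' @param n_train_subjects,n_test_subjects per-class subject counts; their
#'   sum must equal each class's subject count.
#' @param seed integer master seed.
#' @return a `split_plan` with mode "subject".
#' @export
split_by_subject <- function(info, n_train_subjects = 17, n_test_subjects = 8, seed) {
  if (inherits(info, "slice_stack")) info <- info$info
  train_rows <- logical(nrow(info))
  for (cl in unique(info$class_label)) {
    in_cl <- info$class_label == cl
    subjects <- sort(unique(info$subject_id[in_cl]))
    need <- n_train_subjects + n_test_subjects
    if (length(subjects) != need)
      stop_labeled("insufficient_subjects",
                   "class %s has %d subjects, split needs exactly %d (%d train + %d test)",
                   cl, length(subjects), need, n_train_subjects, n_test_subjects)
    shuffled <- with_seed(derive_seed(seed, "subject-split", cl),
                          sample(subjects))
    train_subj <- shuffled[seq_len(n_train_subjects)]
    train_rows[in_cl] <- info$subject_id[in_cl] %in% train_subj
  }
  new_split_plan("subject", seed,
                 info[train_rows, , drop = FALSE],
                 info[!train_rows, , drop = FALSE])
}

#' Slice-level hold-out split (the leaky strategy)
#'
#' Per class, slices are pooled across subjects and partitioned uniformly at
#' random, `floor(train_fraction * N)` to train and the remainder to test.
#' With more than one slice per subject, slices of the same subject land on
#' both sides with near certainty — the data-leakage mechanism this package
#' demonstrates. Deterministic given `seed`.
#'
#' @inheritParams split_by_subject
#' @param train_fraction proportion of slices assigned to train, in (0, 1);
#'   default 0.7 (a 70/30 split).
#' @return a `split_plan` with mode "slice".
#' @export
split_by_slice <- function(info, train_fraction = 0.7, seed) {
  if (inherits(info, "slice_stack")) info <- info$info
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_labeled("bad_fraction", "train_fraction must be in (0, 1), got %g",
                 train_fraction)
  train_rows <- logical(nrow(info))
  for (cl in unique(info$class_label)) {
    idx <- which(info$class_label == cl)
    if (length(idx) < 2)
      stop_labeled("too_few_slices", "class %s has fewer than 2 slices", cl)
    n_train <- floor(train_fraction * length(idx))
    chosen <- with_seed(derive_seed(seed, "slice-split", cl),
                        sample(idx, n_train))
    train_rows[chosen] <- TRUE
  }
  new_split_plan("slice", seed,
                 info[train_rows, , drop = FALSE],
                 info[!train_rows, , drop = FALSE])
}

#' Audit a split plan for subject-identity leakage
#'
#' A plan leaks when at least one subject contributes slices to both the
#' train and the test side — the model can then recognize the subject
#' rather than the diagnosis.
#'
#' @param plan a `split_plan`.
#' @return a `leakage_audit`: list(leaky, shared_subjects, shared_count).
#' @export
audit_leakage <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  shared <- sort(intersect(unique(plan$train$subject_id),
                           unique(plan$test$subject_id)))
  structure(list(leaky = length(shared) > 0,
                 shared_subjects = shared,
                 shared_count = length(shared)),
            class = "leakage_audit")
}

#' @export
print.leakage_audit <- function(x, ...) {
  if (x$leaky)
    cat(sprintf("<leakage_audit> LEAKY: %d subject(s) on both sides (%s)\n",
                x$shared_count, paste(utils::head(x$shared_subjects, 5), collapse = ", ")))
  else cat("<leakage_audit> clean: train and test subjects are disjoint\n")
  invisible(x)
}

#' Serialize a split plan (and its audit) to JSON
#' @param plan a `split_plan`.
#' @param path output path.
#' @export
write_split_plan <- function(plan, path) {
  audit <- audit_leakage(plan)
  jsonlite::write_json(list(
    mode = plan$mode, seed = plan$seed,
    n_train = nrow(plan$train), n_test = nrow(plan$test),
    train_ids = slice_keys(plan$train), test_ids = slice_keys(plan$test),
    audit = list(leaky = audit$leaky, shared_subjects = audit$shared_subjects,
                 shared_count = audit$shared_count)
  ), path, auto_unbox = TRUE)
  invisible(path)
}

#' Attach pixel data to the two sides of a split plan
#' @param plan a `split_plan`.
#' @param stack the bound `slice_stack` the plan was made from (with pixels).
#' @return list of two `slice_stack`s: `train` and `test`.
#' @export
materialize_split <- function(plan, stack) {
  stopifnot(inherits(plan, "split_plan"), inherits(stack, "slice_stack"))
  keys <- slice_keys(stack$info)
  pick <- function(side) {
    idx <- match(slice_keys(side), keys)
    if (anyNA(idx))
      stop_labeled("unknown_slice", "plan references slices absent from the stack")
    new_slice_stack(stack$pixels[idx], stack$info[idx, , drop = FALSE],
                    stack$provenance)
  }
  list(train = pick(plan$train), test = pick(plan$test))
}
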