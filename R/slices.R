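#' Number of 2D slices obtained from a 4D volume shape
#'
#' Slicing runs along the depth and time dimensions, so a volume of shape
#' (H, W, D, T) yields exactly D x T axial slices of shape H x W. Computed
#' from the shape alone — no array is materialized, so full-scale shapes
#' like (99, 117, 95, 976) are free to query.
#'
#' @param volume_shape integer 4-vector (H, W, D, T).
#' @return integer slice count D * T.
#' @export
slice_count <- function(volume_shape) {
  if (length(volume_shape) != 4 || any(volume_shape < 1))
    stop_labeled("bad_shape", "need a positive 4-vector (H, W, D, T)")
  as.integer(volume_shape[3]) * as.integer(volume_shape[4])
}

new_slice_stack <- function(pixels, info, provenance = list(filtered = FALSE,
                                                            sampled_n = NA_integer_)) {
  structure(list(pixels = pixels, info = info, provenance = provenance),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("<slice_stack> %d slices, %d subject(s)%s%s\n",
              nrow(x$info), length(unique(x$info$subject_id)),
              if (isTRUE(x$provenance$filtered)) ", filtered" else "",
              if (!is.na(x$provenance$sampled_n))
                sprintf(", sampled n=%d", x$provenance$sampled_n) else ""))
  invisible(x)
}

#' @export
length.slice_stack <- function(x) nrow(x$info)

#' Keep only each subject's earliest scan
#'
#' Subjects scanned on multiple dates contribute duplicate anatomy; the
#' earliest scan per subject is retained to avoid that. Output has exactly
#' one row per `subject_id` (the minimum `scan_date`), ordered by subject,
#' independent of input row order.
#'
#' @param cohort cohort manifest data.frame with `subject_id` and `scan_date`.
#' @return deduplicated manifest.
#' @export
select_earliest_scan <- function(cohort) {
  dates <- as.Date(cohort$scan_date)
  if (any(is.na(dates)))
    stop_labeled("bad_date", "unparseable scan_date in cohort manifest")
  key <- paste(cohort$subject_id, dates)
  if (anyDuplicated(key))
    stop_labeled("duplicate_scan", "duplicate (subject, date) rows: %s",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
  ord <- order(cohort$subject_id, dates)
  sorted <- cohort[ord, , drop = FALSE]
  out <- sorted[!duplicated(sorted$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract all depth-by-time 2D slices of a volume
#'
#' Slice (d, t) is `data[, , d + 1, t + 1]` (indices reported 0-based);
#' slices are ordered with depth varying fastest within each timepoint.
#' The per-slice mean BOLD signal is recorded for percentile filtering.
#'
#' @param volume a [volume4d()].
#' @return a `slice_stack` of exactly D x T slices.
#' @export
extract_slices <- function(volume) {
  stopifnot(inherits(volume, "volume4d"))
  sh <- dim(volume$data)
  H <- sh[1]; W <- sh[2]; D <- sh[3]; T <- sh[4]
  means <- colMeans(matrix(volume$data, nrow = H * W))
  grid <- expand.grid(depth_index = 0:(D - 1), time_index = 0:(T - 1))
  pixels <- vector("list", D * T)
  for (i in seq_len(D * T))
    pixels[[i]] <- volume$data[, , grid$depth_index[i] + 1L, grid$time_index[i] + 1L]
  info <- data.frame(subject_id = volume$subject_id,
                     class_label = volume$class_label,
                     depth_index = grid$depth_index,
                     time_index = grid$time_index,
                     mean_signal = means,
                     stringsAsFactors = FALSE)
  new_slice_stack(pixels, info)
}

#' Per-slice manifest without materializing pixel data
#'
#' Computes the same (subject, depth, time, mean signal) table as
#' [extract_slices()] but stores no pixels, so it scales to full-size
#' volumes; the returned stack can be filtered and sampled like any other.
#'
#' @param volume a [volume4d()].
#' @return a `slice_stack` with `pixels = NULL`.
#' @export
slice_manifest <- function(volume) {
  stopifnot(inherits(volume, "volume4d"))
  sh <- dim(volume$data)
  means <- colMeans(matrix(volume$data, nrow = sh[1] * sh[2]))
  grid <- expand.grid(depth_index = 0:(sh[3] - 1), time_index = 0:(sh[4] - 1))
  info <- data.frame(subject_id = volume$subject_id,
                     class_label = volume$class_label,
                     depth_index = grid$depth_index,
                     time_index = grid$time_index,
                     mean_signal = means,
                     stringsAsFactors = FALSE)
  new_slice_stack(NULL, info)
}

#' Keep the slices whose mean signal reaches a percentile threshold
#'
#' Retains slices with `mean_signal >=` the given percentile of all mean
#' signals in the stack (the "top (100 - p)%"); ties at the threshold are
#' retained and original ordering is preserved. The percentile uses linear
#' interpolation between order statistics (`stats::quantile` type 7), so at
#' the default 90th percentile a stack of N distinct means retains
#' `N - floor(1 + 0.9 * (N - 1))` slices — about 10%.
#'
#' @param stack a `slice_stack`.
#' @param percentile threshold percentile in (0, 100); default 90.
#' @return the filtered `slice_stack` (provenance records the filter).
#' @export
filter_top_percentile <- function(stack, percentile = 90) {
  stopifnot(inherits(stack, "slice_stack"))
  if (nrow(stack$info) == 0)
    stop_labeled("empty_stack", "cannot filter an empty slice stack")
  if (percentile <= 0 || percentile >= 100)
    stop_labeled("bad_percentile", "percentile must be in (0, 100), got %g", percentile)
  thr <- stats::quantile(stack$info$mean_signal, percentile / 100,
                         type = 7, names = FALSE)
  keep <- stack$info$mean_signal >= thr
  out <- stack
  out$info <- stack$info[keep, , drop = FALSE]
  rownames(out$info) <- NULL
  if (!is.null(stack$pixels)) out$pixels <- stack$pixels[keep]
  out$provenance$filtered <- TRUE
  out$provenance$filter_percentile <- percentile
  out
}

#' Randomly sample slices from a stack without replacement
#'
#' @param stack a `slice_stack`.
#' @param n sample size (default 700, the per-subject count used for binary
#'   classification at full scale); `n = 0` gives an empty stack.
#' @param seed integer seed; the draw is deterministic given it.
#' @param allow_replacement if TRUE, stacks smaller than `n` are sampled with
#'   replacement (logged); otherwise that case is an error naming the subject.
#' @return the sampled `slice_stack`, retained slices in original order
#'   (duplicates possible only with replacement).
#' @export
sample_slices <- function(stack, n = 700, seed, allow_replacement = FALSE) {
  stopifnot(inherits(stack, "slice_stack"))
  n <- as.integer(n)
  N <- nrow(stack$info)
  if (n > N && !allow_replacement)
    stop_labeled("too_few_slices",
                 "subject %s has %d slices, cannot sample %d without replacement",
                 paste(unique(stack$info$subject_id), collapse = ","), N, n)
  replace <- n > N
  if (replace)
    message(sprintf("sampling %d from %d slices WITH replacement (subject %s)",
                    n, N, paste(unique(stack$info$subject_id), collapse = ",")))
  idx <- with_seed(seed, sample.int(N, n, replace = replace))
  idx <- sort(idx)
  out <- stack
  out$info <- stack$info[idx, , drop = FALSE]
  rownames(out$info) <- NULL
  if (!is.null(stack$pixels)) out$pixels <- stack$pixels[idx]
  out$provenance$sampled_n <- n
  out
}

#' Concatenate per-subject slice stacks into one collection
#' @param stacks list of `slice_stack` objects (same pixel shape).
#' @return a single `slice_stack`.
#' @export
bind_stacks <- function(stacks) {
  stopifnot(length(stacks) > 0, all(vapply(stacks, inherits, TRUE, "slice_stack")))
  info <- do.call(rbind, lapply(stacks, `[[`, "info"))
  rownames(info) <- NULL
  pix <- lapply(stacks, `[[`, "pixels")
  pixels <- if (any(vapply(pix, is.null, TRUE))) NULL else do.call(c, pix)
  new_slice_stack(pixels, info, provenance = stacks[[1]]$provenance)
}

#' Rebuild a 4D array from a complete slice stack (content oracle)
#'
#' Inverse of [extract_slices()]: given all D x T slices of one volume,
#' reassembles the original (H, W, D, T) array exactly.
#' @param stack a complete, unfiltered `slice_stack` with pixels.
#' @param volume_shape the original (H, W, D, T).
#' @return numeric 4D array.
#' @export
assemble_volume <- function(stack, volume_shape) {
  stopifnot(inherits(stack, "slice_stack"), !is.null(stack$pixels))
  out <- array(NA_real_, dim = volume_shape)
  for (i in seq_len(nrow(stack$info)))
    out[, , stack$info$depth_index[i] + 1L, stack$info$time_index[i] + 1L] <-
      stack$pixels[[i]]
  out
}

#' Write a slice manifest CSV
#' @param stack a `slice_stack`.
#' @param path output CSV path.
#' @export
write_slice_manifest <- function(stack, path) {
  utils::write.csv(stack$info, path, row.names = FALSE)
  invisible(path)
}
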