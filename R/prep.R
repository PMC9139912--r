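#' Enhance one 2D slice into a CNN-ready 3-channel image
#'
#' Applies per-slice min-max normalization to [0, 1] (a constant slice maps
#' to all zeros), bilinear resizing to `target_size` x `target_size`, and
#' replication to 3 identical channels. Per-slice normalization is used
#' deliberately: it cannot carry statistics across the train/test boundary.
#'
#' @param pixels H x W numeric matrix (or a `Slice2D`-style list with a
#'   `pixels` element), all values finite.
#' @param target_size output spatial size S (default 224, the conventional
#'   pretrained-CNN input; desk-scale experiments use 32).
#' @return numeric array of dim (S, S, 3) with values in [0, 1].
#' @export
enhance_slice <- function(pixels, target_size = 224) {
  if (is.list(pixels) && !is.null(pixels$pixels)) pixels <- pixels$pixels
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)))
    stop_labeled("nonfinite_pixels", "slice contains non-finite pixel values")
  rng <- range(pixels)
  norm <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1])
          else matrix(0, nrow(pixels), ncol(pixels))
  resized <-
    if (nrow(norm) == target_size && ncol(norm) == target_size) norm
    else as.matrix(EBImage::resize(norm, w = target_size, h = target_size,
                                   filter = "bilinear"))
  # bilinear interpolation is a convex combination, but clamp against
  # floating-point spill beyond [0, 1]
  resized[resized < 0] <- 0
  resized[resized > 1] <- 1
  array(resized, dim = c(target_size, target_size, 3))
}

#' Prepare a slice collection for training/inference
#'
#' Runs [enhance_slice()] over every slice of a stack and assigns the binary
#' label for the active classification problem.
#'
#' @param stack a `slice_stack` with pixels.
#' @param positive_class diagnosis treated as class 1; every other label in
#'   the stack becomes class 0.
#' @param target_size spatial size passed to [enhance_slice()].
#' @return list with `x` (array S x S x 3 x N), `y` (integer 0/1 labels),
#'   and `info` (the slice provenance table).
#' @export
prepare_slices <- function(stack, positive_class, target_size = 32) {
  stopifnot(inherits(stack, "slice_stack"))
  if (is.null(stack$pixels))
    stop_labeled("no_pixels", "stack carries no pixel data (manifest-only)")
  n <- nrow(stack$info)
  if (n == 0) stop_labeled("empty_stack", "no slices to prepare")
  x <- array(0, dim = c(target_size, target_size, 3, n))
  for (i in seq_len(n))
    x[, , , i] <- enhance_slice(stack$pixels[[i]], target_size)
  y <- as.integer(stack$info$class_label == positive_class)
  list(x = x, y = y, info = stack$info)
}
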