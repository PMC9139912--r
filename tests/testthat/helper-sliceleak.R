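# Shared fixture builders; everything is generated in code at test time.

# A tiny cohort spec for fast tests.
tiny_spec <- function(...) {
  args <- utils::modifyList(list(
    n_per_class = 2, class_labels = c("CN", "AD"),
    volume_shape = c(8, 8, 4, 5), fingerprint_sd = 1, class_effect_sd = 0,
    noise_sd = 1, baseline = 100, scans_per_subject = 1, seed = 42L), list(...))
  do.call(cohort_spec, args)
}

# A slice manifest (no pixels) for split tests: `n_subj` subjects per class,
# `per_subj` slices each, laid out on a depth x time grid.
make_info <- function(n_subj, per_subj, classes = c("A", "B")) {
  do.call(rbind, lapply(classes, function(cl) {
    do.call(rbind, lapply(seq_len(n_subj), function(s) {
      data.frame(subject_id = sprintf("sub-%s-%02d", cl, s),
                 class_label = cl,
                 depth_index = (seq_len(per_subj) - 1L) %% 10L,
                 time_index = (seq_len(per_subj) - 1L) %/% 10L,
                 mean_signal = seq_len(per_subj),
                 stringsAsFactors = FALSE)
    }))
  }))
}

# A slice stack with arbitrary pixel matrices and given per-slice means.
stack_with_means <- function(means, subject = "sub-X", h = 4, w = 4) {
  pixels <- lapply(means, function(m) matrix(m, h, w))
  info <- data.frame(subject_id = rep(subject, length(means)),
                     class_label = rep("A", length(means)),
                     depth_index = seq_along(means) - 1L,
                     time_index = rep(0L, length(means)),
                     mean_signal = means, stringsAsFactors = FALSE)
  sliceleak:::new_slice_stack(pixels, info)
}

# Linearly separable two-class image set: class 0 bright in the top half,
# class 1 bright in the bottom half, plus mild noise.
separable_images <- function(n_per_class, size = 16, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    x <- array(stats::runif(size * size * 3 * n, 0, 0.2), c(size, size, 3, n))
    y <- rep(c(0L, 1L), each = n_per_class)
    for (i in seq_len(n)) {
      rows <- if (y[i] == 0) 1:(size / 2) else (size / 2 + 1):size
      x[rows, , , i] <- x[rows, , , i] + 0.7
    }
    x[x > 1] <- 1
    list(x = x, y = y)
  })
}
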