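#' Specification of a synthetic fMRI cohort
#'
#' Describes a multi-subject resting-state fMRI cohort with three additive
#' signal components per voxel:
#' \itemize{
#'   \item a \emph{subject fingerprint} — a smooth spatial pattern drawn once
#'     per subject and constant over time, the anatomical-identity signal
#'     that slice-level train/test splitting can leak;
#'   \item a \emph{class pattern} — a smooth spatial pattern drawn once per
#'     diagnostic group, the (optional) genuine diagnostic signal;
#'   \item i.i.d. Gaussian noise per voxel per timepoint.
#' }
#' Both spatial patterns are standardized random fields, so `fingerprint_sd`
#' and `class_effect_sd` are their amplitudes in BOLD units.
#'
#' @param n_per_class subjects per diagnostic group (default 25, the cohort
#'   size of the replication design this harness emulates).
#' @param class_labels ordered character vector of diagnosis names.
#' @param volume_shape integer 4-vector (H, W, D, T). The default is a
#'   desk-scale shape; full-scale shapes such as c(99, 117, 95, 197) are
#'   accepted but expensive.
#' @param fingerprint_sd amplitude (sd) of the subject-specific pattern; >= 0.
#' @param class_effect_sd amplitude (sd) of the class-specific pattern; >= 0.
#' @param noise_sd sd of the per-voxel, per-timepoint noise; > 0.
#' @param baseline mean BOLD level added to every voxel (arbitrary units).
#' @param scans_per_subject number of scan dates per subject (>= 1); extra
#'   scans share the subject fingerprint but draw fresh noise, to exercise
#'   earliest-scan deduplication.
#' @param smoothness Gaussian sd, in voxels, of the low-pass filter applied
#'   to the fingerprint and class fields (spatially coherent patterns are
#'   what a convolutional net can exploit, as real anatomy is).
#' @param seed master integer seed; per-subject and per-class sub-seeds are
#'   derived by hashing so generation is order-independent.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 25,
                        class_labels = c("CN", "MCI", "EMCI", "LMCI", "AD"),
                        volume_shape = c(24, 28, 22, 10),
                        fingerprint_sd = 3,
                        class_effect_sd = 0,
                        noise_sd = 1,
                        baseline = 100,
                        scans_per_subject = 1,
                        smoothness = 2,
                        seed = 1L) {
  if (length(volume_shape) != 4 || any(volume_shape < 1))
    stop_labeled("bad_shape", "volume_shape must be 4 positive integers, got (%s)",
                 paste(volume_shape, collapse = ", "))
  if (n_per_class < 1) stop_labeled("bad_spec", "n_per_class must be >= 1")
  if (anyDuplicated(class_labels)) stop_labeled("bad_spec", "duplicate class labels")
  if (fingerprint_sd < 0 || class_effect_sd < 0)
    stop_labeled("bad_spec", "pattern amplitudes must be nonnegative")
  if (noise_sd <= 0) stop_labeled("bad_spec", "noise_sd must be positive")
  if (scans_per_subject < 1) stop_labeled("bad_spec", "scans_per_subject must be >= 1")
  structure(list(
    n_per_class = as.integer(n_per_class),
    class_labels = as.character(class_labels),
    volume_shape = as.integer(volume_shape),
    fingerprint_sd = fingerprint_sd,
    class_effect_sd = class_effect_sd,
    noise_sd = noise_sd,
    baseline = baseline,
    scans_per_subject = as.integer(scans_per_subject),
    smoothness = smoothness,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d classes x %d subjects, volume (%s)\n",
              length(x$class_labels), x$n_per_class,
              paste(x$volume_shape, collapse = " x ")))
  cat(sprintf("  fingerprint_sd=%g class_effect_sd=%g noise_sd=%g baseline=%g seed=%d\n",
              x$fingerprint_sd, x$class_effect_sd, x$noise_sd, x$baseline, x$seed))
  invisible(x)
}

# Smooth standardized 3D Gaussian random field: white noise low-pass filtered
# separably along each axis, then rescaled to mean 0, sd 1. Uses the current
# RNG state (callers seed it).
smooth_field3d <- function(dims, sigma) {
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  if (sigma > 0) {
    for (ax in 1:3) x <- smooth_along_axis(x, ax, sigma)
  }
  (x - mean(x)) / stats::sd(x)
}

# Band-matrix Gaussian smoothing along one axis of a 3D array, with edge
# renormalization (kernel weights re-sum to 1 at boundaries).
smooth_along_axis <- function(x, axis, sigma) {
  d <- dim(x)
  n <- d[axis]
  half <- max(1L, ceiling(3 * sigma))
  offs <- (-half):half
  w <- stats::dnorm(offs, sd = sigma)
  K <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    j <- seq_len(n) + offs[k]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + w[k]
  }
  K <- K / rowSums(K)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- K %*% matrix(xp, nrow = n)
  aperm(array(m, dim = d[perm]), order(perm))
}

#' Construct a 4D BOLD volume object
#'
#' @param data numeric 4D array (H, W, D, T), all finite.
#' @param subject_id subject identifier string.
#' @param class_label diagnosis name.
#' @param scan_date a `Date`.
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, subject_id, class_label, scan_date) {
  if (length(dim(data)) != 4)
    stop_labeled("bad_volume", "volume data must have exactly 4 dimensions")
  if (!all(is.finite(data)))
    stop_labeled("bad_volume", "volume data contains non-finite values")
  structure(list(data = data, subject_id = as.character(subject_id),
                 class_label = as.character(class_label),
                 scan_date = as.Date(scan_date)),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d> %s (%s, %s): %s\n", x$subject_id, x$class_label,
              format(x$scan_date), paste(dim(x$data), collapse = " x ")))
  invisible(x)
}

#' Generate one subject's synthetic 4D BOLD volume
#'
#' The volume is `baseline + fingerprint + class pattern + noise`, where the
#' fingerprint is a smooth spatial field fixed for the subject (identical in
#' every scan and timepoint), the class pattern is a smooth field shared by
#' all subjects of the same diagnosis, and the noise is i.i.d. Gaussian per
#' voxel per timepoint (fresh per scan). Deterministic given
#' `(spec, subject_id, seed, scan_index)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_id subject identifier; seeds the fingerprint draw.
#' @param class_label one of `spec$class_labels`.
#' @param seed master seed (defaults to `spec$seed`).
#' @param scan_index 1-based scan number; changes the noise draw and the scan
#'   date, never the fingerprint.
#' @return a [volume4d()].
#' @export
generate_subject_volume <- function(spec, subject_id, class_label,
                                    seed = spec$seed, scan_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!class_label %in% spec$class_labels)
    stop_labeled("unknown_class", "class_label '%s' not in spec classes (%s)",
                 class_label, paste(spec$class_labels, collapse = ", "))
  sh <- spec$volume_shape
  if (any(sh < 1)) stop_labeled("bad_shape", "zero-sized volume shape")
  spatial <- sh[1:3]; T <- sh[4]

  fp <- with_seed(derive_seed(seed, "fingerprint", subject_id),
                  smooth_field3d(spatial, spec$smoothness)) * spec$fingerprint_sd
  cp <- with_seed(derive_seed(seed, "classpattern", class_label),
                  smooth_field3d(spatial, spec$smoothness)) * spec$class_effect_sd
  noise <- with_seed(derive_seed(seed, "noise", subject_id, scan_index),
                     array(stats::rnorm(prod(sh), sd = spec$noise_sd), dim = sh))

  static <- spec$baseline + fp + cp        # (H, W, D), constant over time
  data <- noise + as.vector(static)        # recycles over the T dimension
  dim(data) <- sh
  volume4d(data, subject_id, class_label, scan_date_for(scan_index))
}

# Scan dates: fixed base date + (scan_index - 1) days, so multiple scans per
# subject are strictly ordered and earliest-scan deduplication is exercised
# deterministically.
scan_date_for <- function(scan_index) as.Date("2021-10-01") + (scan_index - 1L)

subject_ids_for <- function(spec) {
  unlist(lapply(spec$class_labels, function(cl)
    sprintf("sub-%s-%02d", cl, seq_len(spec$n_per_class))))
}

#' Generate a full synthetic cohort and write it to disk
#'
#' Creates `n_per_class x length(class_labels)` subjects, each with
#' `scans_per_subject` scans at strictly increasing dates, writes one
#' NIfTI-1 (.nii.gz) file per subject-scan, and a `cohort.csv` sidecar
#' manifest with columns `subject_id, class_label, scan_date, path`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if missing).
#' @return the cohort manifest as a data.frame (invisibly also written to
#'   `file.path(dir, "cohort.csv")`).
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop_labeled("unwritable_dir", "cannot write cohort to '%s'", dir)
  rows <- list()
  for (cl in spec$class_labels) {
    for (i in seq_len(spec$n_per_class)) {
      sid <- sprintf("sub-%s-%02d", cl, i)
      for (k in seq_len(spec$scans_per_subject)) {
        vol <- generate_subject_volume(spec, sid, cl, scan_index = k)
        path <- file.path(dir, sprintf("%s_scan-%02d.nii.gz", sid, k))
        RNifti::writeNifti(vol$data, path)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, class_label = cl,
          scan_date = vol$scan_date, path = path,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  tab
}

#' Read a cohort volume back from its manifest row
#' @param path path to a NIfTI file written by [generate_cohort()].
#' @param subject_id,class_label,scan_date metadata to attach.
#' @return a [volume4d()].
#' @export
read_cohort_volume <- function(path, subject_id, class_label, scan_date) {
  img <- RNifti::readNifti(path)
  volume4d(array(as.numeric(img), dim = dim(img)), subject_id, class_label,
           as.Date(scan_date))
}
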