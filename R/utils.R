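#' @keywords internal
"_PACKAGE"

#' Deterministic 32-bit string/seed hash
#'
#' FNV-1a over the UTF-8 bytes of its arguments, folded to a positive
#' integer below 2^31. Used to derive per-subject and per-class RNG seeds
#' from a single master seed so that generation is order-independent:
#' adding or reordering subjects never perturbs another subject's draw.
#'
#' @param ... atomic values; coerced to character and joined with "\\x1f".
#' @return a single integer in [1, 2^31 - 1].
#' @export
derive_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "\x1f")
  bytes <- as.integer(charToRaw(key))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime, split to stay in double range
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483646 + 1)
}

#' Run an expression with a fixed RNG seed, restoring state afterwards
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Labeled error helper: all package errors carry a "sliceleak_error" class
#' @noRd
stop_labeled <- function(label, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("sliceleak_", label), "sliceleak_error", "error", "condition"),
    list(message = sprintf("[%s] %s", label, msg), call = sys.call(-1))
  ))
}

#' Cheap deterministic checksum of a numeric parameter vector
#'
#' Sensitive to value, position and length; used to compare model
#' initialisations and detect parameter drift, not for cryptography.
#' @noRd
param_checksum <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0) return("empty")
  s1 <- sum(x)
  s2 <- sum(x * x)
  s3 <- sum(x * (seq_len(n) %% 997L))
  sprintf("%d:%.10e:%.10e:%.10e", n, s1, s2, s3)
}
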