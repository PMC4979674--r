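#' Geometric mean
#'
#' Geometric mean of strictly positive values, computed on the log scale for
#' numerical stability.
#'
#' @param x Numeric vector of positive values.
#' @param na.rm Drop `NA` values before computing.
#' @return A single number; `NaN` if no values remain.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(is.na(x))) return(NA_real_)
  if (length(x) == 0L) return(NaN)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## stop() with call.=FALSE everywhere; keeps user-facing errors clean
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("'%s' must be a single finite number", name)
}

## tiny FNV-1a over a canonical string; used to fingerprint run configs
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## deterministic derived seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1L))
}
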