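#' Construct a SILAC intensity matrix
#'
#' Protein-level heavy/light raw MS1 intensities across replicates, the
#' standard protein-groups shape: one row per protein, one heavy and one
#' light intensity column per replicate. Zero intensities denote absent
#' signal and are stored as missing.
#'
#' @param proteins Character vector of protein ids (unique).
#' @param heavy,light Numeric matrices, proteins x replicates; `NA` (or 0)
#'   means no signal.
#' @param strain Strain label.
#' @return A data frame of class `silac_matrix` with columns `protein`,
#'   `intensity_H_rep<j>`, `intensity_L_rep<j>` and attributes `strain`,
#'   `n_replicates`.
#' @export
silac_matrix <- function(proteins, heavy, light, strain = "unknown") {
  heavy <- as.matrix(heavy)
  light <- as.matrix(light)
  if (anyDuplicated(proteins)) abort("protein ids must be unique")
  if (nrow(heavy) != length(proteins) || nrow(light) != length(proteins))
    abort("intensity matrices must have one row per protein")
  if (ncol(heavy) != ncol(light))
    abort("heavy and light channels must have the same number of replicates")
  heavy[!is.na(heavy) & heavy == 0] <- NA_real_
  light[!is.na(light) & light == 0] <- NA_real_
  if (any(heavy < 0, na.rm = TRUE) || any(light < 0, na.rm = TRUE))
    abort("intensities must be non-negative")
  R <- ncol(heavy)
  out <- data.frame(protein = as.character(proteins),
                    stringsAsFactors = FALSE)
  for (j in seq_len(R)) out[[sprintf("intensity_H_rep%d", j)]] <- heavy[, j]
  for (j in seq_len(R)) out[[sprintf("intensity_L_rep%d", j)]] <- light[, j]
  structure(out, strain = strain, n_replicates = R,
            class = c("silac_matrix", "data.frame"))
}

#' Number of replicates of a SILAC matrix
#' @param x A `silac_matrix`.
#' @return Integer replicate count.
#' @export
n_replicates <- function(x) attr(x, "n_replicates")

heavy_cols <- function(x) grep("^intensity_H_rep", names(x), value = TRUE)
light_cols <- function(x) grep("^intensity_L_rep", names(x), value = TRUE)

#' Extract a channel as a matrix
#' @param x A `silac_matrix`.
#' @param channel `"H"` or `"L"`.
#' @return Numeric matrix proteins x replicates, protein ids as rownames.
#' @export
channel_matrix <- function(x, channel = c("H", "L")) {
  channel <- match.arg(channel)
  cols <- if (channel == "H") heavy_cols(x) else light_cols(x)
  m <- as.matrix(x[, cols, drop = FALSE])
  rownames(m) <- x$protein
  m
}

#' @export
print.silac_matrix <- function(x, ...) {
  cat(sprintf("SILAC intensity matrix: %d proteins x %d replicates (strain %s)\n",
              nrow(x), n_replicates(x), attr(x, "strain")))
  n_missing <- sum(is.na(channel_matrix(x, "H"))) + sum(is.na(channel_matrix(x, "L")))
  cat(sprintf("  missing cells: %d of %d (%.1f%%)\n", n_missing,
              2L * nrow(x) * n_replicates(x),
              100 * n_missing / (2L * nrow(x) * n_replicates(x))))
  invisible(x)
}
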