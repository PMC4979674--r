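#' Per-replicate log2 light/heavy ratios
#'
#' Computes log2(light/heavy) for every protein and replicate. A ratio is
#' defined only where both channels carry signal; zero intensity counts as
#' absent signal, so those cells are missing (the count of such cells is
#' attached as attribute `n_flagged_zero`).
#'
#' @param silac A [silac_matrix()].
#' @return Numeric matrix (proteins x replicates) of log2 ratios, protein
#'   ids as rownames.
#' @export
compute_log_ratios <- function(silac) {
  H <- channel_matrix(silac, "H")
  L <- channel_matrix(silac, "L")
  n_zero <- sum((!is.na(H) & H == 0) | (!is.na(L) & L == 0))
  H[H == 0] <- NA_real_
  L[L == 0] <- NA_real_
  r <- log2(L) - log2(H)
  colnames(r) <- sprintf("log2_ratio_rep%d", seq_len(ncol(r)))
  structure(r, n_flagged_zero = n_zero)
}

#' Filter proteins by replicate coverage
#'
#' Retains proteins quantified in at least `min_reps` replicates, where a
#' replicate counts as quantified when an MS1 signal is present in either the
#' light or the heavy channel (the criterion used to select proteins seen in
#' at least three of four biological replicates).
#'
#' @param silac A [silac_matrix()].
#' @param min_reps Minimum number of replicates with signal (default 3).
#' @param require_both Count a replicate only when both channels have signal.
#' @return The filtered `silac_matrix`, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
filter_by_replicates <- function(silac, min_reps = 3L, require_both = FALSE) {
  R <- n_replicates(silac)
  if (min_reps > R)
    abort("'min_reps' (%d) exceeds the number of replicates (%d)", min_reps, R)
  H <- channel_matrix(silac, "H")
  L <- channel_matrix(silac, "L")
  present <- if (require_both) !is.na(H) & !is.na(L) else !is.na(H) | !is.na(L)
  keep <- rowSums(present) >= min_reps
  out <- silac[keep, , drop = FALSE]
  structure(out, strain = attr(silac, "strain"), n_replicates = R,
            n_kept = sum(keep), n_dropped = sum(!keep),
            class = class(silac))
}

#' Relative isotope abundance
#'
#' RIA = H / (H + L) * 100, the percentage of heavy signal used to verify
#' SILAC label incorporation. Undefined (returned as `NA` with a warning)
#' where both channels are zero or missing.
#'
#' @param heavy,light Non-negative intensities (vectorized).
#' @return RIA percentages in \[0, 100\].
#' @export
incorporation_efficiency <- function(heavy, light) {
  if (length(heavy) != length(light))
    abort("'heavy' and 'light' must have the same length")
  if (any(heavy < 0, na.rm = TRUE) || any(light < 0, na.rm = TRUE))
    abort("intensities must be non-negative")
  total <- heavy + light
  bad <- is.na(total) | total == 0
  if (any(bad))
    warning("RIA undefined where heavy + light == 0; returning NA",
            call. = FALSE)
  out <- 100 * heavy / total
  out[bad] <- NA_real_
  out
}

## One pass of regression-to-mean: OLS of each column on the across-column
## mean over commonly observed rows, then map the column onto the mean scale.
.regress_to_mean_once <- function(mat, intercept_only = FALSE) {
  ref <- rowMeans(mat, na.rm = TRUE)
  common <- stats::complete.cases(mat)
  if (sum(common) < 2L)
    abort("normalization error: fewer than 2 proteins shared across replicates")
  a <- numeric(ncol(mat)); b <- rep(1, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    x <- mat[common, j]; r <- ref[common]
    if (intercept_only) {
      a[j] <- mean(x) - mean(r)
    } else {
      b[j] <- stats::cov(x, r) / stats::var(r)
      if (!is.finite(b[j]) || abs(b[j]) < 1e-12)
        abort("normalization error: degenerate regression (zero slope)")
      a[j] <- mean(x) - b[j] * mean(r)
    }
    mat[, j] <- (mat[, j] - a[j]) / b[j]
  }
  list(mat = mat, a = a, b = b)
}

#' Linear-regression normalization of log2 intensities
#'
#' Centres each replicate channel by ordinary least squares against the
#' across-replicate mean: each column of log2 intensities is regressed on the
#' row mean over commonly observed proteins and mapped onto that reference
#' (slope and intercept, or intercept only with `method = "center"`). The
#' regression-to-mean step is iterated until the fixed point (the reference
#' mean changes once columns move), so the operation is idempotent;
#' convergence is typically reached in fewer than ten iterations.
#'
#' @param mat Numeric matrix of log2 intensities (proteins x channel
#'   columns), e.g. `log2(channel_matrix(x, "H"))` column-bound with the
#'   light channel.
#' @param method `"ols"` (slope + intercept, default), `"center"`
#'   (intercept only) or `"none"`.
#' @param tol Convergence tolerance on the maximum absolute change.
#' @param max_iter Iteration cap.
#' @return The normalized matrix, with attributes `offsets` (a data frame of
#'   composite per-column intercept/slope) and `iterations`.
#' @export
normalize_linear_regression <- function(mat, method = c("ols", "center", "none"),
                                        tol = 1e-12, max_iter = 100L) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (method == "none") {
    return(structure(mat,
                     offsets = data.frame(column = colnames(mat),
                                          intercept = 0, slope = 1),
                     iterations = 0L))
  }
  A <- numeric(ncol(mat)); B <- rep(1, ncol(mat))
  it <- 0L
  repeat {
    it <- it + 1L
    step <- .regress_to_mean_once(mat, intercept_only = (method == "center"))
    change <- max(abs(step$mat - mat), na.rm = TRUE)
    ## composite transform x' = (x - A)/B accumulated across passes
    A <- A + step$a * B
    B <- B * step$b
    mat <- step$mat
    if (change < tol || it >= max_iter) break
  }
  structure(mat,
            offsets = data.frame(column = colnames(mat) %||% seq_len(ncol(mat)),
                                 intercept = A, slope = B),
            iterations = it)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a SILAC matrix
#'
#' Applies [normalize_linear_regression()] jointly to the log2 heavy and
#' light intensity columns of a SILAC matrix (all channels against one
#' common reference mean, as when normalizing all replicate datasets to the
#' mean intensity of every dataset).
#'
#' @param silac A [silac_matrix()].
#' @inheritParams normalize_linear_regression
#' @return A `silac_matrix` with normalized intensities (back on the raw
#'   scale), carrying the `offsets` attribute.
#' @export
normalize_silac <- function(silac, method = c("ols", "center", "none"),
                            tol = 1e-12, max_iter = 100L) {
  method <- match.arg(method)
  H <- channel_matrix(silac, "H")
  L <- channel_matrix(silac, "L")
  R <- ncol(H)
  mat <- cbind(log2(H), log2(L))
  colnames(mat) <- c(sprintf("H_rep%d", seq_len(R)), sprintf("L_rep%d", seq_len(R)))
  norm <- normalize_linear_regression(mat, method = method, tol = tol,
                                      max_iter = max_iter)
  out <- silac_matrix(silac$protein,
                      2^norm[, seq_len(R), drop = FALSE],
                      2^norm[, R + seq_len(R), drop = FALSE],
                      strain = attr(silac, "strain"))
  attr(out, "offsets") <- attr(norm, "offsets")
  attr(out, "iterations") <- attr(norm, "iterations")
  out
}

#' Per-protein differential test (one-way ANOVA, heavy vs light)
#'
#' For each protein, compares the normalized log2 heavy intensities against
#' the normalized log2 light intensities across replicates with a one-way
#' two-group ANOVA (pooled-variance F test). Proteins with fewer than
#' `min_per_group` observations in either channel, or zero pooled
#' within-group variance, are flagged untestable and carry no p-value.
#'
#' @param silac A (normalized) [silac_matrix()].
#' @param min_per_group Minimum observations per channel (default 2).
#' @return Data frame: `protein`, `mean_log2_fc` (light minus heavy group
#'   mean), `f`, `df1`, `df2`, `p_value`, `testable`.
#' @export
test_differential <- function(silac, min_per_group = 2L) {
  H <- log2(channel_matrix(silac, "H"))
  L <- log2(channel_matrix(silac, "L"))
  nH <- rowSums(!is.na(H)); nL <- rowSums(!is.na(L))
  mH <- rowMeans(H, na.rm = TRUE); mL <- rowMeans(L, na.rm = TRUE)
  ssH <- rowSums((H - mH)^2, na.rm = TRUE)
  ssL <- rowSums((L - mL)^2, na.rm = TRUE)
  n <- nH + nL
  grand <- (nH * mH + nL * mL) / n
  ssb <- nH * (mH - grand)^2 + nL * (mL - grand)^2
  df1 <- 1
  df2 <- n - 2
  msw <- (ssH + ssL) / df2
  f <- ssb / df1 / msw
  testable <- nH >= min_per_group & nL >= min_per_group & is.finite(f)
  p <- ifelse(testable, stats::pf(f, df1, df2, lower.tail = FALSE), NA_real_)
  data.frame(protein = silac$protein,
             mean_log2_fc = mL - mH,
             f = ifelse(testable, f, NA_real_),
             df1 = ifelse(testable, df1, NA_integer_),
             df2 = ifelse(testable, df2, NA_integer_),
             p_value = p,
             testable = testable,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector (monotone in
#' rank, capped at 1). Missing values are passed through.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Global shift estimate: median fold change
#'
#' Median over proteins of the per-protein mean log2(light/heavy) ratio.
#' Quantifies a global mixing or cell-size shift: with a light:heavy
#' cell-equivalent factor g the estimate converges to log2(g).
#'
#' @param ratios A log2-ratio matrix from [compute_log_ratios()], or a
#'   [silac_matrix()] (ratios are computed first).
#' @return The median of per-protein mean log2 ratios (a single number).
#' @export
median_fold_change <- function(ratios) {
  if (inherits(ratios, "silac_matrix")) ratios <- compute_log_ratios(ratios)
  ratios <- as.matrix(ratios)
  per_protein <- rowMeans(ratios, na.rm = TRUE)
  per_protein <- per_protein[is.finite(per_protein)]
  if (length(per_protein) == 0L)
    abort("no quantified proteins: cannot compute a median fold change")
  stats::median(per_protein)
}

#' Oblate-spheroid cell volume
#'
#' Volume of a yeast cell approximated as an oblate spheroid with equatorial
#' diameter `r1` and polar diameter `r2`: `V = 4/3 * pi * r1 * r2^2`
#' (cubic micrometres for inputs in micrometres).
#'
#' @param r1 Equatorial diameter (> 0).
#' @param r2 Polar diameter (> 0).
#' @return Volume.
#' @export
cell_volume <- function(r1, r2) {
  if (any(r1 <= 0) || any(r2 <= 0))
    abort("cell dimensions must be positive")
  4 / 3 * pi * r1 * r2^2
}

#' LOESS curve for an MA plot
#'
#' Locally weighted regression (tricube weights, locally linear) of the log2
#' ratio M on the mean log2 intensity A, evaluated on a uniform grid.
#' Diagnostic for global and intensity-dependent bias.
#'
#' @param m Log2 ratios (M values).
#' @param a Mean log2 intensities (A values), same length.
#' @param span LOESS span (default 0.3).
#' @param n_grid Number of grid points.
#' @return Data frame with columns `a` and `m_fit`.
#' @export
ma_loess <- function(m, a, span = 0.3, n_grid = 100L) {
  ok <- is.finite(m) & is.finite(a)
  m <- m[ok]; a <- a[ok]
  if (length(m) < 10L) abort("need at least 10 points for a LOESS curve")
  fit <- stats::loess(m ~ a, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(a), max(a), length.out = n_grid)
  data.frame(a = grid, m_fit = stats::predict(fit, newdata = data.frame(a = grid)))
}

#' SILAC quantification pipeline
#'
#' Runs the full protein quantification chain on a SILAC matrix: replicate
#' filtering, raw log2 ratios and global median fold change,
#' linear-regression normalization, per-protein heavy-vs-light ANOVA, and
#' Benjamini-Hochberg adjustment.
#'
#' @param silac A [silac_matrix()].
#' @param min_reps Replicate filter threshold (see [filter_by_replicates()]).
#' @param normalize Normalization method: `"ols"`, `"center"` or `"none"`.
#' @param alpha Significance level for the reported flags.
#' @return An object of class `quant_table`: a data frame with per-protein
#'   raw and normalized mean log2 fold changes, p-values, BH-adjusted
#'   p-values and significance flags; attributes carry the global shift
#'   estimates (raw and normalized), filter counts, normalization offsets
#'   and `alpha`.
#' @export
silac_quant <- function(silac, min_reps = 3L, normalize = c("ols", "center", "none"),
                        alpha = 0.05) {
  normalize <- match.arg(normalize)
  filtered <- filter_by_replicates(silac, min_reps = min_reps)
  if (nrow(filtered) == 0L) abort("no proteins pass the replicate filter")
  raw_ratios <- compute_log_ratios(filtered)
  shift_raw <- median_fold_change(raw_ratios)
  normed <- normalize_silac(filtered, method = normalize)
  norm_ratios <- compute_log_ratios(normed)
  tests <- test_differential(normed)
  tests$adjusted_p_value <- adjust_bh(tests$p_value)

  out <- data.frame(protein = filtered$protein,
                    raw_mean_log2_fc = rowMeans(raw_ratios, na.rm = TRUE),
                    norm_mean_log2_fc = rowMeans(norm_ratios, na.rm = TRUE),
                    n_quantified_reps = rowSums(!is.na(raw_ratios)),
                    stringsAsFactors = FALSE)
  out <- merge(out, tests[, c("protein", "f", "p_value", "adjusted_p_value",
                              "testable")],
               by = "protein", sort = FALSE)
  out$significant_raw <- !is.na(out$p_value) & out$p_value < alpha
  out$significant_adj <- !is.na(out$adjusted_p_value) &
    out$adjusted_p_value < alpha
  structure(out,
            shift_raw = shift_raw,
            shift_normalized = median_fold_change(norm_ratios),
            n_input = nrow(silac),
            n_kept = attr(filtered, "n_kept"),
            n_dropped = attr(filtered, "n_dropped"),
            offsets = attr(normed, "offsets"),
            normalize = normalize,
            alpha = alpha,
            class = c("quant_table", "data.frame"))
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("SILAC quantification: %d proteins (of %d input; %d dropped by replicate filter)\n",
              nrow(x), attr(x, "n_input"), attr(x, "n_dropped")))
  cat(sprintf("  global shift (median log2 L/H): raw %.3f, normalized %.3f\n",
              attr(x, "shift_raw"), attr(x, "shift_normalized")))
  cat(sprintf("  significant at p < %.3g: %d raw, %d BH-adjusted\n",
              attr(x, "alpha"), sum(x$significant_raw), sum(x$significant_adj)))
  invisible(x)
}

#' @export
summary.quant_table <- function(object, ...) {
  up <- sum(object$significant_raw & object$norm_mean_log2_fc > 0)
  down <- sum(object$significant_raw & object$norm_mean_log2_fc < 0)
  up_adj <- sum(object$significant_adj & object$norm_mean_log2_fc > 0)
  down_adj <- sum(object$significant_adj & object$norm_mean_log2_fc < 0)
  res <- list(n_proteins = nrow(object),
              n_dropped = attr(object, "n_dropped"),
              shift_raw = attr(object, "shift_raw"),
              shift_normalized = attr(object, "shift_normalized"),
              alpha = attr(object, "alpha"),
              up_raw = up, down_raw = down,
              up_adj = up_adj, down_adj = down_adj)
  class(res) <- "summary.quant_table"
  res
}

#' @export
print.summary.quant_table <- function(x, ...) {
  cat(sprintf("%d proteins quantified (%d dropped); raw shift %.3f, normalized %.3f\n",
              x$n_proteins, x$n_dropped, x$shift_raw, x$shift_normalized))
  cat(sprintf("  raw p < %.3g: %d up, %d down; BH-adjusted: %d up, %d down\n",
              x$alpha, x$up_raw, x$down_raw, x$up_adj, x$down_adj))
  invisible(x)
}
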