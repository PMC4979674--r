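## TSV readers/writers for the pipeline's plain-text interchange formats.
## All writers emit header rows; all readers validate the schema and name
## the offending column or line in their error messages.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) abort("%s file not found: %s", what, path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) abort("malformed %s TSV '%s': %s", what, path,
                              conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort("malformed %s TSV '%s': missing column(s) %s (line 1)", what, path,
          paste(sprintf("'%s'", missing), collapse = ", "))
  df
}

#' Read / write an edge-list TSV
#'
#' Two tab-separated columns of node ids (header `from`, `to`; headerless
#' two-column files are also accepted on read).
#'
#' @param path File path.
#' @return `read_edges_tsv`: a two-column data frame.
#' @export
read_edges_tsv <- function(path) {
  if (!file.exists(path)) abort("edge-list file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1]][1:2], c("from", "to"))
  df <- utils::read.delim(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    abort("malformed edge-list TSV '%s': expected 2 tab-separated columns (line 1)",
          path)
  names(df)[1:2] <- c("from", "to")
  df[, 1:2]
}

#' @rdname read_edges_tsv
#' @param edges Two-column data frame.
#' @export
write_edges_tsv <- function(edges, path) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an abundance TSV
#'
#' Columns `protein`, `value`, `unit` (`ppm` or `cpc`). Values in ppm are
#' converted to copies per cell with `value * total_molecules / 1e6`.
#'
#' @param path File path.
#' @param total_molecules Total molecules per cell used for the ppm
#'   conversion (recorded in attribute `scale_factor`).
#' @return Data frame `protein`, `cpc`.
#' @export
read_abundance_tsv <- function(path, total_molecules = 5e7) {
  df <- read_tsv_checked(path, c("protein", "value"), "abundance")
  unit <- if ("unit" %in% names(df)) df$unit else rep("cpc", nrow(df))
  value <- as.numeric(df$value)
  bad <- which(!unit %in% c("ppm", "cpc"))
  if (length(bad))
    abort("malformed abundance TSV '%s': unknown unit '%s' (line %d)",
          path, unit[bad[1]], bad[1] + 1L)
  cpc <- ifelse(unit == "ppm", value * total_molecules / 1e6, value)
  if (any(cpc < 0, na.rm = TRUE)) abort("abundance values must be non-negative")
  structure(data.frame(protein = as.character(df$protein), cpc = cpc,
                       stringsAsFactors = FALSE),
            scale_factor = total_molecules)
}

#' @rdname read_abundance_tsv
#' @param abundance Data frame `protein`, `cpc`.
#' @export
write_abundance_tsv <- function(abundance, path) {
  out <- data.frame(protein = abundance$protein, value = abundance$cpc,
                    unit = "cpc")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a turnover TSV
#'
#' Columns `protein`, `value`, `unit` (`kdeg_per_min` or `half_life_min`);
#' an empty value field means missing. Half-lives are converted with
#' [half_life_to_kdeg()].
#'
#' @param path File path.
#' @return Data frame `protein`, `kdeg`, `missing`.
#' @export
read_turnover_tsv <- function(path) {
  df <- read_tsv_checked(path, c("protein", "value"), "turnover")
  unit <- if ("unit" %in% names(df)) df$unit else rep("kdeg_per_min", nrow(df))
  value <- as.numeric(df$value)
  bad <- which(!unit %in% c("kdeg_per_min", "half_life_min"))
  if (length(bad))
    abort("malformed turnover TSV '%s': unknown unit '%s' (line %d)",
          path, unit[bad[1]], bad[1] + 1L)
  kdeg <- ifelse(unit == "half_life_min" & !is.na(value),
                 log(2) / value, value)
  data.frame(protein = as.character(df$protein), kdeg = kdeg,
             missing = is.na(kdeg), stringsAsFactors = FALSE)
}

#' @rdname read_turnover_tsv
#' @param turnover Data frame `protein`, `kdeg` (`NA` = missing).
#' @export
write_turnover_tsv <- function(turnover, path) {
  out <- data.frame(protein = turnover$protein, value = turnover$kdeg,
                    unit = "kdeg_per_min")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write a SILAC intensity TSV
#'
#' Columns `protein`, `intensity_H_rep1..n`, `intensity_L_rep1..n`; empty
#' fields are missing.
#'
#' @param path File path.
#' @param strain Strain label to attach.
#' @return A [silac_matrix()].
#' @export
read_intensity_tsv <- function(path, strain = "unknown") {
  df <- read_tsv_checked(path, "protein", "intensity")
  hc <- grep("^intensity_H_rep", names(df), value = TRUE)
  lc <- grep("^intensity_L_rep", names(df), value = TRUE)
  if (length(hc) == 0L || length(hc) != length(lc))
    abort("malformed intensity TSV '%s': need matching intensity_H_rep*/intensity_L_rep* columns (line 1)",
          path)
  silac_matrix(df$protein,
               as.matrix(df[, hc, drop = FALSE]),
               as.matrix(df[, lc, drop = FALSE]),
               strain = strain)
}

#' @rdname read_intensity_tsv
#' @param silac A [silac_matrix()].
#' @export
write_intensity_tsv <- function(silac, path) {
  utils::write.table(as.data.frame(silac), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Accepts a tab-separated protein-groups table with a `Protein IDs` column
#' and per-experiment `Intensity H <exp>` / `Intensity L <exp>` columns, and
#' converts it to a [silac_matrix()].
#'
#' @param path File path.
#' @param strain Strain label.
#' @return A [silac_matrix()].
#' @export
read_maxquant_proteingroups <- function(path, strain = "unknown") {
  df <- read_tsv_checked(path, "Protein IDs", "proteinGroups")
  hc <- grep("^Intensity H ", names(df), value = TRUE)
  lc <- grep("^Intensity L ", names(df), value = TRUE)
  if (length(hc) == 0L || length(hc) != length(lc))
    abort("malformed proteinGroups TSV '%s': need matching 'Intensity H <exp>'/'Intensity L <exp>' columns (line 1)",
          path)
  ## align experiments by suffix
  exps <- sub("^Intensity H ", "", hc)
  lc <- paste("Intensity L", exps)
  missing <- setdiff(lc, names(df))
  if (length(missing))
    abort("malformed proteinGroups TSV '%s': missing column '%s' (line 1)",
          path, missing[1])
  silac_matrix(df[["Protein IDs"]],
               as.matrix(df[, hc, drop = FALSE]),
               as.matrix(df[, lc, drop = FALSE]),
               strain = strain)
}

#' Write a quantification table TSV
#'
#' @param quant A [silac_quant()] result.
#' @param path File path.
#' @export
write_quant_tsv <- function(quant, path) {
  utils::write.table(as.data.frame(quant), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a quantification table TSV
#' @param path File path.
#' @return Data frame.
#' @export
read_quant_tsv <- function(path) {
  read_tsv_checked(path, c("protein", "raw_mean_log2_fc", "p_value"),
                   "quantification")
}

#' Write / read a node topology profile TSV
#' @param profile A [node_topology()] data frame.
#' @param path File path.
#' @export
write_topology_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
read_topology_tsv <- function(path) {
  read_tsv_checked(path, c("node", "degree", "betweenness"), "topology")
}

#' Write / read a workload profile TSV
#' @param workload A [chaperone_workload()] result.
#' @param path File path.
#' @export
write_workload_tsv <- function(workload, path) {
  utils::write.table(as.data.frame(workload), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_workload_tsv
#' @export
read_workload_tsv <- function(path) {
  read_tsv_checked(path, c("chaperone", "flux", "n_substrates"), "workload")
}

#' Write ground truth as JSON
#' @param ground_truth Ground-truth list from the generators.
#' @param path File path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
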