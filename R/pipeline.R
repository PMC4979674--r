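#' Run the full chaperome analysis pipeline
#'
#' End-to-end orchestration: simulate (or load) a chaperome network,
#' abundances, turnover rates and a SILAC experiment; quantify the SILAC
#' data; profile the network topology before and after deleting a chaperone;
#' compute folding workloads and their post-deletion redistribution; and
#' assemble a machine-readable report. All randomness flows from the seed in
#' `config`, so identical configurations reproduce identical reports.
#'
#' @param config A [sim_config()] (synthetic mode), or a list with element
#'   `files` naming paths `edges`, `abundance`, `turnover`, `intensity`
#'   (file mode).
#' @param delete Chaperone id to delete; default: the chaperone with the
#'   highest betweenness centrality.
#' @param min_reps,alpha,normalize Passed to [silac_quant()].
#' @param hsp70_ids HSP70 family ids for the workload split.
#' @param outdir Optional directory; when given, every stage artifact (TSV /
#'   JSON) is written there.
#' @param top_k Number of top-betweenness nodes tabulated in the report.
#' @return An object of class `chaperome_report` (a nested list with
#'   `provenance`, `quant`, `topology` and `workload` summaries plus the
#'   full stage objects in `objects`).
#' @export
run_pipeline <- function(config = sim_config(), delete = NULL,
                         min_reps = 3L, alpha = 0.05, normalize = "ols",
                         hsp70_ids = hsp70_family(), outdir = NULL,
                         top_k = 15L) {
  if (inherits(config, "sim_config")) {
    network <- generate_network(config)
    abt <- generate_abundance_turnover(config, igraph::V(network)$name)
    silac <- generate_silac_experiment(config, abt$abundance)
    inputs <- list(mode = "synthetic", seed = config$seed,
                   config_hash = fnv1a_hash(paste(
                     names(unclass(config)),
                     vapply(unclass(config), format, ""), collapse = ";")))
    ground_truth <- c(abt$ground_truth, silac$ground_truth)
    abundance <- abt$abundance
    turnover <- abt$turnover
    silac <- silac$silac
  } else if (is.list(config) && !is.null(config$files)) {
    f <- config$files
    for (nm in c("edges", "abundance", "turnover", "intensity"))
      if (is.null(f[[nm]])) abort("file mode requires a '%s' path", nm)
    edges <- read_edges_tsv(f$edges)
    roles <- NULL
    if (!is.null(f$roles)) {
      rdf <- read_tsv_checked(f$roles, c("node", "role"), "roles")
      roles <- stats::setNames(rdf$role, rdf$node)
    }
    network <- build_graph(edges, roles = roles)
    abundance <- read_abundance_tsv(f$abundance)
    turnover <- read_turnover_tsv(f$turnover)
    silac <- read_intensity_tsv(f$intensity)
    inputs <- list(mode = "files", paths = f,
                   config_hash = fnv1a_hash(paste(unlist(f), collapse = ";")))
    ground_truth <- NULL
  } else {
    abort("'config' must be a sim_config or a list with a 'files' element")
  }

  ## --- quantification -----------------------------------------------------
  quant <- silac_quant(silac, min_reps = min_reps, normalize = normalize,
                       alpha = alpha)

  ## --- topology -----------------------------------------------------------
  wt_profile <- node_topology(network)
  chap_profile <- wt_profile[wt_profile$role == "chaperone", ]
  if (is.null(delete))
    delete <- chap_profile$node[which.max(chap_profile$betweenness)]
  del <- delete_node(network, delete)
  mut_profile <- node_topology(del$network)
  ks <- compare_attribute_distributions(wt_profile, mut_profile)

  ## --- workload -----------------------------------------------------------
  workload <- chaperone_workload(network, abundance, turnover)
  impact <- deletion_extra_workload(workload, delete, hsp70_ids = hsp70_ids)
  rho <- tryCatch(bc_workload_correlation(wt_profile, workload, top_n = top_k),
                  error = function(e) NA_real_)

  top_bc <- utils::head(wt_profile[order(-wt_profile$betweenness),
                                   c("node", "role", "degree", "betweenness")],
                        top_k)
  report <- structure(list(
    provenance = inputs,
    quant = list(
      n_input = attr(quant, "n_input"),
      n_passing_filter = attr(quant, "n_kept"),
      n_significant_raw = sum(quant$significant_raw),
      n_significant_adj = sum(quant$significant_adj),
      median_fold_change_raw = attr(quant, "shift_raw"),
      median_fold_change_normalized = attr(quant, "shift_normalized")
    ),
    topology = list(
      wt_nodes = igraph::vcount(network),
      wt_edges = igraph::ecount(network),
      deleted = delete,
      mutant_nodes = igraph::vcount(del$network),
      mutant_edges = igraph::ecount(del$network),
      n_orphans = del$n_orphans,
      orphan_fraction = del$orphan_fraction,
      ks = ks,
      top_bc = top_bc
    ),
    workload = list(
      top_chaperones = utils::head(as.data.frame(workload), top_k),
      total_flux = attr(workload, "total_flux"),
      deletion_extra = utils::head(as.data.frame(impact), top_k),
      orphaned_flux = attr(impact, "orphaned_flux"),
      family_split = as.list(attr(impact, "family_split")),
      bc_workload_spearman = as.numeric(rho)
    ),
    objects = list(network = network, quant = quant,
                   wt_profile = wt_profile, mutant = del,
                   workload = workload, impact = impact,
                   ground_truth = ground_truth)
  ), class = "chaperome_report")

  if (!is.null(outdir)) write_report_artifacts(report, silac, abundance,
                                               turnover, outdir)
  report
}

write_report_artifacts <- function(report, silac, abundance, turnover,
                                   outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  network <- report$objects$network
  write_edges_tsv(as.data.frame(igraph::as_edgelist(network)),
                  file.path(outdir, "edges.tsv"))
  write_abundance_tsv(abundance, file.path(outdir, "abundance.tsv"))
  write_turnover_tsv(turnover, file.path(outdir, "turnover.tsv"))
  write_intensity_tsv(silac, file.path(outdir, "intensity.tsv"))
  write_quant_tsv(report$objects$quant, file.path(outdir, "quant.tsv"))
  write_topology_tsv(report$objects$wt_profile,
                     file.path(outdir, "topology_wt.tsv"))
  write_topology_tsv(node_topology(report$objects$mutant$network),
                     file.path(outdir, "topology_mutant.tsv"))
  write_workload_tsv(report$objects$workload,
                     file.path(outdir, "workload.tsv"))
  utils::write.table(as.data.frame(report$objects$impact),
                     file.path(outdir, "deletion_impact.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$objects$ground_truth))
    write_ground_truth_json(report$objects$ground_truth,
                            file.path(outdir, "ground_truth.json"))
  write_report_json(report, file.path(outdir, "report.json"))
  invisible(outdir)
}

#' Write a pipeline report as JSON
#'
#' Serializes the summary sections of a [run_pipeline()] report (not the
#' full stage objects) to a versioned JSON document.
#'
#' @param report A `chaperome_report`.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  out <- report[c("provenance", "quant", "topology", "workload")]
  out$schema_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @export
print.chaperome_report <- function(x, ...) {
  cat("Chaperome pipeline report\n")
  cat(sprintf("  mode: %s (config hash %s)\n", x$provenance$mode,
              x$provenance$config_hash))
  q <- x$quant
  cat(sprintf("  quant: %d/%d proteins pass filter; shift raw %.3f -> normalized %.3f; %d raw / %d adj significant\n",
              q$n_passing_filter, q$n_input, q$median_fold_change_raw,
              q$median_fold_change_normalized, q$n_significant_raw,
              q$n_significant_adj))
  t <- x$topology
  cat(sprintf("  topology: WT %d nodes / %d edges; delete %s -> %d nodes / %d edges, %d orphans (%.1f%%)\n",
              t$wt_nodes, t$wt_edges, t$deleted, t$mutant_nodes,
              t$mutant_edges, t$n_orphans, 100 * t$orphan_fraction))
  w <- x$workload
  cat(sprintf("  workload: total flux %.4g cpc/min; deletion orphaned %.4g; BC-workload Spearman (top %d) %.3f\n",
              w$total_flux, w$orphaned_flux,
              nrow(w$top_chaperones), w$bc_workload_spearman))
  invisible(x)
}
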