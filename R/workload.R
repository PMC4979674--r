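#' Canonical yeast HSP70 family members
#'
#' The default id set used for HSP70-vs-other workload splits: cytosolic
#' SSA/SSB/SSE/SSZ members plus the mitochondrial and ER HSP70s.
#'
#' @return Character vector of gene names.
#' @export
hsp70_family <- function() {
  c("SSA1", "SSA2", "SSA3", "SSA4",
    "SSB1", "SSB2",
    "SSC1", "SSQ1", "ECM10",
    "SSE1", "SSE2", "SSZ1",
    "KAR2", "LHS1")
}

#' Protein synthesis rate at steady state
#'
#' At steady state (constant concentration), synthesis balances degradation,
#' so `k_syn = cpc * k_deg` (copies per cell per minute).
#'
#' @param cpc Copies per cell (>= 0), vectorized.
#' @param kdeg Degradation rate constant per minute (> 0), vectorized.
#' @return Synthesis rate, copies per cell per minute.
#' @export
synthesis_rate <- function(cpc, kdeg) {
  if (any(cpc < 0, na.rm = TRUE)) abort("abundance must be non-negative")
  if (any(kdeg <= 0, na.rm = TRUE)) abort("'kdeg' must be positive")
  cpc * kdeg
}

#' Convert a half-life to a degradation rate constant
#'
#' First-order decay: `k_deg = ln(2) / t_half`.
#'
#' @param t_half Half-life in minutes (> 0), vectorized.
#' @return Rate constant per minute.
#' @export
half_life_to_kdeg <- function(t_half) {
  if (any(t_half <= 0, na.rm = TRUE)) abort("half-life must be positive")
  log(2) / t_half
}

#' Impute missing degradation rates with the geometric mean
#'
#' Replaces missing `kdeg` entries with the geometric mean of the observed
#' ones, which leaves the geometric mean of the completed table unchanged.
#'
#' @param turnover Data frame with columns `protein`, `kdeg` (`NA` =
#'   missing) and optionally `missing`.
#' @return The completed data frame; `missing`/`imputed` flags record which
#'   entries were filled, and attribute `imputed_value` holds the value used.
#' @export
impute_kdeg <- function(turnover) {
  if (!all(c("protein", "kdeg") %in% names(turnover)))
    abort("'turnover' must have columns 'protein' and 'kdeg'")
  obs <- turnover$kdeg[!is.na(turnover$kdeg)]
  if (length(obs) == 0L) abort("all k_deg values are missing; cannot impute")
  gm <- geometric_mean(obs)
  miss <- is.na(turnover$kdeg)
  turnover$kdeg[miss] <- gm
  turnover$imputed <- miss
  structure(turnover, imputed_value = gm, n_imputed = sum(miss))
}

## substrate -> chaperone incidence from a graph or an explicit edge subset
.substrate_chaperone_edges <- function(network, interaction_subset = NULL) {
  roles <- stats::setNames(igraph::V(network)$role, igraph::V(network)$name)
  if (is.null(interaction_subset)) {
    el <- igraph::as_edgelist(network)
  } else {
    el <- as.matrix(as.data.frame(interaction_subset)[, 1:2])
    known <- el[, 1] %in% names(roles) & el[, 2] %in% names(roles)
    el <- el[known, , drop = FALSE]
  }
  if (nrow(el) == 0L)
    return(data.frame(substrate = character(0), chaperone = character(0)))
  r1 <- roles[el[, 1]]; r2 <- roles[el[, 2]]
  ## keep chaperone-substrate pairs only; chaperone-chaperone edges carry no
  ## substrate folding flux
  cs <- r1 == "chaperone" & r2 == "substrate"
  sc <- r1 == "substrate" & r2 == "chaperone"
  out <- rbind(data.frame(substrate = el[cs, 2], chaperone = el[cs, 1],
                          stringsAsFactors = FALSE),
               data.frame(substrate = el[sc, 1], chaperone = el[sc, 2],
                          stringsAsFactors = FALSE))
  unique(out)
}

#' Chaperone folding workload
#'
#' Estimates each chaperone's folding flux `F_c` as the sum over its
#' substrates of the substrate synthesis rate `k_syn = cpc * k_deg`, divided
#' equally pro rata among the chaperones that interact with the substrate: a
#' substrate bound by `m` chaperones contributes `k_syn / m` to each. When a
#' high-confidence `interaction_subset` is supplied, both the flux scope and
#' the multiplicity `m` are taken from that subset.
#'
#' @param network An `igraph` chaperome graph with `role` vertex attributes.
#' @param abundance Data frame `protein`, `cpc` (copies per cell).
#' @param turnover Data frame `protein`, `kdeg`; missing values are imputed
#'   with [impute_kdeg()].
#' @param interaction_subset Optional two-column edge list restricting the
#'   interactions used (e.g. a filtered high-quality subset).
#' @return An object of class `workload_profile`: data frame `chaperone`,
#'   `flux` (copies/cell/min), `n_substrates`; attributes `ledger` (per
#'   substrate-chaperone share), `total_flux`, `skipped_substrates` (no
#'   abundance record), `n_imputed_kdeg`.
#' @export
chaperone_workload <- function(network, abundance, turnover,
                               interaction_subset = NULL) {
  edges <- .substrate_chaperone_edges(network, interaction_subset)
  turnover <- impute_kdeg(turnover)
  substrates <- unique(edges$substrate)
  have <- substrates %in% abundance$protein & substrates %in% turnover$protein
  skipped <- substrates[!have]
  edges <- edges[edges$substrate %in% substrates[have], , drop = FALSE]

  cpc <- stats::setNames(abundance$cpc, abundance$protein)
  kdeg <- stats::setNames(turnover$kdeg, turnover$protein)
  ksyn <- synthesis_rate(cpc[edges$substrate], kdeg[edges$substrate])
  m <- table(edges$substrate)[edges$substrate]
  ledger <- data.frame(substrate = edges$substrate,
                       chaperone = edges$chaperone,
                       share = as.numeric(ksyn / as.integer(m)),
                       stringsAsFactors = FALSE)

  chaps <- igraph::V(network)$name[igraph::V(network)$role == "chaperone"]
  flux <- stats::setNames(rep(0, length(chaps)), chaps)
  agg <- tapply(ledger$share, ledger$chaperone, sum)
  flux[names(agg)] <- as.numeric(agg)
  nsub <- stats::setNames(rep(0L, length(chaps)), chaps)
  cnt <- table(ledger$chaperone)
  nsub[names(cnt)] <- as.integer(cnt)

  out <- data.frame(chaperone = chaps, flux = unname(flux),
                    n_substrates = unname(nsub), stringsAsFactors = FALSE)
  out <- out[order(-out$flux), ]
  rownames(out) <- NULL
  structure(out,
            ledger = ledger,
            total_flux = sum(ledger$share),
            skipped_substrates = skipped,
            n_imputed_kdeg = attr(turnover, "n_imputed"),
            class = c("workload_profile", "data.frame"))
}

#' @export
print.workload_profile <- function(x, n = 10L, ...) {
  cat(sprintf("Chaperone workload: %d chaperones, total flux %.4g copies/cell/min\n",
              nrow(x), attr(x, "total_flux")))
  if (length(attr(x, "skipped_substrates")))
    cat(sprintf("  %d substrate(s) skipped (no abundance/turnover record)\n",
                length(attr(x, "skipped_substrates"))))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Workload redistribution after a chaperone deletion
#'
#' When a chaperone is deleted, each substrate share it held is
#' redistributed equally among that substrate's remaining chaperones; shares
#' of substrates with no remaining chaperone are counted as orphaned flux.
#' The per-chaperone extra workload is additionally split between the HSP70
#' family and other chaperones.
#'
#' @param profile A [chaperone_workload()] result.
#' @param deleted Chaperone id to delete.
#' @param hsp70_ids Ids counted as HSP70 family (default [hsp70_family()]).
#' @return An object of class `deletion_impact`: data frame `chaperone`,
#'   `extra_workload`; attributes `deleted`, `deleted_flux`,
#'   `orphaned_flux`, `family_split` (named vector `hsp70`/`other`),
#'   `n_orphaned_substrates`.
#' @export
deletion_extra_workload <- function(profile, deleted,
                                    hsp70_ids = hsp70_family()) {
  ledger <- attr(profile, "ledger")
  if (!deleted %in% profile$chaperone)
    abort("unknown chaperone '%s'", deleted)
  mine <- ledger[ledger$chaperone == deleted, , drop = FALSE]
  others <- ledger[ledger$chaperone != deleted, , drop = FALSE]

  extra <- stats::setNames(rep(0, nrow(profile)), profile$chaperone)
  orphaned <- 0
  n_orphaned <- 0L
  if (nrow(mine) > 0) {
    remaining <- split(others$chaperone, others$substrate)
    for (i in seq_len(nrow(mine))) {
      s <- mine$substrate[i]
      rem <- remaining[[s]]
      if (is.null(rem) || length(rem) == 0L) {
        orphaned <- orphaned + mine$share[i]
        n_orphaned <- n_orphaned + 1L
      } else {
        extra[rem] <- extra[rem] + mine$share[i] / length(rem)
      }
    }
  }
  extra <- extra[names(extra) != deleted]
  fam <- names(extra) %in% hsp70_ids
  out <- data.frame(chaperone = names(extra), extra_workload = unname(extra),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$extra_workload), ]
  rownames(out) <- NULL
  structure(out,
            deleted = deleted,
            deleted_flux = profile$flux[profile$chaperone == deleted],
            orphaned_flux = orphaned,
            n_orphaned_substrates = n_orphaned,
            family_split = c(hsp70 = sum(extra[fam]),
                             other = sum(extra[!fam])),
            class = c("deletion_impact", "data.frame"))
}

#' @export
print.deletion_impact <- function(x, n = 10L, ...) {
  fam <- attr(x, "family_split")
  cat(sprintf("Deletion of %s: flux %.4g redistributed, %.4g orphaned (%d substrate(s))\n",
              attr(x, "deleted"), attr(x, "deleted_flux") - attr(x, "orphaned_flux"),
              attr(x, "orphaned_flux"), attr(x, "n_orphaned_substrates")))
  cat(sprintf("  extra workload: HSP70 family %.4g, other chaperones %.4g\n",
              fam["hsp70"], fam["other"]))
  print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Spearman correlation between betweenness and workload
#'
#' Rank correlation between betweenness centrality and folding workload over
#' the `top_n` chaperones ranked by betweenness.
#'
#' @param profile A [node_topology()] data frame.
#' @param workload A [chaperone_workload()] result.
#' @param top_n Number of top-betweenness chaperones to use (default 15).
#' @return Spearman rho (a single number), with attribute `n_used`.
#' @export
bc_workload_correlation <- function(profile, workload, top_n = 15L) {
  chap <- profile[profile$role == "chaperone", c("node", "betweenness")]
  merged <- merge(chap, workload[, c("chaperone", "flux")],
                  by.x = "node", by.y = "chaperone")
  if (nrow(merged) < 3L)
    abort("need at least 3 chaperones with both betweenness and workload")
  merged <- merged[order(-merged$betweenness), ]
  merged <- utils::head(merged, top_n)
  rho <- stats::cor(merged$betweenness, merged$flux, method = "spearman")
  structure(rho, n_used = nrow(merged))
}
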