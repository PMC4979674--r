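#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: a hub-dominated
#' chaperone--substrate network, log-normal abundances and degradation rates,
#' and replicate SILAC experiments with multiplicative noise, a global
#' light:heavy mixing shift, spiked differentially abundant proteins and
#' missing-at-random dropout.
#'
#' Defaults emulate a scaled-down yeast chaperome experiment: 63 chaperones,
#' 2000 substrates with about five chaperone partners each, biological
#' quadruplicates, log2 replicate noise of 0.3 and 10% random dropout.
#' Degradation rates default to a median around 0.01 per minute (roughly a
#' 70 minute half-life); abundances to a median of 5000 copies per cell.
#'
#' @param n_chaperones Number of chaperone nodes (>= 1).
#' @param n_substrates Number of substrate nodes (>= 1).
#' @param mean_substrate_multiplicity Average number of chaperones bound per
#'   substrate (>= 1).
#' @param hub_exponent Preferential-attachment strength; substrates pick
#'   chaperones with probability proportional to `(degree + 1)^hub_exponent`.
#'   0 gives uniform attachment, larger values stronger hubs.
#' @param chaperone_edge_prob Probability of an edge between each pair of
#'   chaperones.
#' @param abundance_log_mean,abundance_log_sd Natural-log mean/sd of protein
#'   abundance (copies per cell).
#' @param kdeg_log_mean,kdeg_log_sd Natural-log mean/sd of the degradation
#'   rate constant (per minute).
#' @param kdeg_missing_frac Fraction of degradation rates flagged missing.
#' @param n_replicates Number of biological replicates per SILAC experiment.
#' @param global_shift Light:heavy cell-equivalent mixing factor (> 0); 1 is
#'   an equal mix, 2 doubles every light intensity.
#' @param de_fraction Fraction of proteins spiked as differentially abundant.
#' @param de_log2_effect_sd Standard deviation of the (two-sided, normal)
#'   log2 spike effects.
#' @param noise_log2_sd Replicate log2 intensity noise (> 0).
#' @param dropout_prob Per-cell probability that an intensity is missing.
#' @param seed Integer seed; the same config and seed reproduce identical
#'   output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chaperones = 63L,
                       n_substrates = 2000L,
                       mean_substrate_multiplicity = 5,
                       hub_exponent = 1,
                       chaperone_edge_prob = 0.05,
                       abundance_log_mean = log(5000),
                       abundance_log_sd = 1.5,
                       kdeg_log_mean = log(0.01),
                       kdeg_log_sd = 1,
                       kdeg_missing_frac = 0.3,
                       n_replicates = 4L,
                       global_shift = 1,
                       de_fraction = 0,
                       de_log2_effect_sd = 1,
                       noise_log2_sd = 0.3,
                       dropout_prob = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_chaperones = as.integer(n_chaperones),
    n_substrates = as.integer(n_substrates),
    mean_substrate_multiplicity = mean_substrate_multiplicity,
    hub_exponent = hub_exponent,
    chaperone_edge_prob = chaperone_edge_prob,
    abundance_log_mean = abundance_log_mean,
    abundance_log_sd = abundance_log_sd,
    kdeg_log_mean = kdeg_log_mean,
    kdeg_log_sd = kdeg_log_sd,
    kdeg_missing_frac = kdeg_missing_frac,
    n_replicates = as.integer(n_replicates),
    global_shift = global_shift,
    de_fraction = de_fraction,
    de_log2_effect_sd = de_log2_effect_sd,
    noise_log2_sd = noise_log2_sd,
    dropout_prob = dropout_prob,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chaperones", "n_substrates", "n_replicates")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      abort("configuration error: '%s' must be a positive count", nm)
  }
  probs <- c("chaperone_edge_prob", "kdeg_missing_frac", "de_fraction",
             "dropout_prob")
  for (nm in probs) {
    stopifnot_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      abort("configuration error: '%s' must lie in [0, 1]", nm)
  }
  for (nm in c("abundance_log_sd", "kdeg_log_sd", "noise_log2_sd",
               "de_log2_effect_sd")) {
    stopifnot_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] < 0)
      abort("configuration error: '%s' must be non-negative", nm)
  }
  stopifnot_scalar_number(cfg$mean_substrate_multiplicity,
                          "mean_substrate_multiplicity")
  if (cfg$mean_substrate_multiplicity < 1)
    abort("configuration error: 'mean_substrate_multiplicity' must be >= 1")
  stopifnot_scalar_number(cfg$hub_exponent, "hub_exponent")
  if (cfg$hub_exponent < 0)
    abort("configuration error: 'hub_exponent' must be >= 0")
  stopifnot_scalar_number(cfg$global_shift, "global_shift")
  if (cfg$global_shift <= 0)
    abort("configuration error: 'global_shift' must be > 0")
  if (is.na(cfg$seed))
    abort("configuration error: 'seed' must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic chaperome experiment configuration\n")
  cat(sprintf("  network : %d chaperones, %d substrates, multiplicity %.2f, hub exponent %.2f\n",
              x$n_chaperones, x$n_substrates, x$mean_substrate_multiplicity,
              x$hub_exponent))
  cat(sprintf("  SILAC   : %d replicates, shift %.3g, DE fraction %.3g, noise sd(log2) %.3g, dropout %.3g\n",
              x$n_replicates, x$global_shift, x$de_fraction, x$noise_log2_sd,
              x$dropout_prob))
  cat(sprintf("  seed    : %d\n", x$seed))
  invisible(x)
}

#' Generate a synthetic chaperome network
#'
#' Builds an undirected simple graph of chaperones and substrates. Each
#' substrate attaches to at least one chaperone; chaperones are drawn with
#' probability proportional to `(current degree + 1)^hub_exponent`, so larger
#' exponents concentrate substrates on a few hubs, reproducing the
#' hub-dominated shape of measured chaperome interactomes. Chaperone pairs
#' are additionally connected independently with `chaperone_edge_prob`.
#'
#' @param config A [sim_config()].
#' @return An `igraph` object with a `role` vertex attribute
#'   (`"chaperone"`/`"substrate"`) and a `provenance` graph attribute
#'   (`"wild-type"`).
#' @export
generate_network <- function(config) {
  validate_sim_config(config)
  if (config$n_chaperones < 1L)
    abort("configuration error: need at least one chaperone")
  set.seed(derive_seed(config$seed, 11L))

  chap_ids <- sprintf("CH%03d", seq_len(config$n_chaperones))
  sub_ids <- sprintf("S%05d", seq_len(config$n_substrates))

  deg <- rep(0L, config$n_chaperones)
  from <- character(0)
  to <- character(0)
  extra <- config$mean_substrate_multiplicity - 1
  for (i in seq_len(config$n_substrates)) {
    m <- 1L + stats::rpois(1L, extra)
    m <- min(m, config$n_chaperones)
    w <- (deg + 1)^config$hub_exponent
    picked <- if (config$n_chaperones == 1L) 1L else
      sample.int(config$n_chaperones, m, replace = FALSE, prob = w)
    deg[picked] <- deg[picked] + 1L
    from <- c(from, chap_ids[picked])
    to <- c(to, rep(sub_ids[i], m))
  }

  if (config$n_chaperones >= 2L && config$chaperone_edge_prob > 0) {
    pairs <- utils::combn(config$n_chaperones, 2L)
    keep <- stats::runif(ncol(pairs)) < config$chaperone_edge_prob
    if (any(keep)) {
      from <- c(from, chap_ids[pairs[1L, keep]])
      to <- c(to, chap_ids[pairs[2L, keep]])
    }
  }

  roles <- c(stats::setNames(rep("chaperone", length(chap_ids)), chap_ids),
             stats::setNames(rep("substrate", length(sub_ids)), sub_ids))
  build_graph(data.frame(from = from, to = to, stringsAsFactors = FALSE),
              roles = roles, nodes = c(chap_ids, sub_ids))
}

#' Generate synthetic abundance and turnover tables
#'
#' Draws copies-per-cell abundances and first-order degradation rate
#' constants log-normally with the configured parameters, and flags a
#' configured fraction of degradation rates as missing (to be imputed
#' downstream with [impute_kdeg()]).
#'
#' @param config A [sim_config()].
#' @param proteins Character vector of protein ids (non-empty).
#' @return A list with `abundance` (data frame: `protein`, `cpc`),
#'   `turnover` (data frame: `protein`, `kdeg`, `missing`), and
#'   `ground_truth` (true abundance and kdeg per protein).
#' @export
generate_abundance_turnover <- function(config, proteins) {
  validate_sim_config(config)
  if (length(proteins) == 0L) abort("'proteins' must be non-empty")
  set.seed(derive_seed(config$seed, 23L))
  n <- length(proteins)
  cpc <- stats::rlnorm(n, config$abundance_log_mean, config$abundance_log_sd)
  kdeg <- stats::rlnorm(n, config$kdeg_log_mean, config$kdeg_log_sd)
  missing <- stats::runif(n) < config$kdeg_missing_frac
  abundance <- data.frame(protein = proteins, cpc = cpc,
                          stringsAsFactors = FALSE)
  turnover <- data.frame(protein = proteins,
                         kdeg = ifelse(missing, NA_real_, kdeg),
                         missing = missing, stringsAsFactors = FALSE)
  ground_truth <- list(true_abundance = stats::setNames(cpc, proteins),
                       true_kdeg = stats::setNames(kdeg, proteins))
  list(abundance = abundance, turnover = turnover,
       ground_truth = ground_truth)
}

#' Generate a synthetic SILAC experiment
#'
#' Simulates replicate heavy/light MS1 intensities for a knockout-vs-reference
#' mix. On the log2 scale, heavy intensities are `log2(a_i) + e`, light
#' intensities `log2(a_i) + log2(global_shift) + d_i + e`, where `a_i` is the
#' protein abundance, `d_i` a spiked log2 effect for the differentially
#' abundant subset (0 otherwise) and `e` independent normal noise with sd
#' `noise_log2_sd`. Each cell is then dropped out (set missing) independently
#' with `dropout_prob`.
#'
#' @param config A [sim_config()].
#' @param abundance Abundance data frame (`protein`, `cpc`) covering all
#'   proteins to simulate.
#' @param strain Strain label stored with the matrix.
#' @return A list with `silac` (a `silac_matrix` data frame: `protein`,
#'   `intensity_H_rep1..n`, `intensity_L_rep1..n`) and `ground_truth`
#'   (`true_global_shift`, `true_de_set`, `true_de_effects`).
#' @export
generate_silac_experiment <- function(config, abundance, strain = "synthetic") {
  validate_sim_config(config)
  if (!all(c("protein", "cpc") %in% names(abundance)))
    abort("'abundance' must have columns 'protein' and 'cpc'")
  set.seed(derive_seed(config$seed, 37L))

  proteins <- abundance$protein
  n <- length(proteins)
  R <- config$n_replicates
  base_log2 <- log2(abundance$cpc)

  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  delta <- numeric(n)
  if (n_de > 0)
    delta[de_idx] <- stats::rnorm(n_de, 0, config$de_log2_effect_sd)

  H <- matrix(2^(base_log2 + stats::rnorm(n * R, 0, config$noise_log2_sd)),
              nrow = n, ncol = R)
  L <- matrix(2^(rep(base_log2 + log2(config$global_shift) + delta, R) +
                   stats::rnorm(n * R, 0, config$noise_log2_sd)),
              nrow = n, ncol = R)
  if (config$dropout_prob > 0) {
    H[matrix(stats::runif(n * R) < config$dropout_prob, n, R)] <- NA_real_
    L[matrix(stats::runif(n * R) < config$dropout_prob, n, R)] <- NA_real_
  }

  silac <- silac_matrix(proteins, H, L, strain = strain)
  ground_truth <- list(
    true_global_shift = config$global_shift,
    true_de_set = proteins[de_idx],
    true_de_effects = stats::setNames(delta[de_idx], proteins[de_idx])
  )
  list(silac = silac, ground_truth = ground_truth)
}

#' Generate an unequal-mix SILAC standard
#'
#' Simulates a spike-in standard obtained by mixing heavy and light cells in
#' a known unequal ratio: no differentially abundant proteins, and the light
#' channel scaled by `1/ratio` cell equivalents. A standard mixed at
#' heavy:light 0.4 therefore has an expected median log2(L/H) of
#' `log2(2.5)`.
#'
#' @param ratio Heavy:light cell-equivalent mixing ratio (> 0).
#' @param config A [sim_config()]; `de_fraction` and `global_shift` are
#'   overridden.
#' @param strain Strain label.
#' @return As [generate_silac_experiment()].
#' @export
generate_mix_standard <- function(ratio, config, strain = "standard") {
  stopifnot_scalar_number(ratio, "ratio")
  if (ratio <= 0) abort("configuration error: 'ratio' must be > 0")
  cfg <- config
  cfg$de_fraction <- 0
  cfg$global_shift <- 1 / ratio
  validate_sim_config(cfg)
  abt <- generate_abundance_turnover(cfg,
                                     sprintf("P%05d", seq_len(cfg$n_substrates)))
  generate_silac_experiment(cfg, abt$abundance, strain = strain)
}
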