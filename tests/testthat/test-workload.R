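## two chaperones A, B (and C where needed) sharing hand-ledgered substrates
toy_network <- function(edges) {
  roles <- c(A = "chaperone", B = "chaperone", C = "chaperone")
  build_graph(edges, roles = roles)
}

test_that("synthesis rate and half-life conversion are exact", {
  expect_equal(synthesis_rate(1000, 0.01), 10)
  expect_equal(synthesis_rate(0, 0.5), 0)
  expect_equal(synthesis_rate(500, 0.002), 1)
  expect_error(synthesis_rate(100, 0), "positive")
  expect_error(synthesis_rate(-1, 0.1), "non-negative")

  expect_equal(half_life_to_kdeg(log(2)), 1)
  expect_equal(half_life_to_kdeg(69.3), log(2) / 69.3)
  expect_equal(half_life_to_kdeg(69.3), 0.01, tolerance = 1e-3)
  expect_true(half_life_to_kdeg(1e6) < half_life_to_kdeg(10))
  expect_error(half_life_to_kdeg(0), "positive")
})

test_that("geometric-mean imputation preserves the geometric mean", {
  tab <- data.frame(protein = c("a", "b", "c"),
                    kdeg = c(0.01, 0.04, NA))
  out <- impute_kdeg(tab)
  expect_equal(out$kdeg[3], 0.02)
  expect_equal(out$imputed, c(FALSE, FALSE, TRUE))
  expect_equal(geometric_mean(out$kdeg), geometric_mean(c(0.01, 0.04)))

  full <- data.frame(protein = c("a", "b"), kdeg = c(0.1, 0.2))
  expect_equal(impute_kdeg(full)$kdeg, c(0.1, 0.2))

  flat <- data.frame(protein = letters[1:5],
                     kdeg = c(0.02, 0.02, 0.02, NA, NA))
  out2 <- impute_kdeg(flat)
  expect_equal(out2$kdeg, rep(0.02, 5))

  expect_error(impute_kdeg(data.frame(protein = "a", kdeg = NA_real_)),
               "all k_deg")
})

test_that("workload splits substrate flux pro rata and conserves totals", {
  ## s1: ksyn 10 shared by A, B -> 5 each
  net <- toy_network(data.frame(from = c("A", "B"), to = c("s1", "s1")))
  ab <- data.frame(protein = "s1", cpc = 1000)
  tu <- data.frame(protein = "s1", kdeg = 0.01)
  w <- chaperone_workload(net, ab, tu)
  expect_equal(w$flux[w$chaperone == "A"], 5)
  expect_equal(w$flux[w$chaperone == "B"], 5)

  ## single chaperone takes the whole flux
  net1 <- toy_network(data.frame(from = "A", to = "s1"))
  w1 <- chaperone_workload(net1, ab, tu)
  expect_equal(w1$flux[w1$chaperone == "A"], 10)

  ## hand ledger: s1 (ksyn 6, A/B/C), s2 (ksyn 4, A)
  net2 <- toy_network(data.frame(from = c("A", "B", "C", "A"),
                                 to = c("s1", "s1", "s1", "s2")))
  ab2 <- data.frame(protein = c("s1", "s2"), cpc = c(600, 400))
  tu2 <- data.frame(protein = c("s1", "s2"), kdeg = c(0.01, 0.01))
  w2 <- chaperone_workload(net2, ab2, tu2)
  flux <- setNames(w2$flux, w2$chaperone)
  expect_equal(unname(flux["A"]), 6)
  expect_equal(unname(flux["B"]), 2)
  expect_equal(unname(flux["C"]), 2)
  expect_equal(attr(w2, "total_flux"), 10)
  ledger <- attr(w2, "ledger")
  for (ch in names(flux))
    expect_equal(unname(flux[ch]), sum(ledger$share[ledger$chaperone == ch]),
                 tolerance = 1e-12)

  ## substrates without abundance are skipped and reported
  net3 <- toy_network(data.frame(from = c("A", "A"), to = c("s1", "s9")))
  w3 <- chaperone_workload(net3, ab, tu)
  expect_equal(attr(w3, "skipped_substrates"), "s9")
  expect_equal(w3$flux[w3$chaperone == "A"], 10)
})

test_that("an explicit interaction subset restricts scope and multiplicity", {
  net <- toy_network(data.frame(from = c("A", "B"), to = c("s1", "s1")))
  ab <- data.frame(protein = "s1", cpc = 1000)
  tu <- data.frame(protein = "s1", kdeg = 0.01)
  sub <- data.frame(from = "A", to = "s1")
  w <- chaperone_workload(net, ab, tu, interaction_subset = sub)
  expect_equal(w$flux[w$chaperone == "A"], 10)
  expect_equal(w$flux[w$chaperone == "B"], 0)
})

test_that("deletion redistributes shares to remaining chaperones exactly", {
  ## substrate share 5 held by deleted A, remaining {B} -> B gains 5
  net <- toy_network(data.frame(from = c("A", "B"), to = c("s1", "s1")))
  ab <- data.frame(protein = "s1", cpc = 1000)
  tu <- data.frame(protein = "s1", kdeg = 0.01)
  w <- chaperone_workload(net, ab, tu)
  imp <- deletion_extra_workload(w, "A")
  expect_equal(imp$extra_workload[imp$chaperone == "B"], 5)
  expect_equal(attr(imp, "orphaned_flux"), 0)

  ## substrate bound only by the deleted chaperone -> orphaned flux
  net1 <- toy_network(data.frame(from = "A", to = "s1"))
  w1 <- chaperone_workload(net1, ab, tu)
  imp1 <- deletion_extra_workload(w1, "A")
  expect_equal(attr(imp1, "orphaned_flux"), 10)
  expect_equal(attr(imp1, "n_orphaned_substrates"), 1)
  expect_true(all(imp1$extra_workload == 0))

  ## hand redistribution: A holds s1 share 2 (remaining B, C) and s2 share 3
  ## (remaining B) -> B +4, C +1
  net2 <- toy_network(data.frame(from = c("A", "B", "C", "A", "B"),
                                 to = c("s1", "s1", "s1", "s2", "s2")))
  ab2 <- data.frame(protein = c("s1", "s2"), cpc = c(600, 600))
  tu2 <- data.frame(protein = c("s1", "s2"), kdeg = c(0.01, 0.01))
  w2 <- chaperone_workload(net2, ab2, tu2)
  imp2 <- deletion_extra_workload(w2, "A")
  extra <- setNames(imp2$extra_workload, imp2$chaperone)
  expect_equal(unname(extra["B"]), 4)
  expect_equal(unname(extra["C"]), 1)
  expect_equal(sum(imp2$extra_workload) + attr(imp2, "orphaned_flux"),
               attr(imp2, "deleted_flux"), tolerance = 1e-12)

  expect_error(deletion_extra_workload(w2, "ZZZ"), "unknown chaperone")
})

test_that("family split separates HSP70 gains from other chaperones", {
  roles <- c(SSA1 = "chaperone", SSB1 = "chaperone", CPR6 = "chaperone")
  net <- build_graph(data.frame(from = c("SSA1", "SSB1", "CPR6"),
                                to = c("s1", "s1", "s1")), roles = roles)
  ab <- data.frame(protein = "s1", cpc = 300)
  tu <- data.frame(protein = "s1", kdeg = 0.01)
  w <- chaperone_workload(net, ab, tu)
  imp <- deletion_extra_workload(w, "SSA1")
  fam <- attr(imp, "family_split")
  expect_equal(unname(fam["hsp70"]), 0.5)  # SSB1 gains 1/2
  expect_equal(unname(fam["other"]), 0.5)  # CPR6 gains 1/2
})

test_that("flux conservation and scale equivariance hold on generated networks", {
  for (seed in c(61L, 62L, 63L)) {
    cfg <- tiny_config(); cfg$seed <- seed
    g <- generate_network(cfg)
    abt <- generate_abundance_turnover(cfg, igraph::V(g)$name)
    w <- chaperone_workload(g, abt$abundance, abt$turnover)

    ## conservation: total flux equals the sum of ksyn over connected
    ## substrates (computed independently from the completed tables)
    tu <- impute_kdeg(abt$turnover)
    subs <- igraph::V(g)$name[igraph::V(g)$role == "substrate"]
    chap_nb <- vapply(subs, function(s) {
      any(igraph::V(g)$role[igraph::neighbors(g, s)] == "chaperone")
    }, logical(1))
    cpc <- setNames(abt$abundance$cpc, abt$abundance$protein)
    kdeg <- setNames(tu$kdeg, tu$protein)
    expected_total <- sum(cpc[subs[chap_nb]] * kdeg[subs[chap_nb]])
    expect_equal(sum(w$flux), expected_total,
                 tolerance = 1e-9 * expected_total)

    ## redistribution conservation for every chaperone
    for (ch in w$chaperone) {
      imp <- deletion_extra_workload(w, ch)
      lhs <- sum(imp$extra_workload) + attr(imp, "orphaned_flux")
      expect_equal(lhs, w$flux[w$chaperone == ch],
                   tolerance = 1e-9 * max(1, lhs))
    }

    ## scale equivariance: scaling abundance scales all fluxes
    ab10 <- abt$abundance; ab10$cpc <- ab10$cpc * 10
    w10 <- chaperone_workload(g, ab10, abt$turnover)
    expect_equal(w10$flux, w$flux * 10, tolerance = 1e-12)
  }
})

test_that("uniform inputs rank chaperones by substrate degree", {
  cfg <- tiny_config()
  g <- generate_network(cfg)
  ids <- igraph::V(g)$name
  ab <- data.frame(protein = ids, cpc = 100)
  tu <- data.frame(protein = ids, kdeg = 0.01)
  w <- chaperone_workload(g, ab, tu)
  ## brute-force ledger oracle: share = sum over substrate neighbours of
  ## ksyn / multiplicity
  roles <- setNames(igraph::V(g)$role, ids)
  oracle <- vapply(w$chaperone, function(ch) {
    nb <- igraph::neighbors(g, ch)$name
    nb <- nb[roles[nb] == "substrate"]
    sum(vapply(nb, function(s) {
      m <- sum(roles[igraph::neighbors(g, s)$name] == "chaperone")
      1 / m
    }, numeric(1)))
  }, numeric(1)) * 100 * 0.01
  expect_equal(w$flux, unname(oracle), tolerance = 1e-9)
})

test_that("betweenness-workload Spearman matches hand-ranked cases", {
  prof <- data.frame(node = c("A", "B", "C", "D"),
                     role = "chaperone",
                     betweenness = c(0.4, 0.3, 0.2, 0.1))
  up <- structure(data.frame(chaperone = c("A", "B", "C", "D"),
                             flux = c(40, 30, 20, 10)),
                  class = c("workload_profile", "data.frame"))
  expect_equal(as.numeric(bc_workload_correlation(prof, up, top_n = 4)), 1)

  down <- up; down$flux <- rev(down$flux)
  expect_equal(as.numeric(bc_workload_correlation(prof, down, top_n = 4)), -1)

  ## BC ranks (1,2,3,4) against workload ranks (2,1,3,4): rho = 0.8
  mixed <- up; mixed$flux <- c(30, 40, 20, 10)
  expect_equal(as.numeric(bc_workload_correlation(prof, mixed, top_n = 4)),
               0.8)

  expect_error(bc_workload_correlation(prof[1:2, ], up), "at least 3")
})
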