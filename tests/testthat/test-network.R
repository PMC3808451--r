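# small end-to-end state shared by the network tests
local_net_state <- function(scenario = "one_directed_edge", seed = 42,
                            n_perm = 50, level = 0.05) {
  fx <- make_fixture(scenario, seed = seed)
  nz <- normalize_phenotypes(fx$cross$pheno)
  basis <- eigentrait_decomp(nz$P_norm)
  fl <- enumerate_pairs(fx$cross)
  ps <- pair_scan(fx$cross, basis, tested_pairs(fl))
  inf <- estimate_influences(ps)
  nl <- build_null(ps, basis, n_perm = n_perm, seed = seed + 1)
  st <- significance_table(inf, nl, method = "fdr", level = level)
  main <- consolidate_main_effects(ps, basis, nl)
  net <- build_adjacency(st, main, fl, fx$cross, basis, nl,
                         method = "fdr", level = level)
  list(fx = fx, basis = basis, fl = fl, ps = ps, inf = inf, nl = nl,
       st = st, main = main, net = net)
}

test_that("main-effect consolidation keeps the most conservative pairing", {
  st <- local_net_state(seed = 1)
  me <- st$main$by_et
  # a marker in exactly one tested pair uses that pair's coefficient
  one_pair <- tibble::tibble(marker1 = "D1M1", marker2 = "D2M1")
  ps1 <- pair_scan(st$fx$cross, st$basis, one_pair)
  me1 <- consolidate_main_effects(ps1, st$basis, st$nl)
  row <- me1$by_et[me1$by_et$marker == "D1M1" & me1$by_et$et == 1, ]
  expect_equal(row$estimate, ps1$b1[ps1$et == 1])
  expect_equal(row$partner, "D2M1")
  # consolidated p per marker/ET is the max over pairings
  full <- dplyr::bind_rows(
    dplyr::transmute(dplyr::filter(st$ps, status == "resolved"),
                     marker = marker1, et, z = t1),
    dplyr::transmute(dplyr::filter(st$ps, status == "resolved"),
                     marker = marker2, et, z = t2))
  pmax_expected <- max(empirical_p(
    full$z[full$marker == "D8M1" & full$et == 1],
    st$nl$variant_phenotype))
  expect_equal(me$p[me$marker == "D8M1" & me$et == 1], pmax_expected)
})

test_that("an effect absorbed by a linked partner vanishes under consolidation", {
  # marker A carries the true effect; B is linked to A (20 cM) with no effect
  # of its own; C is an unlinked bystander. Paired with C, B shows a marginal
  # (borrowed) effect; paired with A, B's effect is explained away. The
  # conservative (max-p) consolidation must reflect the vanishing pairing.
  sim <- simulate_backcross(400, list(c(2, 20), c(1, 0)), seed = 31)
  me <- matrix(0, 3, 2, dimnames = list(sim$map$marker, c("ph1", "ph2")))
  me["D1M1", ] <- c(1, 0.6) # A; B = D1M2 has no effect; C = D2M1
  tr <- truth_model(me, noise_sd = 1, pheno_loadings = c(0.5, 0.5))
  P <- simulate_phenotypes(sim$geno, tr, seed = 32)
  x <- cross(P, sim$geno, sim$map)
  nz <- normalize_phenotypes(x$pheno)
  basis <- eigentrait_decomp(nz$P_norm)
  fl <- enumerate_pairs(x)
  ps <- pair_scan(x, basis, tested_pairs(fl))
  nl <- build_null(ps, basis, n_perm = 20, seed = 33)
  main <- consolidate_main_effects(ps, basis, nl)
  b_row <- main$by_et[main$by_et$marker == "D1M2" & main$by_et$et == 1, ]
  expect_equal(b_row$partner, "D1M1")
  # B's borrowed effect in the bystander pairing is clearly stronger
  borrowed <- abs(ps$t1[ps$marker1 == "D1M2" & ps$marker2 == "D2M1" &
                          ps$et == 1])
  expect_lt(abs(b_row$z), borrowed)
})

test_that("adjacency holds significant z weights with correct orientation", {
  st <- local_net_state(seed = 42)
  W <- st$net$weights
  expect_equal(rownames(W), st$net$markers)
  expect_equal(colnames(W), c(st$net$markers, st$net$phenotypes))
  # the planted suppressive edge is present, negative, and asymmetric
  expect_lt(W["D3M1", "D8M1"], 0)
  expect_equal(W["D8M1", "D3M1"], 0)
  # every nonzero marker-marker weight is exactly one significant table entry
  hit <- dplyr::filter(st$st, significant)
  nz <- which(W[, st$net$markers] != 0, arr.ind = TRUE)
  expect_equal(nrow(nz), nrow(hit))
  for (k in seq_len(nrow(nz))) {
    src <- rownames(W)[nz[k, 1]]
    tgt <- st$net$markers[nz[k, 2]]
    row <- hit[hit$source == src & hit$target == tgt, ]
    expect_equal(nrow(row), 1L)
    expect_equal(W[src, tgt], row$z)
  }
  # no self-edges
  expect_true(all(diag(W[, st$net$markers]) == 0))
})

test_that("tightening the level never adds edges (monotone nesting)", {
  st <- local_net_state(seed = 43, level = 0.2)
  lax <- st$net
  strict <- build_adjacency(
    significance_table(st$inf, st$nl, method = "fdr", level = 0.01),
    st$main, st$fl, st$fx$cross, st$basis, st$nl,
    method = "fdr", level = 0.01)
  lax_edges <- lax$weights != 0
  strict_edges <- strict$weights != 0
  expect_true(all(lax_edges[strict_edges]))
})

test_that("zero-significance networks are empty with correct shape", {
  st <- local_net_state("null", seed = 44, n_perm = 10, level = 1e-6)
  expect_true(all(st$net$weights == 0))
  expect_equal(dim(st$net$weights), c(20L, 22L))
  td <- tidy(st$net)
  expect_equal(nrow(td), 0)
})

test_that("untested pairs are masked and carry no weight", {
  # two tightly linked markers (d = 0.1 cM) are excluded by the LD rule
  sim <- simulate_backcross(150, list(c(2, 0.1), c(1, 0), c(1, 0)), seed = 3)
  me <- matrix(0, 4, 2, dimnames = list(sim$map$marker, c("ph1", "ph2")))
  tr <- truth_model(me, noise_sd = 1, pheno_loadings = c(0.7, 0.7))
  P <- simulate_phenotypes(sim$geno, tr, seed = 4)
  x <- cross(P, sim$geno, sim$map)
  nz <- normalize_phenotypes(x$pheno)
  basis <- eigentrait_decomp(nz$P_norm)
  fl <- enumerate_pairs(x)
  expect_true(any(fl$pairs$status == "excluded_ld"))
  ps <- pair_scan(x, basis, tested_pairs(fl))
  inf <- estimate_influences(ps)
  nl <- build_null(ps, basis, n_perm = 5, seed = 5)
  st <- significance_table(inf, nl)
  main <- consolidate_main_effects(ps, basis, nl)
  net <- build_adjacency(st, main, fl, x, basis, nl)
  expect_true(net$untested["D1M1", "D1M2"])
  expect_true(net$untested["D1M2", "D1M1"])
  expect_equal(net$weights["D1M1", "D1M2"], 0)
})

test_that("exports round-trip and GraphML parses with directed edges", {
  st <- local_net_state(seed = 42)
  f1 <- tempfile(fileext = ".csv")
  export_network(st$net, f1, "adjacency_csv")
  M <- read_adjacency_csv(f1)
  expect_equal(M, st$net$weights, tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", "_untested.csv", f1)))

  f2 <- tempfile(fileext = ".csv")
  export_network(st$net, f2, "edge_list")
  el <- utils::read.csv(f2)
  expect_equal(nrow(el), sum(st$net$weights != 0))
  expect_true(all(c("source", "target", "weight", "sign", "kind") %in%
                    names(el)))

  f3 <- tempfile(fileext = ".graphml")
  export_network(st$net, f3, "graphml")
  g <- igraph::read_graph(f3, format = "graphml")
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), sum(st$net$weights != 0))
  expect_error(export_network(st$net, tempfile(), "nope"), "arg")
})

test_that("covariate pseudo-markers order first and act as sources", {
  fx <- make_fixture("example_like", seed = 2)
  x <- promote_covariates(fx$cross, "mom")
  expect_equal(x$map$marker[1], "mom")
  fl <- enumerate_pairs(x)
  expect_true("mom" %in% c(fl$pairs$marker1, fl$pairs$marker2))
})
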