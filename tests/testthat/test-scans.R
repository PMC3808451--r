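test_that("single scan recovers exact and orthogonal constructions", {
  g <- matrix(rep(c(0, 1), each = 6), 12, 1, dimnames = list(NULL, "m1"))
  # ET equal to the centered marker: coefficient 1, zero residual
  et1 <- g[, 1]
  # second ET orthogonal to the marker (and the intercept) by construction
  et2 <- rep(c(-1, 1), 6)
  x <- toy_cross(g)
  b <- fake_basis(cbind(et1, et2))
  sc <- single_scan(x, b)
  expect_equal(sc$estimate[sc$et == 1], 1, tolerance = 1e-10)
  expect_equal(sc$estimate[sc$et == 2], 0, tolerance = 1e-10)
  expect_equal(sc$n_used, c(12L, 12L))
})

test_that("a marker doubling as covariate is flagged unresolved", {
  set.seed(1)
  g <- cbind(m1 = rbinom(20, 1, 0.5), m2 = rbinom(20, 1, 0.5))
  x <- toy_cross(g)
  b <- fake_basis(matrix(rnorm(40), 20, 2))
  sc <- single_scan(x, b, covariates = "m1")
  expect_true(all(sc$status[sc$marker == "m1"] == "unresolved"))
  expect_true(all(sc$status[sc$marker == "m2"] == "resolved"))
})

test_that("marker covariate selection filters on max |t| across ETs", {
  scan <- tibble::tibble(
    marker = rep(c("a", "b", "c"), each = 2), et = rep(1:2, 3),
    estimate = 1, se = 1,
    statistic = c(1, 0.5, -3, 1, 5, 2),
    n_used = 10L, status = "resolved"
  )
  expect_equal(select_marker_covariates(scan, 2), c("b", "c"))
  expect_equal(select_marker_covariates(scan, 1e6), character(0))
  expect_equal(select_marker_covariates(scan, 1e-9), c("a", "b", "c"))
})

test_that("LD filter counts two-locus classes and applies the minimum rule", {
  # identical columns: classes (0,1) and (1,0) empty -> excluded
  g <- cbind(a = rep(c(0, 1), each = 12), b = rep(c(0, 1), each = 12))
  fl <- enumerate_pairs(toy_cross(g))
  expect_equal(fl$pairs$status, "excluded_ld")
  expect_equal(fl$pairs$n01, 0)
  expect_equal(fl$pairs$n10, 0)

  # boundary: exactly 6 in every class is testable
  g2 <- cbind(a = rep(c(0, 0, 1, 1), each = 6),
              b = rep(c(0, 1, 0, 1), each = 6))
  fl2 <- enumerate_pairs(toy_cross(g2))
  expect_equal(fl2$pairs$status, "tested")
  expect_equal(unlist(fl2$pairs[, c("n00", "n01", "n10", "n11")]),
               c(n00 = 6, n01 = 6, n10 = 6, n11 = 6))

  # a single class below the cutoff excludes the pair and records the counts
  g3 <- cbind(a = rep(c(0, 0, 1, 1), c(5, 7, 6, 6)),
              b = rep(c(0, 1, 0, 1), c(5, 7, 6, 6)))
  fl3 <- enumerate_pairs(toy_cross(g3))
  expect_equal(fl3$pairs$status, "excluded_ld")
  expect_equal(fl3$pairs$n00, 5)

  # intercross dosage 0.5 is binarized only for the filter
  g4 <- cbind(a = rep(c(0, 0.5, 1), 8), b = rep(c(0, 0.5, 1), c(8, 8, 8)))
  fl4 <- enumerate_pairs(toy_cross(g4))
  expect_true(all(c(fl4$pairs$n00, fl4$pairs$n11) > 0))
})

test_that("pair order is canonical (map order) and enumeration deterministic", {
  set.seed(2)
  g <- matrix(rbinom(200, 1, 0.5), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  fl <- enumerate_pairs(toy_cross(g))
  expect_equal(nrow(fl$pairs), 6)
  expect_true(all(match(fl$pairs$marker1, colnames(g)) <
                    match(fl$pairs$marker2, colnames(g))))
  fl2 <- enumerate_pairs(toy_cross(g))
  expect_identical(fl$pairs, fl2$pairs)
})

test_that("pair scan recovers a noiseless interaction model exactly", {
  g <- expand.grid(a = c(0, 1), b = c(0, 1))
  g <- g[rep(1:4, 6), ]
  et <- 0.5 * g$a - 0.2 * g$b + 0.3 * g$a * g$b
  x <- toy_cross(as.matrix(g))
  basis <- fake_basis(cbind(et, rnorm(24)))
  ps <- pair_scan(x, basis, tibble::tibble(marker1 = "a", marker2 = "b"))
  row <- ps[ps$et == 1, ]
  expect_equal(row$b1, 0.5, tolerance = 1e-10)
  expect_equal(row$b2, -0.2, tolerance = 1e-10)
  expect_equal(row$b12, 0.3, tolerance = 1e-10)
})

test_that("pair-scan coefficients and covariance match the OLS oracle", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(15:30, 1)
    g <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5),
               cv = rbinom(n, 1, 0.5))
    # guarantee all four classes occupied
    g[1:4, c("a", "b")] <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
    y1 <- rnorm(n)
    y2 <- rnorm(n)
    x <- toy_cross(g)
    basis <- fake_basis(cbind(y1, y2))
    ps <- pair_scan(x, basis, tibble::tibble(marker1 = "a", marker2 = "b"),
                    covariates = "cv")
    X <- cbind(1, g[, "cv"], g[, "a"], g[, "b"], g[, "a"] * g[, "b"])
    for (e in 1:2) {
      orc <- ols_oracle(X, if (e == 1) y1 else y2)
      row <- ps[ps$et == e, ]
      expect_equal(c(row$b1, row$b2, row$b12), unname(orc$beta[3:5]),
                   tolerance = 1e-8)
      V <- matrix(c(row$c11, row$c12, row$c13, row$c12, row$c22, row$c23,
                    row$c13, row$c23, row$c33), 3, 3)
      expect_equal(V, unname(orc$cov[3:5, 3:5]), tolerance = 1e-8)
    }
  }
})

test_that("pair-scan covariance matches the hand-computed normal equations", {
  # fixed 12-sample design, noise fixed by seed
  g <- cbind(a = rep(c(0, 1), each = 6), b = rep(c(0, 1), 6))
  set.seed(11)
  y <- 0.4 * g[, "a"] + rnorm(12, sd = 0.5)
  x <- toy_cross(g)
  basis <- fake_basis(cbind(y, rnorm(12)))
  ps <- pair_scan(x, basis, tibble::tibble(marker1 = "a", marker2 = "b"))
  X <- cbind(1, g[, "a"], g[, "b"], g[, "a"] * g[, "b"])
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / (12 - 4)
  V <- s2 * solve(crossprod(X))
  row <- ps[ps$et == 1, ]
  expect_equal(row$c33, unname(V[4, 4]), tolerance = 1e-10)
  expect_equal(row$se12, sqrt(unname(V[4, 4])), tolerance = 1e-10)
})

test_that("pairs containing a declared covariate are skipped, NAs dropped", {
  set.seed(4)
  g <- cbind(a = rbinom(30, 1, 0.5), b = rbinom(30, 1, 0.5),
             cv = rbinom(30, 1, 0.5))
  g[1:4, c("a", "b")] <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  g[5, "a"] <- NA
  x <- toy_cross(g)
  basis <- fake_basis(matrix(rnorm(60), 30, 2))
  ps <- pair_scan(x, basis,
                  tibble::tibble(marker1 = c("a", "a"),
                                 marker2 = c("b", "cv")),
                  covariates = "cv")
  expect_true(all(ps$status[ps$marker2 == "cv"] == "skipped_covariate"))
  expect_equal(unique(ps$n_used[ps$marker2 == "b"]), 29L)
})

test_that("interaction matrix is symmetric with untested cells NA", {
  fx <- make_fixture("one_directed_edge", seed = 2)
  nz <- normalize_phenotypes(fx$cross$pheno)
  basis <- eigentrait_decomp(nz$P_norm)
  fl <- enumerate_pairs(fx$cross)
  ps <- pair_scan(fx$cross, basis, tested_pairs(fl))
  M <- interaction_matrix(ps, 1)
  expect_equal(M, t(M))
  expect_true(all(is.na(diag(M))))
})
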