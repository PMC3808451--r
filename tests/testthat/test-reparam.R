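test_that("two-ET systems solve exactly, matching hand-derived cases", {
  # zero interaction -> zero influences
  s0 <- solve_influences(b1 = c(1, 0.2), b2 = c(0.3, 1), b12 = c(0, 0))
  expect_equal(c(s0$m12, s0$m21), c(0, 0))

  # orthogonal main effects: system is a transposition
  s1 <- solve_influences(b1 = c(1, 0), b2 = c(0, 1), b12 = c(0.5, -0.2))
  expect_equal(c(s1$m12, s1$m21), c(-0.2, 0.5), tolerance = 1e-12)

  # forward-generated from the model identity, then inverted
  b1 <- c(2, 1); b2 <- c(1, 3)
  b12 <- 0.3 * b2 + (-0.1) * b1 # = (0.1, 0.8)
  expect_equal(b12, c(0.1, 0.8))
  s2 <- solve_influences(b1, b2, b12)
  expect_equal(c(s2$m12, s2$m21), c(0.3, -0.1), tolerance = 1e-12)
  expect_equal(s2$residual, c(0, 0), tolerance = 1e-12)
})

test_that("reparametrization is exact for N = 2 on random systems", {
  set.seed(10)
  for (i in 1:200) {
    b1 <- rnorm(2); b2 <- rnorm(2); b12 <- rnorm(2)
    s <- solve_influences(b1, b2, b12)
    if (s$status != "resolved") next
    recon <- s$m12 * b2 + s$m21 * b1
    expect_lt(max(abs(recon - b12)), 1e-10)
  }
})

test_that("refitting with the reparametrized interaction leaves residuals unchanged", {
  set.seed(11)
  g <- cbind(a = rbinom(60, 1, 0.5), b = rbinom(60, 1, 0.5))
  g[1:4, ] <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  Y <- matrix(rnorm(120), 60, 2)
  x <- toy_cross(g)
  basis <- fake_basis(Y)
  ps <- pair_scan(x, basis, tibble::tibble(marker1 = "a", marker2 = "b"))
  s <- solve_influences(ps$b1, ps$b2, ps$b12)
  X <- cbind(1, g[, "a"], g[, "b"], g[, "a"] * g[, "b"])
  for (e in 1:2) {
    fit <- lm.fit(X, Y[, e])
    b12_re <- s$m12 * ps$b2[e] + s$m21 * ps$b1[e]
    co <- fit$coefficients
    yhat_re <- X %*% c(co[1], co[2], co[3], b12_re)
    expect_equal(drop(yhat_re), unname(fit$fitted.values), tolerance = 1e-12)
  }
})

test_that("N > 2 returns the least-squares solution (oracle + grid)", {
  set.seed(12)
  for (i in 1:50) {
    N <- sample(3:5, 1)
    b1 <- rnorm(N); b2 <- rnorm(N); b12 <- rnorm(N)
    s <- solve_influences(b1, b2, b12)
    X <- cbind(b2, b1)
    oracle <- drop(solve(crossprod(X), crossprod(X, b12)))
    expect_equal(c(s$m12, s$m21), unname(oracle), tolerance = 1e-10)
  }
  # residual of the solution beats a grid of alternatives
  b1 <- c(1, -0.5, 0.3); b2 <- c(0.2, 1, -1); b12 <- c(0.4, -0.1, 0.6)
  s <- solve_influences(b1, b2, b12)
  rss <- function(m) sum((b12 - m[1] * b2 - m[2] * b1)^2)
  best <- rss(c(s$m12, s$m21))
  grid <- expand.grid(m12 = seq(-2, 2, 0.1), m21 = seq(-2, 2, 0.1))
  expect_true(all(apply(grid, 1, rss) >= best - 1e-12))
})

test_that("degenerate pleiotropy (parallel effect vectors) is unresolved", {
  s <- solve_influences(b1 = c(1, 2), b2 = c(0.5, 1), b12 = c(0.3, 0.6))
  expect_equal(s$status, "unresolved")
  expect_true(is.na(s$m12))
  expect_error(solve_influences(1, 1, 1), "at least 2")
})

test_that("error propagation matches the identity-Jacobian configuration", {
  # pass-through case: m = (b12_2, b12_1); only var(b12_j) = v nonzero
  v1 <- 0.04; v2 <- 0.09
  covs <- list(diag(c(0, 0, v1)), diag(c(0, 0, v2)))
  pe <- propagate_errors(b1 = c(1, 0), b2 = c(0, 1), b12 = c(0.5, -0.2),
                         covs = covs)
  expect_equal(pe$se_m12, sqrt(v2), tolerance = 1e-12)
  expect_equal(pe$se_m21, sqrt(v1), tolerance = 1e-12)
})

test_that("analytic Jacobian agrees with central differences", {
  set.seed(13)
  for (i in 1:20) {
    N <- sample(2:4, 1)
    b1 <- rnorm(N); b2 <- rnorm(N); b12 <- rnorm(N)
    s <- solve_influences(b1, b2, b12)
    if (s$status != "resolved") next
    J <- pleionet:::.influence_jacobian(b1, b2, b12, c(s$m12, s$m21),
                                        s$residual)
    theta <- as.vector(rbind(b1, b2, b12))
    fn <- function(th) {
      m <- matrix(th, 3)
      f <- solve_influences(m[1, ], m[2, ], m[3, ])
      c(f$m12, f$m21)
    }
    h <- 1e-6
    Jnum <- sapply(seq_along(theta), function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h * max(1, abs(theta[k]))
      tm[k] <- tm[k] - h * max(1, abs(theta[k]))
      (fn(tp) - fn(tm)) / (tp[k] - tm[k])
    })
    expect_equal(J, Jnum, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("noiseless coefficients give zero SEs and a degenerate flag", {
  covs <- list(matrix(0, 3, 3), matrix(0, 3, 3))
  pe <- propagate_errors(b1 = c(1, 0), b2 = c(0, 1), b12 = c(0.5, -0.2),
                         covs = covs)
  expect_equal(pe$status, "degenerate")
  expect_equal(c(pe$se_m12, pe$se_m21), c(0, 0))
})

test_that("delta-method SEs agree with Monte-Carlo propagation", {
  set.seed(14)
  nmc <- 2e4
  for (i in 1:5) {
    b1 <- rnorm(2, sd = 1); b2 <- rnorm(2, sd = 1); b12 <- rnorm(2, sd = 0.3)
    sv <- svd(cbind(b2, b1), nu = 0, nv = 0)$d
    if (sv[1] / sv[2] > 5) next # keep comfortably resolved systems
    covs <- lapply(1:2, function(j) diag(rep(0.01^2, 3)))
    pe <- propagate_errors(b1, b2, b12, covs)
    draws <- matrix(rnorm(nmc * 6, sd = 0.01), nmc, 6)
    th <- sweep(draws, 2, as.vector(rbind(b1, b2, b12)), "+")
    # vectorized 2x2 solve
    det <- th[, 2] * th[, 4] - th[, 5] * th[, 1]
    m12 <- (th[, 3] * th[, 4] - th[, 1] * th[, 6]) / det
    m21 <- (th[, 2] * th[, 6] - th[, 3] * th[, 5]) / det
    expect_equal(pe$se_m12, sd(m12), tolerance = 0.05)
    expect_equal(pe$se_m21, sd(m21), tolerance = 0.05)
  }
})

test_that("standardized effects carry the influence sign and unit invariance", {
  fx <- make_fixture("one_directed_edge", seed = 3)
  nz <- normalize_phenotypes(fx$cross$pheno)
  basis <- eigentrait_decomp(nz$P_norm)
  ps <- pair_scan(fx$cross, basis,
                  tibble::tibble(marker1 = "D3M1", marker2 = "D8M1"))
  inf <- estimate_influences(ps)
  expect_equal(inf$status, "resolved")
  expect_equal(sign(inf$z_m12), sign(inf$m12))
  expect_equal(inf$z_m12, inf$m12 / inf$se_m12)

  # doubling phenotype units leaves z unchanged (rank-normalization already
  # guarantees it; check the reparametrization alone too)
  ps2 <- ps
  for (cl in c("b1", "b2", "b12", "se1", "se2", "se12")) {
    ps2[[cl]] <- 2 * ps2[[cl]]
  }
  for (cl in c("c11", "c12", "c13", "c22", "c23", "c33")) {
    ps2[[cl]] <- 4 * ps2[[cl]]
  }
  inf2 <- estimate_influences(ps2)
  expect_equal(inf2$z_m12, inf$z_m12, tolerance = 1e-10)
  expect_equal(inf2$z_m21, inf$z_m21, tolerance = 1e-10)
})
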