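# shared test helpers: tiny crosses, hand-made bases, independent oracles

# a minimal backcross with explicit genotype/phenotype values
toy_cross <- function(geno, pheno = NULL, chr = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("m", seq_len(ncol(geno)))
  }
  if (is.null(pheno)) {
    set.seed(42)
    pheno <- matrix(rnorm(2 * nrow(geno)), nrow(geno), 2,
                    dimnames = list(NULL, c("ph1", "ph2")))
  }
  if (is.null(chr)) chr <- rep("1", ncol(geno))
  if (is.null(pos)) pos <- seq_len(ncol(geno))
  cross(pheno, geno,
        tibble::tibble(marker = colnames(geno), chr = as.character(chr),
                       pos = pos))
}

# fabricate an eigentrait basis with a prescribed ET matrix (orthonormality of
# U is not needed by the regression code paths under test)
fake_basis <- function(U, phenotypes = c("ph1", "ph2")) {
  U <- as.matrix(U)
  colnames(U) <- paste0("ET", seq_len(ncol(U)))
  structure(
    list(U = U, d = rep(1, ncol(U)),
         V = diag(ncol(U))[seq_along(phenotypes), , drop = FALSE] + 0,
         rows_used = seq_len(nrow(U)), phenotypes = phenotypes,
         selected = seq_len(ncol(U))),
    class = "eigentrait_basis"
  )
}

# lines of a valid 2-phenotype / 1-marker R/qtl csv toy file
toy_csv_lines <- function(gt = c("A", "H", "H"), pos_row = TRUE) {
  c("ph1,ph2,m1",
    ",,1",
    if (pos_row) ",,5.5",
    paste0("1.2,0.1,", gt[1]),
    paste0("2.5,-0.4,", gt[2]),
    paste0("0.3,1.7,", gt[3]))
}

write_toy_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

# independent step-through oracles for multiple-testing adjustments
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force normal-equations OLS used as the regression oracle
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  r <- y - X %*% beta
  s2 <- sum(r^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), cov = s2 * solve(XtX))
}

# reverse a covariate promotion given the original value range (test-only
# inverse of promote_covariates)
unpromote_covariate <- function(x, name, original_range, pheno_after) {
  v <- x$geno[, name] * diff(original_range) + original_range[1]
  keep <- x$map$marker != name
  ph <- cbind(x$pheno, v)
  colnames(ph)[ncol(ph)] <- name
  ph <- ph[, pheno_after, drop = FALSE]
  cross(ph, x$geno[, keep, drop = FALSE], x$map[keep, , drop = FALSE],
        covar = setdiff(x$covar, name), ids = x$ids)
}
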