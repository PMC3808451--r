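#' Rank-based inverse-normal phenotype normalization
#'
#' Each phenotype column is mapped to normal scores via Blom ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))` with ties averaged, then standardized to
#' mean 0 and variance 1 over observed entries. Missing values are preserved
#' in place. The returned record stores the empirical value-to-score mapping
#' per column so the same transform can be applied to held-out values by
#' interpolation.
#'
#' @param P Numeric matrix (samples x phenotypes) with column names.
#' @return List with `P_norm` (transformed matrix, same shape) and `record`
#'   (per-column list: sorted observed values, their final scores, and the
#'   post-transform mean/sd used for standardization).
#' @export
normalize_phenotypes <- function(P) {
  P <- as.matrix(P)
  if (is.null(colnames(P))) colnames(P) <- paste0("P", seq_len(ncol(P)))
  out <- P
  record <- vector("list", ncol(P))
  names(record) <- colnames(P)
  for (j in seq_len(ncol(P))) {
    v <- P[, j]
    obs <- !is.na(v)
    n <- sum(obs)
    if (n < 3) {
      stop("phenotype '", colnames(P)[j], "' has fewer than 3 observed values",
           call. = FALSE)
    }
    if (stats::var(v[obs]) == 0) {
      stop("phenotype '", colnames(P)[j], "' is constant", call. = FALSE)
    }
    r <- rank(v[obs], ties.method = "average")
    z <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
    mu <- mean(z)
    sdv <- stats::sd(z)
    z <- (z - mu) / sdv
    out[obs, j] <- z
    o <- order(v[obs])
    record[[j]] <- list(values = v[obs][o], scores = z[o], mean = mu, sd = sdv)
  }
  list(P_norm = out, record = record)
}

#' Apply a stored normalization to new values
#'
#' Interpolates held-out values through the empirical value-to-score map
#' captured by [normalize_phenotypes()]; values outside the observed range are
#' clamped to the extreme scores.
#'
#' @param v Numeric vector of raw values.
#' @param rec One column's entry of the `record` from [normalize_phenotypes()].
#' @return Numeric vector of normalized scores.
#' @export
apply_normalization <- function(v, rec) {
  stats::approx(rec$values, rec$scores, xout = v, rule = 2, ties = "ordered")$y
}

#' Decompose normalized phenotypes into eigentraits
#'
#' Thin singular value decomposition of the complete-case normalized phenotype
#' matrix, `P = U diag(sigma) V'`. The orthonormal columns of `U` are the
#' eigentraits (ETs): uncorrelated linear recombinations of the phenotypes,
#' used as regression responses downstream. Rows with any missing phenotype
#' are excluded and reported. Sign convention: each right-singular vector's
#' largest-magnitude loading is made positive, so results are reproducible
#' across linear-algebra backends.
#'
#' @param P_norm Normalized phenotype matrix (see [normalize_phenotypes()]).
#' @return An `eigentrait_basis`: list with `U` (n_complete x r eigentraits),
#'   `d` (singular values), `V` (phenotype loadings), `rows_used` (indices of
#'   complete rows in the input), `phenotypes` (column names), `selected`
#'   (ET indices used downstream; defaults to the first two).
#' @export
eigentrait_decomp <- function(P_norm) {
  P_norm <- as.matrix(P_norm)
  if (ncol(P_norm) < 2) {
    stop("eigentrait decomposition needs at least 2 phenotypes", call. = FALSE)
  }
  if (is.null(colnames(P_norm))) {
    colnames(P_norm) <- paste0("P", seq_len(ncol(P_norm)))
  }
  rows_used <- which(stats::complete.cases(P_norm))
  if (length(rows_used) <= ncol(P_norm)) {
    stop("too few complete phenotype rows for decomposition", call. = FALSE)
  }
  X <- P_norm[rows_used, , drop = FALSE]
  s <- svd(X, nu = ncol(X), nv = ncol(X))
  for (i in seq_along(s$d)) {
    k <- which.max(abs(s$v[, i]))
    if (s$v[k, i] < 0) {
      s$v[, i] <- -s$v[, i]
      s$u[, i] <- -s$u[, i]
    }
  }
  colnames(s$u) <- paste0("ET", seq_along(s$d))
  dimnames(s$v) <- list(colnames(P_norm), colnames(s$u))
  structure(
    list(U = s$u, d = s$d, V = s$v, rows_used = rows_used,
         phenotypes = colnames(P_norm),
         selected = seq_len(min(2L, length(s$d)))),
    class = "eigentrait_basis"
  )
}

#' @export
print.eigentrait_basis <- function(x, ...) {
  cat("<eigentrait_basis> ", length(x$d), " ETs from ",
      length(x$phenotypes), " phenotypes, ", nrow(x$U),
      " complete samples\n", sep = "")
  vf <- variance_fractions(x)
  cat("  variance fractions:", paste(sprintf("%.3f", vf), collapse = " "), "\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Global variance fraction of each eigentrait
#'
#' @param basis An [eigentrait_decomp()] result.
#' @return Numeric vector `sigma_i^2 / sum(sigma^2)`; non-increasing, sums
#'   to 1.
#' @export
variance_fractions <- function(basis) {
  stopifnot(inherits(basis, "eigentrait_basis"))
  basis$d^2 / sum(basis$d^2)
}

#' Select the leading eigentraits for analysis
#'
#' The first ETs typically carry the correlated signal among the phenotypes
#' and the leading divergences between them; by default the first two are
#' analyzed, and at most 12 are allowed (beyond that, extra components tend to
#' dilute the significance of directed interactions).
#'
#' @param basis An [eigentrait_decomp()] result.
#' @param k Number of leading ETs to select, `2 <= k <= min(12, r)`.
#' @return The basis with `selected = 1:k`.
#' @export
select_ets <- function(basis, k = 2) {
  stopifnot(inherits(basis, "eigentrait_basis"))
  r <- length(basis$d)
  if (k < 2 || k > 12 || k > r) {
    stop("k must be between 2 and min(12, ", r, ") = ", min(12, r),
         call. = FALSE)
  }
  basis$selected <- seq_len(k)
  basis
}

#' Back-project eigentrait-space effects to phenotype space
#'
#' An effect vector estimated on the selected ETs is rotated back to the
#' phenotype scale as `sum_i beta_et[i] * sigma_i * V[, i]`. When a covariance
#' matrix for `beta_et` is supplied, it is propagated through the same linear
#' map.
#'
#' @param beta_et Numeric vector of effects, one per selected ET.
#' @param basis An [eigentrait_decomp()] result.
#' @param cov_et Optional covariance matrix of `beta_et`.
#' @return Named numeric vector of phenotype-space effects; if `cov_et` is
#'   given, the phenotype-space covariance is attached as attribute `"cov"`.
#' @export
back_project_effects <- function(beta_et, basis, cov_et = NULL) {
  stopifnot(inherits(basis, "eigentrait_basis"))
  sel <- basis$selected
  if (length(beta_et) != length(sel)) {
    stop("beta_et has length ", length(beta_et), " but ", length(sel),
         " ETs are selected", call. = FALSE)
  }
  A <- basis$V[, sel, drop = FALSE] %*% diag(basis$d[sel], length(sel))
  out <- drop(A %*% beta_et)
  names(out) <- basis$phenotypes
  if (!is.null(cov_et)) {
    attr(out, "cov") <- A %*% cov_et %*% t(A)
  }
  out
}

#' Eigentrait report table
#'
#' The tabular content behind the usual ET bar chart: one row per eigentrait
#' with its global variance fraction and one loading column per phenotype.
#'
#' @param basis An [eigentrait_decomp()] result.
#' @param path Optional CSV path; when given the table is also written there.
#' @return A tibble.
#' @export
et_report <- function(basis, path = NULL) {
  stopifnot(inherits(basis, "eigentrait_basis"))
  tab <- tibble::tibble(
    et = seq_along(basis$d),
    variance_fraction = variance_fractions(basis),
    selected = seq_along(basis$d) %in% basis$selected
  )
  tab <- dplyr::bind_cols(
    tab,
    tibble::as_tibble(t(basis$V), .name_repair = "minimal")
  )
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' @rdname et_report
#' @param x An `eigentrait_basis`.
#' @param ... Unused.
#' @export
tidy.eigentrait_basis <- function(x, ...) {
  tibble::tibble(
    et = rep(seq_along(x$d), each = length(x$phenotypes)),
    phenotype = rep(x$phenotypes, length(x$d)),
    loading = as.vector(x$V),
    variance_fraction = rep(variance_fractions(x), each = length(x$phenotypes))
  )
}

#' @rdname et_report
#' @export
glance.eigentrait_basis <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$U),
    n_phenotypes = length(x$phenotypes),
    n_ets = length(x$d),
    n_selected = length(x$selected),
    selected_variance = sum(variance_fractions(x)[x$selected])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
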