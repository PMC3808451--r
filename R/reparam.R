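#' Solve the directed-influence reparametrization for one pair
#'
#' The two-locus model per eigentrait j is
#' `ET_j ~ b0 + b1 x1 + b2 x2 + b12 x1 x2`. The reparametrization replaces the
#' N interaction coefficients (one per ET) with two directed influence
#' coefficients `m12` (marker 1 is the source rescaling marker 2's effective
#' dose) and `m21` (the reverse), via the identity
#'
#'   `b12_j = m12 * b2_j + m21 * b1_j`   for every ET j.
#'
#' With N = 2 ETs this 2x2 linear system is solved exactly (fitted values and
#' residuals of the pairwise model are unchanged); with N > 2 the
#' least-squares solution of the Nx2 system is returned. Near-parallel main
#' effect vectors (degenerate pleiotropy) make the direction unidentifiable:
#' when the system's singular-value ratio exceeds `cond_tol` the pair is
#' reported unresolved.
#'
#' @param b1,b2,b12 Numeric vectors of length N (one entry per ET): the two
#'   main-effect and the interaction coefficients.
#' @param cond_tol Condition-number tolerance of the Nx2 system.
#' @return List with `m12`, `m21`, `status` (`"resolved"`/`"unresolved"`) and
#'   `residual` (vector of `b12 - X m`, zero for N = 2).
#' @export
solve_influences <- function(b1, b2, b12, cond_tol = 1e8) {
  N <- length(b12)
  if (N < 2) stop("at least 2 ETs are required", call. = FALSE)
  stopifnot(length(b1) == N, length(b2) == N)
  if (anyNA(c(b1, b2, b12))) {
    return(list(m12 = NA_real_, m21 = NA_real_, status = "unresolved",
                residual = rep(NA_real_, N)))
  }
  X <- cbind(b2, b1)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > cond_tol || !all(is.finite(sv))) {
    return(list(m12 = NA_real_, m21 = NA_real_, status = "unresolved",
                residual = rep(NA_real_, N)))
  }
  m <- unname(qr.solve(X, b12))
  list(m12 = m[1], m21 = m[2], status = "resolved",
       residual = as.vector(b12 - X %*% m))
}

# Analytic Jacobian of (m12, m21) with respect to theta =
# (b1_1, b2_1, b12_1, ..., b1_N, b2_N, b12_N), for the least-squares solution
# m = (X'X)^-1 X' y with X = [b2 | b1], y = b12. Uses the standard matrix
# perturbation identity dm = P (dy - dX m) + (X'X)^-1 dX' r with
# P = (X'X)^-1 X', r = y - X m (r = 0 when N = 2).
.influence_jacobian <- function(b1, b2, b12, m, residual) {
  N <- length(b12)
  X <- cbind(b2, b1)
  XtXi <- solve(crossprod(X))
  P <- XtXi %*% t(X) # 2 x N
  J <- matrix(0, 2, 3 * N)
  for (j in seq_len(N)) {
    # d/d b1_j: X[j, 2]
    J[, 3 * j - 2] <- -P[, j] * m[2] + XtXi[, 2] * residual[j]
    # d/d b2_j: X[j, 1]
    J[, 3 * j - 1] <- -P[, j] * m[1] + XtXi[, 1] * residual[j]
    # d/d b12_j: y[j]
    J[, 3 * j] <- P[, j]
  }
  J
}

#' Delta-method standard errors for directed influences
#'
#' First-order propagation of the per-ET coefficient covariances through the
#' reparametrization. The stacked coefficient vector
#' `theta = (b1_j, b2_j, b12_j)_j` carries a block-diagonal covariance (one
#' 3x3 block per ET; cross-ET covariances are zero because the ETs are
#' orthogonal and fitted in separate regressions). The Jacobian of
#' `(m12, m21)` in `theta` is computed analytically, and
#' `Cov(m) = J Sigma J'`.
#'
#' @inheritParams solve_influences
#' @param covs List of N 3x3 covariance matrices of `(b1, b2, b12)`, one per
#'   ET.
#' @param fit A [solve_influences()] result for the same coefficients
#'   (computed if omitted).
#' @param cond_tol Condition-number tolerance, as in [solve_influences()].
#' @return List with `se_m12`, `se_m21`, `cov_m` (2x2), and `status`:
#'   `"resolved"`, `"unresolved"`, or `"degenerate"` when both SEs are zero
#'   (noiseless input — standardized effects undefined).
#' @export
propagate_errors <- function(b1, b2, b12, covs, fit = NULL, cond_tol = 1e8) {
  if (is.null(fit)) fit <- solve_influences(b1, b2, b12, cond_tol)
  if (fit$status != "resolved") {
    return(list(se_m12 = NA_real_, se_m21 = NA_real_, cov_m = NULL,
                status = "unresolved"))
  }
  N <- length(b12)
  stopifnot(length(covs) == N)
  J <- .influence_jacobian(b1, b2, b12, c(fit$m12, fit$m21), fit$residual)
  if (!all(is.finite(J))) {
    return(list(se_m12 = NA_real_, se_m21 = NA_real_, cov_m = NULL,
                status = "unresolved"))
  }
  V <- matrix(0, 2, 2)
  for (j in seq_len(N)) {
    Jj <- J[, (3 * j - 2):(3 * j), drop = FALSE]
    V <- V + Jj %*% covs[[j]] %*% t(Jj)
  }
  se <- sqrt(pmax(diag(V), 0))
  status <- if (all(se == 0)) "degenerate" else "resolved"
  list(se_m12 = se[1], se_m21 = se[2], cov_m = V, status = status)
}

#' Directed influence estimates for every scanned pair
#'
#' Applies the reparametrization and delta-method error propagation to each
#' resolved pair of a [pair_scan()] result, yielding the two directed
#' influences with standardized effects `z = m / se` — the statistics ranked
#' against permutation nulls. Negative influences are suppressive, positive
#' ones enhancing.
#'
#' @param ps A [pair_scan()] tibble.
#' @param cond_tol Condition-number tolerance for the reparametrization
#'   system.
#' @return An `influence_table` tibble: one row per pair with `marker1`,
#'   `marker2`, `m12`, `m21`, `se_m12`, `se_m21`, `z_m12`, `z_m21`, `status`.
#' @export
estimate_influences <- function(ps, cond_tol = 1e8) {
  pairs <- attr(ps, "pairs")
  if (is.null(pairs)) {
    pairs <- dplyr::distinct(ps, .data$pair_id, .data$marker1, .data$marker2)
  }
  n_et <- length(unique(ps$et))
  core <- .influences_core(
    coef = .ps_array(ps, c("b1", "b2", "b12")),
    covs = .ps_array(ps, c("c11", "c12", "c13", "c22", "c23", "c33")),
    ok = apply(matrix(ps$status == "resolved", nrow = n_et), 2, all),
    cond_tol = cond_tol
  )
  out <- tibble::tibble(
    pair_id = unique(ps$pair_id),
    marker1 = pairs$marker1, marker2 = pairs$marker2,
    m12 = unname(core[, "m12"]), m21 = unname(core[, "m21"]),
    se_m12 = unname(core[, "se12"]), se_m21 = unname(core[, "se21"]),
    z_m12 = unname(core[, "z12"]), z_m21 = unname(core[, "z21"]),
    status = c("unresolved", "resolved", "degenerate")[core[, "status"] + 1]
  )
  class(out) <- c("influence_table", class(out))
  out
}

# reshape a pair_scan tibble into a (stat, et, pair) array
.ps_array <- function(ps, cols) {
  n_et <- length(unique(ps$et))
  P <- nrow(ps) / n_et
  a <- array(NA_real_, c(length(cols), n_et, P))
  for (i in seq_along(cols)) {
    a[i, , ] <- ps[[cols[i]]]
  }
  a
}

# Vector core shared by estimate_influences() and the permutation loop.
# coef: (3, n_et, P) array of (b1, b2, b12); covs: (6, n_et, P) array of the
# upper-triangle covariance entries (c11, c12, c13, c22, c23, c33).
# Returns a P x 7 matrix: m12, m21, se12, se21, z12, z21, status
# (0 unresolved, 1 resolved, 2 degenerate).
.influences_core <- function(coef, covs, ok, cond_tol = 1e8) {
  P <- dim(coef)[3]
  out <- matrix(NA_real_, P, 7,
                dimnames = list(NULL, c("m12", "m21", "se12", "se21",
                                        "z12", "z21", "status")))
  out[, "status"] <- 0
  for (k in seq_len(P)) {
    if (!isTRUE(ok[[k]])) next
    b1 <- coef[1, , k]; b2 <- coef[2, , k]; b12 <- coef[3, , k]
    fit <- solve_influences(b1, b2, b12, cond_tol)
    if (fit$status != "resolved") next
    cv <- covs[, , k, drop = FALSE]
    covlist <- lapply(seq_len(dim(coef)[2]), function(j) {
      matrix(c(cv[1, j, 1], cv[2, j, 1], cv[3, j, 1],
               cv[2, j, 1], cv[4, j, 1], cv[5, j, 1],
               cv[3, j, 1], cv[5, j, 1], cv[6, j, 1]), 3, 3)
    })
    pe <- propagate_errors(b1, b2, b12, covlist, fit = fit)
    if (pe$status == "unresolved") next
    out[k, "m12"] <- fit$m12
    out[k, "m21"] <- fit$m21
    out[k, "se12"] <- pe$se_m12
    out[k, "se21"] <- pe$se_m21
    if (pe$status == "degenerate") {
      out[k, "status"] <- 2
    } else {
      out[k, "z12"] <- if (pe$se_m12 > 0) fit$m12 / pe$se_m12 else NA_real_
      out[k, "z21"] <- if (pe$se_m21 > 0) fit$m21 / pe$se_m21 else NA_real_
      out[k, "status"] <- 1
    }
  }
  out
}
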