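#' Genome-wide single-marker scan on the selected eigentraits
#'
#' For each marker and each selected ET, fits
#' `ET ~ intercept + covariates + marker` by ordinary least squares on jointly
#' observed samples. The t-statistics are the usual basis for choosing
#' strong-main-effect markers as pair-scan covariates.
#'
#' @param x A [cross()].
#' @param basis An [eigentrait_decomp()] result on the cross's phenotypes.
#' @param covariates Marker names entered as regression covariates.
#' @return Tibble with one row per (marker, ET): `marker`, `et`, `estimate`,
#'   `se`, `statistic`, `n_used`, `status` (`"resolved"` or `"unresolved"` for
#'   rank-deficient designs, e.g. a marker that is also a covariate).
#' @export
single_scan <- function(x, basis, covariates = character()) {
  stopifnot(inherits(x, "cross"), inherits(basis, "eigentrait_basis"))
  Y <- basis$U[, basis$selected, drop = FALSE]
  G <- x$geno[basis$rows_used, , drop = FALSE]
  C <- G[, covariates, drop = FALSE]
  ets <- basis$selected
  res <- purrr::map(colnames(G), function(mk) {
    xg <- G[, mk]
    rows <- which(!is.na(xg) & stats::complete.cases(C))
    X <- cbind(1, C[rows, , drop = FALSE], xg[rows])
    fit <- .ols_multi(X, Y[rows, , drop = FALSE])
    k <- ncol(X)
    if (!fit$ok) {
      return(tibble::tibble(marker = mk, et = ets, estimate = NA_real_,
                            se = NA_real_, statistic = NA_real_,
                            n_used = length(rows), status = "unresolved"))
    }
    est <- fit$coef[k, ]
    se <- sqrt(pmax(fit$xtxinv[k, k] * fit$sigma2, 0))
    tibble::tibble(marker = mk, et = ets, estimate = est, se = se,
                   statistic = ifelse(se > 0, est / se, NA_real_),
                   n_used = length(rows), status = "resolved")
  })
  dplyr::bind_rows(res)
}

#' Choose pair-scan covariates from single-scan statistics
#'
#' Markers whose maximum |t| across the selected ETs exceeds `threshold` are
#' returned. Very strong main-effect markers can mask interactions between
#' other pairs, so the caller may pass these into [pair_scan()] as covariates;
#' the choice is deliberately left to the user.
#'
#' @param scan A [single_scan()] tibble.
#' @param threshold Positive |t| cutoff.
#' @return Character vector of marker names, in map order of `scan`.
#' @export
select_marker_covariates <- function(scan, threshold) {
  stopifnot(threshold > 0)
  hits <- scan |>
    dplyr::filter(.data$status == "resolved", !is.na(.data$statistic)) |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(tmax = max(abs(.data$statistic)), .groups = "drop") |>
    dplyr::filter(.data$tmax > threshold) |>
    dplyr::pull("marker")
  intersect(unique(scan$marker), hits)
}

#' Enumerate testable marker pairs (linkage-disequilibrium filter)
#'
#' All unordered pairs of markers (promoted covariates included) are
#' candidates. For each pair, genotypes are binarized by rounding to
#' `{0, 1}` (dosage >= 0.5 rounds up; regression always uses the raw dosages)
#' and the four two-locus genotype classes (0,0), (0,1), (1,0), (1,1) are
#' counted over jointly observed samples. A pair in which any class has fewer
#' than `min_class_count` observations is excluded as being in linkage
#' disequilibrium — its interaction term is not identifiable — with its class
#' counts recorded. Pairs with no jointly observed samples are excluded
#' separately.
#'
#' @param x A [cross()].
#' @param min_class_count Minimum observations required in every one of the
#'   four two-locus classes (default 6).
#' @return A `pair_filter` object: tibble `pairs` with `marker1`, `marker2`
#'   (in map order, marker1 before marker2), class counts `n00`, `n01`, `n10`,
#'   `n11`, and `status` in `tested` / `excluded_ld` / `excluded_other`; plus
#'   `min_class_count` metadata.
#' @export
enumerate_pairs <- function(x, min_class_count = 6) {
  stopifnot(inherits(x, "cross"))
  G <- x$geno
  m <- ncol(G)
  if (m < 2) stop("need at least 2 markers to enumerate pairs", call. = FALSE)
  I1 <- matrix(0, nrow(G), m)
  I0 <- matrix(0, nrow(G), m)
  ok <- !is.na(G)
  I1[ok & G >= 0.5] <- 1
  I0[ok & G < 0.5] <- 1
  n11 <- crossprod(I1)
  n10 <- crossprod(I1, I0) # marker1 in class 1, marker2 in class 0
  n01 <- crossprod(I0, I1)
  n00 <- crossprod(I0)
  ut <- upper.tri(n11)
  i <- row(n11)[ut]
  j <- col(n11)[ut]
  tab <- tibble::tibble(
    marker1 = colnames(G)[i],
    marker2 = colnames(G)[j],
    n00 = n00[ut], n01 = n01[ut], n10 = n10[ut], n11 = n11[ut]
  )
  total <- tab$n00 + tab$n01 + tab$n10 + tab$n11
  minc <- pmin(tab$n00, tab$n01, tab$n10, tab$n11)
  tab$status <- dplyr::case_when(
    total == 0 ~ "excluded_other",
    minc < min_class_count ~ "excluded_ld",
    TRUE ~ "tested"
  )
  structure(list(pairs = tab, min_class_count = min_class_count),
            class = "pair_filter")
}

#' @export
print.pair_filter <- function(x, ...) {
  n <- table(factor(x$pairs$status,
                    levels = c("tested", "excluded_ld", "excluded_other")))
  cat("<pair_filter> ", nrow(x$pairs), " candidate pairs: ",
      n[["tested"]], " tested, ", n[["excluded_ld"]],
      " excluded (LD, any class < ", x$min_class_count, "), ",
      n[["excluded_other"]], " excluded (no joint samples)\n", sep = "")
  invisible(x)
}

#' Tested pairs of a pair filter
#' @param filter A [enumerate_pairs()] result.
#' @return Tibble with columns `marker1`, `marker2`.
#' @export
tested_pairs <- function(filter) {
  stopifnot(inherits(filter, "pair_filter"))
  filter$pairs |>
    dplyr::filter(.data$status == "tested") |>
    dplyr::select("marker1", "marker2")
}

# ---- internal OLS engine ---------------------------------------------------

# Multi-response OLS via one QR factorization. Returns coefficients per
# response, per-response sigma^2, and the unscaled (X'X)^-1.
.ols_multi <- function(X, Y) {
  qx <- qr(X)
  p <- ncol(X)
  if (qx$rank < p || nrow(X) <= p) {
    return(list(ok = FALSE))
  }
  qty <- qr.qty(qx, Y)
  R <- qr.R(qx)
  coef <- backsolve(R, qty[seq_len(p), , drop = FALSE])
  # undo any column pivoting
  coef[qx$pivot, ] <- coef
  rss <- colSums(qty[-seq_len(p), , drop = FALSE]^2)
  df <- nrow(X) - p
  xtxinv <- chol2inv(R)
  xtxinv[qx$pivot, qx$pivot] <- xtxinv
  list(ok = TRUE, coef = coef, sigma2 = rss / df, xtxinv = xtxinv, df = df)
}

# Precompute per-pair designs (QR of [1 | covariates | x1 | x2 | x1*x2]) so a
# permutation only re-applies a new response matrix. `rows` index into the
# basis's complete-case rows.
.prepare_pair_designs <- function(x, basis, pairs, covariates = character()) {
  G <- x$geno[basis$rows_used, , drop = FALSE]
  C <- G[, covariates, drop = FALSE]
  skipped <- pairs$marker1 %in% covariates | pairs$marker2 %in% covariates
  designs <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (skipped[k]) next
    x1 <- G[, pairs$marker1[k]]
    x2 <- G[, pairs$marker2[k]]
    rows <- which(!is.na(x1) & !is.na(x2) & stats::complete.cases(C))
    X <- cbind(1, C[rows, , drop = FALSE], x1[rows], x2[rows],
               x1[rows] * x2[rows])
    p <- ncol(X)
    qx <- qr(X)
    if (qx$rank < p || length(rows) <= p) {
      designs[[k]] <- list(ok = FALSE, rows = rows)
      next
    }
    R <- qr.R(qx)
    xtxinv <- chol2inv(R)
    xtxinv[qx$pivot, qx$pivot] <- xtxinv
    piv <- order(qx$pivot)
    idx <- c(p - 2L, p - 1L, p) # positions of b1, b2, b12
    designs[[k]] <- list(ok = TRUE, rows = rows, qr = qx, p = p,
                         pivot_order = piv, xtxinv3 = xtxinv[idx, idx],
                         idx = idx, df = length(rows) - p)
  }
  list(designs = designs, skipped = skipped,
       n_et = length(basis$selected))
}

# Apply prepared designs to a response matrix Y (rows aligned with
# basis$rows_used; one column per selected ET). Returns arrays:
#   coef:  3 x n_et x n_pairs  (b1, b2, b12)
#   tmain: 2 x n_et x n_pairs  (standardized main effects)
#   sigma2: n_et x n_pairs; xtxinv3: 3 x 3 x n_pairs; ok, df, n_used vectors
.apply_pair_designs <- function(prep, Y) {
  P <- length(prep$designs)
  n_et <- ncol(Y)
  coef <- array(NA_real_, c(3, n_et, P))
  tmain <- array(NA_real_, c(2, n_et, P))
  sigma2 <- matrix(NA_real_, n_et, P)
  xtxinv3 <- array(NA_real_, c(3, 3, P))
  ok <- logical(P)
  df <- integer(P)
  n_used <- integer(P)
  for (k in seq_len(P)) {
    d <- prep$designs[[k]]
    if (is.null(d) || !d$ok) next
    Yr <- Y[d$rows, , drop = FALSE]
    qty <- qr.qty(d$qr, Yr)
    b <- backsolve(qr.R(d$qr), qty[seq_len(d$p), , drop = FALSE])
    b <- b[d$pivot_order, , drop = FALSE][d$idx, , drop = FALSE]
    rss <- colSums(qty[-seq_len(d$p), , drop = FALSE]^2)
    s2 <- rss / d$df
    coef[, , k] <- b
    sigma2[, k] <- s2
    xtxinv3[, , k] <- d$xtxinv3
    se1 <- sqrt(d$xtxinv3[1, 1] * s2)
    se2 <- sqrt(d$xtxinv3[2, 2] * s2)
    tmain[1, , k] <- ifelse(se1 > 0, b[1, ] / se1, NA_real_)
    tmain[2, , k] <- ifelse(se2 > 0, b[2, ] / se2, NA_real_)
    ok[k] <- TRUE
    df[k] <- d$df
    n_used[k] <- length(d$rows)
  }
  list(coef = coef, tmain = tmain, sigma2 = sigma2, xtxinv3 = xtxinv3,
       ok = ok, df = df, n_used = n_used)
}

#' Two-locus pair scan on the selected eigentraits
#'
#' For every pair and every selected ET, fits
#' `ET ~ intercept + covariates + x1 + x2 + x1:x2` by OLS on jointly observed
#' samples, storing the main-effect and interaction coefficients together with
#' the 3x3 covariance of `(b1, b2, b12)`. Pairs containing a declared
#' regression covariate are skipped (status `"skipped_covariate"`), and
#' rank-deficient designs are flagged `"unresolved"`.
#'
#' @param x A [cross()].
#' @param basis An [eigentrait_decomp()] result.
#' @param pairs Tibble with columns `marker1`, `marker2` (e.g.
#'   [tested_pairs()]).
#' @param covariates Marker names entered as regression covariates.
#' @return A `pair_scan` tibble: one row per (pair, ET) with coefficients
#'   `b1`, `b2`, `b12`, standard errors, standardized main effects `t1`, `t2`,
#'   the covariance entries `c11 ... c33` of `(b1, b2, b12)`, `df`, `n_used`,
#'   `status`. The prepared designs are attached as attribute `"prep"` for
#'   reuse in permutation testing.
#' @export
pair_scan <- function(x, basis, pairs, covariates = character()) {
  stopifnot(inherits(x, "cross"), inherits(basis, "eigentrait_basis"))
  pairs <- tibble::as_tibble(pairs)[, c("marker1", "marker2")]
  prep <- .prepare_pair_designs(x, basis, pairs, covariates)
  Y <- basis$U[, basis$selected, drop = FALSE]
  out <- .pairscan_tibble(prep, .apply_pair_designs(prep, Y), pairs,
                          basis$selected)
  attr(out, "prep") <- prep
  attr(out, "pairs") <- pairs
  attr(out, "selected_ets") <- basis$selected
  class(out) <- c("pair_scan", class(out))
  out
}

.pairscan_tibble <- function(prep, ap, pairs, ets) {
  P <- nrow(pairs)
  n_et <- length(ets)
  status <- rep("resolved", P)
  status[!ap$ok] <- "unresolved"
  status[prep$skipped] <- "skipped_covariate"
  # flatten arrays: row order = (pair 1: et1..etk, pair 2: ...)
  flat <- function(a, i) as.vector(a[i, , ])
  cov_flat <- function(i, j) {
    rep(ap$xtxinv3[i, j, ], each = n_et) * as.vector(ap$sigma2)
  }
  tibble::tibble(
    pair_id = rep(seq_len(P), each = n_et),
    marker1 = rep(pairs$marker1, each = n_et),
    marker2 = rep(pairs$marker2, each = n_et),
    et = rep(ets, P),
    b1 = flat(ap$coef, 1), b2 = flat(ap$coef, 2), b12 = flat(ap$coef, 3),
    se1 = sqrt(pmax(cov_flat(1, 1), 0)),
    se2 = sqrt(pmax(cov_flat(2, 2), 0)),
    se12 = sqrt(pmax(cov_flat(3, 3), 0)),
    t1 = flat(ap$tmain, 1), t2 = flat(ap$tmain, 2),
    c11 = cov_flat(1, 1), c12 = cov_flat(1, 2), c13 = cov_flat(1, 3),
    c22 = cov_flat(2, 2), c23 = cov_flat(2, 3), c33 = cov_flat(3, 3),
    df = rep(ap$df, each = n_et),
    n_used = rep(ap$n_used, each = n_et),
    status = rep(status, each = n_et)
  )
}

#' Interaction-coefficient matrix per eigentrait
#'
#' Spreads the pair-scan interaction coefficients into a symmetric
#' markers-by-markers matrix for one ET (untested cells `NA`) — the tabular
#' content behind the usual pair-scan heatmaps.
#'
#' @param ps A [pair_scan()] tibble.
#' @param et Which selected ET.
#' @param markers Optional marker ordering for rows/columns.
#' @param path Optional CSV path.
#' @return A matrix with marker dimnames.
#' @export
interaction_matrix <- function(ps, et, markers = NULL, path = NULL) {
  d <- dplyr::filter(ps, .data$et == !!et, .data$status == "resolved")
  if (is.null(markers)) {
    markers <- unique(c(ps$marker1, ps$marker2))
  }
  M <- matrix(NA_real_, length(markers), length(markers),
              dimnames = list(markers, markers))
  M[cbind(d$marker1, d$marker2)] <- d$b12
  M[cbind(d$marker2, d$marker1)] <- d$b12
  if (!is.null(path)) {
    utils::write.csv(M, path, row.names = TRUE)
  }
  M
}
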