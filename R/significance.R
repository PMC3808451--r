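#' Permute the eigentrait matrix against fixed genotypes
#'
#' Returns the selected-ET matrix with rows permuted by a uniformly random
#' permutation of sample indices. All ET columns are permuted jointly, so the
#' correlation structure among ETs is preserved; genotypes (covariate
#' pseudo-markers included) stay fixed, so linkage disequilibrium is preserved
#' too. This breaks exactly the genotype-phenotype association and guards
#' against false positives arising from linkage between markers.
#'
#' @param basis An [eigentrait_decomp()] result.
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @param perm Optional explicit permutation (for tests).
#' @return Matrix of permuted selected-ET values (rows aligned with
#'   `basis$rows_used`).
#' @export
permute_ets <- function(basis, seed, perm = NULL) {
  stopifnot(inherits(basis, "eigentrait_basis"))
  Y <- basis$U[, basis$selected, drop = FALSE]
  if (is.null(perm)) {
    perm <- withr::with_seed(seed, sample.int(nrow(Y)))
  }
  Y[perm, , drop = FALSE]
}

# derive independent per-permutation seeds from one master seed
.derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Build pooled permutation null distributions
#'
#' For each permutation the ET matrix is row-permuted, the pair scan is re-run
#' on the identical pair list and covariates (the per-pair design
#' factorizations are reused), the reparametrization is applied, and all
#' resolved standardized effects are pooled: directed influence z's into the
#' variant-variant null, standardized main-effect coefficients into the
#' variant-phenotype null. Pooling across pairs and permutations buys large
#' null samples at a fraction of the cost of per-parameter nulls, with
#' indistinguishable significance estimates.
#'
#' @param ps A [pair_scan()] result (its attached designs are reused).
#' @param basis The [eigentrait_decomp()] used for the scan.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Master seed; per-permutation seeds are derived by a fixed
#'   splitting rule so results do not depend on execution order.
#' @param cond_tol Condition tolerance passed to the reparametrization.
#' @param keep_per_pair Also retain the per-(pair, direction, permutation)
#'   statistics (matrices `z12`, `z21` of size pairs x permutations), so
#'   pooled significance can be compared against per-parameter nulls.
#' @return A `null_distributions` object: list with `variant_variant` and
#'   `variant_phenotype` numeric pools, `n_perm`, and `per_perm` counts of
#'   resolved statistics per permutation (plus `z12`/`z21` when
#'   `keep_per_pair`).
#' @export
build_null <- function(ps, basis, n_perm = 100, seed = 1, cond_tol = 1e8,
                       keep_per_pair = FALSE) {
  stopifnot(n_perm >= 1)
  prep <- attr(ps, "prep")
  if (is.null(prep)) stop("pair_scan result lacks attached designs", call. = FALSE)
  seeds <- .derive_seeds(seed, n_perm)
  vv <- vector("list", n_perm)
  vp <- vector("list", n_perm)
  per_perm <- integer(n_perm)
  P <- length(prep$designs)
  z12 <- if (keep_per_pair) matrix(NA_real_, P, n_perm)
  z21 <- if (keep_per_pair) matrix(NA_real_, P, n_perm)
  for (i in seq_len(n_perm)) {
    Yp <- permute_ets(basis, seeds[i])
    ap <- .apply_pair_designs(prep, Yp)
    core <- .influences_core(ap$coef,
                             .covs_from_apply(ap),
                             ok = ap$ok & !prep$skipped, cond_tol = cond_tol)
    z <- c(core[, "z12"], core[, "z21"])
    vv[[i]] <- z[is.finite(z)]
    tm <- as.vector(ap$tmain)
    vp[[i]] <- tm[is.finite(tm)]
    per_perm[i] <- length(vv[[i]])
    if (keep_per_pair) {
      z12[, i] <- core[, "z12"]
      z21[, i] <- core[, "z21"]
    }
  }
  structure(
    list(variant_variant = unlist(vv), variant_phenotype = unlist(vp),
         n_perm = n_perm, per_perm = per_perm, seed = seed,
         z12 = z12, z21 = z21),
    class = "null_distributions"
  )
}

# pack the covariance entries of an .apply_pair_designs() result into the
# (6, n_et, P) upper-triangle layout used by .influences_core()
.covs_from_apply <- function(ap) {
  n_et <- nrow(ap$sigma2)
  P <- ncol(ap$sigma2)
  covs <- array(NA_real_, c(6, n_et, P))
  ut <- cbind(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))
  for (u in 1:6) {
    covs[u, , ] <- rep(ap$xtxinv3[ut[u, 1], ut[u, 2], ], each = n_et) *
      as.vector(ap$sigma2)
  }
  covs
}

#' @export
print.null_distributions <- function(x, ...) {
  cat("<null_distributions> ", x$n_perm, " permutations\n", sep = "")
  cat("  variant-variant pool:  ", length(x$variant_variant), " values\n",
      sep = "")
  cat("  variant-phenotype pool:", length(x$variant_phenotype), "values\n")
  invisible(x)
}

#' Empirical p-value against a pooled null
#'
#' Two-sided add-one estimator:
#' `p = (1 + #(|null| >= |z|)) / (1 + n_null)`. The add-one convention avoids
#' p = 0 and ties with the null count against the observation.
#'
#' @param observed_z Numeric vector of observed standardized effects.
#' @param null Numeric vector of pooled null standardized effects (non-empty).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
empirical_p <- function(observed_z, null) {
  if (!length(null)) stop("null distribution is empty", call. = FALSE)
  a <- sort(abs(null))
  n <- length(a)
  # count of null values >= |z| via binary search on the sorted magnitudes;
  # left.open makes exact ties count in favour of the null (>= convention)
  ge <- n - findInterval(abs(observed_z), a, left.open = TRUE)
  ifelse(is.na(observed_z), NA_real_, (1 + ge) / (1 + n))
}

#' Multiple-testing adjustment of empirical p-values
#'
#' Supported methods: `"holm"` step-down familywise control, `"fdr"`
#' (Benjamini-Hochberg step-up), and `"lfdr"` — the local false discovery
#' rate, concretized as the kernel-density ratio `pi0 * f0(z) / f(z)` with
#' `f0` estimated on the pooled null, `f` on the observed statistics, a shared
#' Silverman bandwidth from the null pool, and the conservative `pi0 = 1`.
#'
#' @param p Numeric vector of p-values in `(0, 1]` (ignored by `"lfdr"`).
#' @param method `"holm"`, `"fdr"`, or `"lfdr"`.
#' @param level Significance level for the `significant` flag.
#' @param z Observed standardized effects (required for `"lfdr"`).
#' @param null Pooled null values (required for `"lfdr"`).
#' @return Tibble with `p`, `adjusted`, `method`, `significant`.
#' @export
adjust_significance <- function(p, method = c("fdr", "holm", "lfdr"),
                                level = 0.01, z = NULL, null = NULL) {
  method <- match.arg(method)
  adjusted <- switch(method,
    holm = stats::p.adjust(p, "holm"),
    fdr = stats::p.adjust(p, "BH"),
    lfdr = {
      if (is.null(z) || is.null(null)) {
        stop("lfdr requires the observed z values and the null pool",
             call. = FALSE)
      }
      .lfdr(z, null)
    }
  )
  tibble::tibble(p = p, adjusted = adjusted, method = method,
                 significant = !is.na(adjusted) & adjusted <= level)
}

.lfdr <- function(z, null) {
  bw <- stats::bw.nrd0(null)
  f0 <- stats::density(null, bw = bw, n = 2048,
                       from = min(c(z, null), na.rm = TRUE) - 3 * bw,
                       to = max(c(z, null), na.rm = TRUE) + 3 * bw)
  zf <- z[is.finite(z)]
  f1 <- stats::density(zf, bw = bw, n = 2048, from = f0$x[1],
                       to = f0$x[length(f0$x)])
  d0 <- stats::approx(f0$x, f0$y, xout = z)$y
  d1 <- stats::approx(f1$x, f1$y, xout = z)$y
  pmin(1, d0 / pmax(d1, .Machine$double.eps))
}

#' Significance table for directed influences
#'
#' Expands an [estimate_influences()] table into one row per directed edge,
#' attaches empirical p-values from the variant-variant null pool, and
#' adjusts for multiple testing.
#'
#' @param inf An [estimate_influences()] tibble.
#' @param null A [build_null()] result.
#' @param method,level Passed to [adjust_significance()].
#' @return Tibble with one row per directed edge: `source`, `target`, `m`,
#'   `se`, `z`, `p`, `adjusted`, `method`, `significant`.
#' @export
significance_table <- function(inf, null, method = "fdr", level = 0.01) {
  stopifnot(inherits(null, "null_distributions"))
  res <- dplyr::filter(inf, .data$status == "resolved")
  edges <- tibble::tibble(
    source = c(res$marker1, res$marker2),
    target = c(res$marker2, res$marker1),
    m = c(res$m12, res$m21),
    se = c(res$se_m12, res$se_m21),
    z = c(res$z_m12, res$z_m21)
  )
  edges <- dplyr::filter(edges, is.finite(.data$z))
  edges$p <- empirical_p(edges$z, null$variant_variant)
  adj <- adjust_significance(edges$p, method = method, level = level,
                             z = edges$z, null = null$variant_variant)
  edges$adjusted <- adj$adjusted
  edges$method <- method
  edges$significant <- adj$significant
  edges
}
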