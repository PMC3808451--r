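#' Simulate backcross genotypes with map-driven linkage
#'
#' One chromosome at a time: the first marker is Bernoulli(1/2) in `{0, 1}`
#' (homozygous recurrent parent vs heterozygote); each subsequent marker
#' recombines against the previous one with the Haldane (no-interference)
#' probability `r = (1 - exp(-2 d / 100)) / 2` for spacing `d` cM.
#' Chromosomes are independent.
#'
#' @param n Number of individuals.
#' @param chromosomes List of `c(n_markers, spacing_cM)` pairs, one per
#'   chromosome.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `geno` (n x total markers, 0/1) and `map` (tibble:
#'   `marker`, `chr`, `pos`). Markers are named `D<chr>M<index>`.
#' @export
simulate_backcross <- function(n, chromosomes, seed = 1) {
  stopifnot(n >= 1, length(chromosomes) >= 1)
  withr::with_seed(seed, {
    geno <- list()
    map <- list()
    for (ci in seq_along(chromosomes)) {
      nm <- chromosomes[[ci]][1]
      d <- chromosomes[[ci]][2]
      stopifnot(nm >= 1, d >= 0)
      r <- 0.5 * (1 - exp(-2 * d / 100))
      G <- matrix(0L, n, nm)
      G[, 1] <- stats::rbinom(n, 1, 0.5)
      if (nm > 1) {
        for (j in 2:nm) {
          flip <- stats::rbinom(n, 1, r)
          G[, j] <- ifelse(flip == 1, 1L - G[, j - 1], G[, j - 1])
        }
      }
      colnames(G) <- sprintf("D%dM%d", ci, seq_len(nm))
      geno[[ci]] <- G
      map[[ci]] <- tibble::tibble(marker = colnames(G),
                                  chr = as.character(ci),
                                  pos = (seq_len(nm) - 1) * d)
    }
    list(geno = do.call(cbind, geno), map = dplyr::bind_rows(map))
  })
}

#' Define a ground-truth generative model
#'
#' @param main_effects Numeric matrix (markers x phenotypes) of additive
#'   effect sizes; rownames are marker names, colnames phenotype names.
#' @param influences Tibble/data frame with columns `source`, `target`, `m`:
#'   directed influence coefficients. The effective dose of the target is
#'   `x_t * (1 + m * x_s)`, so `m = -1` with the source present fully
#'   suppresses the target and the pairwise regression identity
#'   `b12 = m * b_target` holds exactly.
#' @param noise_sd Per-phenotype residual standard deviations (recycled).
#' @param pheno_loadings Numeric vector: per-phenotype loading of one shared
#'   latent trait, used to induce the moderate phenotype correlations the
#'   method needs.
#' @return A `truth_model` list.
#' @export
truth_model <- function(main_effects, influences = NULL, noise_sd = 1,
                        pheno_loadings = NULL) {
  main_effects <- as.matrix(main_effects)
  if (is.null(influences)) {
    influences <- tibble::tibble(source = character(), target = character(),
                                 m = numeric())
  }
  influences <- tibble::as_tibble(influences)
  stopifnot(all(c(influences$source, influences$target) %in%
                  rownames(main_effects)))
  noise_sd <- rep_len(noise_sd, ncol(main_effects))
  stopifnot(all(noise_sd > 0))
  if (is.null(pheno_loadings)) pheno_loadings <- rep(0, ncol(main_effects))
  structure(list(main_effects = main_effects, influences = influences,
                 noise_sd = noise_sd, pheno_loadings = pheno_loadings),
            class = "truth_model")
}

#' Simulate phenotypes from genotypes and a truth model
#'
#' Each influence `(s, t, m)` rescales the target's dose:
#' `dose_t = x_t * (1 + m * x_s)`. Phenotype k is then
#' `dose %*% main_effects[, k] + pheno_loadings[k] * latent + noise`, with one
#' shared standard-normal latent trait per individual and independent
#' Gaussian noise.
#'
#' @param geno 0/1 genotype matrix with marker column names.
#' @param truth A [truth_model()].
#' @param seed Integer seed.
#' @return Numeric phenotype matrix (n x phenotypes).
#' @export
simulate_phenotypes <- function(geno, truth, seed = 1) {
  stopifnot(inherits(truth, "truth_model"))
  me <- truth$main_effects
  stopifnot(all(rownames(me) %in% colnames(geno)))
  dose <- geno[, rownames(me), drop = FALSE]
  for (i in seq_len(nrow(truth$influences))) {
    s <- truth$influences$source[i]
    t <- truth$influences$target[i]
    m <- truth$influences$m[i]
    dose[, t] <- dose[, t] * (1 + m * geno[, s])
  }
  withr::with_seed(seed, {
    n <- nrow(geno)
    latent <- stats::rnorm(n)
    P <- dose %*% me +
      outer(latent, truth$pheno_loadings) +
      sapply(truth$noise_sd, function(s) stats::rnorm(n, 0, s))
    colnames(P) <- colnames(me)
    P
  })
}

#' Ready-made simulation scenarios with known ground truth
#'
#' * `"null"` — 200 individuals, 20 unlinked markers, 2 phenotypes correlated
#'   only through a shared latent trait; no genetic effects at all.
#' * `"one_directed_edge"` — 400 individuals, 12 unlinked markers; the source
#'   marker affects both phenotypes, the target affects only the first, and
#'   the source fully suppresses the target (`m = -1`). The source's
#'   independent effect on the second phenotype is what identifies the
#'   direction.
#' * `"hub"` — one source suppressing three targets.
#' * `"example_like"` — scaled like a classic mouse backcross study: 203
#'   individuals, 83 markers on 19 autosomes at 10 cM spacing, 3 phenotypes
#'   with pairwise correlations near 0.6, one binary covariate column
#'   (`"mom"`) left among the phenotypes for promotion.
#'
#' @param scenario Scenario name.
#' @param seed Integer seed.
#' @return List with `cross` (a [cross()]) and `truth` (a [truth_model()]).
#' @export
make_fixture <- function(scenario = c("null", "one_directed_edge", "hub",
                                      "example_like"),
                         seed = 1) {
  scenario <- match.arg(scenario)
  seeds <- .derive_seeds(seed, 3)
  if (scenario == "null") {
    sim <- simulate_backcross(200, rep(list(c(1, 0)), 20), seeds[1])
    me <- matrix(0, 20, 2,
                 dimnames = list(sim$map$marker, c("ph1", "ph2")))
    truth <- truth_model(me, noise_sd = 1, pheno_loadings = c(0.8, 0.8))
  } else if (scenario == "one_directed_edge") {
    sim <- simulate_backcross(400, rep(list(c(1, 0)), 12), seeds[1])
    me <- matrix(0, 12, 2,
                 dimnames = list(sim$map$marker, c("ph1", "ph2")))
    me["D3M1", ] <- c(1, 1)   # source: pleiotropic
    me["D8M1", 1] <- 1        # target: first phenotype only
    truth <- truth_model(
      me,
      influences = tibble::tibble(source = "D3M1", target = "D8M1", m = -1),
      noise_sd = 1, pheno_loadings = c(0.5, 0.5)
    )
  } else if (scenario == "hub") {
    sim <- simulate_backcross(400, rep(list(c(1, 0)), 12), seeds[1])
    me <- matrix(0, 12, 2,
                 dimnames = list(sim$map$marker, c("ph1", "ph2")))
    me["D2M1", ] <- c(1, 1)
    me[c("D5M1", "D8M1", "D11M1"), 1] <- 1
    truth <- truth_model(
      me,
      influences = tibble::tibble(source = "D2M1",
                                  target = c("D5M1", "D8M1", "D11M1"),
                                  m = -1),
      noise_sd = 1, pheno_loadings = c(0.5, 0.5)
    )
  } else {
    chrs <- rep(list(c(4, 10)), 19)
    for (k in seq_len(83 - 4 * 19)) chrs[[k]][1] <- chrs[[k]][1] + 1
    sim <- simulate_backcross(203, chrs, seeds[1])
    me <- matrix(0, 83, 3,
                 dimnames = list(sim$map$marker,
                                 c("weight", "glucose", "insulin")))
    me["D1M2", ] <- c(0.5, 0.3, 0.5)
    me["D12M2", 1] <- 0.5
    me["D15M2", 1:2] <- c(0.4, 0.4)
    truth <- truth_model(
      me,
      influences = tibble::tibble(source = "D1M2", target = "D12M2",
                                  m = -0.8),
      noise_sd = 0.8, pheno_loadings = c(1, 1, 1)
    )
  }
  P <- simulate_phenotypes(sim$geno, truth, seeds[2])
  if (scenario == "example_like") {
    mom <- withr::with_seed(seeds[3], stats::rbinom(nrow(P), 1, 0.5))
    # maternal covariate modulates weight a little, like a real environment
    P[, "weight"] <- P[, "weight"] + 0.3 * mom
    P <- cbind(P, mom = mom)
  }
  list(cross = cross(P, sim$geno, sim$map), truth = truth)
}

#' Write a truth model as a plain key-value file
#'
#' @param truth A [truth_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_model <- function(truth, path) {
  stopifnot(inherits(truth, "truth_model"))
  me <- truth$main_effects
  lines <- c(
    paste0("phenotypes=", paste(colnames(me), collapse = ",")),
    paste0("noise_sd=", paste(truth$noise_sd, collapse = ",")),
    paste0("pheno_loadings=", paste(truth$pheno_loadings, collapse = ",")),
    unlist(lapply(seq_len(nrow(me)), function(i) {
      if (all(me[i, ] == 0)) return(character())
      paste0("main_effect.", rownames(me)[i], "=",
             paste(me[i, ], collapse = ","))
    })),
    unlist(lapply(seq_len(nrow(truth$influences)), function(i) {
      paste0("influence.", truth$influences$source[i], ".",
             truth$influences$target[i], "=", truth$influences$m[i])
    }))
  )
  writeLines(lines, path)
  invisible(path)
}
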