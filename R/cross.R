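#' Construct a cross object
#'
#' A `cross` bundles the sample-aligned data of a mapping population: a
#' phenotype matrix, a genotype (allele-dosage) matrix, a marker map, and the
#' names of any covariates that have been promoted to pseudo-markers. It is the
#' single source of aligned data for every downstream step.
#'
#' @param pheno Numeric matrix, samples in rows, phenotypes in columns
#'   (column names required). Missing values allowed.
#' @param geno Numeric matrix, samples in rows, markers in columns (column
#'   names required). Entries are allele dosages in `[0, 1]` (backcross:
#'   `{0, 1}`; intercross: `{0, 0.5, 1}`) or `NA`.
#' @param map Data frame with columns `marker`, `chr` (character; `"0"` is
#'   reserved for promoted covariates) and `pos` (cM, may be `NA`), one row per
#'   genotype column, in column order.
#' @param covar Character vector of marker names that are promoted covariates.
#' @param ids Optional sample identifiers; defaults to rownames of `pheno` or
#'   `1..n`.
#'
#' @return An object of class `cross`: a list with elements `pheno`, `geno`,
#'   `map` (tibble), `covar`, `ids`.
#' @export
#' @examples
#' g <- matrix(c(0, 1, 1, 0), 4, 1, dimnames = list(NULL, "m1"))
#' p <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("bw", "glu")))
#' x <- cross(p, g, data.frame(marker = "m1", chr = "1", pos = 0))
#' x
cross <- function(pheno, geno, map, covar = character(), ids = NULL) {
  pheno <- as.matrix(pheno)
  geno <- as.matrix(geno)
  storage.mode(pheno) <- "double"
  storage.mode(geno) <- "double"
  map <- tibble::as_tibble(map)
  if (!all(c("marker", "chr", "pos") %in% names(map))) {
    if (!"pos" %in% names(map)) map$pos <- NA_real_
  }
  map$chr <- as.character(map$chr)
  map$pos <- as.numeric(map$pos)
  if (is.null(ids)) {
    ids <- rownames(pheno)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(pheno)))
  }
  ids <- as.character(ids)

  if (nrow(pheno) != nrow(geno)) {
    stop("phenotype and genotype matrices must have the same number of rows (",
         nrow(pheno), " vs ", nrow(geno), ")", call. = FALSE)
  }
  if (is.null(colnames(pheno)) || is.null(colnames(geno))) {
    stop("pheno and geno require column names", call. = FALSE)
  }
  if (nrow(map) != ncol(geno) || !identical(map$marker, colnames(geno))) {
    stop("map rows must match genotype columns, in order", call. = FALSE)
  }
  if (anyDuplicated(map$marker)) {
    stop("marker names must be unique", call. = FALSE)
  }
  gv <- geno[!is.na(geno)]
  if (length(gv) && (min(gv) < 0 || max(gv) > 1)) {
    stop("genotype dosages must lie in [0, 1]", call. = FALSE)
  }
  if (!all(covar %in% map$marker)) {
    stop("covariate markers not found in map: ",
         paste(setdiff(covar, map$marker), collapse = ", "), call. = FALSE)
  }
  rownames(pheno) <- ids
  rownames(geno) <- ids
  structure(
    list(pheno = pheno, geno = geno, map = map,
         covar = as.character(covar), ids = ids),
    class = "cross"
  )
}

#' @export
print.cross <- function(x, ...) {
  cat("<cross> ", nrow(x$pheno), " individuals\n", sep = "")
  cat("  phenotypes: ", ncol(x$pheno), " (",
      paste(utils::head(colnames(x$pheno), 5), collapse = ", "),
      if (ncol(x$pheno) > 5) ", ..." else "", ")\n", sep = "")
  cat("  markers:    ", ncol(x$geno), " on chromosomes ",
      paste(unique(x$map$chr), collapse = ", "), "\n", sep = "")
  if (length(x$covar)) {
    cat("  covariate pseudo-markers: ", paste(x$covar, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Promote phenotype columns to covariate pseudo-markers
#'
#' Experimental covariates (sex, treatment, maternal environment, ...) are
#' moved out of the phenotype matrix and appended to the genotype matrix on
#' chromosome `"0"`, min-max rescaled to `[0, 1]` so that they behave as
#' allele dosages in every downstream operation (pair enumeration, pair-scan
#' regression, permutation testing).
#'
#' @param x A [cross()].
#' @param names Character vector of phenotype column names to promote.
#' @return A `cross` with the named columns removed from `pheno`, appended to
#'   `geno` on chromosome `"0"`, and listed in `covar`.
#' @export
promote_covariates <- function(x, names) {
  stopifnot(inherits(x, "cross"))
  missing_cols <- setdiff(names, colnames(x$pheno))
  if (length(missing_cols)) {
    stop("phenotype column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(colnames(x$pheno), names)
  if (length(keep) < 2) {
    stop("promoting ", length(names), " covariate(s) would leave fewer than ",
         "2 phenotypes", call. = FALSE)
  }
  newg <- x$geno
  newmap <- x$map
  for (nm in names) {
    v <- x$pheno[, nm]
    rng <- range(v, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      stop("covariate '", nm, "' is constant and cannot be rescaled",
           call. = FALSE)
    }
    v <- (v - rng[1]) / (rng[2] - rng[1])
    newg <- cbind(newg, v)
    colnames(newg)[ncol(newg)] <- nm
    newmap <- dplyr::bind_rows(
      newmap,
      tibble::tibble(marker = nm, chr = "0", pos = NA_real_)
    )
  }
  # covariates sort before autosomes: chromosome "0" first
  ord <- order(newmap$chr != "0")
  newmap <- newmap[ord, , drop = FALSE]
  newg <- newg[, newmap$marker, drop = FALSE]
  cross(x$pheno[, keep, drop = FALSE], newg, newmap,
        covar = union(x$covar, names), ids = x$ids)
}

#' Drop markers fully redundant with their neighbour
#'
#' Scans each chromosome in map order and drops any marker whose genotype
#' column is identical, on jointly observed samples (at least one such
#' sample), to the previous retained marker on the same chromosome. The
#' earlier marker of each redundant run is kept. Exact equality is required:
#' a single differing sample keeps both markers.
#'
#' @param x A [cross()].
#' @return A list with elements `cross` (the reduced cross) and `dropped`
#'   (character vector of removed marker names).
#' @export
drop_redundant_markers <- function(x) {
  stopifnot(inherits(x, "cross"))
  dropped <- character()
  keep <- rep(TRUE, ncol(x$geno))
  chrs <- x$map$chr
  last_kept <- NA_integer_
  last_chr <- NA_character_
  for (j in seq_len(ncol(x$geno))) {
    if (!identical(chrs[j], last_chr)) {
      last_chr <- chrs[j]
      last_kept <- j
      next
    }
    a <- x$geno[, last_kept]
    b <- x$geno[, j]
    both <- !is.na(a) & !is.na(b)
    if (sum(both) >= 1 && all(a[both] == b[both])) {
      keep[j] <- FALSE
      dropped <- c(dropped, x$map$marker[j])
    } else {
      last_kept <- j
    }
  }
  out <- cross(x$pheno, x$geno[, keep, drop = FALSE],
               x$map[keep, , drop = FALSE],
               covar = intersect(x$covar, x$map$marker[keep]), ids = x$ids)
  list(cross = out, dropped = dropped)
}

#' Genotype code presets
#'
#' Named dosage maps for the common cross designs: `"backcross"` codes the
#' two genotype classes `A` (homozygous recurrent parent) and `H`
#' (heterozygote) as 0 and 1; `"intercross"` adds `B` (homozygous donor) with
#' `A`/`H`/`B` as 0/0.5/1. Numeric tokens in the file are always accepted as
#' literal dosages in addition to the map.
#'
#' @param preset `"backcross"` or `"intercross"`, or a named numeric vector
#'   used as-is.
#' @return Named numeric vector mapping text codes to dosages.
#' @export
genotype_codes <- function(preset = c("backcross", "intercross")) {
  if (is.numeric(preset) && !is.null(names(preset))) {
    return(preset)
  }
  preset <- match.arg(preset)
  switch(preset,
    backcross = c(A = 0, H = 1),
    intercross = c(A = 0, H = 0.5, B = 1)
  )
}
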