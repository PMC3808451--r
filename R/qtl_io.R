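#' Read a cross from an R/qtl "csv" file
#'
#' Parses the single-file comma-separated cross format: the first row holds
#' phenotype names followed by marker names; the second row is blank under the
#' phenotype columns and carries the chromosome label under each marker; an
#' optional third row carries cM positions (blank under phenotypes); every
#' following row is one individual. Phenotype and genotype blocks are split by
#' the blank-chromosome convention.
#'
#' @param path Path to the CSV file.
#' @param genotype_codes Named numeric vector mapping genotype text codes to
#'   dosages in `[0, 1]`; see [genotype_codes()]. Numeric tokens are accepted
#'   as literal dosages. Required — the format does not declare its own codes.
#' @param missing_codes Character vector of tokens treated as missing.
#' @return A [cross()].
#' @export
read_cross_csv <- function(path,
                           genotype_codes = pleionet::genotype_codes("backcross"),
                           missing_codes = c("-", "NA", "")) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE, blank.lines.skip = FALSE,
                         na.strings = NULL)
  if (nrow(raw) < 3) stop("malformed cross file: fewer than 3 rows", call. = FALSE)
  raw[] <- lapply(raw, trimws)
  header <- as.character(raw[1, ])
  chr_row <- as.character(raw[2, ])

  is_pheno <- chr_row == ""
  if (!any(is_pheno)) {
    stop("malformed header: no phenotype block (row 2 has no blank ",
         "chromosome cells)", call. = FALSE)
  }
  if (!all(diff(is_pheno) <= 0)) {
    stop("malformed header: phenotype columns (blank chromosome in row 2) ",
         "must precede marker columns", call. = FALSE)
  }
  n_ph <- sum(is_pheno)
  n_mk <- ncol(raw) - n_ph
  if (n_mk == 0) stop("cross file contains zero markers", call. = FALSE)
  if (n_ph == 0) stop("cross file contains zero phenotypes", call. = FALSE)

  # optional position row: blank under all phenotype columns; blank marker
  # cells (e.g. covariate pseudo-markers) mean "no position"
  row3 <- as.character(raw[3, ])
  mk3 <- row3[!is_pheno]
  has_pos <- all(row3[is_pheno] == "") &&
    all(mk3 == "" | suppressWarnings(!is.na(as.numeric(mk3))))
  pos <- if (has_pos) {
    suppressWarnings(as.numeric(ifelse(mk3 == "", NA, mk3)))
  } else {
    rep(NA_real_, n_mk)
  }
  data_start <- if (has_pos) 4L else 3L
  if (nrow(raw) < data_start) {
    stop("cross file has no individual rows", call. = FALSE)
  }
  body <- raw[seq(data_start, nrow(raw)), , drop = FALSE]

  ph_txt <- as.matrix(body[, is_pheno, drop = FALSE])
  ph_txt[ph_txt %in% missing_codes] <- NA
  pheno <- matrix(suppressWarnings(as.numeric(ph_txt)), nrow(body), n_ph,
                  dimnames = list(NULL, header[is_pheno]))
  bad_ph <- !is.na(ph_txt) & is.na(pheno)
  if (any(bad_ph)) {
    idx <- which(bad_ph, arr.ind = TRUE)[1, ]
    stop("non-numeric phenotype value '", ph_txt[bad_ph][1], "' at row ",
         idx[1] + data_start - 1, ", phenotype '",
         header[is_pheno][idx[2]], "'", call. = FALSE)
  }

  gt_txt <- as.matrix(body[, !is_pheno, drop = FALSE])
  geno <- matrix(NA_real_, nrow(body), n_mk,
                 dimnames = list(NULL, header[!is_pheno]))
  is_missing <- array(gt_txt %in% missing_codes, dim(gt_txt))
  coded <- !is_missing & array(gt_txt %in% names(genotype_codes), dim(gt_txt))
  geno[coded] <- genotype_codes[gt_txt[coded]]
  left <- !is_missing & !coded
  if (any(left)) {
    num <- suppressWarnings(as.numeric(gt_txt[left]))
    if (anyNA(num)) {
      bad <- unique(gt_txt[left][is.na(num)])
      idx <- which(left, arr.ind = TRUE)
      first <- idx[which(is.na(num))[1], ]
      stop("unknown genotype code(s): ", paste(bad, collapse = ", "),
           " (first at row ", first[1] + data_start - 1, ", marker '",
           header[!is_pheno][first[2]], "')", call. = FALSE)
    }
    geno[left] <- num
  }

  map <- tibble::tibble(marker = header[!is_pheno],
                        chr = chr_row[!is_pheno], pos = pos)
  # chromosome "0" is reserved for promoted covariates
  cross(pheno, geno, map, covar = map$marker[map$chr == "0"])
}

#' Write a cross to an R/qtl "csv" file
#'
#' Inverse of [read_cross_csv()]. Genotypes are written as text codes when an
#' exact inverse of `genotype_codes` applies, otherwise as numeric dosages;
#' missing values are written as `missing_code`. Promoted covariates are
#' written like any other marker (their chromosome `"0"` identifies them).
#'
#' @param x A [cross()].
#' @param path Output file path.
#' @param genotype_codes Named numeric vector; dosages matching a code value
#'   exactly are written as the code.
#' @param missing_code Token for missing values.
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(x, path,
                            genotype_codes = pleionet::genotype_codes("backcross"),
                            missing_code = "-") {
  stopifnot(inherits(x, "cross"))
  n_ph <- ncol(x$pheno)
  n_mk <- ncol(x$geno)
  header <- c(colnames(x$pheno), x$map$marker)
  chr_row <- c(rep("", n_ph), x$map$chr)
  pos_row <- c(rep("", n_ph),
               ifelse(is.na(x$map$pos), "", format(x$map$pos, trim = TRUE)))

  inv <- stats::setNames(names(genotype_codes), as.character(genotype_codes))
  gt <- matrix(as.character(x$geno), nrow(x$geno), n_mk)
  hit <- !is.na(x$geno) & as.character(x$geno) %in% names(inv) &
    !x$map$marker[col(x$geno)] %in% x$covar
  gt[hit] <- inv[as.character(x$geno)[hit]]
  gt[is.na(x$geno)] <- missing_code
  ph <- matrix(as.character(x$pheno), nrow(x$pheno), n_ph)
  ph[is.na(x$pheno)] <- missing_code

  lines <- c(
    paste(header, collapse = ","),
    paste(chr_row, collapse = ","),
    if (any(pos_row != "")) paste(pos_row, collapse = ","),
    apply(cbind(ph, gt), 1, paste, collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
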