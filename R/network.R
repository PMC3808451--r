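#' Consolidate marker main effects across pairings
#'
#' Every tested pair containing a marker yields one main-effect estimate for
#' that marker per ET. Consolidation keeps, per (marker, ET), the entry with
#' the largest empirical p — the most conservative surviving effect — so a
#' main effect is claimed only if it survives conditioning on every tested
#' partner (this is what makes a fully suppressed effect vanish from the
#' network). The chosen ET-space effect vector is back-projected to phenotype
#' space for reporting per-phenotype sign and magnitude.
#'
#' @param ps A [pair_scan()] tibble.
#' @param basis The [eigentrait_decomp()] used for the scan.
#' @param null A [build_null()] result (variant-phenotype pool).
#' @return List with `by_et` (tibble: `marker`, `et`, `estimate`, `se`, `z`,
#'   `p`, `partner` — the pairing that delivered the conservative entry) and
#'   `by_phenotype` (tibble: `marker`, `phenotype`, `effect` — back-projected
#'   consolidated coefficients, plus `z_proj`, the back-projection of the
#'   consolidated z vector used as the display weight).
#' @export
consolidate_main_effects <- function(ps, basis, null) {
  stopifnot(inherits(null, "null_distributions"))
  long <- dplyr::bind_rows(
    ps |> dplyr::filter(.data$status == "resolved") |>
      dplyr::transmute(marker = .data$marker1, partner = .data$marker2,
                       et = .data$et, estimate = .data$b1, se = .data$se1,
                       z = .data$t1),
    ps |> dplyr::filter(.data$status == "resolved") |>
      dplyr::transmute(marker = .data$marker2, partner = .data$marker1,
                       et = .data$et, estimate = .data$b2, se = .data$se2,
                       z = .data$t2)
  ) |> dplyr::filter(is.finite(.data$z))
  long$p <- empirical_p(long$z, null$variant_phenotype)
  by_et <- long |>
    dplyr::group_by(.data$marker, .data$et) |>
    dplyr::slice_max(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("marker", "et", "estimate", "se", "z", "p", "partner")

  sel <- basis$selected
  by_phenotype <- by_et |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(d, key) {
      b <- d$estimate[match(sel, d$et)]
      zv <- d$z[match(sel, d$et)]
      b[is.na(b)] <- 0
      zv[is.na(zv)] <- 0
      eff <- back_project_effects(b, basis)
      # display scale for the dimensionless z vector: singular values in
      # per-sample (phenotype-sd) units, so z_proj stays O(z)
      zproj <- back_project_effects(zv, basis) / sqrt(nrow(basis$U) - 1)
      tibble::tibble(phenotype = names(eff), effect = unname(eff),
                     z_proj = unname(zproj))
    }) |>
    dplyr::ungroup()
  list(by_et = by_et, by_phenotype = by_phenotype)
}

#' Assemble the directed interaction network
#'
#' Builds the asymmetric adjacency matrix of significant effects: source
#' markers in rows; target markers, then phenotypes, in columns. A
#' marker-to-marker cell holds the standardized directed influence `z` when
#' that edge is significant at `level`, else 0. Marker-to-phenotype columns
#' hold the back-projection of the consolidated main-effect z's restricted to
#' ETs significant at the same level. Pairs excluded by the LD filter are
#' recorded in a parallel `untested` mask.
#'
#' @param sig A [significance_table()] tibble (directed variant-variant
#'   edges).
#' @param main A [consolidate_main_effects()] result.
#' @param filter A [enumerate_pairs()] result.
#' @param x The [cross()] (for marker ordering: chromosome `"0"` covariates
#'   first, then chromosome and position).
#' @param basis The [eigentrait_decomp()] (phenotype names and back-projection
#'   of significant ET effects).
#' @param null A [build_null()] result (to threshold consolidated main
#'   effects).
#' @param method,level Significance method and level shared by both edge
#'   kinds.
#' @return An `interaction_network`: list with `weights` (matrix), `untested`
#'   (logical matrix over marker columns), `markers`, `phenotypes`,
#'   `metadata`.
#' @export
build_adjacency <- function(sig, main, filter, x, basis, null,
                            method = "fdr", level = 0.01) {
  stopifnot(inherits(x, "cross"), inherits(filter, "pair_filter"))
  map <- x$map
  suppressWarnings(chrnum <- as.numeric(map$chr))
  ord <- order(map$chr != "0", chrnum, map$pos, method = "radix",
               na.last = TRUE)
  markers <- map$marker[ord]
  phenos <- basis$phenotypes
  bad <- setdiff(unique(c(sig$source, sig$target, main$by_et$marker)), markers)
  if (length(bad)) {
    stop("markers absent from the cross map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  W <- matrix(0, length(markers), length(markers) + length(phenos),
              dimnames = list(markers, c(markers, phenos)))
  hit <- dplyr::filter(sig, .data$significant)
  if (nrow(hit)) {
    W[cbind(hit$source, hit$target)] <- hit$z
  }

  # marker -> phenotype columns from significant consolidated main effects
  me <- main$by_et
  adj <- adjust_significance(me$p, method = method, level = level,
                             z = me$z, null = null$variant_phenotype)
  me$significant <- adj$significant
  sel <- basis$selected
  for (mk in unique(me$marker)) {
    d <- me[me$marker == mk, ]
    zv <- rep(0, length(sel))
    keep <- d$et[d$significant]
    if (!length(keep)) next
    zv[match(keep, sel)] <- d$z[d$significant]
    W[mk, phenos] <- back_project_effects(zv, basis) / sqrt(nrow(basis$U) - 1)
  }

  untested <- matrix(FALSE, length(markers), length(markers),
                     dimnames = list(markers, markers))
  ld <- dplyr::filter(filter$pairs, .data$status != "tested")
  if (nrow(ld)) {
    untested[cbind(ld$marker1, ld$marker2)] <- TRUE
    untested[cbind(ld$marker2, ld$marker1)] <- TRUE
  }
  structure(
    list(weights = W, untested = untested, markers = markers,
         phenotypes = phenos,
         metadata = list(method = method, level = level,
                         n_perm = null$n_perm)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  nm <- length(x$markers)
  vv <- sum(x$weights[, x$markers] != 0)
  vp <- sum(x$weights[, x$phenotypes] != 0)
  cat("<interaction_network> ", nm, " markers, ", length(x$phenotypes),
      " phenotypes\n", sep = "")
  cat("  significant edges: ", vv, " variant-variant, ", vp,
      " variant-phenotype (", x$metadata$method, " <= ",
      x$metadata$level, ", ", x$metadata$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Tidy a network into an edge list
#'
#' One row per nonzero (significant) edge, strongest first.
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A tibble with `source`, `target`, `weight`, `sign`, `kind`.
#' @export
tidy.interaction_network <- function(x, ...) {
  net <- x
  W <- net$weights
  nz <- which(W != 0, arr.ind = TRUE)
  tibble::tibble(
    source = rownames(W)[nz[, 1]],
    target = colnames(W)[nz[, 2]],
    weight = W[nz],
    sign = ifelse(W[nz] > 0, "enhancing", "suppressive"),
    kind = ifelse(colnames(W)[nz[, 2]] %in% net$phenotypes,
                  "variant_phenotype", "variant_variant")
  ) |> dplyr::arrange(dplyr::desc(abs(.data$weight)))
}

#' @rdname tidy.interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  net <- x
  tibble::tibble(
    n_markers = length(net$markers),
    n_phenotypes = length(net$phenotypes),
    n_edges_vv = sum(net$weights[, net$markers] != 0),
    n_edges_vp = sum(net$weights[, net$phenotypes] != 0),
    n_untested_pairs = sum(net$untested[upper.tri(net$untested)]),
    method = net$metadata$method,
    level = net$metadata$level
  )
}

#' Export a network to disk
#'
#' `"adjacency_csv"` writes the full labelled weight matrix plus a parallel
#' `<path>_untested.csv` mask; `"edge_list"` writes one row per nonzero edge
#' (source, target, weight, sign, kind); `"graphml"` writes standard GraphML
#' with `weight`, `sign` and `kind` edge attributes (readable by igraph,
#' Cytoscape, Gephi).
#'
#' @param net An `interaction_network`.
#' @param path Output file path.
#' @param format One of `"adjacency_csv"`, `"edge_list"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("adjacency_csv", "edge_list", "graphml")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  if (format == "adjacency_csv") {
    utils::write.csv(net$weights, path, row.names = TRUE)
    mask_path <- sub("(\\.csv)?$", "_untested.csv",
                     path)[1]
    utils::write.csv(net$untested, mask_path, row.names = TRUE)
  } else if (format == "edge_list") {
    utils::write.csv(tidy.interaction_network(net), path, row.names = FALSE)
  } else {
    el <- tidy.interaction_network(net)
    g <- igraph::graph_from_data_frame(
      el, directed = TRUE,
      vertices = data.frame(name = c(net$markers, net$phenotypes),
                            kind = c(rep("marker", length(net$markers)),
                                     rep("phenotype", length(net$phenotypes))))
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an adjacency CSV
#' @param path Path written by [export_network()] with `"adjacency_csv"`.
#' @return Numeric matrix with dimnames.
#' @export
read_adjacency_csv <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}
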