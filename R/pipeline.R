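#' Configuration for a full analysis run
#'
#' Defaults follow the canonical analysis settings: first two eigentraits,
#' every two-locus genotype class needs at least 6 observations, 100
#' permutations, FDR correction at level 0.01.
#'
#' @param input Path to an R/qtl "csv" cross file, or a [cross()] object.
#' @param covariates Phenotype columns to promote to covariate pseudo-markers.
#' @param genotype_preset `"backcross"`, `"intercross"`, or a named dosage
#'   map (ignored when `input` is already a cross).
#' @param n_ets Number of leading eigentraits to analyze (2..12).
#' @param min_class_count LD pair-filter threshold.
#' @param t_threshold Optional |t| cutoff: markers exceeding it in the single
#'   scan become pair-scan regression covariates. `NULL` disables.
#' @param n_perm Number of permutations for the null pools.
#' @param method Multiple-testing method: `"fdr"`, `"holm"`, or `"lfdr"`.
#' @param level Significance level.
#' @param seed Master seed for all randomness.
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output.
#' @param max_pairs,max_perm Optional caps on tested pairs (by map order) and
#'   permutations, for preliminary runs.
#' @return A `run_config` list.
#' @export
run_config <- function(input, covariates = character(),
                       genotype_preset = "backcross", n_ets = 2,
                       min_class_count = 6, t_threshold = NULL,
                       n_perm = 100, method = "fdr", level = 0.01,
                       seed = 1, out_dir = NULL,
                       max_pairs = NULL, max_perm = NULL) {
  stopifnot(n_ets >= 2, n_ets <= 12, n_perm >= 1, level > 0, level <= 1)
  structure(
    list(input = input, covariates = covariates,
         genotype_preset = genotype_preset, n_ets = n_ets,
         min_class_count = min_class_count, t_threshold = t_threshold,
         n_perm = n_perm, method = method, level = level, seed = seed,
         out_dir = out_dir, max_pairs = max_pairs, max_perm = max_perm),
    class = "run_config"
  )
}

#' Run the full directed-network analysis
#'
#' Executes the whole workflow: read (or take) the cross, promote covariates,
#' drop fully redundant markers, normalize phenotypes, decompose into
#' eigentraits, single-marker scan, pair enumeration with the LD filter,
#' two-locus pair scan, reparametrization into directed influences,
#' permutation null pools, empirical p-values, multiple-testing adjustment,
#' main-effect consolidation, network assembly, and (when `out_dir` is set)
#' export of every table plus a machine-readable JSON manifest and a log. The
#' run is fully reproducible from the manifest.
#'
#' @param config A [run_config()].
#' @param preliminary Internal flag set by [preview_run()].
#' @return A `pleionet_run` list: `cross`, `basis`, `single`, `filter`,
#'   `pairscan`, `influences`, `null`, `sig`, `main_effects`, `network`,
#'   `manifest`.
#' @export
run_full_analysis <- function(config, preliminary = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
  }
  stage <- "read"
  manifest <- list(config = config[setdiff(names(config), "input")],
                  preliminary = preliminary, stages = list())
  result <- tryCatch({
    x <- if (inherits(config$input, "cross")) {
      config$input
    } else {
      read_cross_csv(config$input,
                     genotype_codes = genotype_codes(config$genotype_preset))
    }
    say("read: ", nrow(x$pheno), " individuals, ", ncol(x$pheno),
        " phenotypes, ", ncol(x$geno), " markers")
    manifest$stages$read <- list(n = nrow(x$pheno),
                                 n_pheno = ncol(x$pheno),
                                 n_markers = ncol(x$geno))

    stage <- "covariates"
    if (length(config$covariates)) {
      x <- promote_covariates(x, config$covariates)
      say("promoted covariates: ", paste(config$covariates, collapse = ", "))
    }

    stage <- "redundant_markers"
    rd <- drop_redundant_markers(x)
    x <- rd$cross
    say("dropped ", length(rd$dropped), " fully redundant marker(s)")
    manifest$stages$markers <- list(dropped = rd$dropped,
                                    retained = ncol(x$geno))

    stage <- "normalize"
    nz <- normalize_phenotypes(x$pheno)

    stage <- "eigentraits"
    basis <- eigentrait_decomp(nz$P_norm)
    basis <- select_ets(basis, min(config$n_ets, length(basis$d)))
    say("eigentraits: ", length(basis$d), " ETs, selected ",
        length(basis$selected), "; ", nrow(x$pheno) - nrow(basis$U),
        " incomplete phenotype row(s) dropped")
    manifest$stages$eigentraits <- list(
      n_complete = nrow(basis$U),
      variance_fractions = variance_fractions(basis),
      selected = basis$selected)

    stage <- "single_scan"
    single <- single_scan(x, basis, covariates = config$covariates)
    reg_covars <- config$covariates
    if (!is.null(config$t_threshold)) {
      extra <- select_marker_covariates(single, config$t_threshold)
      reg_covars <- union(reg_covars, extra)
      say("marker covariates above |t| = ", config$t_threshold, ": ",
          paste(extra, collapse = ", "))
    }

    stage <- "enumerate_pairs"
    filter <- enumerate_pairs(x, min_class_count = config$min_class_count)
    pairs <- tested_pairs(filter)
    n_candidates <- nrow(filter$pairs)
    if (!is.null(config$max_pairs) && nrow(pairs) > config$max_pairs) {
      pairs <- pairs[seq_len(config$max_pairs), ]
      say("pair cap applied: ", config$max_pairs)
    }
    say("pairs: ", n_candidates, " candidates, ", nrow(pairs), " tested, ",
        sum(filter$pairs$status == "excluded_ld"), " excluded (LD)")
    manifest$stages$pairs <- list(
      candidates = n_candidates, tested = nrow(pairs),
      excluded_ld = sum(filter$pairs$status == "excluded_ld"),
      excluded_other = sum(filter$pairs$status == "excluded_other"))

    stage <- "pair_scan"
    ps <- pair_scan(x, basis, pairs, covariates = reg_covars)

    stage <- "reparametrize"
    inf <- estimate_influences(ps)
    say("influences: ", sum(inf$status == "resolved"), " resolved of ",
        nrow(inf), " pairs")
    manifest$stages$influences <- list(
      resolved = sum(inf$status == "resolved"),
      unresolved = sum(inf$status == "unresolved"),
      degenerate = sum(inf$status == "degenerate"))

    stage <- "permutations"
    n_perm <- config$n_perm
    if (!is.null(config$max_perm)) n_perm <- min(n_perm, config$max_perm)
    null <- build_null(ps, basis, n_perm = n_perm, seed = config$seed)
    say("null pools: ", length(null$variant_variant), " variant-variant, ",
        length(null$variant_phenotype), " variant-phenotype (",
        n_perm, " permutations)")
    manifest$stages$permutations <- list(
      n_perm = n_perm,
      pool_vv = length(null$variant_variant),
      pool_vp = length(null$variant_phenotype),
      p_floor = 1 / (length(null$variant_variant) + 1))

    stage <- "significance"
    sig <- significance_table(inf, null, method = config$method,
                              level = config$level)

    stage <- "main_effects"
    main <- consolidate_main_effects(ps, basis, null)

    stage <- "network"
    net <- build_adjacency(sig, main, filter, x, basis, null,
                           method = config$method, level = config$level)
    say("network: ", sum(net$weights[, net$markers] != 0),
        " variant-variant edges, ",
        sum(net$weights[, net$phenotypes] != 0),
        " variant-phenotype edges at ", config$method, " <= ", config$level)
    manifest$stages$network <- glance.interaction_network(net)

    manifest$seed <- config$seed
    manifest$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    run <- structure(
      list(cross = x, basis = basis, single = single, filter = filter,
           pairscan = ps, influences = inf, null = null, sig = sig,
           main_effects = main, network = net, manifest = manifest,
           log = log_lines),
      class = "pleionet_run"
    )
    if (!is.null(config$out_dir)) .write_run_outputs(run, config)
    run
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    stop("analysis failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

.write_run_outputs <- function(run, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  et_report(run$basis, file.path(out, "et_report.csv"))
  utils::write.csv(run$single, file.path(out, "single_scan.csv"),
                   row.names = FALSE)
  utils::write.csv(run$filter$pairs, file.path(out, "pair_filter.csv"),
                   row.names = FALSE)
  for (e in run$basis$selected) {
    interaction_matrix(run$pairscan, e, markers = run$network$markers,
                       path = file.path(out, sprintf("b12_matrix_et%d.csv", e)))
  }
  utils::write.csv(run$influences, file.path(out, "influences.csv"),
                   row.names = FALSE)
  utils::write.csv(run$sig, file.path(out, "significance.csv"),
                   row.names = FALSE)
  utils::write.csv(run$main_effects$by_et,
                   file.path(out, "main_effects_by_et.csv"), row.names = FALSE)
  utils::write.csv(run$main_effects$by_phenotype,
                   file.path(out, "main_effects_by_phenotype.csv"),
                   row.names = FALSE)
  writeLines(format(run$null$variant_variant, trim = TRUE, digits = 10),
             file.path(out, "null_variant_variant.txt"))
  writeLines(format(run$null$variant_phenotype, trim = TRUE, digits = 10),
             file.path(out, "null_variant_phenotype.txt"))
  export_network(run$network, file.path(out, "adjacency.csv"),
                 "adjacency_csv")
  export_network(run$network, file.path(out, "edges.csv"), "edge_list")
  export_network(run$network, file.path(out, "network.graphml"), "graphml")
  jsonlite::write_json(run$manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(out, "run.log"))
  invisible(out)
}

#' @export
print.pleionet_run <- function(x, ...) {
  cat("<pleionet_run>", if (isTRUE(x$manifest$preliminary)) " (preliminary)",
      "\n", sep = "")
  print(x$network)
  invisible(x)
}

#' Preliminary run with fewer permutations
#'
#' Same pipeline as [run_full_analysis()], but with a reduced permutation
#' count; outputs are tagged `preliminary` in the manifest. Because null
#' pools concatenate statistics over all pairs, even a handful of
#' permutations yields a usable provisional null (the attainable p-value
#' floor `1 / (pool size + 1)` is reported in the manifest).
#'
#' @param config A [run_config()]; `n_perm` here is the reduced count and
#'   must be below `full_n_perm`.
#' @param full_n_perm The permutation count a full run would use.
#' @return A `pleionet_run`, tagged preliminary.
#' @export
preview_run <- function(config, full_n_perm = 100) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_perm >= full_n_perm) {
    stop("preview requires n_perm (", config$n_perm,
         ") below the full count (", full_n_perm, ")", call. = FALSE)
  }
  run_full_analysis(config, preliminary = TRUE)
}

#' @rdname tidy.interaction_network
#' @export
glance.pleionet_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_individuals = nrow(x$cross$pheno),
      n_perm = x$null$n_perm,
      preliminary = isTRUE(x$manifest$preliminary)
    ),
    glance.interaction_network(x$network)
  )
}
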