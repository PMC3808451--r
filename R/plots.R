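#' Plot eigentrait variance fractions and phenotype loadings
#'
#' Bar panel of the global variance fraction per ET alongside the phenotype
#' loading composition of each ET.
#'
#' @param basis An [eigentrait_decomp()] result.
#' @return A ggplot object.
#' @export
plot_eigentraits <- function(basis) {
  d <- tidy.eigentrait_basis(basis)
  d$et <- factor(paste0("ET", d$et),
                 levels = paste0("ET", seq_along(basis$d)))
  lab <- tibble::tibble(
    et = factor(paste0("ET", seq_along(basis$d)),
                levels = levels(d$et)),
    vf = variance_fractions(basis)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phenotype, y = .data$loading,
                                  fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$et)) +
    ggplot2::geom_text(
      data = lab, inherit.aes = FALSE,
      ggplot2::aes(x = Inf, y = Inf,
                   label = sprintf("%.1f%% var", 100 * .data$vf)),
      hjust = 1.1, vjust = 1.5, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "loading",
                  title = "Eigentrait composition") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eigentrait_basis <- function(object, ...) plot_eigentraits(object)

#' Heatmap of pair-scan interaction coefficients for one ET
#'
#' @param ps A [pair_scan()] tibble.
#' @param et Which selected ET to show.
#' @param markers Optional marker ordering.
#' @return A ggplot object.
#' @export
plot_interaction_matrix <- function(ps, et, markers = NULL) {
  M <- interaction_matrix(ps, et, markers = markers)
  d <- tibble::as_tibble(as.data.frame(as.table(M), stringsAsFactors = FALSE))
  names(d) <- c("marker1", "marker2", "b12")
  d$marker1 <- factor(d$marker1, levels = rownames(M))
  d$marker2 <- factor(d$marker2, levels = rev(colnames(M)))
  ggplot2::ggplot(d, ggplot2::aes(.data$marker1, .data$marker2,
                                  fill = .data$b12)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "b12",
                  title = sprintf("Interaction coefficients, ET%d", et)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Adjacency heatmap of a directed interaction network
#'
#' Sources in rows, targets (markers then phenotypes) in columns; red =
#' suppressive, blue = enhancing, grey = pairs untested under the LD filter.
#'
#' @param net An `interaction_network`.
#' @return A ggplot object.
#' @export
plot_network_adjacency <- function(net) {
  W <- net$weights
  d <- tibble::as_tibble(as.data.frame(as.table(W), stringsAsFactors = FALSE))
  names(d) <- c("source", "target", "weight")
  um <- net$untested
  d$untested <- FALSE
  idx <- d$target %in% colnames(um)
  d$untested[idx] <- um[cbind(d$source[idx], d$target[idx])]
  d$weight[d$weight == 0] <- NA
  d$source <- factor(d$source, levels = rev(rownames(W)))
  d$target <- factor(d$target, levels = colnames(W))
  ggplot2::ggplot(d, ggplot2::aes(.data$target, .data$source)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$weight)) +
    ggplot2::geom_point(data = dplyr::filter(d, .data$untested),
                        colour = "grey60", size = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", na.value = "white") +
    ggplot2::labs(x = "target", y = "source", fill = "z",
                  title = "Directed influences (significant edges)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.interaction_network <- function(object, ...) {
  plot_network_adjacency(object)
}
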