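#' Plot the delta-index scan
#'
#' Standard BSA-seq scan figure: per-window mean delta index along each
#' chromosome for the SNP and InDel tracks, the simulated null CI band at
#' the first configured level, and the association threshold lines.
#'
#' @param object A [bsa_scan()] object.
#' @param chrom Optional chromosome subset.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_scan <- function(object, chrom = NULL, ...) {
  w <- tidy(object)
  if (!is.null(chrom)) w <- w[w$chrom %in% chrom, ]
  w <- w[w$reliable, ]
  lv1 <- sprintf("ci_lo_%g", object$config$ci_levels[1] * 100)
  hv1 <- sprintf("ci_hi_%g", object$config$ci_levels[1] * 100)
  thr <- object$config$delta_threshold
  mid <- (w$start + w$end) / 2
  ggplot2::ggplot(w, ggplot2::aes(x = mid / 1e6, y = .data$mean_delta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lv1]], ymax = .data[[hv1]]),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$track)) +
    ggplot2::geom_hline(yintercept = c(-thr, thr),
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::facet_grid(.data$track ~ .data$chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(Delta ~ "(index)"),
                  colour = NULL) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype-phenotype comparison
#'
#' Phenotype distributions of REF and ALT carriers per environment
#' (boxplots), annotated with the Welch p-values.
#'
#' @param object A [haplotype_compare()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_haplotype <- function(object, ...) {
  d <- object$data
  lab <- object$tests |>
    mutate(label = ifelse(.data$tested, sprintf("p = %.2g", .data$p_value), "n.t."))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$allele, y = .data$phenotype,
                                  fill = .data$allele)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~environment, nrow = 1) +
    ggplot2::geom_text(data = lab, inherit.aes = FALSE, size = 3,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$label),
                       vjust = 1.5) +
    ggplot2::labs(x = NULL, y = "phenotype") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot GO enrichment results
#'
#' Dot plot of enriched terms: study-set count against term, sized by the
#' annotated background count and coloured by p-value.
#'
#' @param object A [go_enrich()] result.
#' @param max_terms Show at most this many terms, smallest p first
#'   (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_enrichment <- function(object, max_terms = 20, ...) {
  d <- as_tibble(utils::head(object, max_terms))
  d$term <- factor(d$term, levels = rev(unique(d$term)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count, y = .data$term,
                                  size = .data$annotated,
                                  colour = .data$p_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "study-set count", y = NULL,
                  size = "annotated", colour = "p") +
    ggplot2::theme_minimal()
}
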