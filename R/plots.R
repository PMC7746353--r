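#' Composition bar chart
#'
#' Stacked per-group bars of the TPM-weighted fraction of each tsRNA
#' type (or amino-acid family, or length).
#'
#' @param comp Composition tibble from [composition()].
#' @param dimension Which breakdown to show: `"type"` (default),
#'   `"amino_acid"` or `"length"`.
#' @return A ggplot object.
#' @export
plot_composition <- function(comp, dimension = "type") {
  dat <- comp |> filter(.data$dimension == !!dimension)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$fraction,
                                    fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "share of total TPM", fill = dimension) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential tsRNAs
#'
#' @param object A `tsrna_diff` result from [diff_test()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tsrna_diff
#' @export
autoplot.tsrna_diff <- function(object, ...) {
  fc <- attr(object, "fc_thresh") %||% 1.5
  alpha <- attr(object, "alpha") %||% 0.05
  dir <- dplyr::case_when(
    object$significant & object$log2fc > 0 ~ "up",
    object$significant ~ "down",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(
    tibble(log2fc = object$log2fc, p = object$p, direction = dir),
    ggplot2::aes(x = .data$log2fc, y = -log10(.data$p), colour = .data$direction)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Enrichment factor against term, sized by observed gene count and
#' coloured by P value, for terms passing the gates (or the top `n`).
#'
#' @param object A `tsrna_enrich` result from [enrich()].
#' @param n Maximum number of terms to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot tsrna_enrich
#' @export
autoplot.tsrna_enrich <- function(object, n = 20, ...) {
  dat <- object |> slice_head(n = n)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$enrichment_factor,
    y = stats::reorder(.data$term_name, -.data$p),
    size = .data$observed, colour = -log10(.data$p)
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enrichment factor", y = NULL, size = "genes",
                  colour = "-log10 P") +
    ggplot2::theme_minimal()
}
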