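#' Plot a fragment matrix
#'
#' Tile view of the SNP matrix: fragments on the y axis (in input order),
#' loci on the x axis, tiles coloured by allele; gaps are blank.
#'
#' @param object an `snp_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.snp_matrix <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    site = rep(seq_len(ncol(object)), each = nrow(object)),
    allele = as.vector(unclass(object))
  ) |>
    dplyr::filter(!is.na(.data$allele))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$site, y = .data$row, fill = factor(.data$allele)
  )) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`0` = "#4477AA", `1` = "#EE6677")) +
    ggplot2::labs(x = "SNP locus", y = "fragment", fill = "allele") +
    ggplot2::theme_minimal()
}

#' Plot experiment results
#'
#' Mean switch errors (or another summarized metric) against the sequencing
#' error rate, one line per fragment count, faceted by mean fragment
#' length.
#'
#' @param object an `hbop_experiment` tibble from [run_experiment()] (raw
#'   replicate rows; summarized internally).
#' @param metric which summary column to draw, e.g.
#'   `"mean_switch_errors"` (default) or `"mean_phased_length"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hbop_experiment <- function(object, metric = "mean_switch_errors",
                                     ...) {
  sm <- summarize_experiment(object)
  ggplot2::ggplot(sm, ggplot2::aes(
    x = .data$e, y = .data[[metric]],
    colour = factor(.data$m), group = factor(.data$m)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$l), labeller = "label_both") +
    ggplot2::labs(
      x = "sequencing error rate e", y = metric,
      colour = "fragments m"
    ) +
    ggplot2::theme_minimal()
}
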