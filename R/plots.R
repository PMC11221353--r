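#' Plot a gene-coverage saturation curve
#'
#' Mean covered-gene proportion against combined reads drawn from the
#' representative population, with a ±1 sd ribbon over repeats and the
#' full-population asymptote as a dashed line.
#'
#' @param object An `ivt_saturation` curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivt_saturation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$combined_reads,
                                       y = .data$mean_proportion)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_proportion - .data$sd_proportion,
      ymax = .data$mean_proportion + .data$sd_proportion), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "asymptote"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "combined reads sampled from population",
                  y = "proportion of target genes covered") +
    ggplot2::theme_minimal()
}

#' Plot retained mismatch counts across the occurrence-threshold sweep
#'
#' @param object An `ivt_threshold_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivt_threshold_sweep <- function(object, ...) {
  counts <- tidy(object)
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$threshold),
                                       y = .data$n_variants)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "occurrence threshold (%)",
                  y = "mismatches retained") +
    ggplot2::theme_minimal()
}

#' Plot gene coverage against the minimum read-count cutoff
#'
#' @param object An `ivt_coverage_cutoff` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivt_coverage_cutoff <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cutoff,
                                       y = 100 * .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum read-count cutoff",
                  y = "% of gene universe observed") +
    ggplot2::theme_minimal()
}

#' Summarise a threshold sweep as retained counts per threshold
#'
#' @param x An `ivt_threshold_sweep`.
#' @param ... Unused.
#' @return A tibble `threshold`, `n_variants`.
#' @export
tidy.ivt_threshold_sweep <- function(x, ...) {
  ths <- attr(x, "thresholds")
  tab <- as_tibble(x) |> count(.data$threshold, name = "n_variants")
  left_join(tibble(threshold = ths), tab, by = "threshold") |>
    mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L))
}
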