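# ggplot2 views of the main result types

#' @export
autoplot.rh_map <- function(object, ...) {
  pos_cols <- grep("^pos_cr_", names(object), value = TRUE)
  if ("ref_bp" %in% names(object)) {
    d <- tidyr::pivot_longer(as_tibble(object), dplyr::all_of(pos_cols),
                             names_to = "panel", values_to = "pos_cr")
    d$panel <- sub("^pos_cr_", "", d$panel)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$ref_bp / 1e6,
                                    y = .data$pos_cr)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_wrap(~panel, scales = "free_y") +
      ggplot2::labs(x = "assembly position (Mb)",
                    y = "RH map position (cR)",
                    title = "RH map versus assembly order")
  } else {
    d <- as_tibble(object)
    ggplot2::ggplot(d, ggplot2::aes(x = .data$order_index,
                                    y = .data[[pos_cols[1]]])) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "map order", y = "position (cR)")
  }
}

#' @export
autoplot.rh_order_comparison <- function(object, ...) {
  d <- object$chromosomes
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom, y = .data$delta_cm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL,
                  y = sprintf("genetic length difference (cM), %s - %s",
                              object$labels[1], object$labels[2]),
                  title = "Genetic length by marker order")
}

#' @export
autoplot.rh_empirical_null <- function(object, ...) {
  d <- tibble(score = object$maxima)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::labs(x = "max cross-chromosome similarity score",
                  y = "resamples",
                  title = "Empirical null of the similarity score")
}

#' @export
autoplot.rh_design_tradeoff <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$n_genotyped,
                               y = .data$expected_mappable)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "markers genotyped",
                  y = "expected markers at distinct positions",
                  title = "RH design trade-off")
}

#' @export
autoplot.rh_intensity_sim <- function(object, ..., max_points = 20000) {
  d <- object$intensities
  if (nrow(d) > max_points) d <- d[sample.int(nrow(d), max_points), ]
  d$call <- call_genotype(d$x, d$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$call)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "X intensity", y = "Y intensity",
                  title = "Signal intensities by genotype call")
}

#' @export
autoplot.rh_placements <- function(object, ...) {
  d <- object |> filter(!is.na(.data$bp_position))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bp_position / 1e6,
                                  y = .data$best_score)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "predicted position (Mb)",
                  y = "best similarity score",
                  title = "Placed uSNPs")
}
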