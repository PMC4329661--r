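#' Plot helpers (ggplot2)
#'
#' Convenience figures mirroring the standard displays of a comparative
#' metagenome analysis: a recruitment panel (per-read identity against
#' alignment position, with the companion 1%-bin identity histogram), a
#' two-sample log-abundance scatter with the y = x diagonal, and
#' rarefaction curves with +/- 1 SD ribbons. All return ggplot objects;
#' ggplot2 must be installed.
#'
#' @param points data.frame from [recruitment_points()].
#' @param hist a `HistogramBins` from [identity_histogram()].
#' @name plots
NULL

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    mc_stop("install ggplot2 to use the plotting helpers")
}

#' @rdname plots
#' @export
plot_recruitment <- function(points) {
  need_ggplot2()
  ggplot2::ggplot(points, ggplot2::aes(x = .data$position,
                                       y = .data$identity)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::facet_wrap(~genome_id, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(55, 100)) +
    ggplot2::labs(x = "position on reference (bp)",
                  y = "read identity (%)")
}

#' @rdname plots
#' @export
plot_identity_histogram <- function(hist) {
  need_ggplot2()
  df <- data.frame(mid = hist$edges[-length(hist$edges)] + 0.5,
                   count = hist$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "read identity (%)", y = "normalized hits")
}

#' @rdname plots
#' @param scatter data.frame from [scatter_points()].
#' @export
plot_scatter <- function(scatter) {
  need_ggplot2()
  ggplot2::ggplot(scatter, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "log10 normalized count (sample A)",
                  y = "log10 normalized count (sample B)")
}

#' @rdname plots
#' @param curve a `RarefactionCurve` from [rarefy_assignments()].
#' @export
plot_rarefaction <- function(curve) {
  need_ggplot2()
  df <- data.frame(depth = curve$depths, mean = curve$mean_richness,
                   sd = curve$sd_richness)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "subsample depth (reads)",
                  y = sprintf("mean richness (%s)", curve$rank_or_unit))
}
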