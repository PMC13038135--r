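#' @exportS3Method ggplot2::autoplot
autoplot.copolymer_ensemble <- function(object,
                                        axis = c("monomers", "oligomers"),
                                        ...) {
  axis <- match.arg(axis)
  h <- chain_length_histogram(object, axis = axis)
  spec <- attr(object, "spec")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(width = 1, fill = "grey20") +
    ggplot2::labs(
      x = sprintf("chain length (%s)", axis), y = "number of chains",
      title = if (!is.null(spec)) spec$label else NULL
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.digest_result <- function(object,
                                   weighting = c("number", "length"),
                                   scale = c("repeat_unit", "monomer"),
                                   ...) {
  weighting <- match.arg(weighting)
  scale <- match.arg(scale)
  h <- digest_histogram(object, weighting = weighting, scale = scale)
  ycol <- if (weighting == "number") "n" else "n_l"
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data[[ycol]])) +
    ggplot2::geom_col(width = 1, fill = "grey20") +
    ggplot2::labs(
      x = if (scale == "repeat_unit") "block length (repeat units)" else "fragment length (monomers)",
      y = if (weighting == "number") "number of fragments" else "length-weighted count",
      title = if (!is.null(object$spec)) object$spec$label else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Overlay SEC-like traces with an inverted log abscissa
#'
#' Plots one or more [sec_like_export()] traces the way size-exclusion
#' chromatograms are presented: `log10` size on the x axis, reversed so the
#' smallest species elute on the right.
#'
#' @param ... Named traces (tibbles from [sec_like_export()]); names become
#'   the legend labels.
#' @return A ggplot object.
#' @examples
#' ps <- simulate_digest(copolymer_spec(
#'   oligomer_pool("diacid", mean_dp = 5, u_fraction = 0.5),
#'   oligomer_pool("diol", mean_dp = 10),
#'   extent_p = 0.9, n_chains = 2000, seed = 2
#' ))
#' rand <- simulate_digest(random_analog_spec(0.2, 5, 10, 0.9, 2000, seed = 3))
#' plot_sec_trace(
#'   random = sec_like_export(rand),
#'   ps = sec_like_export(ps, normalize_to = sec_like_export(rand))
#' )
#' @export
plot_sec_trace <- function(...) {
  traces <- list(...)
  if (is.null(names(traces)) || any(!nzchar(names(traces)))) {
    names(traces) <- paste0("trace", seq_along(traces))
  }
  dat <- purrr::imap_dfr(traces, function(tr, nm) {
    dplyr::mutate(tr, trace = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log10_size, y = .data$intensity,
                                    colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "log10 size (inverted)", y = "number-weighted intensity") +
    ggplot2::theme_minimal()
}
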