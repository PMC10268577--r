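#' Plot methods
#'
#' `autoplot()` on a `run_summary` draws the invariant-distribution share
#' bars (with cross-run standard-error bars); on a `chain_run` it draws
#' the strategy-count time series of the recorded trace.
#'
#' @param object A `run_summary` or `chain_run`.
#' @param top_n For crowded 16-strategy sets, keep the `top_n` largest
#'   enforcer shares (producers are always shown). Default keeps all.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @method autoplot run_summary
#' @export
autoplot.run_summary <- function(object, top_n = Inf, ...) {
  s <- object$summary
  if (is.finite(top_n)) {
    keep_enf <- s |>
      dplyr::filter(.data$role == "enforcer") |>
      dplyr::slice_max(.data$mean_share, n = top_n)
    s <- dplyr::bind_rows(dplyr::filter(s, .data$role == "producer"), keep_enf)
  }
  s$label <- factor(s$label, levels = s$label)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$mean_share,
                                  fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_share - .data$se,
                   ymax = .data$mean_share + .data$se),
      width = 0.25) +
    ggplot2::labs(x = NULL, y = "time-average share",
                  title = sprintf("Invariant distribution (%d runs x %s periods)",
                                  object$runs,
                                  format(object$periods, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot chain_run
#' @export
autoplot.chain_run <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$period, y = .data$n / length(object$final$assign),
                               colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "period", y = "share", colour = "strategy") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param x Object to plot.
#' @export
plot.run_summary <- function(x, ...) print(autoplot.run_summary(x, ...))

#' @rdname plots
#' @export
plot.chain_run <- function(x, ...) print(autoplot.chain_run(x, ...))
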