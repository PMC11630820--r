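#' Weber plot of one or more datasets
#'
#' Phase delay (filled symbols, left axis, degrees) and modulation ratio
#' (open symbols, right axis) against modulation frequency on a log axis,
#' optionally with fitted curves.
#'
#' @param datasets an [fd_dataset()] or list of them.
#' @param fit optional `fd_fit` whose predictions are drawn as curves.
#' @param pairs pair registry (needed when `fit` is given).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
weber_plot <- function(datasets, fit = NULL, pairs = default_pairs(), ...) {
  if (inherits(datasets, "fd_dataset")) datasets <- list(datasets)
  cols <- seq_along(datasets)
  fr <- range(unlist(lapply(datasets, function(d) d$frequencies)))
  graphics::plot(NA, xlim = fr / 1e6, ylim = c(0, 100), log = "x",
                 xlab = "modulation frequency (MHz)",
                 ylab = "phase delay (deg) / 100 x modulation", ...)
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    graphics::points(d$frequencies / 1e6, d$phase_deg, col = cols[i], pch = 16)
    graphics::points(d$frequencies / 1e6, d$mod_ratio * 100, col = cols[i], pch = 1)
  }
  if (!is.null(fit)) {
    preds <- predict_fit(fit, datasets, pairs)
    for (i in seq_along(datasets)) {
      d <- datasets[[i]]
      graphics::lines(d$frequencies / 1e6, preds[[i]]$phase_deg, col = cols[i])
      graphics::lines(d$frequencies / 1e6, preds[[i]]$mod_ratio * 100,
                      col = cols[i], lty = 2)
    }
  }
  invisible(NULL)
}

#' Phasor plot with the universal circle
#'
#' @param datasets an [fd_dataset()] or list of them.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
phasor_plot <- function(datasets, ...) {
  if (inherits(datasets, "fd_dataset")) datasets <- list(datasets)
  th <- seq(0, pi, length.out = 200)
  graphics::plot(0.5 + 0.5 * cos(th), 0.5 * sin(th), type = "l", col = "grey",
                 xlab = "g (in-phase)", ylab = "s (out-of-phase)",
                 xlim = c(0, 1), ylim = c(0, 0.6), asp = 1, ...)
  for (i in seq_along(datasets)) {
    ph <- dataset_phasor(datasets[[i]])
    graphics::points(ph$g, ph$s, col = i, pch = 16)
  }
  invisible(NULL)
}

#' Plot a distance distribution
#'
#' @param x a `distance_distribution`.
#' @param r distance grid, Angstrom.
#' @param overlay optional `distribution_table` drawn as a dashed curve.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot.distance_distribution <- function(x, r = seq(10, 60, by = 0.1),
                                       overlay = NULL, ...) {
  d <- distribution_density(x, r)
  graphics::plot(r, d, type = "l", xlab = "distance (A)",
                 ylab = "probability density", ...)
  if (!is.null(overlay))
    graphics::lines(overlay$r, overlay$density, lty = 2, col = "grey40")
  invisible(NULL)
}

#' Plot a chi-square profile scan
#'
#' @param x a `profile_scan` from [profile_parameter()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot.profile_scan <- function(x, ...) {
  graphics::plot(x$value, x$chi2, type = "b",
                 xlab = attr(x, "param"), ylab = expression(chi^2), ...)
  invisible(NULL)
}
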