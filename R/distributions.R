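#' Single-Gaussian donor-acceptor distance distribution
#'
#' Distance heterogeneity within one conformational state is modeled as a
#' Gaussian over donor-acceptor distance with mean \eqn{\bar r} and standard
#' deviation \eqn{\sigma}. The sigma fitting bounds (0.5-10 A) are enforced
#' at the fitting layer, not here, so forward simulation can explore outside
#' them; this constructor only rejects degenerate widths.
#'
#' @param rbar mean distance, Angstrom.
#' @param sigma standard deviation, Angstrom, strictly positive.
#' @return A `distance_distribution` with one component of weight 1.
#' @examples
#' make_single(39.6, 5)
#' @export
make_single <- function(rbar, sigma) {
  new_distance_distribution(rbar = rbar, sigma = sigma, weight = 1)
}

#' Sum-of-two-Gaussians distance distribution
#'
#' Two-state mixture: component 1 is the long-distance (resting) state,
#' component 2 the short-distance (active) state; `A2` is the fractional
#' area of component 2 and is interpreted as the probability of the active
#' conformation.
#'
#' @param r1,s1 mean and sd of component 1 (Angstrom).
#' @param r2,s2 mean and sd of component 2 (Angstrom).
#' @param A2 fraction of component 2, in \[0, 1\].
#' @return A `distance_distribution` with weights `(1 - A2, A2)`.
#' @examples
#' make_two_state(40.9, 4.3, 29.5, 0.84, A2 = 0.12)
#' @export
make_two_state <- function(r1, s1, r2, s2, A2) {
  if (!is.numeric(A2) || length(A2) != 1L || !is.finite(A2) || A2 < 0 || A2 > 1)
    stop("'A2' must lie in [0, 1]")
  new_distance_distribution(rbar = c(r1, r2), sigma = c(s1, s2),
                            weight = c(1 - A2, A2))
}

new_distance_distribution <- function(rbar, sigma, weight) {
  stopifnot(length(rbar) == length(sigma), length(rbar) == length(weight))
  if (any(!is.finite(rbar)) || any(!is.finite(sigma)))
    stop("distribution parameters must be finite")
  if (any(sigma <= 0))
    stop("'sigma' must be strictly positive (Angstrom)")
  if (any(weight < 0) || any(weight > 1))
    stop("component weights must lie in [0, 1]")
  if (abs(sum(weight) - 1) > 1e-12)
    stop("component weights must sum to 1")
  structure(list(components = data.frame(rbar = rbar, sigma = sigma,
                                         weight = weight)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat("<distance_distribution>\n")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Discretize a distance distribution onto a weighted grid
#'
#' Each Gaussian component is sampled on a uniform grid over
#' `rbar +/- span * sigma`, truncated to r > 0, weighted by the normal
#' density with trapezoid quadrature weights, and renormalized so that
#' weights sum to the component weight (total 1). Truncation at r <= 0 is
#' checked: when it would remove more than 1e-6 probability mass the
#' function warns and renormalizes anyway, since distances near zero are
#' unphysical.
#'
#' @param dist a `distance_distribution`.
#' @param n_points grid points per component, at least 25 (default 501).
#' @param span half-width of the grid in multiples of sigma (default 5).
#' @return `data.frame` with columns `r` (Angstrom) and `w` (weights summing
#'   to 1).
#' @export
discretize <- function(dist, n_points = 501L, span = 5) {
  stopifnot(inherits(dist, "distance_distribution"))
  if (n_points < 25L) stop("'n_points' must be at least 25")
  comp <- dist$components
  out_r <- out_w <- vector("list", nrow(comp))
  for (i in seq_len(nrow(comp))) {
    if (comp$weight[i] == 0) next
    lost <- stats::pnorm(0, comp$rbar[i], comp$sigma[i])
    if (lost > 1e-6)
      warning(sprintf(
        "truncation at r <= 0 removes %.2g probability mass for component %d (rbar = %.3g, sigma = %.3g)",
        lost, i, comp$rbar[i], comp$sigma[i]))
    gw <- .gauss_grid(comp$rbar[i], comp$sigma[i], n_points, span)
    out_r[[i]] <- gw$r
    out_w[[i]] <- gw$w * comp$weight[i]
  }
  data.frame(r = unlist(out_r), w = unlist(out_w))
}

# uniform grid over rbar +/- span*sigma truncated to r > 0, normal density
# with trapezoid weights, renormalized to sum 1
.gauss_grid <- function(rbar, sigma, n_points, span) {
  r <- seq(rbar - span * sigma, rbar + span * sigma, length.out = n_points)
  r <- r[r > 0]
  if (length(r) < 2L) stop("distance grid collapsed: distribution lies almost entirely at r <= 0")
  w <- stats::dnorm(r, rbar, sigma)
  w[c(1L, length(w))] <- w[c(1L, length(w))] / 2
  list(r = r, w = w / sum(w))
}

#' Mean FRET efficiency of a distance distribution
#'
#' \eqn{\langle E \rangle = \int P(r) E(r) dr} computed on the discretized
#' grid, the quantity a steady-state measurement reports.
#'
#' @inheritParams discretize
#' @param R0 Forster radius, Angstrom.
#' @return Scalar mean efficiency.
#' @export
average_efficiency <- function(dist, R0, n_points = 501L, span = 5) {
  g <- discretize(dist, n_points = n_points, span = span)
  sum(g$w * efficiency_from_distance(g$r, R0))
}

#' Mixture probability density over distance
#'
#' Density of the (untruncated) Gaussian mixture, used for plotting and for
#' exporting distributions in the two-column table format.
#'
#' @param dist a `distance_distribution`.
#' @param r distances (Angstrom) at which to evaluate.
#' @return Density values.
#' @export
distribution_density <- function(dist, r) {
  stopifnot(inherits(dist, "distance_distribution"))
  comp <- dist$components
  d <- numeric(length(r))
  for (i in seq_len(nrow(comp)))
    d <- d + comp$weight[i] * stats::dnorm(r, comp$rbar[i], comp$sigma[i])
  d
}
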