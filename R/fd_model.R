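#' Nuisance parameters of a lifetime experiment
#'
#' Besides the distance distribution, each frequency-domain measurement
#' carries three nuisance contributions: a donor-only fraction (molecules
#' lacking a functional acceptor, decaying at the unquenched `tau_donor`), a
#' small background fraction, and a per-experiment timing offset `t0`.
#'
#' `f_donor_only` and `f_background` are AMPLITUDE (molecule) fractions;
#' they are converted to fractional steady-state intensities by lifetime
#' weighting inside [fd_response()]. The one exception is a background with
#' `tau_background = 0` (the default), which is treated as pure scatter: its
#' amplitude is taken directly as a fraction of the detected intensity and
#' it contributes phasor coordinates (g, s) = (1, 0).
#'
#' @param f_donor_only donor-only amplitude fraction, in \[0, 1).
#' @param f_background background amplitude fraction, bounded above by
#'   `max_background` (default 0.05, the usual experimental bound).
#' @param tau_background background lifetime in ns; 0 means pure scatter.
#' @param t0 timing offset in ns; adds `omega * t0` to the phase and leaves
#'   the modulation untouched.
#' @param max_background upper bound enforced on `f_background`.
#' @return An object of class `nuisance_params`.
#' @export
nuisance_params <- function(f_donor_only = 0, f_background = 0,
                            tau_background = 0, t0 = 0,
                            max_background = 0.05) {
  if (f_donor_only < 0 || f_donor_only >= 1)
    stop("'f_donor_only' must lie in [0, 1)")
  if (f_background < 0 || f_background > max_background)
    stop(sprintf("'f_background' must lie in [0, %g]", max_background))
  if (f_donor_only + f_background >= 1)
    stop("'f_donor_only' + 'f_background' must be < 1")
  if (tau_background < 0) stop("'tau_background' must be >= 0 (ns)")
  structure(list(f_donor_only = f_donor_only, f_background = f_background,
                 tau_background = tau_background, t0 = t0),
            class = "nuisance_params")
}

#' Exponential species mixture underlying a decay
#'
#' A multi-exponential intensity decay \eqn{I(t) = \sum_j \alpha_j
#' e^{-t/\tau_j}} represented by pre-exponential amplitudes (summing to 1)
#' and lifetimes. A lifetime of exactly 0 denotes a scatter species.
#'
#' @param amplitudes nonnegative pre-exponential weights summing to 1.
#' @param lifetimes lifetimes in ns, same length, all >= 0 (0 = scatter).
#' @return An object of class `species_mixture`.
#' @export
species_mixture <- function(amplitudes, lifetimes) {
  if (length(amplitudes) == 0L) stop("mixture must contain at least one species")
  stopifnot(length(amplitudes) == length(lifetimes))
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  if (any(lifetimes < 0)) stop("lifetimes must be >= 0 (ns)")
  s <- sum(amplitudes)
  if (s <= 0) stop("amplitudes must sum to a positive value")
  structure(list(amplitudes = amplitudes / s, lifetimes = lifetimes),
            class = "species_mixture")
}

#' Expand a distance distribution into an exponential species mixture
#'
#' Discretizes the distribution and assigns each grid distance `r_k` the
#' quenched lifetime `tau_D * (1 - E(r_k))` with amplitude
#' `(1 - f_donor_only - f_background) * w_k`, then appends a donor-only
#' species at `tau_donor` and a background species at `tau_background`.
#'
#' @param dist a `distance_distribution`.
#' @param pair a [forster_pair()].
#' @param nuisance a [nuisance_params()] (the `t0` field is not used here;
#'   it enters at [fd_response()]).
#' @param n_points,span discretization controls, see [discretize()].
#' @return A `species_mixture`.
#' @export
species_from_distribution <- function(dist, pair, nuisance = nuisance_params(),
                                      n_points = 501L, span = 5) {
  stopifnot(inherits(pair, "forster_pair"), inherits(nuisance, "nuisance_params"))
  g <- discretize(dist, n_points = n_points, span = span)
  f_sig <- 1 - nuisance$f_donor_only - nuisance$f_background
  amps <- f_sig * g$w
  taus <- fret_lifetime(g$r, pair)
  if (nuisance$f_donor_only > 0) {
    amps <- c(amps, nuisance$f_donor_only)
    taus <- c(taus, pair$tau_donor)
  }
  if (nuisance$f_background > 0) {
    amps <- c(amps, nuisance$f_background)
    taus <- c(taus, nuisance$tau_background)
  }
  species_mixture(amps, taus)
}

#' Frequency-domain response of an exponential mixture
#'
#' For a mixture with fractional steady-state intensities
#' \eqn{f_j = \alpha_j \tau_j / \sum_k \alpha_k \tau_k} the out-of-phase and
#' in-phase transform components at angular frequency \eqn{\omega = 2\pi\nu}
#' are \eqn{N(\omega) = \sum_j f_j \omega\tau_j/(1 + \omega^2\tau_j^2)} and
#' \eqn{D(\omega) = \sum_j f_j/(1 + \omega^2\tau_j^2)}; the measured phase
#' delay is \eqn{\phi = \arctan(N/D) + \omega t_0} (degrees) and the
#' modulation ratio \eqn{m = \sqrt{N^2 + D^2}} (independent of `t0`).
#' Scatter species (lifetime 0) contribute their amplitude directly as an
#' intensity fraction with (N, D) contribution (0, f).
#'
#' @param mix a [species_mixture()].
#' @param frequency modulation frequency or frequencies, Hz, positive.
#' @param t0 timing offset, ns.
#' @return List with numeric vectors `phase_deg` and `mod_ratio`.
#' @examples
#' m <- species_mixture(1, 17.2)
#' fd_response(m, 1e7) # phase 47.2 deg, modulation 0.679
#' @export
fd_response <- function(mix, frequency, t0 = 0) {
  stopifnot(inherits(mix, "species_mixture"))
  if (any(frequency <= 0)) stop("'frequency' must be positive (Hz)")
  nd <- .fd_nd(mix$amplitudes, mix$lifetimes, 2 * pi * frequency * 1e-9)
  phase <- atan2(nd$N, nd$D) + 2 * pi * frequency * 1e-9 * t0
  list(phase_deg = phase * 180 / pi, mod_ratio = sqrt(nd$N^2 + nd$D^2))
}

# core transform: amplitudes alpha, lifetimes tau (ns), omega in rad/ns.
# scatter species (tau == 0) carry their amplitude as an intensity fraction.
.fd_nd <- function(alpha, tau, omega) {
  pos <- tau > 0
  f_sc <- sum(alpha[!pos])
  it <- alpha[pos] * tau[pos]
  sit <- sum(it)
  if (sit <= 0 && f_sc < 1)
    stop("mixture has no steady-state intensity")
  if (sit > 0) {
    f <- (1 - f_sc) * it / sit
    wt <- outer(omega, tau[pos])
    den <- 1 + wt * wt
    N <- drop((wt / den) %*% f)
    D <- drop((1 / den) %*% f) + f_sc
  } else {
    N <- rep(0, length(omega))
    D <- rep(f_sc, length(omega))
  }
  list(N = N, D = D)
}

#' Frequency-domain dataset (one Weber-plot experiment)
#'
#' Holds measured (or simulated) phase delays and modulation ratios over a
#' strictly increasing grid of modulation frequencies, plus the condition
#' metadata the global fit keys on.
#'
#' Phase delays are validated against (-90, 180) degrees: with a timing
#' offset `t0` of a few hundred picoseconds the high harmonics of a
#' long-lived donor can legitimately exceed 90 degrees.
#'
#' @param frequencies modulation frequencies, Hz, strictly increasing.
#' @param phase_deg phase delays, degrees.
#' @param mod_ratio modulation ratios in (0, 1].
#' @param condition ligand condition label (`"apo"`, `"cAMP"`, `"cGMP"`).
#' @param acceptor acceptor name resolving in the pair registry.
#' @param ionic ionic condition label (mM KCl), e.g. 150 or 500.
#' @param replicate_id replicate identifier.
#' @param sample_id labeled-protein sample identifier; datasets sharing a
#'   `sample_id` share their donor-only fraction in global fits. Defaults to
#'   `acceptor/ionic/replicate_id`.
#' @param phase_sd,mod_sd optional per-point measurement uncertainties.
#' @return An object of class `fd_dataset`.
#' @export
fd_dataset <- function(frequencies, phase_deg, mod_ratio,
                       condition = "apo", acceptor = "Fe(phenM)3",
                       ionic = 500, replicate_id = "r1", sample_id = NULL,
                       phase_sd = NULL, mod_sd = NULL) {
  n <- length(frequencies)
  if (length(phase_deg) != n || length(mod_ratio) != n)
    stop("'frequencies', 'phase_deg' and 'mod_ratio' must have equal length")
  if (n < 1L) stop("dataset must contain at least one frequency")
  if (any(frequencies <= 0)) stop("frequencies must be positive (Hz)")
  if (any(diff(frequencies) <= 0)) {
    bad <- which(diff(frequencies) <= 0)[1L] + 1L
    stop(sprintf("frequencies must be strictly increasing (row %d violates)", bad))
  }
  if (any(mod_ratio <= 0) || any(mod_ratio > 1)) {
    bad <- which(mod_ratio <= 0 | mod_ratio > 1)[1L]
    stop(sprintf("mod_ratio must lie in (0, 1] (row %d: %g)", bad, mod_ratio[bad]))
  }
  if (any(phase_deg <= -90) || any(phase_deg >= 180)) {
    bad <- which(phase_deg <= -90 | phase_deg >= 180)[1L]
    stop(sprintf("phase_deg must lie in (-90, 180) (row %d: %g)", bad, phase_deg[bad]))
  }
  if (!is.null(phase_sd) && (length(phase_sd) != n || any(phase_sd <= 0)))
    stop("'phase_sd' must be positive and match the frequency grid")
  if (!is.null(mod_sd) && (length(mod_sd) != n || any(mod_sd <= 0)))
    stop("'mod_sd' must be positive and match the frequency grid")
  if (is.null(sample_id))
    sample_id <- paste(acceptor, ionic, replicate_id, sep = "/")
  structure(list(frequencies = as.numeric(frequencies),
                 phase_deg = as.numeric(phase_deg),
                 mod_ratio = as.numeric(mod_ratio),
                 condition = condition, acceptor = acceptor,
                 ionic = ionic, replicate_id = replicate_id,
                 sample_id = sample_id,
                 phase_sd = phase_sd, mod_sd = mod_sd),
            class = "fd_dataset")
}

#' @export
print.fd_dataset <- function(x, ...) {
  cat(sprintf("<fd_dataset> %s | %s | %s mM KCl | rep %s: %d frequencies (%.3g-%.3g MHz)\n",
              x$condition, x$acceptor, x$ionic, x$replicate_id,
              length(x$frequencies), min(x$frequencies) / 1e6,
              max(x$frequencies) / 1e6))
  invisible(x)
}

# stable per-dataset experiment id used for nuisance-parameter naming
dataset_id <- function(ds) {
  paste(ds$acceptor, ds$condition, ds$ionic, ds$replicate_id, sep = "/")
}

#' Predict a noise-free frequency-domain dataset
#'
#' Runs the forward model — distribution to species mixture to phase and
#' modulation — over a frequency grid and packages the result as an
#' `fd_dataset`. Deterministic.
#'
#' @inheritParams species_from_distribution
#' @param frequencies modulation frequencies, Hz, strictly increasing.
#' @param ... condition metadata forwarded to [fd_dataset()].
#' @return An `fd_dataset` with predicted phase and modulation.
#' @export
predict_dataset <- function(dist, pair, nuisance = nuisance_params(),
                            frequencies = default_frequencies(),
                            n_points = 501L, span = 5, ...) {
  mix <- species_from_distribution(dist, pair, nuisance,
                                   n_points = n_points, span = span)
  resp <- fd_response(mix, frequencies, t0 = nuisance$t0)
  fd_dataset(frequencies, resp$phase_deg, resp$mod_ratio,
             acceptor = pair$acceptor, ...)
}

#' Default modulation frequency grid
#'
#' 14 log-spaced frequencies from the 10 MHz fundamental to 200 MHz,
#' covering the harmonics range of a digital frequency-domain instrument.
#' Measured grids read from files override this.
#'
#' @param n number of frequencies.
#' @param from,to range in Hz.
#' @return Numeric vector of frequencies (Hz), strictly increasing.
#' @export
default_frequencies <- function(n = 14L, from = 1e7, to = 2e8) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Phasor coordinates of frequency-domain points
#'
#' Model-free representation: `g = m cos(phi)` (in-phase) and
#' `s = m sin(phi)` (out-of-phase). Single-exponential decays fall on the
#' universal semicircle `(g - 1/2)^2 + s^2 = 1/4`; mixtures fall inside it,
#' on the chord connecting their components.
#'
#' @param phase_deg phase delay(s), degrees.
#' @param mod_ratio modulation ratio(s).
#' @return `data.frame` with columns `g` and `s`.
#' @export
phasor_coordinates <- function(phase_deg, mod_ratio) {
  stopifnot(length(phase_deg) == length(mod_ratio))
  phi <- phase_deg * pi / 180
  data.frame(g = mod_ratio * cos(phi), s = mod_ratio * sin(phi))
}

#' Phasor coordinates of a dataset
#'
#' @param ds an `fd_dataset`.
#' @return `data.frame` with `frequency_hz`, `g`, `s`.
#' @export
dataset_phasor <- function(ds) {
  stopifnot(inherits(ds, "fd_dataset"))
  cbind(frequency_hz = ds$frequencies,
        phasor_coordinates(ds$phase_deg, ds$mod_ratio))
}
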