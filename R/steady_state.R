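#' Fluorescence intensity time course with reagent events
#'
#' One cuvette record: donor intensity sampled over time with annotated
#' reagent additions (acceptor, cyclic nucleotide, TCEP reversal).
#'
#' @param time times, seconds, strictly increasing.
#' @param intensity fluorescence intensities, arbitrary units, positive.
#' @param events `data.frame` with columns `time` (s) and `label`, ordered.
#' @return Object of class `timecourse`.
#' @export
timecourse <- function(time, intensity,
                       events = data.frame(time = numeric(0),
                                           label = character(0))) {
  stopifnot(length(time) == length(intensity))
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  if (any(intensity <= 0)) stop("'intensity' must be positive")
  if (!all(c("time", "label") %in% names(events)))
    stop("'events' needs columns 'time' and 'label'")
  events <- events[order(events$time), , drop = FALSE]
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 events = events),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d samples over %.0f-%.0f s; events: %s\n",
              length(x$time), min(x$time), max(x$time),
              if (nrow(x$events)) paste(x$events$label, collapse = ", ")
              else "none"))
  invisible(x)
}

.window_mean <- function(course, window) {
  sel <- course$time >= window[1] & course$time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  mean(course$intensity[sel])
}

#' Normalize a time course to its pre-event baseline
#'
#' Divides intensities by the mean over a baseline window that must precede
#' the first reagent addition; the baseline mean becomes 1. Normalization is
#' scale invariant, so absolute instrument units never enter downstream
#' analysis.
#'
#' @param course a [timecourse()].
#' @param baseline_window numeric length-2 `(from, to)` in seconds.
#' @return A normalized `timecourse`.
#' @export
normalize_course <- function(course, baseline_window) {
  stopifnot(inherits(course, "timecourse"), length(baseline_window) == 2L)
  if (nrow(course$events) && baseline_window[2] > min(course$events$time))
    stop("baseline window must precede the first event")
  b <- .window_mean(course, baseline_window)
  timecourse(course$time, course$intensity / b, course$events)
}

#' Steady-state FRET efficiency from paired time courses
#'
#' The cysteine-containing (acceptor-labeled) course is referenced to a
#' no-cysteine control measured separately, which corrects for intensity
#' changes not caused by bound acceptor:
#' \eqn{E = 1 - mean(F_{Cys}/F_{NoCys})} over a plateau window. Windows are
#' explicit user inputs placed after the relevant reagent addition and
#' before the next; a window straddling an event is rejected.
#'
#' @param cys_course,nocys_course normalized [timecourse()]s.
#' @param window numeric length-2 plateau window, seconds.
#' @param condition condition label attached to the estimate.
#' @return Object of class `efficiency_estimate` with fields `E`,
#'   `condition`, `window`.
#' @export
fret_efficiency <- function(cys_course, nocys_course, window,
                            condition = NA_character_) {
  stopifnot(inherits(cys_course, "timecourse"),
            inherits(nocys_course, "timecourse"), length(window) == 2L)
  ev <- cys_course$events$time
  if (any(ev > window[1] & ev < window[2]))
    stop("plateau window overlaps a reagent-addition event")
  sel <- cys_course$time >= window[1] & cys_course$time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  t_in <- cys_course$time[sel]
  ref <- stats::approx(nocys_course$time, nocys_course$intensity,
                       xout = t_in, rule = 2)$y
  E <- 1 - mean(cys_course$intensity[sel] / ref)
  structure(list(E = E, condition = condition, window = window),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> E = %.3f (%s, window %.0f-%.0f s)\n",
              x$E, x$condition, x$window[1], x$window[2]))
  invisible(x)
}

#' Correct an observed efficiency for unlabeled protein
#'
#' A fraction `f_unlabeled` of molecules carrying no acceptor contributes
#' zero transfer, diluting the observed efficiency; the true per-labeled
#' efficiency is `E_obs / (1 - f_unlabeled)`. This is the exact inverse of
#' mixing a zero-efficiency population into the sample.
#'
#' @param E_obs observed efficiency fraction.
#' @param f_unlabeled unlabeled fraction in \[0, 1).
#' @return Corrected efficiency; an error if it reaches or exceeds 1.
#' @export
correct_unlabeled <- function(E_obs, f_unlabeled) {
  if (f_unlabeled < 0 || f_unlabeled >= 1)
    stop("'f_unlabeled' must lie in [0, 1)")
  E <- E_obs / (1 - f_unlabeled)
  if (any(E >= 1))
    stop("corrected efficiency reaches 1: E_obs is incompatible with the assumed unlabeled fraction")
  E
}

#' Weighted-average distance from a steady-state efficiency
#'
#' Applies the inverse Forster equation to the mean efficiency; the result
#' is the single weighted-average distance a steady-state experiment
#' reports (distribution shape is not recoverable here).
#'
#' @param E efficiency fraction in (0, 1), or an `efficiency_estimate`.
#' @param pair a [forster_pair()].
#' @return Distance in Angstrom.
#' @export
weighted_avg_distance <- function(E, pair) {
  stopifnot(inherits(pair, "forster_pair"))
  if (inherits(E, "efficiency_estimate")) E <- E$E
  distance_from_efficiency(E, pair$R0)
}

#' Assemble and fit a dose-response relation
#'
#' Efficiency changes at increasing ligand concentration are normalized to
#' the maximal change and fitted with the Hill equation via [hill_fit()].
#'
#' @param conc ligand concentrations, uM, positive, at least 3.
#' @param delta_E efficiency change at each concentration.
#' @param fix_h optional fixed Hill coefficient.
#' @return List with `conc`, `normalized`, and the `hill_fit`.
#' @export
dose_response <- function(conc, delta_E, fix_h = NULL) {
  stopifnot(length(conc) == length(delta_E))
  if (length(conc) < 3L) stop("at least 3 concentrations are required")
  if (max(delta_E) <= 0 || stats::sd(delta_E) == 0)
    stop("responses have no dynamic range")
  normalized <- delta_E / max(delta_E)
  list(conc = conc, normalized = normalized,
       fit = hill_fit(conc, normalized, fix_h = fix_h))
}

#' Check TCEP reversal of acceptor quenching
#'
#' Quality-control flag: after TCEP removes the cysteine-bound acceptor the
#' cysteine course should return to the no-cysteine level. Reversal windows
#' are parsed for QC only and never enter efficiency computation.
#'
#' @param cys_course,nocys_course normalized [timecourse()]s.
#' @param window post-TCEP plateau window, seconds.
#' @param tol allowed deviation of the mean ratio from 1.
#' @return Logical: `TRUE` when the ratio returns to within `tol` of 1.
#' @export
check_reversal <- function(cys_course, nocys_course, window, tol = 0.05) {
  sel <- cys_course$time >= window[1] & cys_course$time <= window[2]
  if (!any(sel)) stop("window contains no samples")
  ref <- stats::approx(nocys_course$time, nocys_course$intensity,
                       xout = cys_course$time[sel], rule = 2)$y
  abs(mean(cys_course$intensity[sel] / ref) - 1) <= tol
}
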