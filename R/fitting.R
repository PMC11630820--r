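#' Observation weights for frequency-domain fitting
#'
#' Default per-point measurement uncertainties used to scale residuals when
#' a dataset carries no `phase_sd`/`mod_sd` columns: 0.2 degrees on phase
#' and 0.004 on modulation, typical of a calibrated digital frequency-domain
#' instrument. The weights actually used are recorded in every fit result.
#'
#' @param phase default phase uncertainty, degrees.
#' @param mod default modulation uncertainty, dimensionless.
#' @return List with elements `phase` and `mod`.
#' @export
fd_weights <- function(phase = 0.2, mod = 0.004) {
  stopifnot(phase > 0, mod > 0)
  list(phase = phase, mod = mod)
}

#' Weighted chi-square of predictions against datasets
#'
#' \eqn{\chi^2 = \sum_{d,\nu} (\phi_{obs}-\phi_{pred})^2/\sigma_\phi^2 +
#' (m_{obs}-m_{pred})^2/\sigma_m^2}, summed over all datasets and
#' frequencies. Per-point uncertainties stored in a dataset take precedence
#' over the configured defaults.
#'
#' @param datasets an `fd_dataset` or list of them.
#' @param predictions matching `fd_dataset`s or lists with `phase_deg` and
#'   `mod_ratio`.
#' @param weights default uncertainties, see [fd_weights()].
#' @return Nonnegative scalar.
#' @export
chi_squared <- function(datasets, predictions, weights = fd_weights()) {
  if (inherits(datasets, "fd_dataset")) datasets <- list(datasets)
  if (!is.null(predictions$phase_deg)) predictions <- list(predictions)
  if (length(datasets) != length(predictions))
    stop("'datasets' and 'predictions' must have equal length")
  total <- 0
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]; pr <- predictions[[i]]
    if (length(pr$phase_deg) != length(ds$phase_deg) ||
        length(pr$mod_ratio) != length(ds$mod_ratio))
      stop("prediction/observation shapes do not match")
    sp <- if (!is.null(ds$phase_sd)) ds$phase_sd else weights$phase
    sm <- if (!is.null(ds$mod_sd)) ds$mod_sd else weights$mod
    total <- total + sum(((ds$phase_deg - pr$phase_deg) / sp)^2) +
      sum(((ds$mod_ratio - pr$mod_ratio) / sm)^2)
  }
  total
}

# ---- internal forward model (fast path used inside optimizers) ----------

# phase (deg) and modulation for a (possibly degenerate) two-Gaussian
# distribution plus nuisance species. omega_ns in rad/ns.
.fd_forward <- function(r1, s1, r2, s2, A2, fdo, fb, tau_b, t0,
                        R0, tauD, omega_ns, n_points, span) {
  g1 <- .gauss_grid(r1, s1, n_points, span)
  if (A2 > 0) {
    g2 <- .gauss_grid(r2, s2, n_points, span)
    r <- c(g1$r, g2$r)
    w <- c((1 - A2) * g1$w, A2 * g2$w)
  } else {
    r <- g1$r; w <- g1$w
  }
  f_sig <- 1 - fdo - fb
  tau <- tauD * (1 - 1 / (1 + (r / R0)^6))
  alpha <- f_sig * w
  if (fdo > 0) { alpha <- c(alpha, fdo); tau <- c(tau, tauD) }
  if (fb > 0)  { alpha <- c(alpha, fb);  tau <- c(tau, tau_b) }
  nd <- .fd_nd(alpha, tau, omega_ns)
  list(phase_deg = (atan2(nd$N, nd$D) + omega_ns * t0) * 180 / pi,
       mod_ratio = sqrt(nd$N^2 + nd$D^2))
}

# scaled residual vector for one dataset
.fd_resid <- function(pred, obs, sp, sm) {
  c((obs$phase_deg - pred$phase_deg) / sp,
    (obs$mod_ratio - pred$mod_ratio) / sm)
}

# parameter table utilities -----------------------------------------------

.param_row <- function(name, value, lower, upper, fixed = FALSE) {
  data.frame(name = name, value = value, lower = lower, upper = upper,
             fixed = fixed, stringsAsFactors = FALSE)
}

# apply user 'fixed'/'init' lists to a parameter table; a list name matches
# either a full parameter name ("A2[cGMP]") or a family ("A2" fixes all).
.apply_user <- function(tab, user, what = c("init", "fixed")) {
  what <- match.arg(what)
  for (nm in names(user)) {
    family <- sub("\\[.*$", "", tab$name)
    idx <- which(tab$name == nm)
    if (length(idx) == 0L) idx <- which(family == nm)
    if (length(idx) == 0L)
      stop(sprintf("unknown parameter '%s'", nm))
    if (what == "init") idx <- idx[!tab$fixed[idx]]  # never move fixed values
    if (length(idx) == 0L) next
    tab$value[idx] <- user[[nm]]
    if (what == "fixed") tab$fixed[idx] <- TRUE
    tab$value[idx] <- pmin(pmax(tab$value[idx], tab$lower[idx]), tab$upper[idx])
  }
  tab
}

.at_bound <- function(value, lower, upper) {
  tol <- 1e-6 * pmax(upper - lower, 1)
  (is.finite(lower) & value <= lower + tol) |
    (is.finite(upper) & value >= upper - tol)
}

.run_lm <- function(tab, resid_fn, control) {
  free <- which(!tab$fixed)
  if (length(free) == 0L) {
    fv <- resid_fn(numeric(0))
    return(list(tab = tab, chi2 = sum(fv^2), fvec = fv, info = 1L,
                message = "all parameters fixed", niter = 0L))
  }
  res <- minpack.lm::nls.lm(par = tab$value[free], lower = tab$lower[free],
                            upper = tab$upper[free], fn = resid_fn,
                            control = control)
  tab$value[free] <- res$par
  list(tab = tab, chi2 = sum(res$fvec^2), fvec = res$fvec,
       info = res$info, message = res$message, niter = res$niter)
}

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                             maxiter = 500, maxfev = 5000)
}

.new_fd_fit <- function(tab, best, datasets, weights, model, n_points, span) {
  tab$at_bound <- !tab$fixed & .at_bound(tab$value, tab$lower, tab$upper)
  structure(list(parameters = tab,
                 chi2 = best$chi2,
                 n_obs = 2L * sum(vapply(datasets, function(d)
                   length(d$frequencies), integer(1))),
                 converged = best$info %in% 1:4,
                 info = best$info, message = best$message,
                 weights = weights, model = model,
                 n_points = n_points, span = span,
                 dataset_ids = vapply(datasets, dataset_id, character(1)),
                 conditions = vapply(datasets, function(d)
                   d$condition, character(1))),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit: %s> chi2 = %.4g over %d observations (%s)\n",
              x$model, x$chi2, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  tab <- x$parameters
  tab$value <- signif(tab$value, 5)
  print(tab[, c("name", "value", "fixed", "at_bound")], row.names = FALSE)
  invisible(x)
}

#' Extract fitted coefficients
#'
#' @param object an `fd_fit`.
#' @param ... unused.
#' @return Named numeric vector of all parameter values (fixed and free).
#' @export
coef.fd_fit <- function(object, ...) {
  stats::setNames(object$parameters$value, object$parameters$name)
}

#' Per-condition active-state fractions from a global fit
#'
#' @param fit an `fd_fit` from [fit_global_two_gaussian()].
#' @return Named numeric vector of A2 values, one per condition.
#' @export
fit_A2 <- function(fit) {
  stopifnot(inherits(fit, "fd_fit"))
  p <- coef(fit)
  a2 <- p[grepl("^A2\\[", names(p))]
  stats::setNames(a2, sub("^A2\\[(.*)\\]$", "\\1", names(a2)))
}

#' Fitted distance distribution for a condition
#'
#' @param fit an `fd_fit`.
#' @param condition condition label; required for global two-Gaussian fits.
#' @return A `distance_distribution` built from the fitted parameters.
#' @export
fit_distribution <- function(fit, condition = NULL) {
  stopifnot(inherits(fit, "fd_fit"))
  p <- coef(fit)
  if (fit$model == "single")
    return(make_single(p[["rbar"]], p[["sigma"]]))
  if (is.null(condition)) stop("'condition' is required for a global fit")
  a2 <- fit_A2(fit)
  if (!condition %in% names(a2)) stop(sprintf("no condition '%s' in fit", condition))
  make_two_state(p[["r1"]], p[["sigma1"]], p[["r2"]], p[["sigma2"]],
                 a2[[condition]])
}

# ---- single-Gaussian fit ------------------------------------------------

#' Fit a single-Gaussian distance distribution to one dataset
#'
#' Bounded Levenberg-Marquardt minimization of the weighted chi-square over
#' the Gaussian mean and width plus the per-experiment nuisance parameters
#' (donor-only fraction, background fraction bounded at 0.05, timing
#' offset). `R0` and `tau_donor` come from `pair` and are held fixed.
#' Lifetime-distribution mixtures have local minima, so by default the fit
#' is restarted from `n_starts` deterministic initial means spanning
#' 20-50 Angstrom and the best chi-square is kept.
#'
#' @param dataset an [fd_dataset()].
#' @param pair the [forster_pair()] for the dataset's acceptor.
#' @param init named list overriding initial values (`rbar`, `sigma`,
#'   `f_donor_only`, `f_background`, `t0`).
#' @param fixed named list of parameters to hold fixed at the given values.
#' @param weights default observation uncertainties, see [fd_weights()].
#' @param n_starts number of multi-start initializations (default 5).
#' @param n_points,span discretization of the Gaussian, see [discretize()].
#' @param tau_background background lifetime (ns), 0 = scatter.
#' @return An `fd_fit` with the parameter table (including bound-hit
#'   flags), chi-square, and convergence information. Parameters pinned at
#'   a bound (e.g. sigma for a donor-only dataset with no FRET information)
#'   are flagged in `parameters$at_bound` rather than reported as interior
#'   estimates.
#' @export
fit_single_gaussian <- function(dataset, pair, init = list(), fixed = list(),
                                weights = fd_weights(), n_starts = 5L,
                                n_points = 501L, span = 5,
                                tau_background = 0) {
  stopifnot(inherits(dataset, "fd_dataset"), inherits(pair, "forster_pair"))
  tab <- rbind(
    .param_row("rbar",          40,   10, 60),
    .param_row("sigma",          5,  0.5, 10),
    .param_row("f_donor_only", 0.1,    0, 0.5),
    .param_row("f_background", 0.0,    0, 0.05),
    .param_row("t0",             0,   -2, 2)
  )
  tab <- .apply_user(tab, init, "init")
  tab <- .apply_user(tab, fixed, "fixed")

  omega_ns <- 2 * pi * dataset$frequencies * 1e-9
  sp <- if (!is.null(dataset$phase_sd)) dataset$phase_sd else weights$phase
  sm <- if (!is.null(dataset$mod_sd)) dataset$mod_sd else weights$mod
  make_resid <- function(tab) {
    free <- which(!tab$fixed)
    full <- tab$value
    function(p) {
      full[free] <- p
      pred <- .fd_forward(full[1], full[2], 0, 1, 0, full[3], full[4],
                          tau_background, full[5], pair$R0, pair$tau_donor,
                          omega_ns, n_points, span)
      .fd_resid(pred, dataset, sp, sm)
    }
  }

  starts <- if (n_starts > 1L && !("rbar" %in% names(init)) &&
                !tab$fixed[tab$name == "rbar"])
    seq(20, 50, length.out = n_starts) else tab$value[tab$name == "rbar"]
  best <- NULL
  for (r0 in starts) {
    tab_i <- tab
    tab_i$value[tab_i$name == "rbar"] <- r0
    res <- .run_lm(tab_i, make_resid(tab_i), .lm_control())
    if (is.null(best) || res$chi2 < best$chi2) best <- res
  }
  .new_fd_fit(best$tab, best, list(dataset), weights, "single",
              n_points, span)
}

# ---- global two-Gaussian fit --------------------------------------------

# deterministic (r1, r2) multi-start grid spanning 20-50 Angstrom
.global_starts <- matrix(c(45, 25,
                           40, 30,
                           50, 20,
                           35, 28,
                           48, 33), ncol = 2, byrow = TRUE)

# seed the global fit from per-condition single-Gaussian prefits: the
# condition fitting longest provides (r1, sigma1), the shortest (r2,
# sigma2), and each condition's A2 start comes from interpolating its
# single-Gaussian mean between the two component means. This places the
# two-Gaussian start inside the basin of the shared-parameter optimum.
.global_prefit_init <- function(datasets, pairs, weights, n_points, span,
                                tau_background) {
  # order-invariant: prefit the lexicographically first dataset of each
  # condition so the multi-start ladder ignores input ordering
  datasets <- datasets[order(vapply(datasets, dataset_id, character(1)))]
  conds <- vapply(datasets, function(d) d$condition, character(1))
  firsts <- datasets[!duplicated(conds)]
  fits <- lapply(firsts, function(d)
    fit_single_gaussian(d, get_pair(d$acceptor, pairs), weights = weights,
                        n_starts = 3L, n_points = n_points, span = span,
                        tau_background = tau_background))
  rb <- vapply(fits, function(f) coef(f)[["rbar"]], numeric(1))
  sg <- vapply(fits, function(f) coef(f)[["sigma"]], numeric(1))
  i1 <- which.max(rb); i2 <- which.min(rb)
  r1 <- rb[i1]; r2 <- rb[i2]
  if (i1 == i2 || r1 - r2 < 2) { r1 <- r1 + 1; r2 <- r2 - 9 }
  # keep starts strictly inside the box: a start pinned on a bound gives
  # the finite-difference Jacobian a dead column
  ini <- list(r1 = min(max(r1, 12), 58), sigma1 = min(max(sg[i1], 0.8), 9),
              r2 = min(max(r2, 12), 58), sigma2 = min(max(sg[i2], 0.8), 9))
  for (k in seq_along(firsts)) {
    a2 <- (ini$r1 - rb[k]) / (ini$r1 - ini$r2)
    ini[[sprintf("A2[%s]", firsts[[k]]$condition)]] <-
      min(max(a2, 0.05), 0.95)
  }
  ini
}

.build_global_tab <- function(datasets) {
  conds <- unique(vapply(datasets, function(d) d$condition, character(1)))
  samples <- unique(vapply(datasets, function(d) d$sample_id, character(1)))
  ids <- vapply(datasets, dataset_id, character(1))
  if (anyDuplicated(ids))
    stop("datasets must have unique acceptor/condition/ionic/replicate combinations")
  tab <- rbind(
    .param_row("r1",     45,   10, 60),
    .param_row("sigma1",  5,  0.5, 10),
    .param_row("r2",     25,   10, 60),
    .param_row("sigma2",  2,  0.5, 10),
    do.call(rbind, lapply(conds, function(cn)
      .param_row(sprintf("A2[%s]", cn), 0.5, 0, 1))),
    do.call(rbind, lapply(samples, function(sm)
      .param_row(sprintf("f_donor_only[%s]", sm), 0.1, 0, 0.5))),
    do.call(rbind, lapply(ids, function(id)
      .param_row(sprintf("f_background[%s]", id), 0, 0, 0.05))),
    do.call(rbind, lapply(ids, function(id)
      .param_row(sprintf("t0[%s]", id), 0, -2, 2)))
  )
  tab
}

#' Global two-Gaussian fit across conditions and acceptors
#'
#' Fits all datasets simultaneously with a sum-of-two-Gaussians distance
#' distribution. The structural parameters `r1`, `sigma1`, `r2`, `sigma2`
#' are shared across every dataset; the active-state fraction `A2` is one
#' parameter per ligand condition (bounded to \[0, 1\]); the donor-only
#' fraction is one parameter per labeled protein sample (`sample_id`); the
#' background fraction (bounded at 0.05) and timing offset `t0` are one
#' parameter per experiment. `R0` and `tau_donor` are taken from the pair
#' registry and held fixed. After fitting, components are reordered so that
#' `r1 > r2` (component 1 = resting, long distance), with `A2` remapped
#' accordingly.
#'
#' Combining several conditions and two acceptors with different `R0` is
#' what makes the two-Gaussian decomposition identifiable; with a single
#' condition the model is weakly identified and a warning is issued.
#'
#' @param datasets list of [fd_dataset()]s spanning conditions/acceptors.
#' @param pairs pair registry, see [default_pairs()].
#' @param init,fixed named lists keyed by full parameter name
#'   (`"A2[cGMP]"`) or family (`"A2"` applies to all conditions).
#' @param weights default observation uncertainties.
#' @param n_starts deterministic multi-start count (default 5; start pairs
#'   `(r1, r2)` span 20-50 Angstrom).
#' @param n_points,span discretization controls.
#' @param tau_background background lifetime (ns), 0 = scatter.
#' @return An `fd_fit` (model `"two_state"`).
#' @export
fit_global_two_gaussian <- function(datasets, pairs = default_pairs(),
                                    init = list(), fixed = list(),
                                    weights = fd_weights(), n_starts = 5L,
                                    n_points = 501L, span = 5,
                                    tau_background = 0) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  lapply(datasets, function(d) stopifnot(inherits(d, "fd_dataset")))
  # canonical dataset order: the fit is then bit-identical under any
  # permutation of the input list
  datasets <- datasets[order(vapply(datasets, dataset_id, character(1)))]
  conds <- unique(vapply(datasets, function(d) d$condition, character(1)))
  if (length(conds) < 2L)
    warning("fewer than 2 conditions: the two-Gaussian model is weakly identified")
  for (d in datasets) get_pair(d$acceptor, pairs)  # fails early if missing R0

  tab <- .build_global_tab(datasets)
  tab <- .apply_user(tab, init, "init")
  tab <- .apply_user(tab, fixed, "fixed")

  # per-dataset constants and parameter indices
  idx <- lapply(datasets, function(d) {
    pr <- get_pair(d$acceptor, pairs)
    list(omega_ns = 2 * pi * d$frequencies * 1e-9,
         R0 = pr$R0, tauD = pr$tau_donor,
         sp = if (!is.null(d$phase_sd)) d$phase_sd else weights$phase,
         sm = if (!is.null(d$mod_sd)) d$mod_sd else weights$mod,
         iA2 = match(sprintf("A2[%s]", d$condition), tab$name),
         ifdo = match(sprintf("f_donor_only[%s]", d$sample_id), tab$name),
         ifb = match(sprintf("f_background[%s]", dataset_id(d)), tab$name),
         it0 = match(sprintf("t0[%s]", dataset_id(d)), tab$name))
  })

  make_resid <- function(tab) {
    free <- which(!tab$fixed)
    full <- tab$value
    function(p) {
      full[free] <- p
      out <- vector("list", length(datasets))
      for (k in seq_along(datasets)) {
        ix <- idx[[k]]
        pred <- .fd_forward(full[1], full[2], full[3], full[4],
                            full[ix$iA2], full[ix$ifdo], full[ix$ifb],
                            tau_background, full[ix$it0],
                            ix$R0, ix$tauD, ix$omega_ns, n_points, span)
        out[[k]] <- .fd_resid(pred, datasets[[k]], ix$sp, ix$sm)
      }
      unlist(out, use.names = FALSE)
    }
  }

  # Multi-start ladder (deterministic): (1) single-Gaussian prefit with
  # per-condition interpolated A2; (2)-(4) prefit geometry with all A2
  # started low/high/middle, probing the A2-vs-sigma1 valley from several
  # directions; (5+) a coarse (r1, r2) grid spanning 20-50 Angstrom. A user
  # init or fixed structural parameter replaces the ladder with that start.
  user_r <- any(c("r1", "r2", "sigma1", "sigma2") %in% names(init)) ||
    any(tab$fixed[tab$name %in% c("r1", "r2")])
  starts <- list(NULL)
  if (!user_r) {
    pre <- .global_prefit_init(datasets, pairs, weights, n_points, span,
                               tau_background)
    geom <- pre[c("r1", "sigma1", "r2", "sigma2")]
    starts <- c(list(pre,
                     c(geom, list(A2 = 0.1)),
                     c(geom, list(A2 = 0.9)),
                     c(geom, list(A2 = 0.5))),
                lapply(seq_len(nrow(.global_starts)),
                       function(s) list(r1 = .global_starts[s, 1],
                                        r2 = .global_starts[s, 2])))
    starts <- starts[seq_len(max(1L, min(n_starts, length(starts))))]
  }
  best <- NULL
  for (st in starts) {
    tab_i <- tab
    if (!is.null(st)) tab_i <- .apply_user(tab_i, st, "init")
    res <- .run_lm(tab_i, make_resid(tab_i), .lm_control())
    if (is.null(best) || res$chi2 < best$chi2) best <- res
  }

  # enforce r1 > r2 (component 1 = resting/long) by relabeling
  tab <- best$tab
  v <- stats::setNames(tab$value, tab$name)
  if (v[["r1"]] < v[["r2"]] &&
      !any(tab$fixed[tab$name %in% c("r1", "r2", "sigma1", "sigma2")])) {
    tab$value[tab$name == "r1"] <- v[["r2"]]
    tab$value[tab$name == "r2"] <- v[["r1"]]
    tab$value[tab$name == "sigma1"] <- v[["sigma2"]]
    tab$value[tab$name == "sigma2"] <- v[["sigma1"]]
    a2i <- grepl("^A2\\[", tab$name)
    tab$value[a2i] <- 1 - tab$value[a2i]
  }
  best$tab <- tab
  .new_fd_fit(tab, best, datasets, weights, "two_state", n_points, span)
}

#' Predictions of a fitted model for its datasets
#'
#' @param fit an `fd_fit`.
#' @param datasets the datasets the fit was produced from (same order).
#' @param pairs pair registry.
#' @param tau_background background lifetime used in the fit.
#' @return List of lists with `phase_deg`, `mod_ratio` per dataset.
#' @export
predict_fit <- function(fit, datasets, pairs = default_pairs(),
                        tau_background = 0) {
  stopifnot(inherits(fit, "fd_fit"))
  if (inherits(datasets, "fd_dataset")) datasets <- list(datasets)
  p <- coef(fit)
  lapply(datasets, function(d) {
    pr <- get_pair(d$acceptor, pairs)
    om <- 2 * pi * d$frequencies * 1e-9
    if (fit$model == "single")
      .fd_forward(p[["rbar"]], p[["sigma"]], 0, 1, 0,
                  p[["f_donor_only"]], p[["f_background"]], tau_background,
                  p[["t0"]], pr$R0, pr$tau_donor, om, fit$n_points, fit$span)
    else
      .fd_forward(p[["r1"]], p[["sigma1"]], p[["r2"]], p[["sigma2"]],
                  p[[sprintf("A2[%s]", d$condition)]],
                  p[[sprintf("f_donor_only[%s]", d$sample_id)]],
                  p[[sprintf("f_background[%s]", dataset_id(d))]],
                  tau_background,
                  p[[sprintf("t0[%s]", dataset_id(d))]],
                  pr$R0, pr$tau_donor, om, fit$n_points, fit$span)
  })
}

# ---- chi-square profile scans -------------------------------------------

#' Chi-square profile of one global-fit parameter
#'
#' Identifiability diagnostic: the chosen parameter is fixed at each grid
#' value in turn, all other free parameters are re-minimized, and the
#' minimized chi-square is recorded. An identifiable parameter shows a
#' resolved interior minimum near its fitted value; a flat profile or a
#' minimum pinned at the grid edge signals poor identifiability.
#'
#' @param datasets list of [fd_dataset()]s.
#' @param pairs pair registry.
#' @param param full parameter name (e.g. `"r2"` or `"A2[cGMP]"`).
#' @param grid numeric vector of values at which to fix the parameter.
#' @param fixed,init,weights,n_points,span,tau_background as in
#'   [fit_global_two_gaussian()].
#' @param base_fit optional previously computed global fit used to
#'   initialize each profile point (computed internally when missing).
#' @return A `profile_scan`: data.frame with `value`, `chi2`, `converged`
#'   and attribute `param`. Grid points where the refit fails are recorded
#'   with `NA` chi-square rather than aborting the scan.
#' @export
profile_parameter <- function(datasets, pairs = default_pairs(), param, grid,
                              fixed = list(), init = list(),
                              weights = fd_weights(), n_points = 501L,
                              span = 5, tau_background = 0,
                              base_fit = NULL) {
  tab <- .build_global_tab(datasets)
  if (!param %in% tab$name)
    stop(sprintf("unknown parameter '%s'", param))
  tab_chk <- .apply_user(tab, fixed, "fixed")
  if (tab_chk$fixed[tab_chk$name == param])
    stop(sprintf("parameter '%s' is fixed; its profile is flat by construction", param))
  if (is.null(base_fit))
    base_fit <- fit_global_two_gaussian(datasets, pairs, init = init,
                                        fixed = fixed, weights = weights,
                                        n_starts = 1L, n_points = n_points,
                                        span = span,
                                        tau_background = tau_background)
  base <- as.list(coef(base_fit))
  chi2 <- conv <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    fx <- fixed; fx[[param]] <- grid[i]
    ini <- base[setdiff(names(base), c(param, names(fx)))]
    ft <- tryCatch(
      fit_global_two_gaussian(datasets, pairs, init = ini, fixed = fx,
                              weights = weights, n_starts = 1L,
                              n_points = n_points, span = span,
                              tau_background = tau_background),
      error = function(e) NULL)
    if (!is.null(ft)) { chi2[i] <- ft$chi2; conv[i] <- ft$converged }
  }
  structure(data.frame(value = grid, chi2 = chi2, converged = as.logical(conv)),
            param = param, class = c("profile_scan", "data.frame"))
}

# ---- donor-only single-exponential fit ----------------------------------

#' Fit a single-exponential lifetime to a donor-only dataset
#'
#' For acceptor-free samples the decay is single exponential; this fits the
#' lifetime and the timing offset `t0` to the Weber-plot data by weighted
#' least squares.
#'
#' @param dataset an [fd_dataset()] measured without acceptor.
#' @param init named list with starting `tau` (ns) and `t0`.
#' @param weights default observation uncertainties.
#' @return List of class `donor_fit` with `tau`, `t0`, `chi2`, `converged`.
#' @export
fit_donor_only <- function(dataset, init = list(tau = 15, t0 = 0),
                           weights = fd_weights()) {
  stopifnot(inherits(dataset, "fd_dataset"))
  omega_ns <- 2 * pi * dataset$frequencies * 1e-9
  sp <- if (!is.null(dataset$phase_sd)) dataset$phase_sd else weights$phase
  sm <- if (!is.null(dataset$mod_sd)) dataset$mod_sd else weights$mod
  fn <- function(p) {
    nd <- .fd_nd(1, p[1], omega_ns)
    pred <- list(phase_deg = (atan2(nd$N, nd$D) + omega_ns * p[2]) * 180 / pi,
                 mod_ratio = sqrt(nd$N^2 + nd$D^2))
    .fd_resid(pred, dataset, sp, sm)
  }
  res <- minpack.lm::nls.lm(par = c(init$tau, init$t0),
                            lower = c(1e-3, -2), upper = c(100, 2),
                            fn = fn, control = .lm_control())
  structure(list(tau = res$par[1], t0 = res$par[2],
                 chi2 = sum(res$fvec^2), converged = res$info %in% 1:4),
            class = "donor_fit")
}
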