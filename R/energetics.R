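#' @name energetics
#' @title Four-state conformational energetics
#' @description
#' The C-terminal domain is modeled with four states (apo/holo x
#' resting/active). The fitted active-state fraction `A2` of a condition is
#' read as `P_active`, and the free energy of the resting-to-active
#' transition is \eqn{\Delta G = -RT \ln(P_{active}/P_{resting})}. Ligand
#' coupling energies are differences, \eqn{\Delta\Delta G_{cNMP} = \Delta
#' G_{cNMP} - \Delta G_{apo}}, and the ionic-strength effect is a second
#' difference, \eqn{\Delta\Delta\Delta G = \Delta\Delta G_{150mM} -
#' \Delta\Delta G_{500mM}}.
#'
#' When a fit pins `A2` at 1, only a bound on the energy can be quoted: the
#' resting-state contribution is floored at `resting_floor` (default 0.01)
#' and the resulting value carries a "more favorable than" bound flag that
#' propagates through all subsequent differences.
NULL

#' Molar gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.98722e-3

#' Free-energy value with bound flag
#'
#' @param value energy in kcal/mol.
#' @param bound logical; `TRUE` when the value is an upper bound ("more
#'   favorable than") arising from a floored probability.
#' @return Object of class `free_energy`.
#' @export
free_energy <- function(value, bound = FALSE) {
  structure(list(value = value, bound = bound), class = "free_energy")
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("%s%.3f kcal/mol%s\n", if (x$bound) "< " else "", x$value,
              if (x$bound) " (bound: more favorable than)" else ""))
  invisible(x)
}

#' @rdname fe_value
#' @export
fe_value <- function(x) if (inherits(x, "free_energy")) x$value else as.numeric(x)

#' Accessors for free-energy values
#'
#' `fe_value()` extracts the numeric energy; `fe_bound()` reports whether it
#' is flagged as a bound. Plain numerics are accepted and treated as
#' unflagged.
#'
#' @param x a `free_energy` or numeric.
#' @return Numeric value, or logical flag.
#' @name fe_value
#' @export
fe_bound <- function(x) if (inherits(x, "free_energy")) x$bound else FALSE

#' Free energy of the resting-to-active transition
#'
#' \eqn{\Delta G = -RT \ln(P_{active}/(1 - P_{active}))}. If `P_active >=
#' 1 - resting_floor` the resting contribution is floored at
#' `resting_floor` and the result is flagged as an upper bound. `P_active
#' = 0` returns `+Inf` with the bound flag set.
#'
#' @param P_active active-state probability in \[0, 1\] (the fitted A2).
#' @param T absolute temperature, K (default 298).
#' @param resting_floor maximum assumed resting contribution when the fit
#'   saturates at `P_active = 1` (default 0.01).
#' @return A [free_energy()] in kcal/mol.
#' @examples
#' delta_G(0.12)          # about +1.2 kcal/mol
#' delta_G(1)             # bound: more favorable than -2.7 kcal/mol
#' @export
delta_G <- function(P_active, T = 298, resting_floor = 0.01) {
  if (!is.numeric(P_active) || length(P_active) != 1L ||
      P_active < 0 || P_active > 1)
    stop("'P_active' must be a single value in [0, 1]")
  if (P_active == 0) return(free_energy(Inf, bound = TRUE))
  if (P_active >= 1 - resting_floor)
    return(free_energy(-R_KCAL * T * log((1 - resting_floor) / resting_floor),
                       bound = TRUE))
  free_energy(-R_KCAL * T * log(P_active / (1 - P_active)))
}

#' Active-state probability from a free energy
#'
#' Logistic inverse of [delta_G()]: \eqn{P_{active} = 1/(1 +
#' e^{\Delta G/RT})}.
#'
#' @param dG free energy, kcal/mol (numeric or `free_energy`).
#' @param T absolute temperature, K.
#' @return Probability in (0, 1).
#' @export
p_active_from_dG <- function(dG, T = 298) {
  1 / (1 + exp(fe_value(dG) / (R_KCAL * T)))
}

#' Ligand coupling energy
#'
#' \eqn{\Delta\Delta G_{cNMP} = \Delta G_{cNMP} - \Delta G_{apo}}, an exact
#' difference; bound flags propagate.
#'
#' @param dG_ligand,dG_apo free energies (numeric or [free_energy()]).
#' @return A `free_energy` in kcal/mol.
#' @export
delta_delta_G <- function(dG_ligand, dG_apo) {
  free_energy(fe_value(dG_ligand) - fe_value(dG_apo),
              bound = fe_bound(dG_ligand) || fe_bound(dG_apo))
}

#' Ionic-strength effect on the coupling energy
#'
#' \eqn{\Delta\Delta\Delta G = \Delta\Delta G_{low salt} - \Delta\Delta
#' G_{high salt}}; positive when activation is less favorable at low salt.
#'
#' @param ddG_low_salt,ddG_high_salt coupling energies (numeric or
#'   [free_energy()]).
#' @return A `free_energy` in kcal/mol.
#' @export
delta3_G <- function(ddG_low_salt, ddG_high_salt) {
  free_energy(fe_value(ddG_low_salt) - fe_value(ddG_high_salt),
              bound = fe_bound(ddG_low_salt) || fe_bound(ddG_high_salt))
}

#' Per-condition energetics table from fitted A2 values
#'
#' Convenience wrapper producing a table of `P_active`, `delta G`, and
#' (when an `"apo"` condition is present) `delta delta G` relative to apo,
#' with bound flags.
#'
#' @param A2 named numeric vector of active-state fractions per condition.
#' @param T absolute temperature, K.
#' @param resting_floor see [delta_G()].
#' @return `data.frame` with columns `condition`, `P_active`, `dG`,
#'   `dG_bound`, `ddG`, `ddG_bound`.
#' @export
state_energetics <- function(A2, T = 298, resting_floor = 0.01) {
  stopifnot(!is.null(names(A2)))
  dg <- lapply(A2, delta_G, T = T, resting_floor = resting_floor)
  out <- data.frame(condition = names(A2), P_active = as.numeric(A2),
                    dG = vapply(dg, fe_value, numeric(1)),
                    dG_bound = vapply(dg, fe_bound, logical(1)),
                    ddG = NA_real_, ddG_bound = NA,
                    row.names = NULL)
  if ("apo" %in% names(A2)) {
    for (i in seq_along(A2)) {
      if (names(A2)[i] == "apo") next
      dd <- delta_delta_G(dg[[i]], dg[["apo"]])
      out$ddG[i] <- fe_value(dd); out$ddG_bound[i] <- fe_bound(dd)
    }
  }
  out
}

# ---- Hill dose-response -------------------------------------------------

#' Hill equation
#'
#' Normalized response \eqn{1/(1 + (K_{1/2}/c)^h)}: 0.5 at `conc ==
#' K_half`, approaching 1 at saturation.
#'
#' @param conc ligand concentration(s), uM, positive.
#' @param K_half half-maximal concentration, uM.
#' @param h Hill coefficient.
#' @return Response fraction(s).
#' @export
hill_eval <- function(conc, K_half, h) {
  if (any(conc <= 0)) stop("'conc' must be positive")
  if (K_half <= 0 || h <= 0) stop("'K_half' and 'h' must be positive")
  1 / (1 + (K_half / conc)^h)
}

#' Fit the Hill equation to normalized responses
#'
#' Least-squares fit of [hill_eval()]; the slope can be held fixed
#' (`fix_h`), as is customary when the data do not constrain it.
#'
#' @param conc concentrations, uM, positive.
#' @param response normalized responses in \[0, 1\].
#' @param fix_h optional fixed Hill coefficient; when `NULL` the slope is
#'   fitted, which requires at least 3 points.
#' @return Object of class `hill_fit` with `K_half`, `h`, `h_fixed`,
#'   `fitted`, `residuals`.
#' @export
hill_fit <- function(conc, response, fix_h = NULL) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("'conc' must be positive")
  if (is.null(fix_h) && length(conc) < 3L)
    stop("at least 3 points are required to fit a free Hill coefficient")
  if (length(conc) < 2L) stop("at least 2 points are required")
  if (stats::sd(response) == 0)
    stop("responses have no dynamic range; Hill fit is undetermined")
  # initialize K at the concentration closest to half-maximal response
  K0 <- conc[which.min(abs(response - 0.5))]
  if (K0 <= 0 || !is.finite(K0)) K0 <- exp(mean(log(conc)))
  if (is.null(fix_h)) {
    fn <- function(p) response - hill_eval(conc, p[1], p[2])
    res <- minpack.lm::nls.lm(par = c(K0, 1), lower = c(1e-9, 0.05),
                              upper = c(1e9, 20), fn = fn,
                              control = .lm_control())
    K <- res$par[1]; h <- res$par[2]
  } else {
    fn <- function(p) response - hill_eval(conc, p[1], fix_h)
    res <- minpack.lm::nls.lm(par = K0, lower = 1e-9, upper = 1e9, fn = fn,
                              control = .lm_control())
    K <- res$par[1]; h <- fix_h
  }
  structure(list(K_half = K, h = h, h_fixed = !is.null(fix_h),
                 fitted = hill_eval(conc, K, h),
                 residuals = response - hill_eval(conc, K, h),
                 converged = res$info %in% 1:4),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> K1/2 = %.4g uM, h = %.3g%s\n", x$K_half, x$h,
              if (x$h_fixed) " (fixed)" else ""))
  invisible(x)
}

#' Aggregate per-experiment energies and compare groups
#'
#' Mean and standard error per group, plus pairwise two-tailed Student's
#' t-tests between groups. Groups with fewer than two values get `NA` SEM
#' and are flagged.
#'
#' @param values per-experiment energies (kcal/mol) or other quantities.
#' @param groups group labels, same length.
#' @return List with `summary` (group, n, mean, sem, sem_defined) and
#'   `comparisons` (group pair, t, df, p) data frames.
#' @export
aggregate_energetics <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  gs <- unique(groups)
  summ <- do.call(rbind, lapply(gs, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               sem_defined = length(v) >= 2L)
  }))
  comps <- NULL
  if (length(gs) >= 2L) {
    pairs <- utils::combn(gs, 2L)
    comps <- do.call(rbind, apply(pairs, 2L, function(pr) {
      v1 <- values[groups == pr[1]]; v2 <- values[groups == pr[2]]
      if (length(v1) < 2L || length(v2) < 2L)
        return(data.frame(group1 = pr[1], group2 = pr[2],
                          t = NA_real_, df = NA_real_, p = NA_real_))
      tt <- stats::t.test(v1, v2, var.equal = TRUE)
      data.frame(group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }))
  }
  list(summary = summ, comparisons = comps)
}
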