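#' Synthetic study design
#'
#' Defines the simulated experiment the generator produces. The defaults
#' reproduce the lifetime study design the analysis was built for: two
#' long-range acceptors (`Fe(phenM)3`, R0 = 41.8 A, and `Ru(bpy)2phenM`,
#' R0 = 43.5 A) sharing the 17.2 ns Acd donor, three ligand conditions
#' (apo, cAMP, cGMP) at 500 mM KCl, one replicate per cell (the canonical
#' six-dataset global-fit layout), a 14-point log-spaced frequency grid
#' from the 10 MHz fundamental to 200 MHz, and Gaussian measurement noise
#' of 0.2 degrees on phase and 0.004 on modulation.
#'
#' The ground-truth distance distribution defaults to the two-state
#' parameters recovered in the original study (r1 = 40.9 A, sigma1 =
#' 4.3 A, r2 = 29.5 A, sigma2 = 0.84 A) with per-condition active-state
#' fractions A2 of 0.12 (apo), 1 (cAMP) and 0.34 (cGMP) at 500 mM KCl; at
#' 150 mM KCl apo/cGMP fractions are 0.127/0.244, the values implied by
#' the reported free energies through the logistic inverse. Nuisance
#' parameters are drawn uniformly per sample/experiment: donor-only
#' fraction in \[0.05, 0.15\] (shared across conditions within a sample),
#' background fraction in \[0, 0.05\] and t0 in \[-0.5, 0.5\] ns per
#' experiment.
#'
#' @param acceptors acceptor names resolving in `pairs`.
#' @param conditions ligand condition labels.
#' @param ionic ionic condition(s), mM KCl; must have truth A2 entries.
#' @param replicates replicates per acceptor x ionic cell.
#' @param frequencies modulation frequency grid, Hz.
#' @param noise named vector `c(phase = deg, mod = fraction)`, >= 0.
#' @param truth list with `r1`, `sigma1`, `r2`, `sigma2` and `A2`, a named
#'   list keyed by ionic label, each a named vector per condition.
#' @param nuisance_ranges list of length-2 ranges for `f_donor_only`,
#'   `f_background`, `t0`.
#' @param tau_background background lifetime, ns (0 = scatter).
#' @param pairs pair registry.
#' @param seed integer seed; together with the design it fully determines
#'   the generated datasets.
#' @return Object of class `study_design`.
#' @export
study_design <- function(acceptors = c("Fe(phenM)3", "Ru(bpy)2phenM"),
                         conditions = c("apo", "cAMP", "cGMP"),
                         ionic = 500,
                         replicates = 1L,
                         frequencies = default_frequencies(),
                         noise = c(phase = 0.2, mod = 0.004),
                         truth = list(
                           r1 = 40.9, sigma1 = 4.3, r2 = 29.5, sigma2 = 0.84,
                           A2 = list(
                             "500" = c(apo = 0.12, cAMP = 1, cGMP = 0.34),
                             "150" = c(apo = 0.127, cAMP = 1, cGMP = 0.244))),
                         nuisance_ranges = list(
                           f_donor_only = c(0.05, 0.15),
                           f_background = c(0, 0.05),
                           t0 = c(-0.5, 0.5)),
                         tau_background = 0,
                         pairs = default_pairs(),
                         seed = 1L) {
  stopifnot(all(noise >= 0), replicates >= 1L)
  for (a in acceptors) get_pair(a, pairs)
  for (io in ionic) {
    a2 <- truth$A2[[as.character(io)]]
    if (is.null(a2) || !all(conditions %in% names(a2)))
      stop(sprintf("truth$A2 must provide every condition for ionic level %s", io))
  }
  structure(list(acceptors = acceptors, conditions = conditions,
                 ionic = ionic, replicates = as.integer(replicates),
                 frequencies = frequencies, noise = noise, truth = truth,
                 nuisance_ranges = nuisance_ranges,
                 tau_background = tau_background, pairs = pairs,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Generate a frequency-domain tmFRET study
#'
#' Simulates every dataset of the design: for each acceptor x ionic x
#' replicate sample a donor-only fraction is drawn (shared across the
#' sample's ligand conditions, as in real experiments where one labeled
#' protein prep is measured under all conditions); for each experiment a
#' background fraction and timing offset are drawn; noise-free phase and
#' modulation are computed by the forward model and seeded Gaussian noise
#' is added. With zero noise the datasets equal the forward-model
#' predictions exactly.
#'
#' @param design a [study_design()].
#' @return List with `datasets` (list of [fd_dataset()]) and `truth` (the
#'   generating parameters, including the drawn nuisance values per
#'   dataset).
#' @export
generate_fd_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  withr::with_seed(design$seed, .generate_fd_study(design))
}

.generate_fd_study <- function(design) {
  tr <- design$truth
  datasets <- list()
  truth_rows <- list()
  for (acc in design$acceptors) {
    pair <- get_pair(acc, design$pairs)
    for (io in design$ionic) {
      a2 <- tr$A2[[as.character(io)]]
      for (rep in seq_len(design$replicates)) {
        rid <- sprintf("r%d", rep)
        sample_id <- paste(acc, io, rid, sep = "/")
        fdo <- stats::runif(1, design$nuisance_ranges$f_donor_only[1],
                            design$nuisance_ranges$f_donor_only[2])
        for (cond in design$conditions) {
          fb <- stats::runif(1, design$nuisance_ranges$f_background[1],
                             design$nuisance_ranges$f_background[2])
          t0 <- stats::runif(1, design$nuisance_ranges$t0[1],
                             design$nuisance_ranges$t0[2])
          dist <- make_two_state(tr$r1, tr$sigma1, tr$r2, tr$sigma2,
                                 a2[[cond]])
          nu <- nuisance_params(fdo, fb, design$tau_background, t0)
          mix <- species_from_distribution(dist, pair, nu)
          resp <- fd_response(mix, design$frequencies, t0 = t0)
          ph <- resp$phase_deg +
            stats::rnorm(length(design$frequencies), 0, design$noise[["phase"]])
          md <- resp$mod_ratio +
            stats::rnorm(length(design$frequencies), 0, design$noise[["mod"]])
          md <- pmin(md, 1)  # modulation ratio cannot exceed 1
          ds <- fd_dataset(design$frequencies, ph, md, condition = cond,
                           acceptor = acc, ionic = io, replicate_id = rid,
                           sample_id = sample_id)
          datasets[[length(datasets) + 1L]] <- ds
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            dataset = dataset_id(ds), condition = cond, acceptor = acc,
            ionic = io, replicate = rid, A2 = a2[[cond]],
            f_donor_only = fdo, f_background = fb, t0 = t0)
        }
      }
    }
  }
  list(datasets = datasets,
       truth = list(r1 = tr$r1, sigma1 = tr$sigma1, r2 = tr$r2,
                    sigma2 = tr$sigma2,
                    per_dataset = do.call(rbind, truth_rows),
                    seed = design$seed))
}

#' Generate a donor-only (acceptor-free) dataset
#'
#' Single-exponential frequency-domain data at the unquenched donor
#' lifetime with seeded Gaussian noise.
#'
#' @param tau_D donor lifetime, ns.
#' @param frequencies frequency grid, Hz.
#' @param noise named vector `c(phase = deg, mod = fraction)`.
#' @param t0 timing offset, ns.
#' @param seed integer seed.
#' @param ... metadata forwarded to [fd_dataset()].
#' @return An [fd_dataset()] with condition `"donor-only"` by default.
#' @export
generate_donor_only <- function(tau_D = 17.2,
                                frequencies = default_frequencies(),
                                noise = c(phase = 0.2, mod = 0.004),
                                t0 = 0, seed = 1L, ...) {
  mix <- species_mixture(1, tau_D)
  resp <- fd_response(mix, frequencies, t0 = t0)
  withr::with_seed(seed, {
    ph <- resp$phase_deg + stats::rnorm(length(frequencies), 0, noise[["phase"]])
    md <- pmin(resp$mod_ratio +
                 stats::rnorm(length(frequencies), 0, noise[["mod"]]), 1)
    fd_dataset(frequencies, ph, md, condition = "donor-only", ...)
  })
}

#' Generate paired cysteine / no-cysteine intensity time courses
#'
#' Emulates a steady-state cuvette experiment: baseline, acceptor addition
#' quenching the cysteine construct to `1 - E_acceptor`, nucleotide
#' addition deepening quenching to `1 - E_nucleotide`, and an optional
#' TCEP event reversing labeling back to the no-cysteine level. The
#' no-cysteine control is flat apart from an optional mild nonspecific
#' quench at acceptor addition. Levels relax exponentially with time
#' constant `tau_kin` (0 gives instantaneous steps, convenient for exact
#' round-trip checks).
#'
#' @param E_acceptor FRET efficiency after acceptor addition.
#' @param E_nucleotide FRET efficiency after nucleotide addition.
#' @param nonspecific fractional nonspecific quench of the control course.
#' @param tau_kin relaxation time constant, s.
#' @param dt sampling interval, s.
#' @param t_end record length, s.
#' @param event_times named vector with `acceptor`, `nucleotide` and
#'   optionally `tcep` times (s).
#' @param noise additive Gaussian intensity noise sd (normalized units).
#' @param seed integer seed.
#' @return List with `cys` and `nocys` [timecourse()]s.
#' @export
generate_timecourses <- function(E_acceptor = 0.45, E_nucleotide = 0.60,
                                 nonspecific = 0, tau_kin = 15, dt = 10,
                                 t_end = 700,
                                 event_times = c(acceptor = 100,
                                                 nucleotide = 300,
                                                 tcep = 500),
                                 noise = 0, seed = 1L) {
  stopifnot(E_acceptor >= 0, E_acceptor < 1, E_nucleotide >= 0,
            E_nucleotide < 1, nonspecific >= 0, nonspecific < 1)
  tt <- seq(0, t_end, by = dt)
  q <- 1 - nonspecific
  labels <- names(event_times)
  ev_t <- as.numeric(event_times)
  cys_targets <- c(q * (1 - E_acceptor), q * (1 - E_nucleotide))
  nocys_targets <- c(q, q)
  if ("tcep" %in% labels) {
    cys_targets <- c(cys_targets[seq_len(2)], q)
    nocys_targets <- c(nocys_targets, q)
  }
  trace <- function(targets) {
    y <- rep(1, length(tt))
    lev <- 1
    for (k in seq_along(ev_t)) {
      after <- tt >= ev_t[k]
      if (tau_kin > 0) {
        y[after] <- targets[k] + (lev - targets[k]) *
          exp(-(tt[after] - ev_t[k]) / tau_kin)
        lev <- targets[k] + (lev - targets[k]) *
          exp(-(if (k < length(ev_t)) ev_t[k + 1] - ev_t[k] else Inf) / tau_kin)
      } else {
        y[after] <- targets[k]
        lev <- targets[k]
      }
    }
    y
  }
  cys_y <- trace(cys_targets)
  nocys_y <- trace(nocys_targets)
  if (noise > 0) {
    withr::with_seed(seed, {
      cys_y <- cys_y + stats::rnorm(length(tt), 0, noise)
      nocys_y <- nocys_y + stats::rnorm(length(tt), 0, noise)
    })
    cys_y <- pmax(cys_y, 1e-6)
    nocys_y <- pmax(nocys_y, 1e-6)
  }
  ev <- data.frame(time = ev_t, label = labels)
  list(cys = timecourse(tt, cys_y, ev), nocys = timecourse(tt, nocys_y, ev))
}

#' Generate a synthetic dose-response table
#'
#' Hill-equation responses over a concentration grid with seeded Gaussian
#' noise. Default truth matches the steady-state dose-response reported
#' for the Fe acceptor (K1/2 = 0.25 uM, h = 1.2).
#'
#' @param K_half half-maximal concentration, uM.
#' @param h Hill coefficient.
#' @param conc concentration grid, uM.
#' @param noise additive Gaussian noise sd on the response.
#' @param seed integer seed.
#' @return `data.frame` with `conc_uM` and `response`.
#' @export
generate_dose_response <- function(K_half = 0.25, h = 1.2,
                                   conc = 10^seq(-2, 1.2, length.out = 9),
                                   noise = 0, seed = 1L) {
  resp <- hill_eval(conc, K_half, h)
  if (noise > 0)
    resp <- withr::with_seed(seed,
                             resp + stats::rnorm(length(conc), 0, noise))
  data.frame(conc_uM = conc, response = resp)
}
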