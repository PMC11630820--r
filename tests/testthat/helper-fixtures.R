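# shared fixtures: the canonical six-dataset study layout at the
# two-state truth (r1 = 40.9, s1 = 4.3, r2 = 29.5, s2 = 0.84,
# A2 = 0.12 / 1 / 0.34 at 500 mM KCl)

truth_pars <- list(r1 = 40.9, sigma1 = 4.3, r2 = 29.5, sigma2 = 0.84,
                   A2 = c(apo = 0.12, cAMP = 1, cGMP = 0.34))

truth_study <- function(seed = 1L, noise = c(phase = 0.2, mod = 0.004)) {
  generate_fd_study(study_design(noise = noise, seed = seed))
}

noise_free_study <- function(seed = 1L) {
  truth_study(seed = seed, noise = c(phase = 0, mod = 0))
}

# 20-seed recovery study, computed once per session and shared between
# the recovery-accuracy and recovery-bias tests (the expensive part is
# identical)
.recovery_cache <- new.env(parent = emptyenv())
recovery_estimates <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.recovery_cache[[key]])) {
    .recovery_cache[[key]] <- do.call(rbind, lapply(seeds, function(s) {
      st <- truth_study(seed = s)
      ft <- fit_global_two_gaussian(st$datasets, n_starts = 3)
      p <- coef(ft)
      a2 <- fit_A2(ft)
      data.frame(seed = s, r1 = p[["r1"]], sigma1 = p[["sigma1"]],
                 r2 = p[["r2"]], sigma2 = p[["sigma2"]],
                 A2_apo = a2[["apo"]], A2_cAMP = a2[["cAMP"]],
                 A2_cGMP = a2[["cGMP"]])
    }))
  }
  .recovery_cache[[key]]
}

# independent time-domain oracle: trapezoid Fourier transform of
# I(t) = sum_j alpha_j exp(-t / tau_j) sampled on a fine grid
td_oracle <- function(amplitudes, lifetimes, frequency_hz, t0_ns = 0) {
  tau <- lifetimes[lifetimes > 0]
  amp <- amplitudes[lifetimes > 0]
  tmax <- 60 * max(tau)
  dt <- min(tau) / 500
  tt <- seq(0, tmax, by = dt)
  I <- numeric(length(tt))
  for (j in seq_along(tau)) I <- I + amp[j] * exp(-tt / tau[j])
  trap <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  tot <- trap(I)
  vapply(frequency_hz, function(f) {
    w <- 2 * pi * f * 1e-9
    N <- trap(I * sin(w * tt)) / tot
    D <- trap(I * cos(w * tt)) / tot
    c(phase_rad = atan2(N, D) + w * t0_ns, mod = sqrt(N^2 + D^2))
  }, c(phase_rad = 0, mod = 0))
}
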