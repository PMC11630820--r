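test_that("nuisance parameters enforce fraction bookkeeping", {
  expect_silent(nuisance_params(0.1, 0.03, 0, 0.2))
  expect_error(nuisance_params(f_donor_only = 1), "\\[0, 1\\)")
  expect_error(nuisance_params(f_background = 0.1), "0.05")
  expect_error(nuisance_params(0.97, 0.04), "< 1")
  expect_silent(nuisance_params(f_background = 0.1, max_background = 0.2))
})

test_that("species expansion books amplitude fractions exactly", {
  fe <- get_pair("Fe(phenM)3")
  m0 <- species_from_distribution(make_single(35, 3), fe)
  expect_equal(sum(m0$amplitudes), 1)
  expect_false(any(m0$lifetimes == 17.2))  # no donor-only species at f = 0
  mix <- species_from_distribution(make_two_state(40.9, 4.3, 29.5, 0.84, 0.34),
                                   fe, nuisance_params(0.1, 0.02))
  expect_equal(sum(mix$amplitudes), 1)
  expect_equal(mix$amplitudes[mix$lifetimes == 17.2], 0.1)  # donor-only
  expect_equal(mix$amplitudes[mix$lifetimes == 0], 0.02)    # scatter
  # f_donor_only -> 1 limit: pure donor decay
  m1 <- species_from_distribution(make_single(35, 3), fe,
                                  nuisance_params(f_donor_only = 0.999999))
  r <- fd_response(m1, 1e7)
  expect_equal(r$phase_deg, atan(2 * pi * 1e7 * 17.2e-9) * 180 / pi,
               tolerance = 1e-4)
})

test_that("single-exponential response matches the analytic closed form", {
  m <- species_mixture(1, 17.2)
  wt <- 2 * pi * 1e7 * 17.2e-9
  r <- fd_response(m, 1e7)
  expect_equal(r$phase_deg, atan(wt) * 180 / pi, tolerance = 1e-12)
  expect_equal(r$mod_ratio, 1 / sqrt(1 + wt^2), tolerance = 1e-12)
  expect_equal(r$phase_deg, 47.221, tolerance = 1e-4)
  expect_equal(r$mod_ratio, 0.67917, tolerance = 1e-4)
  # low-frequency limit: no phase lag, full modulation
  r0 <- fd_response(m, 1)
  expect_lt(r0$phase_deg, 1e-4)
  expect_gt(r0$mod_ratio, 1 - 1e-6)
  expect_error(fd_response(m, -1e7), "positive")
})

test_that("t0 shifts phase by omega*t0 and leaves modulation alone", {
  mix <- species_mixture(c(0.4, 0.6), c(3, 12))
  a <- fd_response(mix, 1e7, t0 = 0)
  b <- fd_response(mix, 1e7, t0 = 1)
  expect_equal(b$phase_deg - a$phase_deg, 2 * pi * 1e7 * 1e-9 * 180 / pi,
               tolerance = 1e-12)  # 3.6 degrees
  expect_equal(b$mod_ratio, a$mod_ratio)
})

test_that("frequency-domain model agrees with time-domain Fourier oracle", {
  set.seed(401)
  freqs <- c(1e7, 3e7, 8e7, 1.5e8)
  for (k in 1:5) {
    n <- sample(2:4, 1)
    amp <- stats::runif(n); amp <- amp / sum(amp)
    tau <- stats::runif(n, 0.5, 18)
    t0 <- stats::runif(1, -0.5, 0.5)
    got <- fd_response(species_mixture(amp, tau), freqs, t0 = t0)
    ora <- td_oracle(amp, tau, freqs, t0)
    expect_lt(max(abs(got$phase_deg * pi / 180 - ora["phase_rad", ])), 1e-4)
    expect_lt(max(abs(got$mod_ratio - ora["mod", ])), 1e-4)
  }
  # full forward fixture including distribution and nuisance species
  # (coarse 25-point grid keeps the oracle's time integral tractable)
  fe <- get_pair("Fe(phenM)3")
  mix <- species_from_distribution(make_two_state(40.9, 4.3, 29.5, 0.84, 0.34),
                                   fe, nuisance_params(0.1, 0.02, 2, 0.3),
                                   n_points = 25L)
  got <- fd_response(mix, freqs, t0 = 0.3)
  ora <- td_oracle(c(mix$amplitudes, 0), c(mix$lifetimes, 0), freqs, 0.3)
  expect_lt(max(abs(got$phase_deg * pi / 180 - ora["phase_rad", ])), 1e-4)
  expect_lt(max(abs(got$mod_ratio - ora["mod", ])), 1e-4)
})

test_that("predicted datasets behave qualitatively like Weber plots", {
  fe <- get_pair("Fe(phenM)3")
  ds <- predict_dataset(make_single(40.9, 4.3), fe,
                        nuisance_params(0.1, 0.02, 0, 0.1), condition = "apo")
  expect_s3_class(ds, "fd_dataset")
  expect_true(all(diff(ds$phase_deg) > 0))   # phase rises with frequency
  expect_true(all(diff(ds$mod_ratio) < 0))   # modulation falls
  # distribution far beyond R0: indistinguishable from donor-only
  far <- predict_dataset(make_single(800, 1), fe)
  dn <- fd_response(species_mixture(1, 17.2), far$frequencies)
  expect_lt(max(abs(far$phase_deg - dn$phase_deg)), 1e-6)
  expect_lt(max(abs(far$mod_ratio - dn$mod_ratio)), 1e-6)
})

test_that("fd_dataset validates its invariants", {
  f <- c(1e7, 2e7, 4e7)
  expect_error(fd_dataset(f, c(10, 20), c(0.9, 0.8, 0.7)), "equal length")
  expect_error(fd_dataset(c(1e7, 4e7, 2e7), c(10, 20, 30), c(0.9, 0.8, 0.7)),
               "increasing")
  expect_error(fd_dataset(f, c(10, 20, 30), c(0.9, 1.2, 0.7)), "0, 1")
  expect_error(fd_dataset(f, c(10, 200, 30), c(0.9, 0.8, 0.7)), "phase_deg")
})

test_that("single exponentials sit on the universal circle", {
  for (tau in c(0.5, 3.6, 8.6, 17.2)) {
    for (f in c(1e7, 5e7, 2e8)) {
      r <- fd_response(species_mixture(1, tau), f)
      ph <- phasor_coordinates(r$phase_deg, r$mod_ratio)
      expect_lt(abs((ph$g - 0.5)^2 + ph$s^2 - 0.25), 1e-12)
    }
  }
  # frozen point: tau = 17.2 ns at 10 MHz -> g = 1/(1+u^2), s = u/(1+u^2)
  u <- 2 * pi * 1e7 * 17.2e-9
  r <- fd_response(species_mixture(1, 17.2), 1e7)
  ph <- phasor_coordinates(r$phase_deg, r$mod_ratio)
  expect_equal(ph$g, 1 / (1 + u^2), tolerance = 1e-12)
  expect_equal(ph$s, u / (1 + u^2), tolerance = 1e-12)
  expect_equal(ph$g, 0.4613, tolerance = 1e-4)
  expect_equal(ph$s, 0.4985, tolerance = 1e-4)
})

test_that("phasors of distribution mixtures are collinear", {
  # mixing the apo-truth and cAMP-truth distributions at five fractions
  # must land on a straight chord: the computational counterpart of a
  # partial agonist's data falling on the apo-to-agonist line
  fe <- get_pair("Fe(phenM)3")
  apo <- species_from_distribution(make_two_state(40.9, 4.3, 29.5, 0.84, 0.12), fe)
  act <- species_from_distribution(make_two_state(40.9, 4.3, 29.5, 0.84, 1), fe)
  for (f in c(1e7, 5e7)) {
    pts <- t(vapply(c(0, 0.25, 0.5, 0.75, 1), function(lam) {
      m <- species_mixture(c((1 - lam) * apo$amplitudes, lam * act$amplitudes),
                           c(apo$lifetimes, act$lifetimes))
      r <- fd_response(m, f)
      unlist(phasor_coordinates(r$phase_deg, r$mod_ratio))
    }, c(g = 0, s = 0)))
    v <- pts[5, ] - pts[1, ]
    for (i in 2:4) {
      u <- pts[i, ] - pts[1, ]
      expect_lt(abs(u[1] * v[2] - u[2] * v[1]), 1e-9)  # cross product
    }
  }
})
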