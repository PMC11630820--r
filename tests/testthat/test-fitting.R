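test_that("chi-square matches a brute-force re-summation", {
  set.seed(77)
  ds <- lapply(1:3, function(i) {
    f <- sort(stats::runif(6, 1e7, 2e8))
    fd_dataset(f, stats::runif(6, 10, 80), stats::runif(6, 0.1, 0.9),
               replicate_id = paste0("r", i),
               phase_sd = if (i == 2) rep(0.3, 6) else NULL)
  })
  pr <- lapply(ds, function(d)
    list(phase_deg = d$phase_deg + stats::rnorm(6),
         mod_ratio = d$mod_ratio + stats::rnorm(6, 0, 0.01)))
  w <- fd_weights()
  brute <- 0
  for (i in 1:3) for (j in 1:6) {
    sp <- if (i == 2) 0.3 else w$phase
    brute <- brute +
      ((ds[[i]]$phase_deg[j] - pr[[i]]$phase_deg[j]) / sp)^2 +
      ((ds[[i]]$mod_ratio[j] - pr[[i]]$mod_ratio[j]) / w$mod)^2
  }
  expect_lt(abs(chi_squared(ds, pr, w) - brute), 1e-12)
  # exact predictions give zero; one observation off by 1 sigma adds 1
  exact <- lapply(ds, function(d) d[c("phase_deg", "mod_ratio")])
  expect_equal(chi_squared(ds, exact, w), 0)
  off <- exact
  off[[1]]$phase_deg[1] <- off[[1]]$phase_deg[1] + w$phase
  expect_equal(chi_squared(ds, off, w), 1)
  expect_error(chi_squared(ds[1:2], exact), "equal length")
})

test_that("single-Gaussian fit recovers noise-free truth", {
  fe <- get_pair("Fe(phenM)3")
  ds <- predict_dataset(make_single(39.6, 4), fe, condition = "apo")
  ft <- fit_single_gaussian(ds, fe,
                            fixed = list(f_donor_only = 0, f_background = 0,
                                         t0 = 0))
  expect_true(ft$converged)
  expect_lt(abs(coef(ft)[["rbar"]] - 39.6), 1e-3)
  expect_lt(abs(coef(ft)[["sigma"]] - 4), 1e-3)
})

test_that("single-Gaussian fit recovers the mean from noisy data", {
  fe <- get_pair("Fe(phenM)3")
  nu <- nuisance_params(0.1, 0.02, 0, 0.2)
  clean <- predict_dataset(make_single(39.6, 4), fe, nu, condition = "apo")
  # four-replicate average halves the single-measurement noise
  ds <- withr::with_seed(5, fd_dataset(
    clean$frequencies,
    clean$phase_deg + stats::rnorm(14, 0, 0.1),
    pmin(clean$mod_ratio + stats::rnorm(14, 0, 0.002), 1)))
  ft <- fit_single_gaussian(ds, fe)
  expect_true(ft$converged)
  expect_lt(abs(coef(ft)[["rbar"]] - 39.6), 0.5)
})

test_that("donor-only data leave the Gaussian unidentifiable, flagged", {
  ds <- generate_donor_only(seed = 3)
  ft <- fit_single_gaussian(ds, get_pair("Fe(phenM)3"))
  p <- ft$parameters
  hit <- p$at_bound[p$name %in% c("rbar", "sigma", "f_donor_only")]
  expect_true(any(hit))
})

test_that("global fit recovers noise-free six-dataset truth exactly", {
  st <- noise_free_study(seed = 7)
  ft <- fit_global_two_gaussian(st$datasets, n_starts = 4)
  expect_true(ft$converged)
  p <- coef(ft)
  expect_lt(abs(p[["r1"]] - 40.9), 1e-2)
  expect_lt(abs(p[["sigma1"]] - 4.3), 1e-2)
  expect_lt(abs(p[["r2"]] - 29.5), 1e-2)
  expect_lt(abs(p[["sigma2"]] - 0.84), 1e-2)
  a2 <- fit_A2(ft)
  expect_lt(max(abs(a2[c("apo", "cAMP", "cGMP")] -
                      truth_pars$A2[c("apo", "cAMP", "cGMP")])), 1e-2)
  # drawn nuisance values are recovered too
  tr <- st$truth$per_dataset
  for (i in seq_len(nrow(tr))) {
    expect_lt(abs(p[[sprintf("t0[%s]", tr$dataset[i])]] - tr$t0[i]), 1e-2)
  }
})

test_that("forcing A2 = 0 on two-state truth strictly worsens chi-square", {
  st <- noise_free_study(seed = 7)
  free <- fit_global_two_gaussian(st$datasets, n_starts = 1)
  null <- fit_global_two_gaussian(st$datasets, n_starts = 1,
                                  fixed = list(A2 = 0))
  expect_gt(null$chi2, free$chi2 + 1)
})

test_that("dataset order does not change the fitted values", {
  st <- noise_free_study(seed = 13)
  f1 <- fit_global_two_gaussian(st$datasets, n_starts = 1)
  f2 <- fit_global_two_gaussian(rev(st$datasets), n_starts = 1)
  p1 <- coef(f1); p2 <- coef(f2)[names(coef(f1))]
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("global fit with A2 pinned at 0 reproduces the single fit", {
  fe <- get_pair("Fe(phenM)3")
  clean <- predict_dataset(make_single(38, 4.5), fe,
                           nuisance_params(0.08, 0, 0, 0.1),
                           condition = "apo")
  ds <- withr::with_seed(9, fd_dataset(
    clean$frequencies, clean$phase_deg + stats::rnorm(14, 0, 0.2),
    pmin(clean$mod_ratio + stats::rnorm(14, 0, 0.004), 1),
    condition = "apo"))
  fs <- fit_single_gaussian(ds, fe)
  cs <- coef(fs)
  suppressWarnings(
    fg <- fit_global_two_gaussian(
      list(ds),
      init = list("r1" = cs[["rbar"]], "sigma1" = cs[["sigma"]],
                  "f_donor_only" = cs[["f_donor_only"]],
                  "f_background" = cs[["f_background"]],
                  "t0" = cs[["t0"]]),
      fixed = list(A2 = 0, r2 = 25, sigma2 = 2)))
  expect_lt(abs(fg$chi2 - fs$chi2), 1e-6)
})

test_that("parameter recovery has low bias across 20 seeded studies", {
  # systematic bias (median signed error) of the shared means and A2
  # fractions must be small at realistic noise
  est <- recovery_estimates()
  expect_lt(abs(stats::median(est$r1 - 40.9)), 0.2)
  expect_lt(abs(stats::median(est$r2 - 29.5)), 0.2)
  expect_lt(abs(stats::median(est$A2_apo - 0.12)), 0.02)
  expect_lt(abs(stats::median(est$A2_cGMP - 0.34)), 0.02)
})

test_that("chi-square profile resolves the short-distance mean", {
  st <- noise_free_study(seed = 21)
  grid <- seq(28.75, 30.25, by = 0.25)
  sc <- profile_parameter(st$datasets, param = "r2", grid = grid)
  expect_s3_class(sc, "profile_scan")
  expect_false(any(is.na(sc$chi2)))
  # minimum at the generating value (29.5) within grid resolution
  expect_equal(sc$value[which.min(sc$chi2)], 29.5)
  # interior minimum: both endpoints are worse
  expect_gt(sc$chi2[1], min(sc$chi2))
  expect_gt(sc$chi2[length(grid)], min(sc$chi2))
})

test_that("profiling a fixed parameter is rejected", {
  st <- noise_free_study(seed = 21)
  expect_error(profile_parameter(st$datasets, param = "sigma2",
                                 grid = c(0.5, 1), fixed = list(sigma2 = 0.84)),
               "fixed")
  expect_error(profile_parameter(st$datasets, param = "no_such",
                                 grid = c(1, 2)), "unknown")
})

test_that("global fit demands resolvable acceptors and warns on 1 condition", {
  st <- noise_free_study(seed = 7)
  ds <- st$datasets[[1]]
  bad <- fd_dataset(ds$frequencies, ds$phase_deg, ds$mod_ratio,
                    acceptor = "unregistered")
  expect_error(fit_global_two_gaussian(list(bad, st$datasets[[2]])),
               "not found")
  expect_warning(fit_global_two_gaussian(list(ds), n_starts = 1,
                                         fixed = list(A2 = 0.12)),
                 "weakly identified")
})

test_that("donor-only single-exponential fit recovers the lifetime", {
  ds <- generate_donor_only(tau_D = 17.2, t0 = 0.2, seed = 8)
  ft <- fit_donor_only(ds)
  expect_true(ft$converged)
  expect_lt(abs(ft$tau - 17.2), 0.1)
  expect_lt(abs(ft$t0 - 0.2), 0.1)
})
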