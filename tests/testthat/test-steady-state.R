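test_that("baseline normalization is exact and scale invariant", {
  tc <- timecourse(seq(0, 200, 10), rep(500, 21),
                   events = data.frame(time = 100, label = "acceptor"))
  n <- normalize_course(tc, c(0, 90))
  expect_equal(n$intensity, rep(1, 21))
  tc2 <- timecourse(tc$time, tc$intensity * 7.3, tc$events)
  expect_equal(normalize_course(tc2, c(0, 90))$intensity, n$intensity)
  expect_error(normalize_course(tc, c(0, 150)), "precede")
  expect_error(normalize_course(tc, c(300, 400)), "precede|no samples")
})

test_that("efficiency follows E = 1 - Fcys/Fnocys on plateau windows", {
  tcs <- generate_timecourses(E_acceptor = 0.45, tau_kin = 0,
                              event_times = c(acceptor = 100,
                                              nucleotide = 300, tcep = 500))
  # identical courses give zero
  e0 <- fret_efficiency(tcs$nocys, tcs$nocys, c(150, 280))
  expect_equal(e0$E, 0)
  e <- fret_efficiency(tcs$cys, tcs$nocys, c(150, 280), condition = "apo")
  expect_equal(e$E, 0.45)
  # window straddling an event is rejected
  expect_error(fret_efficiency(tcs$cys, tcs$nocys, c(250, 350)), "overlaps")
  # nonspecific quench of the control cancels in the ratio:
  # nocys at 0.90, cys at 0.495 -> E = 1 - 0.495/0.90 = 0.45
  tcq <- generate_timecourses(E_acceptor = 0.45, nonspecific = 0.1,
                              tau_kin = 0)
  eq <- fret_efficiency(tcq$cys, tcq$nocys, c(150, 280))
  expect_equal(eq$E, 0.45, tolerance = 1e-12)
})

test_that("unlabeled-fraction correction inverts population mixing", {
  expect_equal(correct_unlabeled(0.45, 0), 0.45)
  expect_equal(correct_unlabeled(0.45, 0.10), 0.5)
  expect_error(correct_unlabeled(0.95, 0.10), "reaches 1")
  expect_error(correct_unlabeled(0.4, 1))
  # exact inverse of mixing a zero-efficiency population
  for (E_true in c(0.2, 0.5, 0.89)) for (f in c(0.05, 0.1, 0.3)) {
    E_obs <- (1 - f) * E_true + f * 0
    expect_equal(correct_unlabeled(E_obs, f), E_true, tolerance = 1e-12)
  }
})

test_that("weighted-average distances come from the inverse Forster law", {
  expect_equal(weighted_avg_distance(0.5, get_pair("Fe(phenM)3")), 41.8)
  expect_equal(weighted_avg_distance(0.8900289, get_pair("Fe(phenM)3")),
               29.5, tolerance = 1e-5)
  expect_equal(weighted_avg_distance(0.30, get_pair("Cu(TETAC)")),
               15.6 * (0.7 / 0.3)^(1 / 6), tolerance = 1e-12)
  expect_equal(weighted_avg_distance(0.30, get_pair("Cu(TETAC)")),
               17.966, tolerance = 1e-3)
})

test_that("dose-response assembly normalizes and fits the Hill equation", {
  conc <- 10^seq(-2, 2, length.out = 9)
  dE <- 0.3 * hill_eval(conc, 0.14, 1)
  dr <- dose_response(conc, dE, fix_h = 1)
  # normalizing to the top observed plateau (0.9986 of the asymptote at
  # the highest concentration) compresses the curve by the same factor
  expect_lt(abs(dr$fit$K_half - 0.14), 1e-3)
  expect_equal(max(dr$normalized), 1)
  # normalized response at K_half is ~0.5 when the top is saturated
  near_K <- hill_eval(0.14, dr$fit$K_half, 1) / hill_eval(max(conc), dr$fit$K_half, 1)
  expect_equal(near_K, 0.5, tolerance = 1e-2)
  expect_error(dose_response(conc, rep(0.2, 9)), "dynamic range")
  expect_error(dose_response(conc[1:2], dE[1:2]), "3 concentrations")
})

test_that("TCEP reversal returns the course to the control level", {
  tcs <- generate_timecourses(E_acceptor = 0.45, E_nucleotide = 0.6,
                              nonspecific = 0.05, tau_kin = 0,
                              event_times = c(acceptor = 100,
                                              nucleotide = 300, tcep = 500))
  expect_true(check_reversal(tcs$cys, tcs$nocys, c(550, 700)))
  # before reversal the course is far from the control
  expect_false(check_reversal(tcs$cys, tcs$nocys, c(350, 450)))
})
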