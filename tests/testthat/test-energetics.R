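test_that("delta G reproduces the four-state worked values at 298 K", {
  # A2 = 0.12 -> about +1.2 kcal/mol
  dg_apo <- delta_G(0.12)
  expect_false(fe_bound(dg_apo))
  expect_equal(round(fe_value(dg_apo), 1), 1.2)
  expect_equal(fe_value(dg_apo), -R_KCAL * 298 * log(0.12 / 0.88))
  # saturated fit (A2 = 1) floored at 0.01 resting: bound at -2.7
  dg_camp <- delta_G(1)
  expect_true(fe_bound(dg_camp))
  expect_equal(round(fe_value(dg_camp), 1), -2.7)
  # symmetric state
  expect_equal(fe_value(delta_G(0.5)), 0)
  # P_active = 0: +Inf with bound flag
  expect_true(is.infinite(fe_value(delta_G(0))))
  expect_true(fe_bound(delta_G(0)))
  expect_error(delta_G(1.2))
})

test_that("coupling energies are exact differences with flag propagation", {
  dd_camp <- delta_delta_G(delta_G(1), delta_G(0.12))
  expect_true(fe_bound(dd_camp))
  expect_equal(round(fe_value(dd_camp), 1), -3.9)
  # printed high-salt values: 0.38 - 1.2
  expect_equal(fe_value(delta_delta_G(0.38, 1.2)), -0.82)
  expect_false(fe_bound(delta_delta_G(0.38, 1.2)))
  expect_equal(fe_value(delta_delta_G(0.7, 0.7)), 0)
  # ionic-strength second difference: -0.47 - (-0.82)
  expect_equal(fe_value(delta3_G(-0.47, -0.82)), 0.35)
  expect_equal(fe_value(delta3_G(-0.5, -0.5)), 0)
  expect_gt(fe_value(delta3_G(-0.47, -0.82)), 0)  # less favorable at low salt
})

test_that("delta G is antisymmetric and inverts through the logistic", {
  for (p in c(0.02, 0.12, 0.34, 0.5, 0.77, 0.95)) {
    expect_equal(fe_value(delta_G(p)), -fe_value(delta_G(1 - p)),
                 tolerance = 1e-12)
    expect_equal(p_active_from_dG(delta_G(p)), p, tolerance = 1e-12)
  }
})

test_that("state energetics table wires A2 through to delta delta G", {
  tab <- state_energetics(c(apo = 0.12, cAMP = 1, cGMP = 0.34))
  expect_equal(tab$condition, c("apo", "cAMP", "cGMP"))
  expect_true(tab$dG_bound[2])
  expect_false(any(tab$dG_bound[c(1, 3)]))
  expect_equal(tab$ddG[3],
               fe_value(delta_G(0.34)) - fe_value(delta_G(0.12)))
  expect_true(is.na(tab$ddG[1]))
})

test_that("Hill evaluation and fitting behave as dose-response theory", {
  expect_equal(hill_eval(0.25, 0.25, 1.7), 0.5)  # half-max at K
  expect_error(hill_eval(-1, 0.25, 1))
  # noise-free self-consistency at the steady-state truth
  conc <- 10^seq(-2, 1, length.out = 8)
  f <- hill_fit(conc, hill_eval(conc, 0.25, 1.2))
  expect_lt(abs(f$K_half - 0.25), 1e-6)
  expect_lt(abs(f$h - 1.2), 1e-6)
  # electrophysiology-style truth with a steep slope
  f2 <- hill_fit(conc, hill_eval(conc, 0.27, 2.9))
  expect_lt(abs(f2$K_half - 0.27), 1e-6)
  expect_lt(abs(f2$h - 2.9), 1e-6)
  # fixed-slope mode
  f3 <- hill_fit(conc, hill_eval(conc, 0.14, 1), fix_h = 1)
  expect_true(f3$h_fixed)
  expect_lt(abs(f3$K_half - 0.14), 1e-8)
  expect_error(hill_fit(c(0.1, 1), c(0.2, 0.8)), "3 points")
  expect_error(hill_fit(conc, rep(0.5, 8)), "dynamic range")
})

test_that("aggregation reports mean, SEM and Student's t comparisons", {
  agg <- aggregate_energetics(c(1.1, 1.2, 1.3, 1.1, 1.1, 1.1),
                              rep(c("a", "b"), each = 3))
  sa <- agg$summary[agg$summary$group == "a", ]
  expect_equal(sa$mean, 1.2)
  expect_equal(sa$sem, 0.1 / sqrt(3), tolerance = 1e-10)
  sb <- agg$summary[agg$summary$group == "b", ]
  expect_equal(sb$sem, 0)  # identical replicates
  # identical groups compare with t = 0, p = 1
  agg2 <- aggregate_energetics(c(1, 2, 3, 1, 2, 3),
                               rep(c("a", "b"), each = 3))
  expect_equal(agg2$comparisons$t, 0)
  expect_equal(agg2$comparisons$p, 1, tolerance = 1e-12)
  # singleton group: SEM undefined and flagged
  agg3 <- aggregate_energetics(c(1, 2, 3, 9), c("a", "a", "a", "b"))
  expect_true(is.na(agg3$summary$sem[agg3$summary$group == "b"]))
  expect_false(agg3$summary$sem_defined[agg3$summary$group == "b"])
})
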