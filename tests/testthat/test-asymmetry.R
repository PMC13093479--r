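# shared fixture: a symmetric double well in the H-transfer regime
asym_profile <- function() {
  profile_from_function(quartic_double_well(1172, 40), -88, 88, by = 0.1,
                        symmetric = TRUE)
}

test_that("tilting adds a linear term and records the minima offset", {
  pr <- asym_profile()
  t0 <- tilt_potential(pr, 0)
  expect_equal(t0$v, pr$v)
  expect_equal(attr(t0, "delta_e0_half_cm1"), 0, tolerance = 1e-8)

  tp <- tilt_potential(pr, 0.4)
  tm <- tilt_potential(pr, -0.4)
  # sign flip mirrors the profile
  expect_equal(tp$v, rev(tm$v), tolerance = 1e-14)
  # for a small tilt the half offset is close to alpha * a
  expect_equal(attr(tp, "delta_e0_half_cm1"), 0.4 * 40, tolerance = 0.05)
  # an absurd tilt removes one well
  expect_error(tilt_potential(pr, 500), "removes one of the wells")
})

test_that("zero-order levels reduce correctly in symmetric and deep-well limits", {
  pr <- asym_profile()
  zl <- zero_order_levels(pr, "left")
  zr <- zero_order_levels(pr, "right")
  expect_equal(zl$energies_cm1[1] + hartree2cm(zl$e_ref),
               zr$energies_cm1[1] + hartree2cm(zr$e_ref),
               tolerance = 1e-6)

  # deep well: the zero-order ground level approaches the harmonic ZPE of
  # the well curvature (8 V_b / a^2 for the quartic)
  deep <- profile_from_function(quartic_double_well(25000, 60), -130, 130,
                                by = 0.2, symmetric = TRUE)
  zd <- zero_order_levels(deep, "left", n_points = 1001)
  w_well <- sqrt(8 * cm2hartree(25000) / 60^2)
  expect_equal(zd$energies_cm1[1], hartree2cm(w_well / 2), tolerance = 0.02)

  # small tilt: the zero-order detuning tracks the minima offset
  tp <- tilt_potential(pr, 0.2)
  zl <- zero_order_levels(tp, "left")
  zr <- zero_order_levels(tp, "right")
  d2 <- (zr$energies_cm1[1] + hartree2cm(zr$e_ref)) -
        (zl$energies_cm1[1] + hartree2cm(zl$e_ref))
  expect_equal(d2, 2 * attr(tp, "delta_e0_half_cm1"), tolerance = 0.4)
})

test_that("the two-level forms agree with the 2x2 eigenproblem and invert each other", {
  expect_equal(two_level_splitting(3, 4), 10)
  expect_equal(two_level_splitting(0, 7.5), 15)
  expect_equal(two_level_coupling(10, 3), 4)
  expect_error(two_level_coupling(5, 3), "no real tunneling")
  set.seed(3)
  for (i in 1:10) {
    d <- runif(1, 0, 5); hw <- runif(1, 0, 5)
    m <- rbind(c(d, hw), c(hw, -d))
    gap <- diff(range(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
    expect_equal(two_level_splitting(d, hw), gap, tolerance = 1e-12)
    expect_equal(two_level_coupling(two_level_splitting(d, hw), d), hw,
                 tolerance = 1e-12)
  }
})

test_that("a resonance scan follows the two-level model and tracks the state diabatically", {
  pr <- asym_profile()
  sc <- resonance_scan(pr, c(0, 0.15, 0.35, 0.7, 1.2), n_points = 401)
  hw0 <- attr(sc, "hbar_omega0_cm1")
  expect_gt(hw0, 0)
  # at resonance both wells are equally occupied
  expect_equal(sc$p_original[1], 0.5, tolerance = 0.01)
  # the no-tunneling gap is a lower bound on the observed splitting
  expect_true(all(sc$delta_dvr >= sc$delta_no_tunneling - 1e-3))
  # two-level prediction from the symmetric coupling
  pred <- two_level_splitting(sc$d, hw0)
  expect_lt(max(abs(sc$delta_dvr - pred) / sc$delta_dvr), 0.02)
  # the tracked state keeps localizing in the original well as |d| grows
  expect_true(all(diff(sc$p_original) > -1e-6))
  expect_gt(sc$p_original[nrow(sc)], 0.95)
})

test_that("isotope substitution splits the wells through mass weighting alone", {
  pes <- oho_chain_pes()
  res <- isotope_asymmetry(pes, pes$system,
                           variant_masses = c(15.9949, 1.00783, 17.9992) *
                             amu_to_me,
                           step = 0.1)
  # identical masses reduce to the symmetric result
  same <- isotope_asymmetry(pes, pes$system,
                            variant_masses = pes$system$masses, step = 0.1)
  expect_equal(same$variant$delta_cm1, same$symmetric$delta_cm1)

  # asymmetry separates the levels
  expect_gt(res$variant$delta_cm1, res$symmetric$delta_cm1)
  dec <- res$decomposition
  expect_gt(dec$d_cm1, 0)
  # the inferred coupling stays at the symmetric half-splitting scale
  expect_lte(dec$hbar_omega_cm1, 1.05 * res$symmetric$delta_cm1 / 2)
  expect_gt(dec$hbar_omega_cm1, 0)
})
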