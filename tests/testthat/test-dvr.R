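test_that("spline interpolation is exact at knots and on polynomials, and guards its range", {
  q <- seq(-5, 5, by = 0.5)
  pr <- list(q = q, v = 2e-3 * q^2)
  f <- spline_profile(pr)
  expect_equal(f(q), pr$v, tolerance = 1e-15)
  mid <- q[-1] - 0.25
  expect_lt(max(abs(f(mid) - 2e-3 * mid^2)), 1e-12)
  expect_error(f(5.2), "outside the tabulated range")
  expect_error(f(-6), "outside the tabulated range")
  expect_error(spline_profile(list(q = c(0, 1, 1, 2), v = rep(0, 4))),
               "duplicate")
  expect_error(spline_profile(list(q = 0:2, v = rep(0, 3))), "at least 4")
})

test_that("sinc-DVR reproduces harmonic oscillator levels", {
  w <- 0.01
  lt <- sinc_dvr_1d(function(q) 0.5 * w^2 * q^2, domain = c(-65, 65),
                    n_points = 513, n_states = 8)
  expect_true(lt$converged)
  expect_lt(max(abs(lt$energies_hartree - w * (0:7 + 0.5))), 1e-9)
  # wavefunction norms are unity in the DVR sense
  expect_equal(colSums(lt$wavefunctions^2), rep(1, 8), tolerance = 1e-10)
})

test_that("quartic-well splitting agrees with an independent finite-difference oracle", {
  f <- quartic_double_well(hartree2cm(0.005), 30)
  dom <- c(-75, 75)
  lt <- sinc_dvr_1d(f, domain = dom, n_points = 301,
                    check_convergence = FALSE, n_states = 2)
  e_fd <- fd_lowest(f, dom, 3001, k = 2)
  d_sinc <- lt$energies_hartree[2] - lt$energies_hartree[1]
  d_fd <- e_fd[2] - e_fd[1]
  expect_lt(abs(d_sinc - d_fd) / d_sinc, 1e-5)
  # heavier effective mass tunnels less
  lt2 <- sinc_dvr_1d(f, domain = dom, n_points = 301, effective_mass = 2,
                     check_convergence = FALSE, n_states = 2)
  expect_lt(lt2$energies_cm1[2] - lt2$energies_cm1[1],
            lt$energies_cm1[2] - lt$energies_cm1[1])
})

test_that("the convergence doubling check flags under-resolved grids", {
  f <- quartic_double_well(3000, 20)
  expect_warning(sinc_dvr_1d(f, domain = c(-45, 45), n_points = 64,
                             n_states = 8),
                 "not converged")
  expect_error(sinc_dvr_1d(function(q) 1e-4 * q, domain = c(0, 10),
                           n_points = 64, check_convergence = FALSE),
               "minimum in its interior")
})

test_that("2d direct-product DVR is separable and consistent with 1d", {
  v1 <- profile_from_function(quartic_double_well(1172, 25), -45, 45, by = 1)
  w2h <- cm2hartree(1200)
  v2 <- profile_from_function(function(p) 0.5 * w2h^2 * p^2, -32, 32, by = 1)
  surf <- structure(list(q_im = v1$q, q1 = v2$q,
                         v = outer(v1$v, v2$v, `+`), e_ts = 0),
                    class = "surface_grid_2d")
  lt2 <- dvr_2d(surf, n_points = c(64, 64), n_states = 13)
  e1 <- sinc_dvr_1d(v1, n_points = 64, check_convergence = FALSE,
                    n_states = 13)
  e2 <- sinc_dvr_1d(v2, n_points = 64, check_convergence = FALSE,
                    n_states = 13)
  sums <- sort(as.numeric(outer(e1$energies_hartree + e1$e_ref,
                                e2$energies_hartree + e2$e_ref, `+`)))
  got <- lt2$energies_hartree + lt2$e_ref
  expect_lt(max(abs(got[1:13] - sums[1:13])), 1e-8)

  # zero-coupling: the 2d ground splitting equals the 1d one
  d1 <- e1$energies_cm1[2] - e1$energies_cm1[1]
  d2 <- lt2$energies_cm1[2] - lt2$energies_cm1[1]
  expect_lt(abs(d1 - d2), 0.01)

  # assignments match the by-construction product ordering
  ord <- order(as.numeric(outer(e1$energies_hartree, e2$energies_hartree,
                                `+`)))
  lab <- expand.grid(n_im = 0:12, n_1 = 0:12)[ord[1:13], ]
  asn <- assign_levels(lt2, 1:13)
  expect_equal(asn$n_im, lab$n_im)
  expect_equal(asn$n_1, lab$n_1)
  expect_false(any(asn$ambiguous))

  # memory guard
  expect_error(dvr_2d(surf, n_points = c(200, 200)), "max_basis")
})

test_that("2d DVR reproduces a separable harmonic bowl", {
  wa <- cm2hartree(1600); wb <- cm2hartree(2200)
  qk <- seq(-48, 48, by = 1); pk <- seq(-40, 40, by = 1)
  surf <- structure(list(q_im = qk, q1 = pk,
                         v = outer(0.5 * wa^2 * qk^2, 0.5 * wb^2 * pk^2, `+`),
                         e_ts = 0),
                    class = "surface_grid_2d")
  lt <- dvr_2d(surf, n_points = c(64, 64), n_states = 3)
  exact <- sort(as.numeric(outer(wa * (0:3 + 0.5), wb * (0:3 + 0.5), `+`)))
  expect_lt(max(abs(lt$energies_cm1[1:3] - hartree2cm(exact[1:3]))), 0.05)
})

test_that("node counts, parity and splittings behave on a symmetric double well", {
  pr <- profile_from_function(quartic_double_well(1172, 30), -60, 60,
                              by = 0.1, symmetric = TRUE)
  lt <- sinc_dvr_1d(pr, n_points = 401, check_convergence = FALSE,
                    n_states = 8)
  asn <- assign_levels(lt, 1:6)
  expect_equal(asn$n_im, 0:5)
  expect_equal(asn$parity, rep(c("even", "odd"), 3))

  # a deeper well keeps several pairs under the barrier
  prd <- profile_from_function(quartic_double_well(5000, 45), -85, 85,
                               by = 0.1, symmetric = TRUE)
  ltd <- sinc_dvr_1d(prd, n_points = 501, check_convergence = FALSE,
                     n_states = 8)
  sp <- level_splittings(ltd)
  expect_gte(nrow(sp), 2L)
  expect_true(all(sp$delta_cm1 > 0))
  expect_gt(sp$delta_cm1[2], sp$delta_cm1[1])  # excited splittings grow
  expect_equal(sp$lower, c(1, 3, 5)[seq_len(nrow(sp))])

  # well probabilities: parity makes the ground state split evenly
  wp <- well_probabilities(lt, 1)
  expect_equal(unname(wp), c(0.5, 0.5), tolerance = 1e-6)
  expect_error(well_probabilities(lt, 1, divider = 100), "outside")

  # a strong tilt localizes the ground state
  tl <- tilt_potential(pr, 20)
  ltt <- sinc_dvr_1d(tl, n_points = 401, check_convergence = FALSE,
                     n_states = 2)
  wpt <- well_probabilities(ltt, 1)
  expect_gt(max(wpt), 0.99)
})

test_that("a single well is flagged as not a double well", {
  w <- cm2hartree(900)
  pr <- profile_from_function(function(q) 0.5 * w^2 * q^2, -40, 40, by = 0.5)
  lt <- sinc_dvr_1d(pr, n_points = 256, check_convergence = FALSE,
                    n_states = 4)
  expect_warning(sp <- level_splittings(lt), "not a double well")
  expect_equal(nrow(sp), 0L)
})

test_that("level tables export cleanly as CSV", {
  pr <- profile_from_function(quartic_double_well(1172, 30), -60, 60,
                              by = 0.1, symmetric = TRUE)
  lt <- sinc_dvr_1d(pr, n_points = 301, check_convergence = FALSE,
                    n_states = 4)
  f <- tempfile(fileext = ".csv")
  write_level_table(lt, f, n_states = 4)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 4L)
  expect_true(all(c("state", "e_cm1", "n_im", "parity", "p_left") %in%
                  names(df)))
  expect_equal(df$p_left + df$p_right, rep(1, 4), tolerance = 1e-6)
})
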