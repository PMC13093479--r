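test_that("constrained relaxation reproduces closed forms for coupled fixtures", {
  # bilinear coupling, relaxing along the Q0 axis explicitly:
  # min over Q1 of V_dw(q) + w^2 Q1^2/2 + b q Q1  =  V_dw(q) - b^2 q^2/(2 w^2)
  spec <- coupled_model_spec(1200, 30, 600, b_coup = 1.5e-6)
  pes <- coupled_model_pes(spec)
  ms <- make_mode_set(diag(2), c(-900, 600), pes$system)
  vdw <- quartic_double_well(1200, 30)
  w2 <- cm2hartree(600)^2
  for (q in c(-25, -10, 5, 18, 31)) {
    r <- relax_at_qim(pes, pes$system, ms, q)
    expect_equal(r$energy, vdw(q) - (1.5e-6 * q)^2 / (2 * w2),
                 tolerance = 1e-10)
  }

  # uncoupled: relaxed energy equals the raw slice
  spec0 <- coupled_model_spec(1200, 30, 600)
  pes0 <- coupled_model_pes(spec0)
  ms0 <- normal_mode_analysis(pes0$system, pes0$hessian(pes0$system$x))
  r0 <- relax_at_qim(pes0, pes0$system, ms0, 12)
  expect_equal(r0$energy, vdw(12), tolerance = 1e-12)

  # symmetric (Q0^2 Q1) coupling: compare against a dense 1d search oracle
  specc <- coupled_model_spec(1200, 30, 600, c_coup = 2.5e-8)
  pesc <- coupled_model_pes(specc)
  msc <- normal_mode_analysis(pesc$system, pesc$hessian(pesc$system$x))
  for (q in c(8, 22, 33)) {
    r <- relax_at_qim(pesc, pesc$system, msc, q)
    oracle <- stats::optimize(function(p) pesc$energy(c(q, p)),
                              c(-50, 50), tol = 1e-12)$objective
    expect_equal(r$energy, oracle, tolerance = 1e-8)
  }
})

test_that("mirrored half-path construction matches the fully computed profile", {
  pes <- coupled_model_pes(c_only_spec())
  ms <- normal_mode_analysis(pes$system, pes$hessian(pes$system$x))
  p_sym <- build_path(pes, pes$system, ms, symmetric = TRUE)
  p_full <- build_path(pes, pes$system, ms, symmetric = FALSE)
  expect_equal(p_sym$q, p_full$q)
  expect_lt(max(abs(p_sym$v - p_full$v)), 1e-10)
  # mirroring halves the number of relaxations (up to the spot checks)
  expect_lt(attr(p_sym, "n_relaxations"), 0.6 * attr(p_full, "n_relaxations"))
  expect_true(all(p_sym$provenance[p_sym$q < 0] == "mirrored"))
  expect_true(all(p_sym$provenance[p_sym$q >= 0] == "relaxed"))

  # stop rule: the march goes past the minima into the repulsive wall
  st <- qimpath:::profile_structure(p_sym)
  expect_gt(max(p_sym$q), st$q_right)
  expect_lt(min(p_sym$q), st$q_left)
  cap <- max(4 * profile_barrier_cm1(p_sym), 5000)
  expect_gte(hartree2cm(p_sym$v[length(p_sym$v)] - st$v_right), cap)

  # relaxation can only lower the energy relative to the raw slice
  im <- imaginary_mode(ms)
  s <- qimpath:::as_coords(pes$system)
  idx <- seq(1, length(p_sym$q), by = 100)
  raw <- vapply(p_sym$q[idx], function(q) {
    pes$energy(s$x + q * im$q_im / sqrt(s$m)) - p_sym$e_zero
  }, numeric(1))
  expect_true(all(p_sym$v[idx] <= raw + 1e-12))
})

test_that("claimed symmetry is verified, not trusted", {
  pes <- coupled_model_pes(c_only_spec())
  tilt <- 2e-5  # hartree per a.u. along Q0: breaks the symmetry
  pes_t <- pes_contract(
    energy = function(x) pes$energy(x) + tilt * x[1],
    gradient = function(x) { g <- pes$gradient(x); g[1] <- g[1] + tilt; g },
    hessian = pes$hessian)
  ms <- normal_mode_analysis(pes$system, pes_t$hessian(pes$system$x))
  expect_error(build_path(pes_t, pes$system, ms, symmetric = TRUE),
               "not symmetric")
})

test_that("harmonic wall extension matches its closed forms and a numeric optimizer", {
  sys3 <- model_system(numeric(3))
  w <- 5e-3
  qim <- c(1, 2, -2) / 3
  ext <- harmonic_wall_extension(sys3, diag(w^2, 3), qim, q_min = 10,
                                 delta_max = 5, step = 1, v_min = 0)
  expect_equal(ext$v, 0.5 * w^2 * (ext$q - 10)^2, tolerance = 1e-12)
  expect_true(all(ext$provenance == "harmonic_extension"))

  h <- diag(c(2e-5, 8e-5, 5e-5))
  ext2 <- harmonic_wall_extension(sys3, h, c(1, 0, 0), q_min = -8,
                                  delta_max = 4, step = 1, v_min = 0,
                                  direction = -1)
  expect_equal(ext2$v, 0.5 * 2e-5 * (ext2$q + 8)^2, tolerance = 1e-12)

  # dense SPD Hessian against an unconstrained optimizer in the complement
  set.seed(42)
  a <- matrix(rnorm(16), 4)
  h4 <- crossprod(a) * 1e-5 + diag(1e-5, 4)
  qim4 <- rnorm(4); qim4 <- qim4 / sqrt(sum(qim4^2))
  sys4 <- model_system(numeric(4))
  ext4 <- harmonic_wall_extension(sys4, h4, qim4, q_min = 0, delta_max = 3,
                                  step = 1, v_min = 0, direction = 1)
  nb <- qr.Q(qr(cbind(qim4, diag(4))))[, 2:4]  # basis orthogonal to qim4
  for (i in seq_along(ext4$q)) {
    delta <- ext4$q[i]
    obj <- function(y) {
      d <- delta * qim4 + as.numeric(nb %*% y)
      0.5 * sum(d * (h4 %*% d))
    }
    o <- stats::optim(numeric(3), obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 1000))
    expect_equal(ext4$v[i], o$value, tolerance = 1e-10)
  }

  # a non-positive-definite Hessian is rejected
  expect_error(harmonic_wall_extension(sys3, diag(c(-1e-5, 1e-5, 1e-5)),
                                       c(1, 0, 0), 5, 3, step = 1),
               "not positive definite")
})

test_that("path projection recovers the coordinate and flags degenerate paths", {
  sys <- model_system(numeric(3), masses = c(4, 1, 1))
  qim <- c(0.8, 0.36, -0.48)
  s <- seq(-6, 6, by = 0.5)
  geoms <- t(vapply(s, function(si) sys$x + si * qim / sqrt(sys$masses),
                    numeric(3)))
  en <- 1e-4 * s^2
  pr <- project_irc(geoms, en, sys, qim)
  expect_equal(pr$q, s, tolerance = 1e-12)
  expect_equal(pr$v, en, tolerance = 1e-14)
  expect_true(all(pr$provenance == "irc_projection"))

  # orthogonal path: every projection vanishes
  perp <- c(0.36, -0.8, 0) / sqrt(sys$masses)  # mass-weighted orthogonal
  perp_geoms <- t(vapply(s, function(si) sys$x + si * perp, numeric(3)))
  expect_error(project_irc(perp_geoms, en, sys, qim), "orthogonal")

  # scrambled path order: projection is not monotone along the path
  expect_warning(project_irc(geoms[c(3, 1, 2, 4:25), ], en[c(3, 1, 2, 4:25)],
                             sys, qim),
                 "not monotone")
})

test_that("the 2d relaxed surface is separable and consistent with the 1d path", {
  # two bath modes; mode 1 uncoupled (the Q1 axis of the scan), mode 2 with
  # symmetric coupling relaxed away
  spec <- coupled_model_spec(1200, 30, c(700, 1000),
                             c_coup = c(0, 2.0e-8))
  pes <- coupled_model_pes(spec)
  ms <- normal_mode_analysis(pes$system, pes$hessian(pes$system$x))
  w1 <- cm2hartree(700)
  qv <- seq(-40, 40, by = 4)
  pv <- seq(-12, 12, by = 4)
  surf <- build_surface_2d(pes, pes$system, ms, q_im_values = qv,
                           q1_index = 1, q1_values = pv)
  j0 <- which(surf$q1 == 0)
  # separability in the uncoupled mode
  sep <- outer(surf$v[, j0], 0.5 * w1^2 * pv^2, `+`)
  expect_lt(max(abs(surf$v - sep)), 1e-10)
  # the q1 = 0 row equals the closed-form relaxed path (and hence build_path)
  expect_equal(surf$v[, j0], pes$relaxed(qv) - pes$relaxed(0),
               tolerance = 1e-9)
  # pointwise brute-force oracle over the remaining mode
  for (k in c(3, 11, 17)) {
    oracle <- stats::optimize(function(z) pes$energy(c(qv[k], 4, z)),
                              c(-60, 60), tol = 1e-12)$objective
    expect_equal(surf$v[k, which(pv == 4)], oracle - surf$e_ts,
                 tolerance = 1e-8)
  }
  expect_error(build_surface_2d(pes, pes$system, ms, qv, q1_index = 9, pv),
               "real TS mode")
})

test_that("profile and surface files round-trip losslessly", {
  pr <- qim_profile(seq(-2, 2, by = 0.5), sin(seq(-2, 2, by = 0.5)) * 1e-3,
                    provenance = "relaxed", zero = "ts", e_zero = -1.23456789,
                    symmetric = TRUE)
  f <- tempfile()
  write_profile(pr, f)
  pr2 <- read_profile(f)
  expect_identical(pr2$q, pr$q)
  expect_identical(pr2$v, pr$v)
  expect_identical(pr2$symmetric, TRUE)
  expect_equal(pr2$e_zero, pr$e_zero)

  surf <- structure(list(q_im = c(-1, 0, 1.5), q1 = c(0, 2),
                         v = matrix(rnorm(6) * 1e-3, 3, 2), e_ts = 0.5),
                    class = "surface_grid_2d")
  fs <- tempfile()
  write_surface(surf, fs)
  s2 <- read_surface(fs)
  expect_identical(s2$v, surf$v)
  expect_identical(s2$q_im, surf$q_im)
  expect_equal(s2$e_ts, surf$e_ts)
})
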