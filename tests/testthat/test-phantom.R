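test_that("uniform phantom matches its closed-form kinetic energy", {
  g <- voxel_grid(20, 20, 20, dx = 2, nt = 3)
  u <- make_uniform(g, c(1, 0, 0))
  expect_equal(u$oracle$volume_ml, 64)
  # KE = 1/2 * 1025 kg/m^3 * 6.4e-5 m^3 * 1 (m/s)^2 = 32.8 mJ
  expect_equal(kinetic_energy(u$field, u$mask), rep(32.8, 3),
               tolerance = 1e-10)
  expect_equal(energy_loss_rate(u$field, u$mask), rep(0, 3))
  expect_equal(vorticity_vol(u$field, u$mask), rep(0, 3))
  z <- make_uniform(g, c(0, 0, 0))
  expect_equal(kinetic_energy(z$field, z$mask), rep(0, 3))
})

test_that("rigid-rotation phantom: vorticity_vol = 2*Omega*V, EL = 0", {
  g <- voxel_grid(40, 40, 40, dx = 1.6, nt = 1)
  rr <- make_rigid_rotation(g, omega = 10)
  vv <- vorticity_vol(rr$field, rr$mask)
  expect_lt(abs(vv / (2 * 10 * rr$oracle$volume_ml) - 1), 0.03)
  # zero strain rate: EL negligible vs a Poiseuille reference on the grid
  po <- make_poiseuille(g, R_mm = 20, L_mm = 50, v_max = 1)
  el_ref <- energy_loss_rate(po$field, po$mask)
  expect_lt(energy_loss_rate(rr$field, rr$mask), 0.01 * el_ref)
  z <- make_rigid_rotation(g, omega = 0)
  expect_equal(max(abs(z$field$v)), 0)
})

test_that("Poiseuille phantom matches EL and KE closed forms", {
  g <- voxel_grid(64, 64, 64, dx = 24 / 64, dy = 24 / 64, dz = 52 / 64,
                  nt = 1)
  po <- make_poiseuille(g, R_mm = 10, L_mm = 50, v_max = 1)
  # EL = 2*pi*mu*L*v_max^2 = 2*pi*4e-3*0.05*1 W ~ 1.257 mW
  expect_equal(po$oracle$el_mW, 2 * pi * 4e-3 * 0.05 * 1e3)
  expect_lt(abs(energy_loss_rate(po$field, po$mask) / po$oracle$el_mW - 1),
            0.05)
  # KE = rho*v^2*V/6 = 1025*1*(pi*1e-4*0.05)/6 J ~ 2.68 mJ
  expect_equal(po$oracle$ke_mJ, 1025 * pi * 1e-4 * 0.05 / 6 * 1e3)
  expect_lt(abs(kinetic_energy(po$field, po$mask) / po$oracle$ke_mJ - 1),
            0.02)
  z <- make_poiseuille(g, R_mm = 10, L_mm = 50, v_max = 0)
  expect_equal(kinetic_energy(z$field, z$mask), 0)
  expect_equal(energy_loss_rate(z$field, z$mask), 0)
  expect_error(make_poiseuille(g, R_mm = 20, L_mm = 50, v_max = 1),
               "exceeds the grid")
})

test_that("Poiseuille EL error strictly decreases under grid refinement", {
  errs <- vapply(c(32, 64, 128), function(n) {
    g <- voxel_grid(n, n, n, dx = 24 / n, dy = 24 / n, dz = 52 / n, nt = 1)
    po <- make_poiseuille(g, R_mm = 10, L_mm = 50, v_max = 1)
    abs(energy_loss_rate(po$field, po$mask) / po$oracle$el_mW - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("Lamb-Oseen phantom: vorticity integrates to Gamma*L", {
  g <- voxel_grid(64, 64, 20, dx = 1, dy = 1, dz = 2, nt = 1)
  lo <- make_lamb_oseen(g, gamma = 0.01, r_c_mm = 6, L_mm = 36)
  expect_equal(lo$oracle$vortvol_mL_s, 0.01 * 0.036 * 1e6)
  # independent check: brute-force integral of the analytic omega_z
  co <- ((1:64) - 1) - 63 / 2
  r2 <- outer(co^2, co^2, `+`) * 1e-6           # m^2
  omega <- 0.01 / (pi * 0.006^2) * exp(-r2 / 0.006^2)
  slice_int <- sum(omega) * 1e-6 * 1e6          # (1/s)*m^2 -> mL/s per m... per slice of dz
  brute <- slice_int * 0.036                    # integrate over L = 36 mm
  expect_lt(abs(brute / lo$oracle$vortvol_mL_s - 1), 0.01)
  expect_lt(abs(vorticity_vol(lo$field, lo$mask) / lo$oracle$vortvol_mL_s
                - 1), 0.05)
  # peak vorticity at the core centre = Gamma / (pi r_c^2)
  grad <- velocity_gradient(lo$field, lo$mask, 1)
  wz <- grad[, , , 2, 1] - grad[, , , 1, 2]
  expect_lt(abs(max(wz) / (0.01 / (pi * 0.006^2)) - 1), 0.05)
  z <- make_lamb_oseen(g, gamma = 0, r_c_mm = 6, L_mm = 36)
  expect_equal(max(abs(z$field$v)), 0)
  expect_error(make_lamb_oseen(g, gamma = 0.01, r_c_mm = 12, L_mm = 36),
               "4 core radii")
})

test_that("beating ellipsoid mask has analytic per-phase volumes", {
  g <- voxel_grid(48, 48, 48, dx = 2, nt = 10)
  msk <- make_beating_ellipsoid_mask(g, semi_axes_ed = c(34, 34, 34),
                                     semi_axes_es = c(28, 28, 30),
                                     systole_frames = 1:4)
  vols <- volume_curve(msk)
  expect_equal(max(attr(msk, "volume_ml_analytic")),
               4 / 3 * pi * 0.034^3 * 1e6 * 1e-3 * 1e3)  # ~164.6 mL
  expect_true(all(abs(vols / attr(msk, "volume_ml_analytic") - 1) < 0.02))
  # ED = ES degenerates to a constant volume curve
  flat <- make_beating_ellipsoid_mask(g, c(30, 30, 30), c(30, 30, 30),
                                      systole_frames = 1:4)
  expect_equal(diff(range(volume_curve(flat))), 0)
})

test_that("add_noise is seed-reproducible and a no-op at sigma = 0", {
  g <- voxel_grid(10, 10, 10, dx = 2, nt = 2)
  u <- make_uniform(g, c(0.3, 0, 0))
  expect_identical(add_noise(u$field, 0), u$field)
  n1 <- add_noise(u$field, 0.05, seed = 11)
  n2 <- add_noise(u$field, 0.05, seed = 11)
  expect_identical(n1$v, n2$v)
  expect_false(identical(add_noise(u$field, 0.05, seed = 12)$v, n1$v))
  expect_error(add_noise(u$field, 0.05), "seed")
})

test_that("noise rectification biases KE by ~ 1/2*rho*V*3*sigma^2", {
  g <- voxel_grid(12, 12, 12, dx = 2, nt = 1)
  z <- make_uniform(g, c(0, 0, 0))
  sigma <- 0.1
  V <- z$oracle$volume_ml * 1e-6
  expected_mJ <- 0.5 * 1025 * V * 3 * sigma^2 * 1e3
  kes <- vapply(1:100, function(s)
    kinetic_energy(add_noise(z$field, sigma, seed = s), z$mask),
    numeric(1))
  expect_lt(abs(mean(kes) / expected_mJ - 1), 0.05)
})

test_that("simulated cohorts carry the planted correlation structure", {
  # slope 0: no association
  sp0 <- cohort_spec(n_subjects = 200, metrics = list(
    ke = list(rest_mean = 2, rest_sd = 0.5, slope = 0, intercept = 50,
              noise_sd = 20)), seed = 5)
  tab0 <- simulate_cohort(sp0)
  rel0 <- relative_difference(tab0$ke_rest, tab0$ke_stress)
  expect_lt(abs(cor(rel0, tab0$vo2max)), 0.3)
  # planted rho = -0.8 recovered within the Fisher-z band at n = 200
  sd_d <- 40; r <- -0.8
  spn <- cohort_spec(n_subjects = 200, metrics = list(
    ke = list(rest_mean = 2, rest_sd = 0.5, slope = r * sd_d / 8.6,
              intercept = 100 - r * sd_d / 8.6 * 30.2,
              noise_sd = sd_d * sqrt(1 - r^2))), seed = 9)
  tabn <- simulate_cohort(spn)
  reln <- relative_difference(tabn$ke_rest, tabn$ke_stress)
  expect_lt(abs(cor(reln, tabn$vo2max) - (-0.8)), 0.08)
  # zero noise: deterministic linearity
  spd <- cohort_spec(n_subjects = 50, metrics = list(
    ke = list(rest_mean = 2, rest_sd = 0.5, slope = -2, intercept = 120,
              noise_sd = 0)), seed = 3)
  tabd <- simulate_cohort(spd)
  reld <- relative_difference(tabd$ke_rest, tabd$ke_stress)
  expect_equal(abs(cor(reld, tabd$vo2max)), 1, tolerance = 1e-12)
})

test_that("cohort relative differences recompute exactly and runs are reproducible", {
  sp <- cohort_spec(seed = 21)
  a <- simulate_cohort(sp)
  b <- simulate_cohort(sp)
  expect_identical(a, b)
  for (m in c("ke", "el", "vort")) {
    rest <- a[[paste0(m, "_rest")]]
    expect_true(all(rest > 0))
    # stress = rest * (1 + delta/100) exactly, so delta recomputes exactly
    delta <- (a[[paste0(m, "_stress")]] / rest - 1) * 100
    expect_equal(a[[paste0(m, "_stress")]], rest * (1 + delta / 100),
                 tolerance = 0)
  }
  expect_error(cohort_spec(n_subjects = 2, seed = 1), "3 subjects")
  expect_error(cohort_spec(), "seed")
})

test_that("pulsatile scale factors modulate the phantom analytically", {
  g <- voxel_grid(16, 16, 16, dx = 2, nt = 4)
  s <- c(1, 0.5, 0.25, 0.75)
  u <- make_uniform(g, c(0.8, 0, 0), scales = s)
  ke <- kinetic_energy(u$field, u$mask)
  expect_equal(ke / ke[1], s^2, tolerance = 1e-12)
  expect_equal(u$oracle$ke_mJ, ke, tolerance = 1e-10)
})
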