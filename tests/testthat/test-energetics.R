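test_that("masked gradients are exact on linear fields", {
  g <- voxel_grid(12, 12, 12, dx = 2, nt = 1)
  a <- 3  # v_x = a * y  (y in metres)
  co <- ((1:12) - 1) * 2e-3
  v <- array(0, c(12, 12, 12, 1, 3))
  v[, , , 1, 1] <- aperm(array(a * co, c(12, 12, 12)), c(2, 1, 3))
  f <- velocity_field(g, v, venc = 10)
  m <- segmentation_mask(g, array(1L, c(12, 12, 12, 1)))
  grad <- velocity_gradient(f, m, 1)
  expect_equal(max(abs(grad[, , , 1, 2] - a)), 0, tolerance = 1e-12)
  expect_equal(max(abs(grad[, , , 1, 1])), 0)
  expect_equal(max(abs(grad[, , , 2, ])), 0)
  # constant field: zero tensor
  u <- make_uniform(g, c(0.7, -0.2, 0.1))
  gz <- velocity_gradient(u$field, u$mask, 1)
  expect_equal(max(abs(gz)), 0)
})

test_that("Poiseuille wall shear approaches 2*v_max/R", {
  n <- 64
  g <- voxel_grid(n, n, n, dx = 24 / n, dy = 24 / n, dz = 52 / n, nt = 1)
  po <- make_poiseuille(g, R_mm = 10, L_mm = 50, v_max = 1)
  grad <- velocity_gradient(po$field, po$mask, 1)
  max_shear <- max(abs(grad[, , , 3, 1:2]))
  expect_lt(abs(max_shear / (2 * 1 / 0.010) - 1), 0.05)
})

test_that("KE, EL and vorticity obey the scaling homogeneities", {
  rf <- random_field_and_mask(n = 8, nt = 2, seed = 4)
  f2 <- rf$field; f2$v <- 2 * f2$v
  expect_equal(kinetic_energy(f2, rf$mask),
               4 * kinetic_energy(rf$field, rf$mask), tolerance = 1e-12)
  expect_equal(energy_loss_rate(f2, rf$mask),
               4 * energy_loss_rate(rf$field, rf$mask), tolerance = 1e-12)
  expect_equal(vorticity_vol(f2, rf$mask),
               2 * vorticity_vol(rf$field, rf$mask), tolerance = 1e-12)
  expect_true(all(kinetic_energy(rf$field, rf$mask) >= 0))
  expect_true(all(energy_loss_rate(rf$field, rf$mask) >= 0))
  expect_true(all(vorticity_vol(rf$field, rf$mask) >= 0))
})

test_that("metrics over well-separated disjoint masks are additive", {
  g <- voxel_grid(16, 16, 16, dx = 2, nt = 1)
  set.seed(8)
  v <- array(rnorm(16^3 * 3, sd = 0.4), c(16, 16, 16, 1, 3))
  f <- velocity_field(g, v, venc = 5)
  ma <- array(0L, c(16, 16, 16, 1)); ma[2:6, 2:6, 2:6, 1] <- 1L
  mb <- array(0L, c(16, 16, 16, 1)); mb[10:15, 10:15, 10:15, 1] <- 1L
  A <- segmentation_mask(g, ma); B <- segmentation_mask(g, mb)
  U <- segmentation_mask(g, ma + mb)
  for (fun in list(kinetic_energy, energy_loss_rate, vorticity_vol))
    expect_equal(fun(f, A) + fun(f, B), fun(f, U), tolerance = 1e-12)
})

test_that("counter-rotating cores add by magnitude without cancellation", {
  g <- voxel_grid(40, 40, 24, dx = 1.5, nt = 1)
  a <- make_rigid_rotation(g, omega = 8, center = c(13, 29.25, 17.25),
                           radius_mm = 9, length_mm = 20)
  b <- make_rigid_rotation(g, omega = -8, center = c(45, 29.25, 17.25),
                           radius_mm = 9, length_mm = 20)
  # each core's velocity restricted to its own (disjoint) mask
  va <- a$field$v; vb <- b$field$v
  for (k in 1:3) {
    va[, , , 1, k] <- va[, , , 1, k] * a$mask$m[, , , 1]
    vb[, , , 1, k] <- vb[, , , 1, k] * b$mask$m[, , , 1]
  }
  both <- velocity_field(g, va + vb, venc = a$field$venc)
  U <- segmentation_mask(g, pmin(a$mask$m + b$mask$m, 1L))
  expect_gt(vorticity_vol(both, U), 0)
  expect_equal(vorticity_vol(both, U),
               vorticity_vol(a$field, a$mask) +
                 vorticity_vol(b$field, b$mask), tolerance = 0.02)
})

test_that("grid mismatch between field and mask is rejected", {
  g <- voxel_grid(6, 6, 6, dx = 1, nt = 2)
  g2 <- voxel_grid(6, 6, 6, dx = 1.1, nt = 2)
  f <- velocity_field(g, array(0, c(6, 6, 6, 2, 3)), venc = 1)
  m <- segmentation_mask(g2, array(1L, c(6, 6, 6, 2)))
  expect_error(kinetic_energy(f, m), "different grids")
  expect_error(energy_loss_rate(f, m), "different grids")
  expect_error(vorticity_vol(f, m), "different grids")
})

test_that("production implementation matches the brute-force per-voxel loops", {
  for (seed in 1:3) {
    rf <- random_field_and_mask(n = 8, nt = 2, seed = seed)
    expect_equal(kinetic_energy(rf$field, rf$mask),
                 naive_kinetic_energy(rf$v, rf$m, rf$spacing),
                 tolerance = 1e-10)
    expect_equal(energy_loss_rate(rf$field, rf$mask),
                 naive_energy_loss(rf$v, rf$m, rf$spacing),
                 tolerance = 1e-10)
    expect_equal(vorticity_vol(rf$field, rf$mask),
                 naive_vorticity_vol(rf$v, rf$m, rf$spacing),
                 tolerance = 1e-10)
  }
})

test_that("phase averages are arithmetic means over the partition", {
  series <- list(ke_mJ = c(2, 4, 1, 1, 1, 1),
                 el_mW = c(1, 1, 2, 2, 2, 2),
                 vortvol_mL_s = c(10, 20, 30, 40, 50, 60))
  p <- phase_partition(1:2, 3:6, 6)
  s <- phase_average(series, p)
  expect_equal(unname(s["ke_avg_systole"]), 3)
  expect_equal(unname(s["ke_avg_diastole"]), 1)
  expect_equal(unname(s["ke_avg_cycle"]), 10 / 6)
  # cycle average lies between systole and diastole averages
  for (stem in c("ke_avg", "el_avg", "vortvol_avg")) {
    lo <- min(s[paste0(stem, c("_systole", "_diastole"))])
    hi <- max(s[paste0(stem, c("_systole", "_diastole"))])
    expect_true(s[paste0(stem, "_cycle")] >= lo - 1e-12 &&
                  s[paste0(stem, "_cycle")] <= hi + 1e-12)
  }
  # constant series: all three averages equal
  cs <- list(ke_mJ = rep(5, 6), el_mW = rep(5, 6), vortvol_mL_s = rep(5, 6))
  expect_true(all(phase_average(cs, p)[1:9] == 5))
  expect_error(phase_average(series, phase_partition(1:2, 3:4, 4)),
               "phases")
})

test_that("pulsatile phantom averages follow mean of squared scale factors", {
  g <- voxel_grid(14, 14, 14, dx = 2, nt = 6)
  s <- c(1, 0.8, 0.5, 0.3, 0.4, 0.9)
  u <- make_uniform(g, c(0.6, 0, 0), scales = s)
  p <- phase_partition(1:2, 3:6, 6)
  avg <- phase_average(energetics_series(u$field, u$mask), p)
  ke1 <- kinetic_energy(u$field, u$mask)[1]
  expect_equal(unname(avg["ke_avg_systole"]), ke1 * mean(s[1:2]^2),
               tolerance = 1e-10)
  expect_equal(unname(avg["ke_avg_diastole"]), ke1 * mean(s[3:6]^2),
               tolerance = 1e-10)
  expect_equal(unname(avg["ke_avg_cycle"]), ke1 * mean(s^2),
               tolerance = 1e-10)
})

test_that("SV normalization divides cycle averages by stroke volume", {
  s <- c(ke_avg_systole = 5, ke_avg_diastole = 2, ke_avg_cycle = 3.3,
         el_avg_systole = 2, el_avg_diastole = 1, el_avg_cycle = 1.5,
         vortvol_avg_systole = 5000, vortvol_avg_diastole = 4000,
         vortvol_avg_cycle = 4400)
  nz <- normalize_by_sv(s, 100)
  expect_equal(unname(nz["ke_cycle_per_sv"]), 0.033)
  expect_equal(unname(nz["vortvol_cycle_per_sv"]), 44)
  expect_equal(normalize_by_sv(s, 200), nz / 2)
  expect_error(normalize_by_sv(s, 0), "stroke volume")
  expect_error(normalize_by_sv(s, -5), "stroke volume")
})
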