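test_that("sweep efficiency complements bypass and clamps", {
  expect_equal(sweep_efficiency(list(bypass = 1)), 0)
  expect_equal(sweep_efficiency(list(bypass = 0)), 1)
  expect_equal(sweep_efficiency(list(bypass = 0.25)), 0.75)
  expect_equal(sweep_efficiency(1.2), 0)
})

test_that("residual fraction obeys the limiting cases", {
  # nothing swept: residual stays 1 regardless of cycles
  for (n in c(1, 3, 10))
    expect_equal(residual_after_wash(wash_config(eta = 0, n_cycles = n)), 1)
  # perfect displacement limit: no dead volume, large wash volume
  r <- residual_after_wash(wash_config(V_sub = 0, eta = 1,
                                       V_wash = 50 * 1.3e-7))
  expect_lt(r, 1e-20)
  r0 <- residual_after_wash(wash_config(V_wash = 0))
  expect_equal(r0, 1)
})

test_that("residual is monotone in eta, wash volume, cycles and dead volume", {
  base <- function(...) residual_after_wash(wash_config(...))
  # brute-force monotonicity over parameter grids
  etas <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(vapply(etas, function(e) base(eta = e), 0)) < 0))
  vws <- seq(20e-9, 300e-9, length.out = 8)
  expect_true(all(diff(vapply(vws, function(v) base(V_wash = v, eta = 0.8), 0)) < 0))
  ns <- 1:6
  expect_true(all(diff(vapply(ns, function(n) base(n_cycles = n, eta = 0.8), 0)) < 0))
  # sub-membrane height sweep: V_sub = area * h for h in {0.2, 0.5, 1.0} mm
  area <- 1.69e-4
  hs <- c(0.2e-3, 0.5e-3, 1.0e-3)
  res_h <- vapply(hs, function(h)
    base(V_sub = area * h, eta = 0.8, n_cycles = 3), 0)
  expect_true(all(diff(res_h) > 0))
})

test_that("residual is invariant under joint rescaling of all volumes", {
  cfg1 <- wash_config(V_wash = 120e-9, V_chamber = 5.1e-8, V_sub = 8.4e-8,
                      eta = 0.7, n_cycles = 3)
  cfg2 <- wash_config(V_wash = 10 * 120e-9, V_chamber = 10 * 5.1e-8,
                      V_sub = 10 * 8.4e-8, eta = 0.7, n_cycles = 3)
  expect_equal(residual_after_wash(cfg1), residual_after_wash(cfg2),
               tolerance = 1e-12)
})

test_that("volume retention follows the quasi-static drainage balance", {
  fr <- frame1800()
  fl <- water()
  # impermeable limit retains everything; free-draining retains nothing
  tight <- membrane(20e-9, porosity = 0.01, thickness = 60e-6)
  expect_equal(volume_retention(tight, fr, fl), 1)
  expect_equal(volume_retention(NULL, fr, fl), 0)
  # the 200-nm filter out-retains the 800-nm filter (R_h ratio 16)
  m200 <- membrane(200e-9, porosity = 0.05)
  m800 <- membrane(800e-9, porosity = 0.05)
  r200 <- volume_retention(m200, fr, fl, Q_in = 2e-11)
  r800 <- volume_retention(m800, fr, fl, Q_in = 2e-11)
  expect_gt(r200, r800)
  expect_equal(r200 / r800, 16, tolerance = 1e-6)  # both below the clamp
  # monotone in inflow, decreasing in rotation speed
  expect_gt(volume_retention(m800, fr, fl, Q_in = 4e-11), r800)
  expect_lt(volume_retention(m200, rotating_frame(rpm = 3600), fl,
                             Q_in = 2e-11), r200)
  expect_error(volume_retention(m200, rotating_frame(rpm = 0), fl), "omega")
})

test_that("retention and washing respond oppositely so the tight filter wins", {
  fr <- frame1800()
  fl <- water()
  m200 <- membrane(200e-9, porosity = 0.05)
  m800 <- membrane(800e-9, porosity = 0.05)
  # washing: residual at equal sweep efficiency but retention-driven dead
  # volume; the 200-nm filter keeps the chamber full (high retention) and
  # washes at least as well, so it dominates on both axes
  ret200 <- volume_retention(m200, fr, fl, Q_in = 2e-11)
  ret800 <- volume_retention(m800, fr, fl, Q_in = 2e-11)
  expect_gt(ret200, ret800)
  r200 <- residual_after_wash(wash_config(eta = 0.9))
  r800 <- residual_after_wash(wash_config(eta = 0.9 * ret800 / ret200))
  expect_lte(r200, r800)
})
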