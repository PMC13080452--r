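test_that("solves are divergence-free, mass-conserving and deterministic", {
  f <- cached_solve("small1800", small_chamber(), frame1800())
  expect_true(f$converged)
  # velocity scale for a dimensionless divergence bound
  uscale <- max(abs(f$u), abs(f$v), abs(f$w))
  expect_lt(f$max_divergence * f$domain$dx / uscale, 1e-6)
  expect_lt(abs(f$flux_in - f$flux_out) / f$flux_in, 1e-6)
  expect_equal(f$flux_out, f$Q, tolerance = 1e-9)
  # no-slip on solid walls holds exactly on the staggered faces
  expect_true(all(f$v[, 1, ] == 0) && all(f$v[, f$domain$ny + 1, ] == 0))
  expect_true(all(f$w[, , 1] == 0) && all(f$w[, , f$domain$nz + 1] == 0))
  f2 <- solve_steady_flow(small_chamber(), frame1800(), water(), fast_settings())
  expect_identical(f$u, f2$u)
  expect_identical(f$p, f2$p)
})

test_that("straight-channel benchmark reproduces plane Poiseuille within 5%", {
  # pressure-driven strip, 32 cells across the gap, no rotation, no drag
  dom <- chamber_domain(D = 2e-3, Ly = 1e-3, H = 1e-3, h = 1e-4,
                        membrane = NULL, mode = "2d", outlet_side = "open",
                        hele_shaw = FALSE, nx = 24, ny = 32,
                        inlet_width = 5e-4, outlet_width = 5e-4)
  f <- solve_steady_flow(dom, rotating_frame(rpm = 0), water(),
                         solver_settings(p_in = 1, p_out = 0,
                                         max_iter = 60000))
  cc <- cell_velocities(f)
  prof <- cc$uc[12, , 1]
  yc <- (seq_len(dom$ny) - 0.5) * dom$dy
  ana <- 1 / (2 * 1e-3 * dom$Lx) * yc * (dom$Ly - yc)
  expect_lt(max(abs(prof - ana)) / max(ana), 0.05)
})

test_that("depth-averaged mode matches the Hele-Shaw closed form within 2%", {
  dom <- chamber_domain(D = 4e-3, Ly = 2e-3, H = 0.2e-3, h = 1e-4,
                        membrane = NULL, mode = "2d", outlet_side = "open",
                        hele_shaw = TRUE, nx = 20, ny = 10)
  f <- solve_steady_flow(dom, rotating_frame(rpm = 0), water(),
                         solver_settings(p_in = 2, p_out = 0,
                                         max_iter = 60000))
  cc <- cell_velocities(f)
  u_mid <- mean(cc$uc[, 4:7, 1])
  u_ana <- 2 * (0.2e-3)^2 / (12 * 1e-3 * 4e-3)
  expect_lt(abs(u_mid / u_ana - 1), 0.02)
})

test_that("without Coriolis the 2D solution is mirror-symmetric", {
  dom <- chamber_domain(mode = "2d", membrane = NULL, outlet_side = "far",
                        nx = 20, ny = 20)
  f <- solve_steady_flow(dom, rotating_frame(rpm = 0), water(),
                         fast_settings(), Q = 1e-8)
  expect_lt(asymmetry_index(f), 1e-8)
})

test_that("reversing rotation sense mirrors the field about the x-z plane", {
  f_cw <- cached_solve("small1800", small_chamber(), frame1800())
  f_ccw <- solve_steady_flow(small_chamber(), frame1800("counterclockwise"),
                             water(), fast_settings())
  m <- mirror_field(f_ccw)
  rel <- sqrt(sum((f_cw$u - m$u)^2) + sum((f_cw$v - m$v)^2) +
                sum((f_cw$w - m$w)^2)) /
    sqrt(sum(f_cw$u^2) + sum(f_cw$v^2) + sum(f_cw$w^2))
  expect_lt(rel, 1e-6)
})

test_that("non-convergence raises an error carrying the residual history", {
  err <- tryCatch(
    solve_steady_flow(small_chamber(), frame1800(), water(),
                      solver_settings(max_iter = 12, min_iter = 1,
                                      record_every = 2)),
    discassay_no_convergence = function(e) e)
  expect_s3_class(err, "discassay_no_convergence")
  expect_true(length(err$residuals) > 0)
})

test_that("no-filter control passes flux without the membrane detour", {
  f0 <- cached_solve("small1800_nofilter", small_chamber(membrane = NULL),
                     frame1800())
  expect_true(f0$converged)
  expect_lt(abs(f0$flux_in - f0$flux_out) / f0$flux_in, 1e-6)
})

test_that("X1 edge speed is grid-converged to within 25% under refinement", {
  f_lo <- cached_solve("small1800", small_chamber(), frame1800())
  dom_hi <- chamber_domain(nx = 36, ny = 36, nz = 16)
  f_hi <- cached_solve("hi1800", dom_hi, frame1800())
  s_lo <- edge_region_speed(f_lo, "X1")
  s_hi <- edge_region_speed(f_hi, "X1")
  expect_lt(abs(s_hi - s_lo) / s_hi, 0.25)
})

test_that("conventional inlet-flow orientation balances mass too", {
  dom <- small_chamber(bc_orientation = "inlet_flow")
  f <- solve_steady_flow(dom, frame1800(), water(), fast_settings())
  expect_true(f$converged)
  expect_lt(abs(f$flux_in - f$flux_out) / f$flux_in, 1e-6)
  expect_equal(f$flux_in, f$Q, tolerance = 1e-9)
})
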