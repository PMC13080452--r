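test_that("rpm/omega conversion is exact and round-trips", {
  expect_equal(rpm_to_omega(1800), 2 * pi * 30)
  expect_equal(omega_to_rpm(rpm_to_omega(137.5)), 137.5)
  fr <- rotating_frame(rpm = 1800)
  expect_equal(fr$omega, 188.4956, tolerance = 1e-6)
  expect_equal(rotating_frame(omega = fr$omega)$rpm, 1800)
  expect_error(rotating_frame(rpm = 10, omega = 1), "exactly one")
})

test_that("body-force densities match hand-evaluated components", {
  fr <- rotating_frame(rpm = 1800)           # clockwise viewed from +z
  fl <- fluid(1000, 1e-3)
  # at rest the Coriolis force vanishes (linear in u)
  f0 <- body_force_density(c(0, 0, 0), c(0.04, 0, 0), fr, fl)
  expect_equal(f0$coriolis, c(0, 0, 0))
  # centrifugal rho*omega^2*r at r = 4 cm
  expect_equal(f0$centrifugal, c(1000 * fr$omega^2 * 0.04, 0, 0))
  expect_equal(f0$centrifugal[1], 1.4212e6, tolerance = 1e-4)
  # outward flow deflects toward +y under clockwise rotation
  fc <- body_force_density(c(0.1, 0, 0), c(0.04, 0, 0), fr, fl)
  expect_equal(fc$coriolis, c(0, 2 * 1000 * fr$omega * 0.1, 0))
  expect_equal(fc$coriolis[2], 3.7699e4, tolerance = 1e-4)
  expect_equal(f0$gravity, c(0, 0, -1000 * 9.80665))
  expect_equal(fc$total, fc$gravity + fc$centrifugal + fc$coriolis)
  expect_error(body_force_density(c(NA, 0, 0), c(0, 0, 0), fr, fl), "finite")
})

test_that("Coriolis force is perpendicular to u and flips with rotation sense", {
  fl <- fluid(998, 1.002e-3)
  set.seed(42)
  for (i in 1:25) {
    u <- rnorm(3)
    pos <- rnorm(3) * 0.01
    cw <- body_force_density(u, pos, rotating_frame(rpm = 700), fl)
    ccw <- body_force_density(u, pos,
                              rotating_frame(rpm = 700, sense = "counterclockwise"),
                              fl)
    expect_equal(sum(cw$coriolis * u), 0)
    expect_equal(cw$coriolis[3], 0)
    expect_equal(ccw$coriolis, -cw$coriolis)
    expect_equal(ccw$centrifugal, cw$centrifugal)
    expect_equal(ccw$gravity, cw$gravity)
  }
})

test_that("centrifugal flow rate equals dP/R from an independent oracle", {
  # oracle: Hagen-Poiseuille resistance and centrifugal pressure head coded
  # from their definitions, independent of the package's formula layout
  oracle_Q <- function(A, dH, L, r, dr, rho, mu, omega)
    (rho * omega^2 * r * dr) / (32 * mu * L / (dH^2 * A))
  fr <- frame1800()
  fl <- water()
  ch <- channel_spec(area = 1e-6, hydraulic_diameter = 5e-4, length = 0.02,
                     r_mean = 0.03, dr = 6e-3)
  expect_equal(centrifugal_flow_rate(ch, fl, fr),
               oracle_Q(1e-6, 5e-4, 0.02, 0.03, 6e-3, 1000, 1e-3, fr$omega),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:100) {
    A <- 10^runif(1, -8, -5)
    dH <- sqrt(A) * runif(1, 0.3, 1.1)   # respects dH^2 <= 4A/pi
    L <- runif(1, 1e-3, 0.05)
    r <- runif(1, 5e-3, 0.05)
    dr <- runif(1, 1e-3, 0.02)
    mu <- 10^runif(1, -3.5, -2)
    rho <- runif(1, 800, 1200)
    om <- runif(1, 1, 400)
    ch <- channel_spec(A, dH, L, r, dr)
    got <- centrifugal_flow_rate(ch, fluid(rho, mu), rotating_frame(omega = om))
    expect_equal(got, oracle_Q(A, dH, L, r, dr, rho, mu, om),
                 tolerance = 1e-12)
  }
})

test_that("flow rate scales as omega^2 and 1/mu", {
  ch <- channel_spec(1e-7, 2e-4, 0.02, 0.03, 5e-3)
  q1 <- centrifugal_flow_rate(ch, water(), rotating_frame(rpm = 600))
  q2 <- centrifugal_flow_rate(ch, water(), rotating_frame(rpm = 1200))
  expect_equal(q2 / q1, 4)
  q3 <- centrifugal_flow_rate(ch, fluid(1000, 2e-3), rotating_frame(rpm = 600))
  expect_equal(q3 / q1, 0.5)
  expect_error(channel_spec(1e-7, 1e-2, 0.02, 0.03, 5e-3), "cross-section")
})

test_that("Ekman number definition, similarity and degenerate rotation", {
  fl <- fluid(1000, 1e-3)   # nu = 1e-6
  fr <- rotating_frame(omega = 188.4956)
  expect_equal(ekman_number(fl, fr, 1e-3), 5.305e-3, tolerance = 1e-4)
  for (k in c(0.1, 2, 17)) {
    expect_equal(ekman_number(fluid(1000, k * 1e-3),
                              rotating_frame(omega = k * 188.4956), 1e-3),
                 ekman_number(fl, fr, 1e-3))
  }
  expect_equal(ekman_number(fl, rotating_frame(omega = 2 * 188.4956), 1e-3),
               ekman_number(fl, fr, 1e-3) / 2)
  expect_identical(ekman_number(fl, rotating_frame(rpm = 0), 1e-3), Inf)
})

test_that("bead Stokes number is overdamped at assay conditions", {
  fl <- fluid(1000, 1e-3)
  expect_equal(stokes_number(bead_spec(), fl, rotating_frame(rpm = 0)), 0)
  stk <- stokes_number(bead_spec(5e-6, 1050), fl, frame1800())
  expect_equal(stk, 2.75e-4, tolerance = 1e-3)
  expect_gte(stk, 1e-4)
  expect_lt(stk, 1e-3)
  stk_small <- stokes_number(bead_spec(0.8e-6, 1050), fl, frame1800())
  expect_equal(stk_small / stk, (0.8 / 5)^2)
})

test_that("membrane hydraulics follow the cylindrical-pore model", {
  fl <- water()
  m200 <- membrane(200e-9, porosity = 0.05, thickness = 10e-6,
                   area = 1.327e-4)
  hy <- membrane_hydraulics(m200, fl)
  expect_equal(hy$kappa, 6.25e-17, tolerance = 1e-4)
  expect_equal(hy$R_h, 1e-3 * 10e-6 / (6.25e-17 * 1.327e-4), tolerance = 1e-4)
  # halving pore diameter at fixed porosity quadruples R_h
  m100 <- membrane(100e-9, porosity = 0.05, thickness = 10e-6, area = 1.327e-4)
  expect_equal(membrane_hydraulics(m100, fl)$R_h / hy$R_h, 4, tolerance = 1e-12)
  m800 <- membrane(800e-9, porosity = 0.05, thickness = 10e-6, area = 1.327e-4)
  expect_equal(hy$R_h / membrane_hydraulics(m800, fl)$R_h, 16, tolerance = 1e-12)
  # monotone in thickness
  thick <- membrane(200e-9, porosity = 0.05, thickness = 20e-6, area = 1.327e-4)
  expect_gt(membrane_hydraulics(thick, fl)$R_h, hy$R_h)
  # porosity / pore-density round trip
  m_pd <- membrane(200e-9, pore_density = m200$pore_density,
                   thickness = 10e-6, area = 1.327e-4)
  expect_equal(m_pd$porosity, 0.05, tolerance = 1e-12)
  expect_error(membrane(200e-9, porosity = 1.2), "porosity")
  expect_error(membrane(200e-9), "exactly one")
  expect_error(membrane(200e-9, porosity = 0.05, pore_density = 1e12),
               "exactly one")
})
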