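test_that("edge-region speed handles zero fields, bands and scaling", {
  pf <- plug_flow_field(speed = 0)
  expect_equal(edge_region_speed(pf, "X1"), 0)
  pf1 <- plug_flow_field(speed = 2e-3)
  expect_equal(edge_region_speed(pf1, "X1"), 2e-3)
  # speeds scale linearly with a uniform rescaling of the field
  pf2 <- pf1
  pf2$u <- 3 * pf1$u
  expect_equal(edge_region_speed(pf2, "X1"), 3 * edge_region_speed(pf1, "X1"))
  expect_error(edge_region_speed(pf1, "X1", band_fraction = 0.001),
               "resolution|cells")
  expect_error(edge_region_speed(pf1, "X1", band_fraction = 0.7), "band_fraction")
})

test_that("asymmetry index is zero for symmetric fields and metric-symmetric", {
  pf <- plug_flow_field(speed = 1e-3)
  expect_equal(asymmetry_index(pf), 0)
  f <- cached_solve("small1800", small_chamber(), frame1800())
  a1 <- asymmetry_index(f)
  a2 <- asymmetry_index(mirror_field(f))
  expect_gt(a1, 0)
  expect_equal(a1, a2, tolerance = 1e-12)
  # invariant under uniform rescaling of the velocity field
  fs <- f
  fs$u <- 5 * f$u; fs$v <- 5 * f$v; fs$w <- 5 * f$w
  expect_equal(asymmetry_index(fs), a1, tolerance = 1e-12)
})

test_that("bypass is 0 for plug flow past a far outlet and seed-stable", {
  pf <- plug_flow_field(speed = 1e-3)
  expect_equal(bypass_fraction(pf, n_tracers = 50), 0)
  f <- cached_solve("small1800", small_chamber(), frame1800())
  b1 <- suppressWarnings(bypass_fraction(f, n_tracers = 2000, seed = 1))
  b2 <- suppressWarnings(bypass_fraction(f, n_tracers = 2000, seed = 99))
  expect_lte(abs(b1 - b2), 1 / 2000 + 1e-12)
  # invariant under uniform rescaling (same streamlines)
  fs <- f
  fs$u <- 2 * f$u; fs$v <- 2 * f$v; fs$w <- 2 * f$w
  expect_equal(suppressWarnings(bypass_fraction(fs, n_tracers = 200, seed = 1)),
               suppressWarnings(bypass_fraction(f, n_tracers = 200, seed = 1)))
})

test_that("no-filter flow bypasses the chamber more than the tight membrane", {
  f_mem <- cached_solve("small1800", small_chamber(), frame1800())
  f_none <- cached_solve("small1800_nofilter", small_chamber(membrane = NULL),
                         frame1800())
  b_mem <- suppressWarnings(bypass_fraction(f_mem, n_tracers = 400, seed = 1))
  b_none <- suppressWarnings(bypass_fraction(f_none, n_tracers = 400, seed = 1))
  expect_gt(b_none, b_mem)
})

test_that("membrane flux fraction partitions the through-flow correctly", {
  f <- cached_solve("small1800", small_chamber(), frame1800())
  # cavity-outlet geometry: all through-flow crosses the membrane
  expect_equal(membrane_flux_fraction(f), 1, tolerance = 0.05)
  expect_equal(membrane_net_flux(f) / f$Q, 1, tolerance = 1e-6)
  f0 <- cached_solve("small1800_nofilter", small_chamber(membrane = NULL),
                     frame1800())
  expect_error(membrane_flux_fraction(f0), "membrane")
  # closed-cavity variant: fraction falls with membrane resistance and the
  # cavity exchange nets to zero (conservation)
  fr <- frame1800()
  fracs <- vapply(c(22e-6, 8e-6, 0.2e-6), function(dp) {
    por <- if (dp > 1.5e-6) 0.2 else 0.05
    dom <- small_chamber(membrane = membrane(dp, porosity = por),
                         outlet_level = "upper")
    fu <- solve_steady_flow(dom, fr, water(), fast_settings())
    expect_lt(abs(membrane_net_flux(fu)) / fu$Q, 1e-6)
    expect_lt(abs(fu$flux_in - fu$flux_out) / fu$flux_in, 1e-6)
    membrane_flux_fraction(fu)
  }, 0)
  expect_true(all(diff(fracs) < 0))
  # impermeable limit: essentially nothing dips below the membrane
  expect_lt(fracs[3], 0.05)
})

test_that("flow_diagnostics bundles a keyed summary row", {
  f <- cached_solve("small1800", small_chamber(), frame1800())
  dg <- suppressWarnings(flow_diagnostics(f, n_tracers = 100))
  expect_s3_class(dg, "flow_diagnostics")
  expect_equal(dg$rpm, 1800)
  expect_gt(dg$R_h, 0)
  expect_true(dg$bypass >= 0 && dg$bypass <= 1)
  expect_true(dg$asymmetry >= 0 && dg$asymmetry <= 1)
  expect_lt(dg$mass_imbalance, 1e-6)
})
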