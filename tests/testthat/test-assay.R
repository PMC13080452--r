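test_that("event summarization uses the median with midpoint convention", {
  expect_equal(summarize_events(c(1, 2, 3)), 2)
  expect_equal(summarize_events(c(1, 2, 3, 4)), 2.5)
  expect_error(summarize_events(numeric(0)), "empty")
  expect_error(bead_event_table(numeric(0)), "empty")
  # sampling behavior: planted log-normal median recovered within 3%
  ev <- generate_bead_events(n = 5000, location = 1000, dispersion = 0.5,
                             seed = 11)
  expect_equal(summarize_events(ev), 1000, tolerance = 0.03)
})

test_that("marker normalization reproduces the printed contrast arithmetic", {
  nm <- normalize_marker(3195, 778)
  expect_equal(nm$dI, 2417)
  # xi is invariant to detector gain
  x1 <- normalize_marker(3195, 778, dI_CD63 = 2417)
  x2 <- normalize_marker(3195 * 7.3, 778 * 7.3, dI_CD63 = 2417 * 7.3)
  expect_equal(x1$xi, x2$xi)
  expect_equal(normalize_marker(778, 778, dI_CD63 = 100)$xi, 0)
  # undefined normalization is flagged, not silently zeroed
  bad <- normalize_marker(900, 778, dI_CD63 = -5)
  expect_true(is.na(bad$xi))
  expect_false(bad$xi_defined)
})

test_that("target-to-background matches the published worked example", {
  expect_equal(signif(target_to_background(3195, 778), 2), 3.1)
  expect_equal(signif(target_to_background(1796, 749), 2), 1.4)
  expect_equal(target_to_background(500, 500), 0)
  expect_error(target_to_background(100, 0), "I_background")
  # the amplified protocol improves contrast by more than 2x
  expect_gt(target_to_background(3195, 778) / target_to_background(1796, 749), 2)
})

test_that("LOD estimation interpolates the blank + 3 sigma crossing", {
  # degenerate threshold: zero blank SD and strictly increasing response
  ts0 <- titration_series(c(1e4, 1e5, 1e6, 1e7),
                          cbind(c(5, 5, 20, 40), c(5, 5, 20, 40)),
                          blanks = c(5, 5, 5))
  ld0 <- estimate_lod(ts0)
  expect_equal(ld0$lod, 1e6)   # first concentration whose mean exceeds 5
  # exact log-linear interpolation on a constructed crossing
  conc <- 10^(3:8)
  m <- c(10, 10, 10, 40, 70, 100)
  ts <- titration_series(conc, cbind(m, m), blanks = c(10, 10, 10))
  thr <- 10  # sd = 0
  ld <- estimate_lod(ts, k_sd = 3)
  expect_equal(ld$lod, 1e6)    # mean first exceeds 10 at 1e6
  # with a positive threshold between points, interpolate in log10(conc)
  ts2 <- titration_series(conc, cbind(m, m), blanks = c(10, 12, 8, 10))
  thr2 <- mean(c(10, 12, 8, 10)) + 3 * sd(c(10, 12, 8, 10))
  i <- which(m > thr2)[1]
  lc <- log10(conc[i - 1]) +
    (thr2 - m[i - 1]) / (m[i] - m[i - 1]) * (log10(conc[i]) - log10(conc[i - 1]))
  expect_equal(estimate_lod(ts2)$lod, 10^lc)
  # widening the blank never lowers the LOD
  lods <- vapply(c(0.5, 1, 2, 4), function(s) {
    b <- c(10 - s, 10 + s, 10 - s, 10 + s)
    estimate_lod(titration_series(conc, cbind(m, m), blanks = b))$lod
  }, 0)
  expect_true(all(diff(lods) >= 0))
  # no crossing reported explicitly
  flat <- titration_series(conc, cbind(rep(10, 6), rep(10, 6)),
                           blanks = c(10, 11, 9))
  expect_identical(estimate_lod(flat)$status, "above_range")
  expect_true(is.na(estimate_lod(flat)$lod))
})

test_that("EV-to-molar conversion reproduces the femtomolar sensitivity", {
  m <- ev_concentration_to_molar(4.6e5, 12)
  expect_equal(m, 9.17e-15, tolerance = 1e-3)
  expect_equal(m * 1e15, 10, tolerance = 0.1)    # the rounded printed figure
  expect_equal(ev_concentration_to_molar(0, 12), 0)
  expect_equal(ev_concentration_to_molar(1, 1), 1000 / 6.02214e23)
})

test_that("z-score standardization is exact, reusable and idempotent", {
  z <- zscore_standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(z$X[, "a"], c(-1, 0, 1))
  expect_equal(colMeans(z$X), c(a = 0, b = 0))
  expect_equal(apply(z$X, 2, sd), c(a = 1, b = 1))
  # idempotence
  z2 <- zscore_standardize(z$X)
  expect_equal(z2$X, z$X, tolerance = 1e-12)
  # large random matrix: column means vanish to machine precision
  set.seed(3)
  Xr <- matrix(rnorm(82 * 9, mean = 5, sd = 2), 82, 9,
               dimnames = list(NULL, paste0("m", 1:9)))
  zr <- zscore_standardize(Xr)
  expect_true(all(abs(colMeans(zr$X)) < 1e-12))
  # stored parameters standardize new data consistently
  expect_equal(apply_zscore(zr, Xr), zr$X)
  # zero-variance column is named in the failure
  Xz <- cbind(good = rnorm(10), flat = rep(2, 10))
  expect_error(zscore_standardize(Xz), "flat")
})
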