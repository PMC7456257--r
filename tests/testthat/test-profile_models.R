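test_that("profile evaluation reproduces hand-computed values", {
  p <- ref_cut()  # selected-quantile coefficients, shelterwood-cut strip
  expect_equal(eval_profile(p, dbh = 2, cr = 0.8, rdinc = 0), 0)
  expect_equal(eval_profile(p, dbh = 2, cr = 0.8, rdinc = 0.8088),
               0.2290, tolerance = 5e-4)

  basic <- profile_params("power_exp_basic", c(1, 1, 0))
  expect_equal(eval_profile(basic, rdinc = 0.5), 0.5)

  # continuity and monotone DBH effect for positive a2
  grid <- seq(0.01, 1, length.out = 200)
  r1 <- eval_profile(p, dbh = 1.5, cr = 0.8, rdinc = grid)
  r2 <- eval_profile(p, dbh = 3.0, cr = 0.8, rdinc = grid)
  expect_true(all(is.finite(r1)))
  expect_true(all(r2 > r1))
})

test_that("Kozak-type forms respect their domain and the crown-base limit", {
  kb <- profile_params("kozak_basic", c(0.5, 1.2, 0.7))
  expect_equal(eval_profile(kb, rdinc = 0), 0)
  expect_error(eval_profile(profile_params("kozak_basic", c(0.5, 1.2, 1.5)),
                            rdinc = 0.5),
               "denominator base")

  km <- profile_params("kozak_mod", c(0.3, 0.6, 0.5, 1, 0.8))
  # exponent vanishes at the crown base: value is c1 * DBH^c2 exactly
  expect_equal(eval_profile(km, dbh = 2, cr = 0.8, rdinc = 1),
               0.3 * 2^0.6)
  expect_true(all(is.finite(
    eval_profile(km, dbh = 2, cr = 0.8, rdinc = seq(0, 1, 0.01)))))
})

test_that("closed-form depth of maximum radius matches the grid argmax", {
  grid <- seq(0, 1, length.out = 1e6 + 1)

  p_cut <- ref_cut()
  ip_cut <- inflection_point(p_cut, cr = 0.8)
  expect_equal(ip_cut, 0.8088, tolerance = 1e-4)
  r <- eval_profile(p_cut, dbh = 2, cr = 0.8, rdinc = grid)
  expect_equal(ip_cut, grid[which.max(r)], tolerance = 1e-6)

  p_unc <- ref_uncut()
  ip_unc <- inflection_point(p_unc, cr = 0.8)
  expect_equal(ip_unc, 0.6448, tolerance = 1e-4)
  r2 <- eval_profile(p_unc, dbh = 2, cr = 0.8, rdinc = grid)
  expect_equal(ip_unc, grid[which.max(r2)], tolerance = 1e-6)

  # boundary case -b/c = 1
  p1 <- profile_params("power_exp_full", c(1, 0.5, 1, 0, -1))
  expect_equal(as.numeric(inflection_point(p1, cr = 0.8)), 1.0)

  # nonnegative exponential rate: monotone profile, flagged
  pm <- profile_params("power_exp_full", c(1, 0.5, 1, 0, 0.2))
  ipm <- inflection_point(pm, cr = 0.8)
  expect_equal(as.numeric(ipm), 1)
  expect_true(attr(ipm, "monotone"))
  expect_equal(largest_crown_radius(pm, dbh = 2, cr = 0.8),
               eval_profile(pm, dbh = 2, cr = 0.8, rdinc = 1))
})

test_that("depth of maximum is linear in crown ratio", {
  p <- ref_cut()
  cf <- p$coefficients
  crs <- c(0.6, 0.7, 0.8, 0.9)
  ips <- vapply(crs, function(cr) as.numeric(inflection_point(p, cr)), 1)
  slope <- diff(ips) / diff(crs)
  expect_equal(slope, rep(cf[["a4"]] / (-cf[["a5"]]), 3), tolerance = 1e-12)
  # so the mean of per-sapling depths equals the depth at the mean CR
  expect_equal(mean(ips), as.numeric(inflection_point(p, mean(crs))),
               tolerance = 1e-12)
})

test_that("largest crown radius dominates a fine evaluation grid", {
  grid <- seq(0, 1, length.out = 10001)
  for (p in list(ref_cut(), ref_uncut())) {
    lcr <- largest_crown_radius(p, dbh = 2.5, cr = 0.75)
    expect_gte(lcr, max(eval_profile(p, dbh = 2.5, cr = 0.75, rdinc = grid)) - 1e-12)
  }
})

test_that("rotational crown volume matches closed forms and refines stably", {
  # cone of basal radius 0.3 over a 2 m crown
  expect_equal(crown_volume(function(t) 0.3 * t, cl = 2),
               pi * 0.09 * 2 / 3, tolerance = 1e-8)
  expect_equal(crown_volume(function(t) 0.3 * t, cl = 2), 0.18850,
               tolerance = 1e-4)
  # cylinder
  expect_equal(crown_volume(function(t) rep(0.3, length(t)), cl = 2),
               pi * 0.09 * 2, tolerance = 1e-8)
  expect_equal(crown_volume(function(t) rep(0.3, length(t)), cl = 2),
               0.56549, tolerance = 1e-4)
  # quadrature refinement: 2,001 vs 200,001 points agree tightly
  fn <- profile_radius_fn(ref_cut(), dbh = 2, cr = 0.8)
  v1 <- crown_volume(fn, cl = 1.85, n = 2001)
  v2 <- crown_volume(fn, cl = 1.85, n = 200001)
  expect_equal(v1, v2, tolerance = 1e-8)
  # empty region
  expect_equal(crown_volume(fn, cl = 2, region = c(0.5, 0.5)), 0)
  # scaling the profile by k scales volume by k^2
  expect_equal(crown_volume(function(t) 2 * fn(t), cl = 1.85),
               4 * crown_volume(fn, cl = 1.85), tolerance = 1e-12)
})

test_that("parameter construction validates form and length", {
  expect_error(profile_params("power_exp_full", 1:3), "5 coefficients")
  expect_error(profile_params("no_such_form", 1:5))
  expect_named(ref_cut()$coefficients, c("a1", "a2", "a3", "a4", "a5"))
  expect_error(inflection_point(profile_params("kozak_basic", c(1, 1, 0.5))),
               "power-exponential")
})

test_that("packaged reference parameter sets expose all published fits", {
  for (strip in c("shelterwood_cut", "uncut")) {
    for (fit in c("ols", "q0.75", "q0.85", "q0.95", "q0.99", "selected")) {
      p <- reference_params(strip, fit)
      expect_s3_class(p, "profile_params")
      expect_length(attr(p, "std"), 5)
    }
  }
  expect_equal(attr(reference_params("shelterwood_cut"), "tau"), 0.88)
  expect_equal(attr(reference_params("uncut"), "tau"), 0.92)
  expect_error(reference_params("uncut", "q0.42"), "no fit")
})
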