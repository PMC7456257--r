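test_that("crown metric differences vanish for identical strips", {
  p <- ref_cut()
  cmp <- crown_metrics_table(list(shelterwood_cut = p, uncut = p))
  expect_true(all(abs(cmp$differences$d_inflection) < 1e-12))
  expect_true(all(abs(cmp$differences$d_largest_radius_m) < 1e-12))
  expect_true(all(abs(cmp$differences$d_upper_volume_m3) < 1e-12))
})

test_that("published parameter sets reproduce the directional findings", {
  cmp <- crown_metrics_table(list(shelterwood_cut = ref_cut(),
                                  uncut = ref_uncut()))
  d <- cmp$differences
  # uncut saplings carry the larger largest crown radius at equal size
  expect_true(all(d$d_largest_radius_m > 0))
  # the shelterwood-cut crowns peak deeper (larger inflection depth)
  expect_true(all(d$d_inflection < 0))
  # the uncut strip's upper-crown volume advantage shrinks with size:
  # the proportional contrast scales as DBH^(2 * (a2_u - a2_c)) with
  # a2_uncut < a2_cut, so it is monotone decreasing
  i1 <- which.min(abs(d$dbh_cm - 1)); i3 <- which.min(abs(d$dbh_cm - 3))
  expect_lt(abs(d$d_upper_volume_rel[i3]), abs(d$d_upper_volume_rel[i1]))
  expect_true(all(d$d_upper_volume_rel > 0))
})

test_that("metric differences are antisymmetric under label swap", {
  a <- crown_metrics_table(list(shelterwood_cut = ref_cut(),
                                uncut = ref_uncut()))
  b <- crown_metrics_table(list(shelterwood_cut = ref_uncut(),
                                uncut = ref_cut()))
  expect_equal(a$differences$d_largest_radius_m,
               -b$differences$d_largest_radius_m, tolerance = 1e-12)
  expect_equal(a$differences$d_upper_volume_m3,
               -b$differences$d_upper_volume_m3, tolerance = 1e-12)
})

test_that("annual growth comparison summarises and tests per year", {
  ds <- generate_stand(stand_config(
    n_saplings = c(shelterwood_cut = 30, uncut = 30), seed = 17))

  # identical strip means with zero spread: difference 0, p = 1
  g0 <- generate_growth_series(ds, growth_config(
    rate_sd = 0,
    post_treatment_rates = list(
      `2014` = c(shelterwood_cut = 12, uncut = 12),
      `2015` = c(shelterwood_cut = 13, uncut = 13),
      `2016` = c(shelterwood_cut = 14, uncut = 14),
      `2017` = c(shelterwood_cut = 15, uncut = 15)),
    seed = 1))
  cmp0 <- annual_growth_compare(g0)
  y14 <- cmp0[cmp0$year == 2014, ]
  expect_equal(diff(y14$mean_increment_cm), 0)
  expect_equal(unique(y14$p_value), 1)

  # large separation: overwhelming evidence
  g1 <- generate_growth_series(ds, growth_config(
    rate_sd = 0.1,
    post_treatment_rates = list(
      `2014` = c(shelterwood_cut = 10, uncut = 20),
      `2015` = c(shelterwood_cut = 10, uncut = 20),
      `2016` = c(shelterwood_cut = 10, uncut = 20),
      `2017` = c(shelterwood_cut = 10, uncut = 20)),
    seed = 2))
  cmp1 <- annual_growth_compare(g1, years = 2014)
  expect_lt(cmp1$p_value[1], 1e-10)
  expect_equal(cmp1$n, c(30, 30))

  expect_error(annual_growth_compare(ds), "no year_YYYY")
})

test_that("the Welch test agrees with a permutation oracle on a toy sample", {
  set.seed(33)
  x <- rnorm(10, 10, 2); y <- rnorm(10, 12, 3)
  ds <- generate_stand(stand_config(
    n_saplings = c(shelterwood_cut = 10, uncut = 10), seed = 3,
    whorl_spacing = 0.4))
  g <- generate_growth_series(ds, growth_config(seed = 4))
  br <- g$branches
  idx <- which(!is.na(br$year_2014))
  strip <- g$saplings$strip_type[match(br$sapling_id[idx], g$saplings$sapling_id)]
  br$year_2014[idx[strip == "shelterwood_cut"]] <- x
  br$year_2014[idx[strip == "uncut"]] <- y
  g$branches <- br
  p_welch <- annual_growth_compare(g, years = 2014)$p_value[1]

  # permutation distribution of the Welch statistic
  tstat <- function(a, b) abs(t.test(a, b)$statistic)
  obs <- tstat(x, y)
  pool <- c(x, y)
  set.seed(44)
  perm <- replicate(4000, {
    s <- sample(20)
    tstat(pool[s[1:10]], pool[s[11:20]])
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_welch - p_perm), 0.04)  # Monte-Carlo error margin
})

test_that("growth power structure: pre-treatment null, late years separated", {
  # the default growth configuration has equal pre-treatment rates and
  # clearly separated final-year rates; with ~30 saplings per strip the
  # pre-treatment year should look null and the final year significant in
  # the vast majority of replicates
  ds <- generate_stand(stand_config(seed = 51))
  pre_ok <- 0L; post_ok <- 0L; reps <- 40L
  for (r in seq_len(reps)) {
    g <- generate_growth_series(ds, growth_config(seed = 100 + r))
    cmp <- annual_growth_compare(g)
    pre_ok <- pre_ok + (cmp$p_value[cmp$year == 2013][1] > 0.05)
    post_ok <- post_ok + (cmp$p_value[cmp$year == 2017][1] < 0.05)
  }
  expect_gte(pre_ok / reps, 0.9)
  expect_gte(post_ok / reps, 0.9)
})

test_that("reports are written completely, with gaps flagged, reproducibly", {
  ds <- generate_stand(stand_config(
    n_saplings = c(shelterwood_cut = 4, uncut = 3), seed = 61))
  ds <- generate_growth_series(ds, growth_config(seed = 61))
  metrics <- crown_metrics_table(list(shelterwood_cut = ref_cut(),
                                      uncut = ref_uncut()))
  growth <- annual_growth_compare(ds)

  dir <- withr::local_tempdir()
  paths <- render_report(dir, dataset = ds, metrics = metrics, growth = growth,
                         seed = 61, config = list(a = 1))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "growth.csv")))
  expect_true(file.exists(file.path(dir, "run.log")))
  log <- readLines(file.path(dir, "run.log"))
  expect_true(any(grepl("seed: 61", log)))
  expect_true(any(grepl("sections_absent: grid_fits, selections", log)))

  # run without growth: section marked absent
  dir2 <- withr::local_tempdir()
  render_report(dir2, dataset = ds, metrics = metrics, seed = 61)
  expect_false(file.exists(file.path(dir2, "growth.csv")))
  log2 <- readLines(file.path(dir2, "run.log"))
  expect_true(any(grepl("growth", log2[grepl("sections_absent", log2)])))

  # identical inputs give identical CSV payloads
  dir3 <- withr::local_tempdir()
  render_report(dir3, dataset = ds, metrics = metrics, growth = growth,
                seed = 61, config = list(a = 1))
  expect_identical(readLines(file.path(dir, "metrics.csv")),
                   readLines(file.path(dir3, "metrics.csv")))
  expect_identical(readLines(file.path(dir, "growth.csv")),
                   readLines(file.path(dir3, "growth.csv")))
})
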