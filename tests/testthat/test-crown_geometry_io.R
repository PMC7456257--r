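test_that("branch geometry derivation matches hand trigonometry", {
  g <- derive_branch_geometry(l_m = 1.0, bc_cm = 40, va_deg = 90, cl_m = 2.0)
  expect_equal(g$dinc_m, 1.0)
  expect_equal(g$ocr_m, 0.40)

  g2 <- derive_branch_geometry(l_m = 1.0, bc_cm = 50, va_deg = 60, cl_m = 2.0)
  expect_equal(g2$dinc_m, 0.75)
  expect_equal(g2$ocr_m, 0.5 * sin(pi / 3), tolerance = 1e-10)
  expect_equal(g2$ocr_m, 0.4330, tolerance = 1e-4)
  expect_equal(g2$rdinc, 0.375)

  # a branch angle above 90 degrees projects negatively: dinc > l
  g3 <- derive_branch_geometry(1.0, 50, 150, 2.0)
  expect_gt(g3$dinc_m, 1.0)
  expect_error(derive_branch_geometry(1, 40, 90, 0), "positive")
})

test_that("crown ratio is CL/HT with the study-mean values", {
  expect_equal(crown_ratio(2.4, 2.4), 1.0)
  expect_equal(crown_ratio(1.85, 2.40), 0.7708, tolerance = 1e-4)
  expect_equal(crown_ratio(1.61, 2.18), 0.7385, tolerance = 1e-4)
  expect_error(crown_ratio(2.5, 2.4), "exceeds")
  expect_error(crown_ratio(1, 0), "positive")
})

test_that("CSV reading handles empty, valid and malformed inputs", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "saplings.csv"); bp <- file.path(dir, "branches.csv")

  writeLines("sapling_id,strip_type,dbh_cm,ht_m,cl_m", sp)
  writeLines("sapling_id,whorl_index,l_m,bl_cm,bc_cm,va_deg,bd_mm,azimuth_deg", bp)
  ds <- read_branch_table(sp, bp)
  expect_s3_class(ds, "crown_dataset")
  expect_equal(nrow(ds$saplings), 0)
  expect_equal(nrow(ds$branches), 0)

  writeLines(c("sapling_id,strip_type,dbh_cm,ht_m,cl_m",
               "s1,uncut,2.0,2.5,2.0"), sp)
  writeLines(c("sapling_id,whorl_index,l_m,bl_cm,bc_cm,va_deg,bd_mm,azimuth_deg",
               "s1,1,1.0,45,40,60,6.1,120"), bp)
  ds1 <- read_branch_table(sp, bp)
  expect_equal(nrow(ds1$saplings), 1)
  expect_equal(nrow(ds1$branches), 1)
  expect_equal(ds1$branches$ocr_m, 0.4 * sin(pi / 3))

  # branch referencing an unknown sapling
  writeLines(c("sapling_id,whorl_index,l_m,bl_cm,bc_cm,va_deg,bd_mm,azimuth_deg",
               "ghost,1,1.0,45,40,60,6.1,120"), bp)
  expect_error(read_branch_table(sp, bp), "unknown sapling_id")

  # missing mandatory column
  writeLines(c("sapling_id,strip_type,dbh_cm,ht_m", "s1,uncut,2.0,2.5"), sp)
  expect_error(read_branch_table(sp, bp), "missing mandatory column")

  # non-numeric cell names the row
  writeLines(c("sapling_id,strip_type,dbh_cm,ht_m,cl_m",
               "s1,uncut,abc,2.5,2.0"), sp)
  expect_error(read_branch_table(sp, bp), "non-numeric value 'abc'.*row 1")
})

test_that("schema mapping renames file columns to the canonical names", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "s.csv"); bp <- file.path(dir, "b.csv")
  writeLines(c("tree,strip_type,DBH,ht_m,cl_m", "s1,uncut,2.0,2.5,2.0"), sp)
  writeLines(c("tree,whorl_index,l_m,bl_cm,bc_cm,va_deg,bd_mm,azimuth_deg",
               "s1,1,1.0,45,40,60,6.1,120"), bp)
  ds <- read_branch_table(sp, bp, schema = c(sapling_id = "tree", dbh_cm = "DBH"))
  expect_equal(ds$saplings$dbh_cm, 2.0)
})

test_that("write then read round-trips all numeric fields", {
  ds <- generate_stand(stand_config(
    n_saplings = c(shelterwood_cut = 4, uncut = 3), seed = 5))
  ds <- generate_growth_series(ds, growth_config(seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_branch_table(ds, dir)
  back <- read_branch_table(paths[["saplings"]], paths[["branches"]])
  for (col in c("dbh_cm", "ht_m", "cl_m")) {
    expect_equal(back$saplings[[col]], ds$saplings[[col]], tolerance = 1e-12)
  }
  for (col in c("l_m", "bc_cm", "va_deg", "rdinc", "ocr_m", "year_2013")) {
    expect_equal(back$branches[[col]], ds$branches[[col]], tolerance = 1e-12)
  }
})

test_that("largest-branch-per-whorl selection keeps the per-whorl maximum", {
  ds <- toy_dataset(rdinc = c(0.5, 0.5, 0.5, 0.8),
                    ocr_m = c(0.2, 0.4, 0.3, 0.1))
  # toy_dataset gives each branch its own whorl; merge the first three
  ds$branches$whorl_index <- c(1, 1, 1, 2)
  out <- largest_branch_per_whorl(ds)
  expect_equal(nrow(out$branches), 2)
  expect_equal(out$branches$ocr_m[1], 0.4)

  # tie on ocr broken by larger branch diameter
  ds2 <- toy_dataset(rdinc = c(0.5, 0.5), ocr_m = c(0.3, 0.3))
  ds2$branches$whorl_index <- c(1, 1)
  ds2$branches$bd_mm <- c(6, 8)
  out2 <- largest_branch_per_whorl(ds2)
  expect_equal(out2$branches$bd_mm, 8)

  # single-branch whorls are identity; output size = distinct (sapling, whorl)
  ds3 <- generate_stand(stand_config(
    n_saplings = c(shelterwood_cut = 3, uncut = 2), seed = 9))
  out3 <- largest_branch_per_whorl(ds3)
  key <- unique(paste(ds3$branches$sapling_id, ds3$branches$whorl_index))
  expect_equal(nrow(out3$branches), length(key))
})

test_that("validation policies route out-of-range relative depths", {
  ds <- toy_dataset(rdinc = c(0.5, 1.05, -0.02), ocr_m = c(0.3, 0.2, 0.25))
  # toy back-solving keeps rdinc exact, including the out-of-range values
  expect_equal(ds$branches$rdinc, c(0.5, 1.05, -0.02), tolerance = 1e-12)

  dropped <- validate_dataset(ds, policy = "drop")
  expect_equal(nrow(dropped$branches), 1)
  expect_equal(nrow(validation_report(dropped)), 2)
  expect_setequal(validation_report(dropped)$rule,
                  c("rdinc_above_1", "rdinc_below_0"))

  clipped <- validate_dataset(ds, policy = "clip")
  expect_equal(nrow(clipped$branches), 3)
  expect_equal(sort(clipped$branches$rdinc), c(0, 0.5, 1))
  # clipped dinc stays consistent with rdinc * cl
  expect_equal(clipped$branches$dinc_m, clipped$branches$rdinc * 2)

  expect_error(validate_dataset(ds, policy = "fail"), "violate rdinc")

  clean <- toy_dataset(rdinc = c(0.4, 0.9), ocr_m = c(0.3, 0.2))
  out <- validate_dataset(clean, policy = "drop")
  expect_equal(nrow(out$branches), 2)
  expect_equal(nrow(validation_report(out)), 0)
})

test_that("unit confusion (ocr exceeding branch length) is flagged not altered", {
  ds <- toy_dataset(rdinc = 0.5, ocr_m = 0.3)
  ds$branches$bl_cm <- 20  # 0.2 m branch cannot carry a 0.3 m radius
  out <- validate_dataset(ds, policy = "clip")
  expect_true("ocr_exceeds_bl" %in% validation_report(out)$rule)
  expect_equal(out$branches$ocr_m, 0.3)
})

test_that("manually excluded saplings are removed with their branches", {
  sap <- data.frame(sapling_id = c("a", "b"), strip_type = "uncut",
                    dbh_cm = 2, ht_m = 2.5, cl_m = 2,
                    excluded_flag = c(FALSE, TRUE))
  br <- data.frame(sapling_id = c("a", "b"), whorl_index = 1,
                   l_m = 1, bl_cm = 40, bc_cm = 40, va_deg = 90,
                   bd_mm = 5, azimuth_deg = 0)
  ds <- crown_dataset(sap, br)
  expect_equal(ds$saplings$sapling_id, "a")
  expect_equal(ds$branches$sapling_id, "a")
})
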