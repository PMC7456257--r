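# In-code fixtures shared across test files.

# Minimal one-sapling dataset whose branch radii are exactly `ocr_m` at
# relative depths `rdinc` (back-solved with a 90-degree branch angle so
# derive_branch_geometry reproduces them bit-exactly).
toy_dataset <- function(rdinc, ocr_m, dbh = 2, ht = 2.5, cl = 2,
                        strip = "uncut", id = "s1") {
  stopifnot(length(rdinc) == length(ocr_m))
  sap <- data.frame(sapling_id = id, strip_type = strip,
                    dbh_cm = dbh, ht_m = ht, cl_m = cl)
  br <- data.frame(sapling_id = id, whorl_index = seq_along(rdinc),
                   l_m = rdinc * cl, bl_cm = ocr_m * 100,
                   bc_cm = ocr_m * 100, va_deg = 90,
                   bd_mm = 5, azimuth_deg = 0)
  crown_dataset(sap, br)
}

# Multi-sapling dataset from per-sapling covariates and a radius generator
# g(dbh, cr, rdinc); used for regression-fit tests.
profile_dataset <- function(n_sapling, n_branch, g, seed = 1,
                            strip = "uncut") {
  set.seed(seed)
  saps <- list(); brs <- list()
  for (i in seq_len(n_sapling)) {
    id <- sprintf("t%02d", i)
    dbh <- runif(1, 1, 4); ht <- runif(1, 1.8, 3.2); cr <- runif(1, 0.6, 0.9)
    cl <- cr * ht
    rdinc <- seq(0.05, 1, length.out = n_branch)
    ocr <- g(dbh, cr, rdinc)
    saps[[i]] <- data.frame(sapling_id = id, strip_type = strip,
                            dbh_cm = dbh, ht_m = ht, cl_m = cl)
    brs[[i]] <- data.frame(sapling_id = id, whorl_index = seq_along(rdinc),
                           l_m = rdinc * cl, bl_cm = pmax(ocr, 1e-3) * 100,
                           bc_cm = pmax(ocr, 1e-3) * 100, va_deg = 90,
                           bd_mm = 5, azimuth_deg = 0)
  }
  crown_dataset(do.call(rbind, saps), do.call(rbind, brs))
}

# Brute-force minimal-area polynomial envelope for degree <= 1: enumerate
# all constraint-pair vertices (and single-point horizontals for degree 0),
# keep the feasible candidate of smallest area. Independent of the LP code.
brute_force_frontier <- function(x, y, degree, support = c(0, 1)) {
  stopifnot(degree <= 1)
  feasible <- function(theta) {
    phi <- theta[1] + if (degree == 1) theta[2] * x else 0
    all(phi >= y - 1e-9)
  }
  area <- function(theta) {
    a <- support[1]; b <- support[2]
    theta[1] * (b - a) + if (degree == 1) theta[2] * (b^2 - a^2) / 2 else 0
  }
  best <- NULL
  if (degree == 0) {
    cand <- list(max(y))
  } else {
    cand <- list()
    n <- length(x)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(x[i] - x[j]) < 1e-12) next
      s <- (y[j] - y[i]) / (x[j] - x[i])
      cand[[length(cand) + 1]] <- c(y[i] - s * x[i], s)
    }
    for (i in seq_len(n)) cand[[length(cand) + 1]] <- c(y[i], 0)
  }
  for (theta in cand) {
    if (!feasible(theta)) next
    if (is.null(best) || area(theta) < area(best) - 1e-12) best <- theta
  }
  best
}

ref_cut <- function() reference_params("shelterwood_cut")
ref_uncut <- function() reference_params("uncut")
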