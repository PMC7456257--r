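# Synthetic sapling stands with a known outermost-crown envelope.
#
# The generator draws whole-tree attributes from truncated normals matched
# to the study's per-strip summary statistics, places branch whorls at a
# fixed vertical spacing, sets each branch's *true* envelope radius from a
# power-exponential profile, and depletes it one-sidedly with a
# multiplicative Beta(alpha, beta) factor on (0, 1]: observations lie on or
# below the envelope, as the outermost-profile concept requires.

.strip_pair <- function(x, strips) {
  if (length(x) == 1) x <- rep(x, length(strips))
  if (is.null(names(x))) names(x) <- strips
  x[strips]
}

#' Configuration of a synthetic sapling stand
#'
#' Defaults reproduce the study conditions: 49 shelterwood-cut and 30 uncut
#' saplings with DBH, HT, crown ratio and branch-angle distributions matched
#' to the published per-strip means and standard deviations (DBH truncated
#' to the (0.5, 5.0) cm sampling window, HT to above 1.3 m, VA to (5, 160)
#' degrees), and the published selected-quantile power-exponential
#' coefficient rows as the true crown envelopes.
#'
#' @param n_saplings Named count per strip
#'   (`c(shelterwood_cut = 49, uncut = 30)`).
#' @param dbh_mean,dbh_sd DBH distribution (cm) per strip.
#' @param ht_mean,ht_sd Total height distribution (m) per strip.
#' @param cr_mean,cr_sd Crown ratio distribution per strip (truncated to
#'   (0.2, 1]).
#' @param va_mean,va_sd Branch insertion angle (degrees) per strip.
#' @param envelope_params Named list of [profile_params] (form
#'   `power_exp_full`) per strip: the generative envelope truth.
#' @param whorl_spacing Vertical distance between whorls (m).
#' @param branches_per_whorl Integer range `c(min, max)`; per-whorl branch
#'   counts are drawn uniformly from it.
#' @param noise_alpha,noise_beta Shape parameters of the Beta depletion
#'   factor `u` with observed radius `= u *` envelope radius.
#' @param seed Integer RNG seed.
#' @return A list of class `stand_config`.
#' @export
stand_config <- function(n_saplings = c(shelterwood_cut = 49, uncut = 30),
                         dbh_mean = c(2.46, 1.36), dbh_sd = c(0.99, 0.54),
                         ht_mean = c(2.40, 2.18), ht_sd = c(0.59, 0.49),
                         cr_mean = c(0.771, 0.739), cr_sd = c(0.08, 0.08),
                         va_mean = c(62, 73), va_sd = c(17, 14),
                         envelope_params = NULL,
                         whorl_spacing = 0.15,
                         branches_per_whorl = c(2L, 4L),
                         noise_alpha = 4, noise_beta = 1.5,
                         seed = 1L) {
  strips <- .strip_levels
  if (is.null(envelope_params)) {
    envelope_params <- list(
      shelterwood_cut = reference_params("shelterwood_cut"),
      uncut = reference_params("uncut"))
  }
  cfg <- list(
    n_saplings = .strip_pair(n_saplings, strips),
    dbh_mean = .strip_pair(dbh_mean, strips), dbh_sd = .strip_pair(dbh_sd, strips),
    ht_mean = .strip_pair(ht_mean, strips), ht_sd = .strip_pair(ht_sd, strips),
    cr_mean = .strip_pair(cr_mean, strips), cr_sd = .strip_pair(cr_sd, strips),
    va_mean = .strip_pair(va_mean, strips), va_sd = .strip_pair(va_sd, strips),
    envelope_params = envelope_params,
    whorl_spacing = whorl_spacing,
    branches_per_whorl = as.integer(branches_per_whorl),
    noise_alpha = noise_alpha, noise_beta = noise_beta,
    seed = as.integer(seed))
  stopifnot(all(cfg$dbh_sd >= 0), all(cfg$ht_sd >= 0), all(cfg$cr_sd >= 0),
            cfg$noise_alpha > 0, cfg$noise_beta > 0,
            all(cfg$cr_mean > 0), all(cfg$cr_mean <= 1),
            cfg$whorl_spacing > 0,
            length(cfg$branches_per_whorl) == 2)
  class(cfg) <- "stand_config"
  cfg
}

# Truncated-normal draws by rejection; falls back to the bound midpoint
# when sd = 0 places the mean outside (lo, hi).
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lo & draw < hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic sapling stand
#'
#' Draws saplings and branches per [stand_config()]. For each branch at
#' relative depth `rdinc` the true envelope radius is
#' `r* = eval_profile(envelope, dbh, cr, rdinc)` and the observed radius is
#' `ocr = r* * u`, `u ~ Beta(noise_alpha, noise_beta)`. The raw measurements
#' `(l, bc, va)` are back-solved so that [derive_branch_geometry()]
#' reproduces `(rdinc, ocr)` exactly:
#' `bc = ocr / sin(va)`, `l = rdinc * cl + bc * cos(va)`.
#' Identical seeds give identical datasets.
#'
#' @param config A [stand_config()].
#' @return A [crown_dataset]; each branch row carries the generative truth
#'   in columns `envelope_m` (true envelope radius) and `noise_u`.
#' @export
generate_stand <- function(config = stand_config()) {
  stopifnot(inherits(config, "stand_config"))
  set.seed(config$seed)
  grid <- seq(0.01, 1, by = 0.01)
  sap_list <- list(); br_list <- list()
  for (strip in .strip_levels) {
    env <- config$envelope_params[[strip]]
    test_r <- eval_profile(env, dbh = 2, cr = 0.8, rdinc = grid)
    if (any(!is.finite(test_r)) || any(test_r < 0)) {
      stop("envelope_params yield negative or non-finite radii on (0, 1)",
           call. = FALSE)
    }
    n <- config$n_saplings[[strip]]
    if (n == 0) next
    dbh <- .rtruncnorm(n, config$dbh_mean[[strip]], config$dbh_sd[[strip]], 0.5, 5.0)
    ht <- .rtruncnorm(n, config$ht_mean[[strip]], config$ht_sd[[strip]], 1.3, Inf)
    cr <- .rtruncnorm(n, config$cr_mean[[strip]], config$cr_sd[[strip]], 0.2, 1)
    cl <- cr * ht
    ids <- sprintf("%s_%03d", ifelse(strip == "shelterwood_cut", "cut", "unc"),
                   seq_len(n))
    sap_list[[strip]] <- data.frame(
      sapling_id = ids, strip_type = strip,
      dbh_cm = dbh, ht_m = ht, cl_m = cl, excluded_flag = FALSE)
    for (i in seq_len(n)) {
      n_whorls <- max(1L, floor(cl[i] / config$whorl_spacing))
      dinc <- config$whorl_spacing * seq_len(n_whorls)
      dinc <- dinc[dinc <= cl[i] + 1e-12]
      if (!length(dinc)) dinc <- cl[i]
      rd <- pmin(dinc / cl[i], 1)
      nb <- sample(seq(config$branches_per_whorl[1], config$branches_per_whorl[2]),
                   length(rd), replace = TRUE)
      whorl <- rep(seq_along(rd), nb)
      rdinc <- rd[whorl]
      r_env <- eval_profile(env, dbh = dbh[i], cr = cr[i], rdinc = rdinc)
      u <- stats::rbeta(length(rdinc), config$noise_alpha, config$noise_beta)
      ocr <- r_env * u
      va <- .rtruncnorm(length(rdinc), config$va_mean[[strip]],
                        config$va_sd[[strip]], 5, 160)
      # keep the back-solved tip distance nonnegative: flatten the angle
      # towards 90 deg where a steep down-swept branch would imply l < 0
      bc_m <- ocr / sin(va * pi / 180)
      l <- rdinc * cl[i] + bc_m * cos(va * pi / 180)
      bad <- which(l < 0)
      if (length(bad)) {
        va[bad] <- 90
        bc_m[bad] <- ocr[bad]
        l[bad] <- rdinc[bad] * cl[i]
      }
      bc_cm <- bc_m * 100
      bl_cm <- bc_cm * stats::runif(length(bc_cm), 1.0, 1.15)
      bd_mm <- pmax(1, 23 * ocr + stats::rnorm(length(ocr), 0, 1.5))
      br_list[[paste(strip, i)]] <- data.frame(
        sapling_id = ids[i], whorl_index = whorl,
        l_m = l, bl_cm = bl_cm, bc_cm = bc_cm, va_deg = va,
        bd_mm = bd_mm, azimuth_deg = stats::runif(length(ocr), 0, 360),
        envelope_m = r_env, noise_u = u)
    }
  }
  if (!length(sap_list)) {
    sap <- data.frame(sapling_id = character(0), strip_type = character(0),
                      dbh_cm = numeric(0), ht_m = numeric(0),
                      cl_m = numeric(0), excluded_flag = logical(0))
    br <- data.frame(sapling_id = character(0), whorl_index = integer(0),
                     l_m = numeric(0), bl_cm = numeric(0), bc_cm = numeric(0),
                     va_deg = numeric(0), bd_mm = numeric(0),
                     azimuth_deg = numeric(0))
    return(crown_dataset(sap, br, provenance = "synthetic stand (empty)"))
  }
  ds <- crown_dataset(do.call(rbind, sap_list), do.call(rbind, br_list),
                      provenance = sprintf("synthetic stand, seed %d", config$seed))
  rownames(ds$saplings) <- NULL
  rownames(ds$branches) <- NULL
  ds
}

#' Configuration of synthetic annual branch growth
#'
#' Emulates the structure of the study's branch-length growth series: equal
#' per-strip growth rates before the treatment year, strip-specific rates
#' afterwards. Defaults follow the published 2013/2014 means (11.2/11.5 and
#' 12.9/14.0 cm for cut/uncut) with the later divergence-then-crossing
#' pattern: the uncut lead widens to 2015, after which the cut strip
#' overtakes.
#'
#' @param years Consecutive calendar years covered by the series.
#' @param treatment_year First year affected by the treatment.
#' @param pre_treatment_rate_mean Mean annual increment (cm/yr) common to
#'   both strips before `treatment_year`.
#' @param post_treatment_rates Named list `year -> c(shelterwood_cut, uncut)`
#'   mean increments (cm/yr).
#' @param rate_sd Between-branch standard deviation (cm/yr).
#' @param seed Integer RNG seed.
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(years = 2013:2017,
                          treatment_year = 2014,
                          pre_treatment_rate_mean = 11.35,
                          post_treatment_rates = list(
                            `2014` = c(shelterwood_cut = 12.9, uncut = 14.0),
                            `2015` = c(shelterwood_cut = 13.6, uncut = 15.8),
                            `2016` = c(shelterwood_cut = 16.5, uncut = 14.6),
                            `2017` = c(shelterwood_cut = 18.5, uncut = 14.9)),
                          rate_sd = 2.5, seed = 1L) {
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("years must be consecutive", call. = FALSE)
  }
  post_years <- years[years >= treatment_year]
  miss <- setdiff(as.character(post_years), names(post_treatment_rates))
  if (length(miss)) {
    stop("post_treatment_rates missing year(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (pre_treatment_rate_mean <= 0 ||
      any(unlist(post_treatment_rates) <= 0)) {
    stop("growth rate means must be positive", call. = FALSE)
  }
  structure(list(years = years, treatment_year = as.integer(treatment_year),
                 pre_treatment_rate_mean = pre_treatment_rate_mean,
                 post_treatment_rates = post_treatment_rates,
                 rate_sd = rate_sd, seed = as.integer(seed)),
            class = "growth_config")
}

#' Attach synthetic annual branch-length growth to a stand
#'
#' Selects one sample branch per sapling — from the fifth whorl where
#' present, mirroring the study's 5-year-old sample branch, otherwise the
#' whorl nearest the fifth — and assigns its annual length increments (cm)
#' as `year_YYYY` columns: normal draws truncated at zero around the
#' per-strip, per-year means of the [growth_config()].
#'
#' @param dataset A [crown_dataset] with at least one sapling per strip.
#' @param config A [growth_config()].
#' @return The dataset with `year_YYYY` columns added (NA for non-sample
#'   branches).
#' @export
generate_growth_series <- function(dataset, config = growth_config()) {
  stopifnot(inherits(dataset, "crown_dataset"), inherits(config, "growth_config"))
  cnt <- dataset_counts(dataset)
  if (nrow(cnt) == 0 || any(cnt$n_saplings < 1)) {
    stop("dataset needs at least one sapling per strip", call. = FALSE)
  }
  set.seed(config$seed)
  br <- dataset$branches
  year_cols <- sprintf("year_%d", config$years)
  for (yc in year_cols) br[[yc]] <- NA_real_
  for (i in seq_len(nrow(dataset$saplings))) {
    id <- dataset$saplings$sapling_id[i]
    strip <- dataset$saplings$strip_type[i]
    rows <- which(br$sapling_id == id)
    if (!length(rows)) next
    whorls <- br$whorl_index[rows]
    target <- rows[which.min(abs(whorls - 5L))]
    for (k in seq_along(config$years)) {
      yr <- config$years[k]
      mu <- if (yr < config$treatment_year) config$pre_treatment_rate_mean
            else config$post_treatment_rates[[as.character(yr)]][[strip]]
      br[[year_cols[k]]][target] <-
        .rtruncnorm(1, mu, config$rate_sd, lo = 0)
    }
  }
  out <- dataset
  out$branches <- br
  out
}
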