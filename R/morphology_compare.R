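# Crown-morphology metrics and between-strip comparisons.

#' Crown morphology metrics across sapling size, by strip
#'
#' For each strip's selected-quantile profile parameters and each DBH on a
#' grid, computes the depth of the largest radius ([inflection_point()]),
#' the largest crown radius, and the upper-crown volume (rotational
#' integral over `[0, inflection]`, see [crown_volume()]), all at a fixed
#' crown ratio — the study fixes CR at 0.80, approximately the sample mean.
#' Differences are tabulated as uncut minus shelterwood-cut, so the table
#' is antisymmetric under swapping the strip labels.
#'
#' @param params_by_strip Named list with elements `shelterwood_cut` and
#'   `uncut`, each a [profile_params] of form `power_exp_full`.
#' @param dbh_grid DBH evaluation grid (cm); default 0.5 to 5.0 by 0.1.
#' @param cr Fixed crown ratio (default 0.80).
#' @param cl Crown length (m) used to scale volumes (default 1.76, the
#'   pooled mean crown length of the study's samples); the same value is
#'   used for both strips so volume differences reflect profile shape only.
#' @return List of class `strip_comparison`: `metrics` (long data.frame:
#'   `strip_type`, `dbh_cm`, `inflection_rdinc`, `largest_radius_m`,
#'   `upper_volume_m3`) and `differences` (per DBH, uncut minus cut;
#'   `d_upper_volume_rel` is the proportional volume difference
#'   `(V_uncut - V_cut) / V_cut`). For the power-exponential form the
#'   volume ratio scales as `DBH^(2 * (a2_uncut - a2_cut))`, so the
#'   proportional difference is monotone in DBH whenever the two strips'
#'   DBH exponents differ — the size trend of the volume contrast is read
#'   from this column; the absolute difference in cubic metres need not be
#'   monotone.
#' @export
crown_metrics_table <- function(params_by_strip,
                                dbh_grid = seq(0.5, 5.0, by = 0.1),
                                cr = 0.80, cl = 1.76) {
  stopifnot(all(c("shelterwood_cut", "uncut") %in% names(params_by_strip)))
  one_strip <- function(strip) {
    p <- params_by_strip[[strip]]
    ip <- as.numeric(inflection_point(p, cr = cr))
    data.frame(
      strip_type = strip, dbh_cm = dbh_grid,
      inflection_rdinc = ip,
      largest_radius_m = vapply(dbh_grid, function(d)
        largest_crown_radius(p, dbh = d, cr = cr), 1),
      upper_volume_m3 = vapply(dbh_grid, function(d)
        crown_volume(profile_radius_fn(p, dbh = d, cr = cr), cl = cl,
                     region = c(0, ip)), 1))
  }
  cut <- one_strip("shelterwood_cut")
  unc <- one_strip("uncut")
  differences <- data.frame(
    dbh_cm = dbh_grid,
    d_inflection = unc$inflection_rdinc - cut$inflection_rdinc,
    d_largest_radius_m = unc$largest_radius_m - cut$largest_radius_m,
    d_upper_volume_m3 = unc$upper_volume_m3 - cut$upper_volume_m3,
    d_upper_volume_rel = unc$upper_volume_m3 / cut$upper_volume_m3 - 1)
  structure(list(metrics = rbind(cut, unc), differences = differences,
                 cr = cr, cl = cl),
            class = "strip_comparison")
}

#' @export
print.strip_comparison <- function(x, ...) {
  cat("<strip_comparison> at CR =", x$cr, "\n")
  d <- x$differences
  mid <- d[which.min(abs(d$dbh_cm - 2)), ]
  cat(sprintf("  at DBH = %.1f cm: d(inflection) = %.3f, d(largest radius) = %.3f m, d(volume) = %.4f m3 (uncut - cut)\n",
              mid$dbh_cm, mid$d_inflection, mid$d_largest_radius_m,
              mid$d_upper_volume_m3))
  invisible(x)
}

#' Compare annual branch-length growth between strips
#'
#' Per calendar year, summarises the annual branch-length increments of the
#' sample branches (the `year_YYYY` columns) by strip and tests the
#' between-strip difference with a two-sided Welch two-sample t-test (the
#' study reports per-year significance without naming a test; unequal
#' variances are plausible between treatments). Unadjusted p-values are the
#' primary report — one planned comparison per year — with a Holm-adjusted
#' column added for transparency.
#'
#' @param dataset A [crown_dataset] whose branches carry `year_YYYY`
#'   columns (see [generate_growth_series()] or the CSV dialect).
#' @param years Optional integer vector restricting the years compared.
#' @return data.frame of class `growth_summary`: per year and strip, `mean`
#'   (cm), `sd`, `n`, and per year `p_value` and `p_holm` (NA when a strip
#'   has fewer than 2 sample branches that year).
#' @export
annual_growth_compare <- function(dataset, years = NULL) {
  stopifnot(inherits(dataset, "crown_dataset"))
  br <- dataset$branches
  year_cols <- grep("^year_\\d{4}$", names(br), value = TRUE)
  if (!length(year_cols)) stop("dataset has no year_YYYY growth columns", call. = FALSE)
  all_years <- as.integer(sub("year_", "", year_cols))
  if (!is.null(years)) {
    keep <- all_years %in% years
    year_cols <- year_cols[keep]; all_years <- all_years[keep]
  }
  idx <- match(br$sapling_id, dataset$saplings$sapling_id)
  strip <- dataset$saplings$strip_type[idx]
  out <- list(); pvals <- numeric(0)
  for (k in seq_along(year_cols)) {
    vals <- br[[year_cols[k]]]
    x <- vals[strip == "shelterwood_cut" & !is.na(vals)]
    y <- vals[strip == "uncut" & !is.na(vals)]
    p <- NA_real_
    if (length(x) >= 2 && length(y) >= 2) {
      p <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                    error = function(e) {
                      # degenerate zero-variance samples: decide by the means
                      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
                    })
    }
    pvals[as.character(all_years[k])] <- p
    out[[k]] <- data.frame(
      year = all_years[k],
      strip_type = c("shelterwood_cut", "uncut"),
      mean_increment_cm = c(mean(x), mean(y)),
      sd_cm = c(stats::sd(x), stats::sd(y)),
      n = c(length(x), length(y)),
      p_value = p)
  }
  res <- do.call(rbind, out)
  holm <- stats::p.adjust(pvals, method = "holm")
  res$p_holm <- holm[as.character(res$year)]
  class(res) <- c("growth_summary", "data.frame")
  res
}

#' Write a self-contained analysis report
#'
#' Collects pipeline outputs into one directory: `metrics.csv` and
#' `growth.csv` tables, `params.json` (fitted coefficient vectors per strip
#' and quantile, in `a1..a5` order), `selection.json` and per-strip
#' distance-matrix CSVs, profile and growth figures (PNG), and `run.log`
#' with seeds, package versions and a configuration hash. Stages whose
#' output is absent are listed as gaps in the log rather than failing the
#' report.
#'
#' @param out_dir Output directory (created if needed).
#' @param dataset,grid_fits,selections,metrics,growth Optional pipeline
#'   outputs: the [crown_dataset], a named list of `quantile_grid` per
#'   strip, a named list of `quantile_selection` per strip, a
#'   `strip_comparison`, a `growth_summary`.
#' @param seed Seed used for the run (logged).
#' @param config Optional configuration object; its serialised hash is
#'   logged.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(out_dir, dataset = NULL, grid_fits = NULL,
                          selections = NULL, metrics = NULL, growth = NULL,
                          seed = NA_integer_, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  gaps <- character(0)
  if (!is.null(dataset)) {
    written <- c(written, write_branch_table(dataset, out_dir))
  } else gaps <- c(gaps, "dataset")
  if (!is.null(metrics)) {
    path <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics$metrics, path, row.names = FALSE, quote = FALSE)
    dpath <- file.path(out_dir, "metric_differences.csv")
    utils::write.csv(metrics$differences, dpath, row.names = FALSE, quote = FALSE)
    written <- c(written, path, dpath)
  } else gaps <- c(gaps, "metrics")
  if (!is.null(growth)) {
    path <- file.path(out_dir, "growth.csv")
    utils::write.csv(as.data.frame(growth), path, row.names = FALSE, quote = FALSE)
    written <- c(written, path)
    gpath <- file.path(out_dir, "growth.png")
    grDevices::png(gpath, width = 720, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    g <- as.data.frame(growth)
    cut <- g[g$strip_type == "shelterwood_cut", ]
    unc <- g[g$strip_type == "uncut", ]
    graphics::plot(cut$year, cut$mean_increment_cm, type = "b", pch = 16,
                   ylim = range(g$mean_increment_cm, na.rm = TRUE),
                   xlab = "year", ylab = "annual branch increment (cm)")
    graphics::lines(unc$year, unc$mean_increment_cm, type = "b", pch = 1, lty = 2)
    graphics::legend("topleft", c("shelterwood-cut", "uncut"),
                     pch = c(16, 1), lty = c(1, 2), bty = "n")
    written <- c(written, gpath)
  } else gaps <- c(gaps, "growth")
  if (!is.null(grid_fits)) {
    params <- lapply(grid_fits, function(gf) {
      fits <- gf$fits[!vapply(gf$fits, is.null, TRUE)]
      lapply(fits, function(f) unname(f$params$coefficients))
    })
    path <- file.path(out_dir, "params.json")
    jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA)
    written <- c(written, path)
  } else gaps <- c(gaps, "grid_fits")
  if (!is.null(selections)) {
    sel <- lapply(selections, function(s) list(
      strip = s$strip, tau_mean = s$tau_mean, tau_argmin = s$tau_argmin,
      per_sapling = s$per_sapling))
    path <- file.path(out_dir, "selection.json")
    jsonlite::write_json(sel, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, path)
    for (nm in names(selections)) {
      dpath <- file.path(out_dir, sprintf("distance_matrix_%s.csv", nm))
      utils::write.csv(selections[[nm]]$distance_matrix, dpath, quote = FALSE)
      written <- c(written, dpath)
    }
  } else gaps <- c(gaps, "selections")
  if (!is.null(metrics) || !is.null(grid_fits)) {
    fpath <- file.path(out_dir, "profiles.png")
    grDevices::png(fpath, width = 720, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    grid <- seq(0, 1, length.out = 401)
    first <- TRUE
    for (strip in c("shelterwood_cut", "uncut")) {
      p <- if (!is.null(metrics)) NULL else NULL
      # draw the selected curve per strip when selections + grid fits exist,
      # otherwise the reference parameter sets
      pp <- tryCatch({
        if (!is.null(selections) && !is.null(grid_fits) &&
            strip %in% names(selections) && strip %in% names(grid_fits)) {
          tau_lab <- sprintf("%.2f", selections[[strip]]$tau_argmin)
          grid_fits[[strip]]$fits[[tau_lab]]$params
        } else reference_params(strip)
      }, error = function(e) NULL)
      if (is.null(pp)) next
      r <- eval_profile(pp, dbh = 2, cr = 0.8, rdinc = grid)
      if (first) {
        graphics::plot(grid, r, type = "l", xlab = "RDINC",
                       ylab = "outer crown radius (m)", ylim = c(0, max(r) * 1.3))
        first <- FALSE
      } else graphics::lines(grid, r, lty = 2)
    }
    if (!first) {
      graphics::legend("topleft", c("shelterwood-cut", "uncut"),
                       lty = c(1, 2), bty = "n")
      written <- c(written, fpath)
    }
  }
  log_path <- file.path(out_dir, "run.log")
  cfg_hash <- if (is.null(config)) "none" else
    substr(.digest_obj(config), 1, 16)
  writeLines(c(
    sprintf("crownprofile %s | R %s",
            as.character(utils::packageVersion("crownprofile")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("seed: %s", seed),
    sprintf("config_hash: %s", cfg_hash),
    sprintf("sections_absent: %s",
            if (length(gaps)) paste(gaps, collapse = ", ") else "none")
  ), log_path)
  written <- c(written, log_path)
  invisible(written)
}

# Stable hash of an R object via its serialised representation.
.digest_obj <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}
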