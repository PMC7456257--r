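# Selecting the quantile whose regression curve best matches the
# nonparametric boundary of each sapling's branch-tip cloud.

#' Standard relative-depth evaluation grid
#'
#' The crown depth interval `[0, 1]` divided into `1/step` even intervals:
#' with the default step 1e-4, 10,001 grid points `0.0000, 0.0001, ...,
#' 1.0000`.
#'
#' @param step Grid spacing.
#' @return Numeric vector of grid points, endpoints included.
#' @export
rdinc_grid <- function(step = 1e-4) {
  seq(0, 1, by = step)
}

#' Mean absolute distance between two curves on a shared grid
#'
#' @param curve_a,curve_b Radii evaluated on the same grid (equal length).
#' @return Mean of `|curve_a - curve_b|` (m).
#' @export
curve_distance <- function(curve_a, curve_b) {
  if (length(curve_a) != length(curve_b)) {
    stop("curves must be evaluated on the same grid", call. = FALSE)
  }
  mean(abs(curve_a - curve_b))
}

#' Fit a per-sapling polynomial frontier for every sapling
#'
#' Runs [select_degree()] on each sapling's `(rdinc, ocr)` branch tips.
#'
#' @param dataset A [crown_dataset].
#' @param max_degree Passed to [select_degree()].
#' @return Named list `sapling_id -> frontier_fit`.
#' @export
fit_sapling_frontiers <- function(dataset, max_degree = 20L) {
  stopifnot(inherits(dataset, "crown_dataset"))
  ids <- dataset$saplings$sapling_id
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    br <- dataset$branches[dataset$branches$sapling_id == id, ]
    if (nrow(br) == 0) next
    out[[id]] <- select_degree(br$rdinc, br$ocr_m, max_degree = max_degree)
  }
  out
}

#' Select the best-matching quantile for one sapling
#'
#' Evaluates every fitted quantile curve at the sapling's covariates over
#' the relative-depth grid, clamps negative radii to zero, and returns the
#' quantile whose curve has the smallest mean absolute distance to the
#' sapling's frontier on the same grid. Ties are broken toward the larger
#' quantile (the outermost curve). Quantiles whose fit failed are skipped
#' with a warning.
#'
#' @param dbh,cr The sapling's covariates.
#' @param grid_fit A `quantile_grid` fitted on the sapling's strip.
#' @param frontier The sapling's boundary: a `frontier_fit` on its own
#'   branches, or — for self-consistency checks — a function of rdinc or a
#'   numeric vector of boundary radii already evaluated on `grid`.
#' @param grid Relative-depth evaluation grid (default [rdinc_grid()]).
#' @return List with `tau` (selected quantile), `distance` (m), and
#'   `distances` (named vector over the whole grid of quantiles).
#' @export
select_quantile_per_sapling <- function(dbh, cr, grid_fit, frontier,
                                        grid = rdinc_grid()) {
  stopifnot(inherits(grid_fit, "quantile_grid"))
  boundary <- if (inherits(frontier, "frontier_fit")) {
    eval_frontier(frontier, grid)
  } else if (is.function(frontier)) {
    frontier(grid)
  } else if (is.numeric(frontier) && length(frontier) == length(grid)) {
    frontier
  } else {
    stop("frontier must be a frontier_fit, a function, or radii on the grid",
         call. = FALSE)
  }
  boundary <- pmax(boundary, 0)
  ok <- !vapply(grid_fit$fits, is.null, TRUE)
  if (!any(ok)) stop("no successful quantile fits available", call. = FALSE)
  if (!all(ok)) {
    warning("skipping failed quantile fit(s) at tau = ",
            paste(names(grid_fit$fits)[!ok], collapse = ", "))
  }
  taus <- grid_fit$taus[ok]
  distances <- vapply(grid_fit$fits[ok], function(f) {
    curve <- pmax(eval_profile(f$params, dbh = dbh, cr = cr, rdinc = grid), 0)
    curve_distance(curve, boundary)
  }, 1)
  best <- max(taus[distances <= min(distances) + 1e-15])
  list(tau = best,
       distance = unname(distances[which(taus == best)]),
       distances = stats::setNames(distances, sprintf("%.2f", taus)))
}

#' Strip-level outermost-quantile selection
#'
#' Applies [select_quantile_per_sapling()] to every sapling of one strip and
#' summarises at the strip level in both ways the study's procedure can be
#' read: (i) `tau_mean` — the mean of the per-sapling best quantiles,
#' rounded to the quantile grid ("averaging all the outermost quantiles");
#' and (ii) `tau_argmin` — the quantile minimising the column mean of the
#' sapling-by-quantile distance matrix (the aggregate smallest-distance
#' criterion). Both are reported; they can differ, and no preference is
#' imposed.
#'
#' @param dataset A [crown_dataset] (will be restricted to `strip`).
#' @param grid_fit A `quantile_grid` fitted on that strip's branches.
#' @param strip `"shelterwood_cut"` or `"uncut"`.
#' @param frontiers Optional named list `sapling_id -> frontier_fit`;
#'   computed by [fit_sapling_frontiers()] when omitted.
#' @param max_degree Frontier degree search bound when `frontiers` is
#'   computed here.
#' @param grid Relative-depth evaluation grid.
#' @return An object of class `quantile_selection`: `strip`, `per_sapling`
#'   (data.frame `sapling_id`, `best_tau`, `distance`), `distance_matrix`
#'   (saplings x quantiles), `tau_mean`, `tau_argmin`, `taus`.
#' @export
select_strip_quantile <- function(dataset, grid_fit,
                                  strip = c("shelterwood_cut", "uncut"),
                                  frontiers = NULL, max_degree = 20L,
                                  grid = rdinc_grid()) {
  strip <- match.arg(strip)
  ds <- filter_strip(dataset, strip)
  if (nrow(ds$saplings) < 1) stop("no saplings in strip ", strip, call. = FALSE)
  if (is.null(frontiers)) frontiers <- fit_sapling_frontiers(ds, max_degree)
  ids <- ds$saplings$sapling_id
  rows <- list(); dist_rows <- list()
  for (i in seq_along(ids)) {
    fr <- frontiers[[ids[i]]]
    if (is.null(fr)) next
    sel <- select_quantile_per_sapling(ds$saplings$dbh_cm[i],
                                       crown_ratio(ds$saplings$cl_m[i],
                                                   ds$saplings$ht_m[i]),
                                       grid_fit, fr, grid = grid)
    rows[[ids[i]]] <- data.frame(sapling_id = ids[i], best_tau = sel$tau,
                                 distance = sel$distance)
    dist_rows[[ids[i]]] <- sel$distances
  }
  if (!length(rows)) stop("no sapling had a frontier fit", call. = FALSE)
  per_sapling <- do.call(rbind, rows)
  rownames(per_sapling) <- NULL
  dist_mat <- do.call(rbind, dist_rows)
  col_mean <- colMeans(dist_mat)
  taus_ok <- grid_fit$taus[match(colnames(dist_mat),
                                 sprintf("%.2f", grid_fit$taus))]
  tau_step <- if (length(grid_fit$taus) > 1) min(diff(grid_fit$taus)) else 0.01
  tau_mean <- round(round(mean(per_sapling$best_tau) / tau_step) * tau_step, 10)
  tau_argmin <- max(taus_ok[col_mean <= min(col_mean) + 1e-15])
  structure(list(strip = strip, per_sapling = per_sapling,
                 distance_matrix = dist_mat,
                 tau_mean = tau_mean, tau_argmin = tau_argmin,
                 taus = grid_fit$taus),
            class = "quantile_selection")
}

#' @export
print.quantile_selection <- function(x, ...) {
  cat(sprintf("<quantile_selection> strip %s, %d saplings\n",
              x$strip, nrow(x$per_sapling)))
  cat(sprintf("  mean of per-sapling best quantiles: %.2f\n", x$tau_mean))
  cat(sprintf("  aggregate smallest-distance quantile: %.2f\n", x$tau_argmin))
  if (!isTRUE(all.equal(x$tau_mean, x$tau_argmin))) {
    cat("  note: the two summary rules disagree; both are reported\n")
  }
  invisible(x)
}
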