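# End-to-end orchestration: data in, quantile-grid fits, boundary-based
# quantile selection, morphology comparison, report out.

#' Run the full outermost-crown-profile pipeline
#'
#' Chains the analysis stages on a dataset (synthetic by default): per-strip
#' nonlinear quantile regression over the quantile grid, per-sapling
#' polynomial frontiers with information-criterion degree choice, selection
#' of the strip-level outermost quantile, crown morphology metrics at fixed
#' crown ratio across sapling size, and (when growth columns are present)
#' the annual branch-growth comparison. Also fits the candidate mean models
#' (`power_exp_full`, `kozak_mod`) by OLS on the largest branch per whorl,
#' pooled over strips, and ranks them — the study's model-comparison step.
#'
#' @param dataset A [crown_dataset]; when `NULL`, one is generated from
#'   `stand_cfg` and `growth_cfg`.
#' @param stand_cfg A [stand_config()] used when `dataset` is `NULL`.
#' @param growth_cfg A [growth_config()] used when `dataset` is `NULL`;
#'   `NULL` skips growth simulation.
#' @param taus Quantile grid (default 0.50..0.99 step 0.01).
#' @param max_degree Frontier degree search bound.
#' @param cr,dbh_grid,cl Morphology evaluation settings, see
#'   [crown_metrics_table()].
#' @param seed Seed for fit multi-starts.
#' @param out_dir Optional report directory, see [render_report()].
#' @param n_starts Multi-start attempts per quantile fit.
#' @return List with `dataset`, `ols_comparison` (ranked `crown_fit`s),
#'   `grid_fits`, `selections`, `selected_params`, `metrics`, `growth`
#'   (or `NULL`), and `report_paths` when `out_dir` was given.
#' @export
run_crown_pipeline <- function(dataset = NULL,
                               stand_cfg = stand_config(),
                               growth_cfg = growth_config(),
                               taus = seq(0.5, 0.99, by = 0.01),
                               max_degree = 20L,
                               cr = 0.80, dbh_grid = seq(0.5, 5.0, by = 0.1),
                               cl = 1.76,
                               seed = 1L, out_dir = NULL, n_starts = 3L) {
  if (is.null(dataset)) {
    dataset <- generate_stand(stand_cfg)
    if (!is.null(growth_cfg)) {
      dataset <- generate_growth_series(dataset, growth_cfg)
    }
  }
  stopifnot(inherits(dataset, "crown_dataset"))
  ols_comparison <- tryCatch({
    fits <- list(
      power_exp_full = fit_ols("power_exp_full", dataset, seed = seed),
      kozak_mod = fit_ols("kozak_mod", dataset, seed = seed))
    compare_models(fits)
  }, error = function(e) {
    warning("OLS model comparison failed: ", conditionMessage(e))
    NULL
  })
  strips <- dataset_counts(dataset)$strip_type
  grid_fits <- list(); selections <- list(); selected_params <- list()
  for (strip in strips) {
    ds <- filter_strip(dataset, strip)
    gf <- fit_quantile_grid("power_exp_full", ds, taus = taus,
                            n_starts = n_starts, seed = seed)
    sel <- select_strip_quantile(dataset, gf, strip = strip,
                                 max_degree = max_degree)
    grid_fits[[strip]] <- gf
    selections[[strip]] <- sel
    selected_params[[strip]] <-
      gf$fits[[sprintf("%.2f", sel$tau_argmin)]]$params
  }
  metrics <- if (all(c("shelterwood_cut", "uncut") %in% names(selected_params))) {
    crown_metrics_table(selected_params, dbh_grid = dbh_grid, cr = cr, cl = cl)
  } else NULL
  growth <- if (any(grepl("^year_\\d{4}$", names(dataset$branches)))) {
    annual_growth_compare(dataset)
  } else NULL
  report_paths <- if (!is.null(out_dir)) {
    render_report(out_dir, dataset = dataset, grid_fits = grid_fits,
                  selections = selections, metrics = metrics, growth = growth,
                  seed = seed, config = list(taus = taus,
                                             max_degree = max_degree, cr = cr))
  } else NULL
  list(dataset = dataset, ols_comparison = ols_comparison,
       grid_fits = grid_fits, selections = selections,
       selected_params = selected_params, metrics = metrics,
       growth = growth, report_paths = report_paths)
}

#' Reproduce the study analysis from measurement CSVs
#'
#' Convenience entry for running the pipeline on field data in the
#' documented CSV dialect — e.g. tables derived from the study's
#' supplementary measurement data, saved as `saplings.csv`/`branches.csv`.
#'
#' @param saplings_path,branches_path CSV paths, see [read_branch_table()].
#' @param ... Passed to [run_crown_pipeline()].
#' @inheritParams read_branch_table
#' @return See [run_crown_pipeline()].
#' @export
reproduce_study <- function(saplings_path, branches_path, schema = NULL,
                            policy = "clip", ...) {
  ds <- read_branch_table(saplings_path, branches_path, schema = schema,
                          policy = policy)
  run_crown_pipeline(dataset = ds, ...)
}

#' Read a stand configuration from YAML
#'
#' Accepts a YAML file whose top-level keys are [stand_config()] arguments;
#' `envelope_params` entries are given as `{form: ..., coefficients: [...]}`
#' per strip.
#'
#' @param path YAML file path.
#' @return A [stand_config()].
#' @export
stand_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$envelope_params)) {
    raw$envelope_params <- lapply(raw$envelope_params, function(e)
      profile_params(e$form, as.numeric(e$coefficients)))
  }
  known <- names(formals(stand_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown stand_config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  flatten <- intersect(names(raw),
                       c("n_saplings", "dbh_mean", "dbh_sd", "ht_mean", "ht_sd",
                         "cr_mean", "cr_sd", "va_mean", "va_sd"))
  for (f in flatten) raw[[f]] <- unlist(raw[[f]])
  do.call(stand_config, raw)
}
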