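# Nonlinear least-squares fitting of crown profile forms, with the study's
# goodness-of-fit statistics.

.extract_fit_data <- function(dataset, branches = c("largest_per_whorl", "all")) {
  stopifnot(inherits(dataset, "crown_dataset"))
  branches <- match.arg(branches)
  if (branches == "largest_per_whorl") dataset <- largest_branch_per_whorl(dataset)
  br <- dataset$branches
  list(ocr = br$ocr_m, dbh = br$dbh_cm, cr = br$cr, rdinc = br$rdinc)
}

.default_init <- function(form, ocr) {
  m <- if (length(ocr)) mean(ocr) else 0.3
  switch(form,
    power_exp_basic = c(m, 1, -1),
    power_exp_full = c(m, 0.5, 1, -0.5, -1),
    kozak_basic = c(max(ocr, 0.3), 1, 0.7),
    kozak_mod = c(m, 0.5, 0.5, 1, 0.5),
    location = stats::median(ocr))
}

.safe_predict <- function(form, theta, dat) {
  p <- tryCatch(profile_params(form, theta), error = function(e) NULL)
  if (is.null(p)) return(rep(NA_real_, length(dat$ocr)))
  tryCatch(eval_profile(p, dbh = dat$dbh, cr = dat$cr, rdinc = dat$rdinc),
           error = function(e) rep(NA_real_, length(dat$ocr)))
}

.multi_starts <- function(init, n_starts, seed) {
  starts <- list(init)
  if (n_starts > 1) {
    set.seed(seed)
    for (k in seq_len(n_starts - 1L)) {
      fac <- stats::runif(length(init), 0.5, 2)
      pert <- init * fac
      pert[init == 0] <- stats::runif(sum(init == 0), -0.5, 0.5)
      starts[[k + 1L]] <- pert
    }
  }
  starts
}

.make_crown_fit <- function(form, theta, dat, method, tau = NA_real_,
                            converged = TRUE, loss = NULL) {
  pred <- .safe_predict(form, theta, dat)
  res <- dat$ocr - pred
  n <- length(dat$ocr)
  p <- length(theta)
  sst <- sum((dat$ocr - mean(dat$ocr))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  structure(list(
    params = profile_params(form, theta),
    method = method, tau = tau,
    r2 = r2,
    r2_adj = if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p),
    rmse = sqrt(sum(res^2) / (n - 1)),
    n_obs = n, n_params = p,
    converged = converged,
    loss_value = if (is.null(loss)) sum(res^2) else loss,
    residuals = res, fitted = pred
  ), class = "crown_fit")
}

#' @export
print.crown_fit <- function(x, ...) {
  lab <- if (x$method == "quantile") sprintf("quantile (tau = %.2f)", x$tau)
         else x$method
  cat(sprintf("<crown_fit> %s, form %s, n = %d\n", lab, x$params$form, x$n_obs))
  print(round(x$params$coefficients, 4))
  cat(sprintf("  R2adj = %.4f, RMSE = %.4f m, loss = %.6g, converged: %s\n",
              x$r2_adj, x$rmse, x$loss_value, x$converged))
  invisible(x)
}

#' Adjusted coefficient of determination
#'
#' `R2 = 1 - SSE/SST` (SST about the mean of the observations) and
#' `R2adj = 1 - (1 - R2) * (n - 1) / (n - p)`.
#'
#' @param obs,pred Observed and predicted radii (same length).
#' @param n_params Number of fitted parameters `p`.
#' @return `R2adj` (dimensionless). Scale-invariant: converting both inputs
#'   m to cm leaves it unchanged.
#' @examples
#' r2_adjusted(c(1, 2, 3), c(1, 2, 4), n_params = 1)  # 0.5
#' @export
r2_adjusted <- function(obs, pred, n_params) {
  n <- length(obs)
  stopifnot(length(pred) == n)
  if (n < n_params + 1) stop("need at least n_params + 1 observations", call. = FALSE)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("zero variance in observations: R2 undefined", call. = FALSE)
  r2 <- 1 - sum((obs - pred)^2) / sst
  1 - (1 - r2) * (n - 1) / (n - n_params)
}

#' Root mean square error with n - 1 denominator
#'
#' `RMSE = sqrt(sum((obs - pred)^2) / (n - 1))` with `n` the total number of
#' branches. Note the `n - 1` denominator — as the study defines it — rather
#' than the more common `n - p`.
#'
#' @param obs,pred Observed and predicted radii (same length, `n >= 2`).
#' @return RMSE in the unit of the inputs.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4))  # sqrt(0.5)
#' @export
rmse <- function(obs, pred) {
  n <- length(obs)
  stopifnot(length(pred) == n)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  sqrt(sum((obs - pred)^2) / (n - 1))
}

#' Fit a crown profile form by nonlinear least squares
#'
#' Minimises the residual sum of squares with Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) from multiple perturbed starts (multiplicative
#' `U(0.5, 2)` on the nonzero entries of the initial vector, seed-controlled)
#' and keeps the best solution. For candidate-model comparison the study's
#' protocol fits on the largest branch per whorl (`branches =
#' "largest_per_whorl"`, the default); `branches = "all"` uses every branch.
#'
#' @param form One of [profile_forms()].
#' @param dataset A [crown_dataset].
#' @param init Optional initial coefficient vector; defaults follow the
#'   published sign pattern (`a1 = mean(ocr)`, `a2 = 0.5`, `a3 = 1`,
#'   `a4 = -0.5`, `a5 = -1` for `power_exp_full`).
#' @param n_starts Number of multi-start attempts (default 20).
#' @param seed Seed for start perturbations.
#' @param branches `"largest_per_whorl"` or `"all"`.
#' @return A `crown_fit` object (coefficients, `r2`, `r2_adj`, `rmse`,
#'   residuals, convergence flag, SSE as `loss_value`).
#' @export
fit_ols <- function(form, dataset, init = NULL, n_starts = 20L, seed = 1L,
                    branches = c("largest_per_whorl", "all")) {
  form <- match.arg(form, names(.profile_forms))
  dat <- .extract_fit_data(dataset, match.arg(branches))
  npar <- .profile_forms[[form]]$npar
  if (length(dat$ocr) <= npar) {
    stop(sprintf("underdetermined fit: %d observation(s) for %d parameters",
                 length(dat$ocr), npar), call. = FALSE)
  }
  if (is.null(init)) init <- .default_init(form, dat$ocr)
  stopifnot(length(init) == npar)
  resid_fn <- function(theta) {
    r <- dat$ocr - .safe_predict(form, theta, dat)
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  any_ok <- FALSE
  for (start in .multi_starts(init, n_starts, seed)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fn(fit$par)^2)
    ok <- fit$info %in% 1:4 && all(is.finite(fit$par))
    any_ok <- any_ok || ok
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, ok = ok)
    }
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  if (!any_ok) {
    warning("no start converged; returning best attempt")
  }
  .make_crown_fit(form, best$par, dat, method = "ols",
                  converged = best$ok, loss = best$sse)
}

#' Rank competing profile fits
#'
#' Orders fits by `r2_adj` (descending), breaking ties by `rmse`
#' (ascending) — the study's model-selection rule ("largest R2adj, smallest
#' RMSE"). All fits must be on the same data.
#'
#' @param fits List of `crown_fit` objects.
#' @return The list reordered, best first.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "crown_fit")))
  n <- vapply(fits, function(f) f$n_obs, 1L)
  obs_sum <- vapply(fits, function(f) sum(f$fitted + f$residuals), 1)
  if (length(unique(n)) > 1 || diff(range(obs_sum)) > 1e-8 * max(1, abs(obs_sum[1]))) {
    stop("fits are not on the same dataset", call. = FALSE)
  }
  ord <- order(-vapply(fits, function(f) f$r2_adj, 1),
               vapply(fits, function(f) f$rmse, 1))
  fits[ord]
}
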