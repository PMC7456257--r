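# Crown profile model forms and derived crown metrics.
#
# All radii are in metres, DBH in cm, RDINC dimensionless in [0, 1]
# (0 = tree tip, 1 = crown base), CR = crown ratio = CL/HT.

.profile_forms <- list(
  power_exp_basic = list(
    npar = 3L, coef_names = c("a1", "a2", "a3"), uses_covariates = FALSE
  ),
  kozak_basic = list(
    npar = 3L, coef_names = c("c1", "c2", "p"), uses_covariates = FALSE
  ),
  power_exp_full = list(
    npar = 5L, coef_names = c("a1", "a2", "a3", "a4", "a5"), uses_covariates = TRUE
  ),
  kozak_mod = list(
    npar = 5L, coef_names = c("c1", "c2", "c3", "c4", "c5"), uses_covariates = TRUE
  ),
  location = list(
    npar = 1L, coef_names = "theta", uses_covariates = FALSE
  )
)

#' Crown profile model forms
#'
#' Names of the supported crown profile model forms:
#' \describe{
#'   \item{`power_exp_basic`}{`OCR = a1 * RDINC^a2 * exp(a3 * RDINC)` — the
#'     basic power-exponential crown radius equation.}
#'   \item{`kozak_basic`}{`OCR = c1 * X^c2` with
#'     `X = (1 - (1 - RDINC)^0.5) / (1 - p^0.5)` — a variable-exponent
#'     (Kozak-type) equation with nominal inflection parameter `p`.}
#'   \item{`power_exp_full`}{`OCR = a1 * DBH^a2 * RDINC^(a3 + a4*CR) *
#'     exp(a5 * RDINC)` — the power-exponential form reparameterised with
#'     sapling covariates DBH and crown ratio CR.}
#'   \item{`kozak_mod`}{`OCR = c1 * DBH^c2 * B^(c5 * (1 - RDINC))` with
#'     `B = (1 - (1 - RDINC)^0.5) / (1 - (c3 * CR^c4)^0.5)` — the modified
#'     Kozak-type form with covariates.}
#'   \item{`location`}{`OCR = theta` — a covariate-free constant, used for
#'     oracle checks of the quantile optimiser.}
#' }
#'
#' @return Character vector of form names.
#' @export
profile_forms <- function() names(.profile_forms)

#' Construct a set of crown profile parameters
#'
#' @param form One of [profile_forms()].
#' @param coefficients Numeric vector of model coefficients, in the fixed
#'   order documented in [profile_forms()] (e.g. `a1..a5` for
#'   `power_exp_full`).
#' @return An object of class `profile_params`.
#' @examples
#' profile_params("power_exp_full", c(0.4030, 0.4751, 1.1811, -0.5538, -0.9125))
#' @export
profile_params <- function(form, coefficients) {
  form <- match.arg(form, names(.profile_forms))
  info <- .profile_forms[[form]]
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != info$npar) {
    stop(sprintf("form '%s' needs %d coefficients, got %d",
                 form, info$npar, length(coefficients)), call. = FALSE)
  }
  if (anyNA(coefficients)) stop("coefficients must not contain NA", call. = FALSE)
  names(coefficients) <- info$coef_names
  structure(list(form = form, coefficients = coefficients),
            class = "profile_params")
}

#' @export
print.profile_params <- function(x, ...) {
  cat("<profile_params> form:", x$form, "\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

# Kozak base X = (1 - sqrt(1 - rdinc)) / (1 - sqrt(denom_arg)); shared by
# both Kozak-type forms. denom_arg must lie in (0, 1).
.kozak_base <- function(rdinc, denom_arg) {
  if (any(!is.finite(denom_arg)) || any(denom_arg <= 0) || any(denom_arg >= 1)) {
    stop("Kozak denominator base outside (0,1): the form requires ",
         "0 < p (or c3*CR^c4) < 1", call. = FALSE)
  }
  (1 - sqrt(pmax(1 - rdinc, 0))) / (1 - sqrt(denom_arg))
}

#' Evaluate a crown profile model
#'
#' Predicts the outer crown radius (m) at one or more relative crown depths.
#' Forms without covariates ignore `dbh` and `cr`.
#'
#' For `kozak_mod` the value at `rdinc = 1` is the limit `c1 * DBH^c2`
#' (exponent `c5 * (1 - RDINC)` vanishes there); this is what the printed
#' formula evaluates to and is computed directly.
#'
#' @param params A [profile_params] object.
#' @param dbh Diameter at breast height (cm); scalar or same length as `rdinc`.
#' @param cr Crown ratio (CL/HT, dimensionless in (0, 1]); scalar or same
#'   length as `rdinc`.
#' @param rdinc Relative depth into the crown, in `[0, 1]`; 0 at the tip.
#' @return Numeric vector of radii (m), same length as `rdinc`.
#' @examples
#' p <- profile_params("power_exp_full",
#'                     c(0.4030, 0.4751, 1.1811, -0.5538, -0.9125))
#' eval_profile(p, dbh = 2, cr = 0.8, rdinc = c(0, 0.5, 0.8088, 1))
#' @export
eval_profile <- function(params, dbh = NULL, cr = NULL, rdinc) {
  stopifnot(inherits(params, "profile_params"))
  if (any(rdinc < -1e-12 | rdinc > 1 + 1e-12, na.rm = TRUE)) {
    stop("rdinc must lie in [0, 1]", call. = FALSE)
  }
  rdinc <- pmin(pmax(rdinc, 0), 1)
  cf <- params$coefficients
  info <- .profile_forms[[params$form]]
  if (info$uses_covariates) {
    if (is.null(dbh) || is.null(cr)) {
      stop(sprintf("form '%s' requires dbh and cr", params$form), call. = FALSE)
    }
  }
  switch(params$form,
    power_exp_basic = {
      out <- cf[["a1"]] * rdinc^cf[["a2"]] * exp(cf[["a3"]] * rdinc)
      out[rdinc == 0 & cf[["a2"]] > 0] <- 0
      unname(out)
    },
    power_exp_full = {
      expo <- cf[["a3"]] + cf[["a4"]] * cr
      out <- cf[["a1"]] * dbh^cf[["a2"]] * rdinc^expo * exp(cf[["a5"]] * rdinc)
      zero <- rdinc == 0 & expo > 0
      out[zero] <- 0
      unname(out)
    },
    kozak_basic = {
      X <- .kozak_base(rdinc, cf[["p"]])
      unname(cf[["c1"]] * X^cf[["c2"]])
    },
    kozak_mod = {
      B <- .kozak_base(rdinc, cf[["c3"]] * cr^cf[["c4"]])
      expo <- cf[["c5"]] * (1 - rdinc)
      out <- cf[["c1"]] * dbh^cf[["c2"]] * B^expo
      at_base <- rdinc == 1
      if (any(at_base)) {
        scale <- cf[["c1"]] * dbh^cf[["c2"]]
        out[at_base] <- if (length(scale) > 1) scale[at_base] else scale
      }
      unname(out)
    },
    location = rep_len(unname(cf[["theta"]]), length(rdinc))
  )
}

#' Radius function of relative crown depth
#'
#' Convenience closure `f(rdinc)` for a fixed sapling, e.g. for
#' [crown_volume()].
#'
#' @inheritParams eval_profile
#' @return A function of one argument (`rdinc`).
#' @export
profile_radius_fn <- function(params, dbh = NULL, cr = NULL) {
  force(params); force(dbh); force(cr)
  function(rdinc) eval_profile(params, dbh = dbh, cr = cr, rdinc = rdinc)
}

#' Depth of the largest crown radius
#'
#' For the power-exponential forms the profile `A * t^b * exp(c*t)` with
#' `b > 0`, `c < 0` attains its maximum on `(0, 1]` at `t* = min(1, b / (-c))`
#' (set the derivative `A t^(b-1) e^(ct) (b + ct)` to zero). For
#' `power_exp_full`, `b = a3 + a4*CR` and `c = a5`, so the depth of maximum
#' radius is linear in CR. In this crown profile literature this depth is
#' called the *inflection point*: the relative depth where the modelled
#' profile reaches the largest crown radius (not a second-derivative
#' inflection).
#'
#' @param params A [profile_params] of form `power_exp_full` or
#'   `power_exp_basic`.
#' @param cr Crown ratio; required for `power_exp_full`, ignored otherwise.
#' @return The relative depth in `(0, 1]`; carries attribute
#'   `monotone = TRUE` when the profile has no interior maximum (`c >= 0`),
#'   in which case 1 is returned.
#' @examples
#' p <- profile_params("power_exp_full",
#'                     c(0.4030, 0.4751, 1.1811, -0.5538, -0.9125))
#' inflection_point(p, cr = 0.8)  # 0.8088
#' @export
inflection_point <- function(params, cr = NULL) {
  stopifnot(inherits(params, "profile_params"))
  cf <- params$coefficients
  bc <- switch(params$form,
    power_exp_full = {
      if (is.null(cr)) stop("power_exp_full requires cr", call. = FALSE)
      c(cf[["a3"]] + cf[["a4"]] * cr, cf[["a5"]])
    },
    power_exp_basic = c(cf[["a2"]], cf[["a3"]]),
    stop(sprintf("inflection_point is defined for power-exponential forms, not '%s'",
                 params$form), call. = FALSE)
  )
  b <- bc[1]; cc <- bc[2]
  if (b <= 0) stop("profile exponent (a3 + a4*cr) must be positive", call. = FALSE)
  if (cc >= 0) return(structure(1, monotone = TRUE))
  min(1, b / (-cc))
}

#' Largest crown radius
#'
#' Radius (m) of the profile at the depth returned by [inflection_point()];
#' for monotone profiles this is the radius at the crown base (`rdinc = 1`).
#'
#' @inheritParams eval_profile
#' @return Radius in metres.
#' @export
largest_crown_radius <- function(params, dbh = NULL, cr = NULL) {
  t_star <- inflection_point(params, cr = cr)
  eval_profile(params, dbh = dbh, cr = cr, rdinc = as.numeric(t_star))
}

#' Crown volume by rotational integral
#'
#' Volume of the solid of revolution of a crown radius profile about the
#' stem: `V = pi * CL * integral over region of r(t)^2 dt`, where `t` is the
#' relative depth RDINC and `CL` (m) converts relative depth to length. The
#' integral uses composite Simpson quadrature.
#'
#' The study's "upper crown" volume corresponds to
#' `region = c(0, inflection_point(...))` — tip down to the depth of the
#' largest radius.
#'
#' @param radius_fn Function mapping rdinc to radius (m), e.g.
#'   [profile_radius_fn()]; must be nonnegative on `region`.
#' @param cl Crown length (m).
#' @param region Integration interval within `[0, 1]`.
#' @param n Number of quadrature points (forced odd, minimum 2001).
#' @return Volume in cubic metres.
#' @examples
#' crown_volume(function(t) 0.3 * t, cl = 2)        # cone: pi*0.09*2/3
#' crown_volume(function(t) rep(0.3, length(t)), 2) # cylinder: pi*0.09*2
#' @export
crown_volume <- function(radius_fn, cl, region = c(0, 1), n = 2001L) {
  stopifnot(is.function(radius_fn), cl >= 0, length(region) == 2)
  a <- region[1]; b <- region[2]
  if (b <= a) return(0)
  n <- max(as.integer(n), 2001L)
  if (n %% 2L == 0L) n <- n + 1L
  t <- seq(a, b, length.out = n)
  y <- radius_fn(t)^2
  if (any(!is.finite(y))) stop("radius_fn returned non-finite values on region", call. = FALSE)
  h <- (b - a) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  integral <- h / 3 * sum(w * y)
  pi * cl * integral
}

#' Published crown profile parameter sets
#'
#' Coefficient rows of the study's Table of power-exponential
#' (`power_exp_full`) fits for naturally regenerated *Pinus tabuliformis*
#' saplings: ordinary least squares and nonlinear quantile regression at
#' q = 0.75, 0.85, 0.95, 0.99 plus the boundary-selected quantiles
#' (q = 0.88 for the shelterwood-cut strip, q = 0.92 for the uncut strip),
#' shipped as a packaged JSON fixture.
#'
#' @param strip `"shelterwood_cut"` or `"uncut"`.
#' @param fit `"ols"`, `"selected"`, or a quantile label such as `"q0.75"`.
#' @return A [profile_params] object with attributes `std` (reported
#'   standard errors) and `tau` (the quantile, `NA` for OLS).
#' @export
reference_params <- function(strip = c("shelterwood_cut", "uncut"),
                             fit = "selected") {
  strip <- match.arg(strip)
  path <- system.file("extdata", "reference_params.json",
                      package = "crownprofile", mustWork = TRUE)
  tab <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rows <- tab[[strip]]
  if (identical(fit, "selected")) fit <- rows$selected
  if (!fit %in% names(rows$fits)) {
    stop(sprintf("no fit '%s' for strip '%s'; available: %s",
                 fit, strip, paste(names(rows$fits), collapse = ", ")),
         call. = FALSE)
  }
  entry <- rows$fits[[fit]]
  p <- profile_params("power_exp_full", entry$estimates)
  attr(p, "std") <- entry$std
  attr(p, "tau") <- if (identical(fit, "ols")) NA_real_ else
    as.numeric(sub("^q", "", fit))
  p
}
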