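# Polynomial frontier (boundary) estimation of branch-tip clouds.
#
# The frontier phi(x) = theta0 + theta1*x + ... + thetap*x^p minimises the
# enclosed area integral over the support subject to lying on or above
# every data point — a linear program in theta:
#
#   min c'theta  s.t.  V theta >= y,  theta free,
#
# with V the n x (p+1) design power matrix and c_k the monomial areas
# (b^(k+1) - a^(k+1))/(k+1). The coefficients are sign-free, so the LP is
# solved through its dual
#
#   max y'lambda  s.t.  V'lambda = c,  lambda >= 0,
#
# a standard-form program with p+1 equality rows, by a dense two-phase
# simplex (Bland's rule, so it cannot cycle). The optimal dual basis names
# the p+1 active (supporting) data points; theta solves V_B theta = y_B on
# that basis, where V_B is nonsingular because basis columns are linearly
# independent by the simplex invariant.

# Dense tableau simplex step: minimise cost over the current tableau.
# Tab is m x (ntot+1) with the RHS in the last column and an identity on
# the basis columns. Returns status 0 = optimal, 1 = unbounded, 2 = maxit.
.simplex_core <- function(Tab, basis, cost, maxit = 50000L, tol = 1e-11) {
  m <- nrow(Tab); ntot <- ncol(Tab) - 1L
  for (it in seq_len(maxit)) {
    red <- drop(cost[basis] %*% Tab[, seq_len(ntot), drop = FALSE]) - cost
    cand <- which(red > tol)          # entering columns improve a minimisation
    if (!length(cand)) {
      return(list(Tab = Tab, basis = basis, status = 0L))
    }
    j <- min(cand)                    # Bland's rule
    col <- Tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tab = Tab, basis = basis, status = 1L))
    ratios <- Tab[pos, ntot + 1L] / col[pos]
    rows <- pos[ratios <= min(ratios) + tol]
    pr <- rows[which.min(basis[rows])]
    piv <- Tab[pr, j]
    Tab[pr, ] <- Tab[pr, ] / piv
    upd <- setdiff(seq_len(m), pr)
    Tab[upd, ] <- Tab[upd, , drop = FALSE] -
      outer(Tab[upd, j], Tab[pr, ])
    basis[pr] <- j
  }
  list(Tab = Tab, basis = basis, status = 2L)
}

# Solve the frontier LP; returns theta (length p+1) and the indices of the
# supporting points, or stops with a diagnostic.
.frontier_lp <- function(V, y, area_coef) {
  m <- ncol(V)   # p + 1 dual rows
  n <- nrow(V)   # data points
  A <- t(V)
  b <- area_coef # all positive on a support within [0, inf)
  if (any(b < 0)) stop("internal: negative area coefficients", call. = FALSE)
  # Phase 1: artificial start, minimise the artificial sum
  Tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- .simplex_core(Tab, basis, cost1)
  if (ph1$status == 2L) stop("frontier LP iteration limit (phase 1)", call. = FALSE)
  if (sum(ph1$Tab[ph1$basis > n, m + n + 1L]) > 1e-8 * max(1, sum(b))) {
    # dual infeasible and the primal is always feasible: the area objective
    # is unbounded below — the cloud does not pin down an envelope of this
    # degree (typically the points do not span the support)
    stop("no finite minimal-area polynomial envelope of degree ", m - 1L,
         ": data do not span the support for this degree", call. = FALSE)
  }
  Tab <- ph1$Tab; basis <- ph1$basis
  # pivot zero-level artificials out of the basis where possible
  for (r in which(basis > n)) {
    piv_col <- which(abs(Tab[r, seq_len(n)]) > 1e-9)
    if (length(piv_col)) {
      j <- piv_col[1]
      Tab[r, ] <- Tab[r, ] / Tab[r, j]
      upd <- setdiff(seq_len(m), r)
      Tab[upd, ] <- Tab[upd, , drop = FALSE] - outer(Tab[upd, j], Tab[r, ])
      basis[r] <- j
    }
  }
  if (any(basis > n)) {
    stop("frontier design is rank-deficient (too few distinct depths for ",
         "this degree)", call. = FALSE)
  }
  # Phase 2: maximise y'lambda == minimise (-y)'lambda, artificials barred
  Tab2 <- Tab[, c(seq_len(n), n + m + 1L), drop = FALSE]
  cost2 <- -y
  ph2 <- .simplex_core(Tab2, basis, cost2)
  if (ph2$status == 1L) {
    stop("frontier LP unbounded: the data admit no finite polynomial ",
         "envelope of this degree", call. = FALSE)
  }
  if (ph2$status != 0L) {
    stop("frontier LP iteration limit reached", call. = FALSE)
  }
  support <- ph2$basis
  theta <- solve(V[support, , drop = FALSE], y[support])
  dual_obj <- sum(y[support] * ph2$Tab[, n + 1L])
  primal_obj <- sum(area_coef * theta)
  if (abs(primal_obj - dual_obj) > 1e-6 * max(1, abs(dual_obj))) {
    warning("frontier LP duality gap ", signif(primal_obj - dual_obj, 3))
  }
  list(theta = theta, support_idx = sort(support))
}

#' Fit a polynomial frontier over a branch-tip cloud
#'
#' Finds the degree-`p` polynomial of minimal area
#' `integral_a^b phi(x) dx` (a linear objective with coefficients
#' `(b^(k+1) - a^(k+1)) / (k + 1)`) subject to `phi(x_i) >= y_i` at every
#' data point. The support defaults to `[0, 1]`: the biological range of
#' relative crown depth. After solving, any residual constraint violation
#' from LP tolerances is absorbed by lifting the intercept, so the envelope
#' invariant `min_i(phi(x_i) - y_i) >= -1e-9` always holds on return.
#'
#' Between data points a polynomial envelope of the *points* need not
#' envelope the underlying curve region; dips below the piecewise-linear
#' interpolant of the point cloud are therefore audited on a 201-point grid
#' and reported in the `audit` field, never constrained away.
#'
#' @param rdinc,ocr Coordinates of the branch tips (equal length); `rdinc`
#'   within `support`, `ocr >= 0`.
#' @param degree Polynomial degree `p >= 0`; capped at `n - 1` (with a
#'   warning) when fewer than `p + 1` points are supplied.
#' @param support Interval `c(a, b)` of the frontier.
#' @return An object of class `frontier_fit`: `degree`, `theta`
#'   (`theta0..thetap`), `support`, `n_points`, `area` (minimised
#'   objective), `slack_sum` (`sum(phi(x_i) - y_i)`), `aic`, `bic`, `audit`
#'   (list: `min_gap`, `n_dips` on the 201-point audit grid).
#' @examples
#' f <- fit_polynomial_frontier(c(0, 0.5, 1), c(0, 0.4, 1), degree = 1)
#' f$theta  # (0, 1): the line through the two active points
#' @export
fit_polynomial_frontier <- function(rdinc, ocr, degree, support = c(0, 1)) {
  n <- length(rdinc)
  stopifnot(length(ocr) == n, n >= 1, degree >= 0, length(support) == 2,
            support[2] > support[1])
  if (any(rdinc < support[1] - 1e-9 | rdinc > support[2] + 1e-9)) {
    stop("rdinc values outside the frontier support", call. = FALSE)
  }
  if (any(ocr < 0)) stop("radii must be nonnegative", call. = FALSE)
  degree <- as.integer(degree)
  if (n < degree + 1L) {
    warning(sprintf("only %d point(s): degree capped at %d", n, n - 1L))
    degree <- n - 1L
  }
  a <- support[1]; b <- support[2]
  k <- 0:degree
  area_coef <- (b^(k + 1) - a^(k + 1)) / (k + 1)
  V <- outer(rdinc, k, `^`)
  if (degree == 0L) {
    theta <- max(ocr)
  } else {
    theta <- .frontier_lp(V, ocr, area_coef)$theta
  }
  phi <- drop(V %*% theta)
  viol <- max(ocr - phi)
  if (viol > 0) {
    theta[1] <- theta[1] + viol
    phi <- phi + viol
  }
  slack <- phi - ocr
  slack_sum <- sum(slack)
  log_slack <- log(max(slack_sum, 1e-300))
  names(theta) <- paste0("theta", k)
  fit <- structure(list(
    degree = degree, theta = theta, support = c(a, b),
    n_points = n,
    area = sum(area_coef * theta),
    slack_sum = slack_sum,
    aic = log_slack + (degree + 1) / n,
    bic = log_slack + log(n) * (degree + 1) / (2 * n)
  ), class = "frontier_fit")
  fit$audit <- .audit_frontier(fit, rdinc, ocr)
  fit
}

# Audit between-point dips: frontier value vs the piecewise-linear upper
# interpolant of the cloud on an equally spaced grid.
.audit_frontier <- function(fit, rdinc, ocr, n_grid = 201L) {
  grid <- seq(fit$support[1], fit$support[2], length.out = n_grid)
  phi <- eval_frontier(fit, grid)
  ord <- order(rdinc, -ocr)
  x <- rdinc[ord]; y <- ocr[ord]
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) >= 2) {
    hull <- stats::approx(x, y, xout = grid, rule = 2)$y
  } else {
    hull <- rep(y[1], n_grid)
  }
  gap <- phi - hull
  list(min_gap = min(gap), n_dips = sum(gap < -1e-9))
}

#' @export
print.frontier_fit <- function(x, ...) {
  cat(sprintf("<frontier_fit> degree %d on %d points, area %.5f\n",
              x$degree, x$n_points, x$area))
  print(round(x$theta, 5))
  cat(sprintf("  AIC %.4f, BIC %.4f; audit: min gap %.2e, %d dip(s)\n",
              x$aic, x$bic, x$audit$min_gap, x$audit$n_dips))
  invisible(x)
}

#' Select the frontier degree by information criteria
#'
#' Fits frontiers of degree `0..max_degree` and scores each with
#' `AIC(p) = log(sum_i(phi_p(x_i) - y_i)) + (p + 1)/n` and
#' `BIC(p) = log(sum_i(phi_p(x_i) - y_i)) + log(n) (p + 1)/(2n)` — the
#' slack-sum criteria of the frontier-estimation literature. The
#' AIC-minimising degree is returned; when AIC and BIC disagree, the
#' smaller of the two degrees is taken (parsimony). Degrees whose LP fails
#' are skipped and recorded.
#'
#' @inheritParams fit_polynomial_frontier
#' @param max_degree Largest candidate degree (default 20; additionally
#'   capped at `n - 1`).
#' @return The selected `frontier_fit`, with a `candidates` attribute
#'   (data.frame of degree, aic, bic, area) and a `skipped` attribute
#'   naming degrees whose fit failed.
#' @export
select_degree <- function(rdinc, ocr, max_degree = 20L, support = c(0, 1)) {
  n <- length(rdinc)
  stopifnot(max_degree >= 0)
  degrees <- 0:min(max_degree, n - 1L)
  fits <- list(); skipped <- character(0)
  for (p in degrees) {
    f <- tryCatch(fit_polynomial_frontier(rdinc, ocr, p, support),
                  error = function(e) e)
    if (inherits(f, "error")) {
      skipped[as.character(p)] <- conditionMessage(f)
    } else {
      fits[[as.character(p)]] <- f
    }
  }
  if (!length(fits)) stop("every candidate degree failed", call. = FALSE)
  tab <- data.frame(
    degree = as.integer(names(fits)),
    aic = vapply(fits, function(f) f$aic, 1),
    bic = vapply(fits, function(f) f$bic, 1),
    area = vapply(fits, function(f) f$area, 1))
  pick <- function(score) {
    best <- min(score)
    tab$degree[score <= best + 1e-12][1]  # smallest degree among ties
  }
  p_star <- min(pick(tab$aic), pick(tab$bic))
  out <- fits[[as.character(p_star)]]
  attr(out, "candidates") <- tab
  attr(out, "skipped") <- skipped
  out
}

#' Evaluate a polynomial frontier
#'
#' Horner-scheme evaluation of the fitted frontier on a grid.
#'
#' @param fit A `frontier_fit`.
#' @param grid Relative depths within the fit's support.
#' @return Radii, same length as `grid`.
#' @export
eval_frontier <- function(fit, grid) {
  stopifnot(inherits(fit, "frontier_fit"))
  theta <- fit$theta
  out <- rep(theta[length(theta)], length(grid))
  if (length(theta) > 1) {
    for (k in (length(theta) - 1L):1L) out <- out * grid + theta[k]
  }
  unname(out)
}
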