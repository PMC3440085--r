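#' Neighbor-similarity weights for a response profile
#'
#' Computes the weights used by the weighted nonlinear least squares (WNLS)
#' fit and the weighted t-test. Each included point i receives
#' \deqn{w^*_i = 1/(1 + d_i^2),} where \eqn{d_i} is the mean absolute
#' response difference between point i and its available included neighbors
#' (the adjacent points on the concentration axis), so isolated spikes that
#' disagree with both neighbors are down-weighted. The quadratic penalty
#' makes the weighted leverage of a lone spike bounded: its contribution to
#' any weighted sum of squares, \eqn{w_i d_i^2 \approx 1}, stays at noise
#' level no matter how extreme the spike, which is what lets the weighted
#' fit ignore single-point-driven curves. Weights are normalized to sum to
#' the effective sample size n, hence all-equal responses give unit weights
#' and every weighted statistic reduces to its unweighted counterpart.
#'
#' @param profile A \code{\link{qhts_profile}}.
#' @return Numeric weight vector, one entry per included point (ordered by
#'   concentration), summing to n.
#' @export
neighbor_weights <- function(profile) {
  stopifnot(inherits(profile, "qhts_profile"))
  u <- .prof_used(profile)
  n <- u$n
  if (n < 2L) stop("neighbor weights need at least 2 included points")
  r <- u$resp
  d_prev <- c(NA_real_, abs(diff(r)))
  d_next <- c(abs(diff(r)), NA_real_)
  d <- rowMeans(cbind(d_prev, d_next), na.rm = TRUE)
  w_star <- 1 / (1 + d^2)
  n * w_star / sum(w_star)
}

## candidate start grid: log10(AC50) spans the tested range +/- 2 decades,
## SLOPE covers shallow to steep sigmoids (bounded fit caps SLOPE at 20)
.start_grid <- function(log_conc) {
  list(log_ac50 = seq(min(log_conc) - 2, max(log_conc) + 2, length.out = 23L),
       slope = c(0.25, 0.5, 1, 2, 4, 8, 16))
}

## For fixed (log10 AC50, SLOPE) the Hill model is linear in (R0, RMAX):
## R = R0 (1-g) + RMAX g. Profile those out with a weighted 2x2 solve at
## every grid node; returns all candidates with their weighted SSE and a
## soft-L1 robust loss (used by the outlier prefit).
.grid_candidates <- function(conc, resp, w) {
  lc <- log10(conc)
  grid <- .start_grid(lc)
  la <- rep(grid$log_ac50, times = length(grid$slope))
  sl <- rep(grid$slope, each = length(grid$log_ac50))
  # n x m matrix of fractional occupancies, one column per grid node
  x <- outer(-lc, la, "+") * rep(sl, each = length(lc))
  x[x > 300] <- 300; x[x < -300] <- -300
  G <- 1 / (1 + 10^x)
  wr <- w * resp
  a11 <- colSums(w * (1 - G)^2)
  a12 <- colSums(w * (1 - G) * G)
  a22 <- colSums(w * G^2)
  b1 <- colSums(wr * (1 - G))
  b2 <- colSums(wr * G)
  det <- a11 * a22 - a12^2
  r0 <- (a22 * b1 - a12 * b2) / det
  rmax <- (a11 * b2 - a12 * b1) / det
  # g essentially constant: the model degenerates to a flat line
  flat <- det <= 1e-9 * (a11 + a22)^2
  if (any(flat)) r0[flat] <- rmax[flat] <- sum(wr) / sum(w)
  R <- resp - (rep(r0, each = length(lc)) +
               G * rep(rmax - r0, each = length(lc)))
  cbind(r0 = r0, rmax = rmax, log_ac50 = la, slope = sl,
        sse = colSums(w * R^2),
        robust = colSums(2 * (sqrt(1 + R^2) - 1)))
}

## Levenberg-Marquardt polish of one candidate, in (R0, RMAX, log10 AC50,
## SLOPE) coordinates with box bounds. Returns c(params, sse) or NULL.
.polish_fit <- function(conc, resp, w, start, bounds) {
  sw <- sqrt(w)
  lc <- log10(conc)
  fn <- function(p) {
    g <- .hill_frac(lc, p[3L], p[4L])
    sw * (resp - (p[1L] + (p[2L] - p[1L]) * g))
  }
  jac <- function(p) {  # same algebra as hill_gradient, in log10(AC50)
    x <- pmin(pmax(p[4L] * (p[3L] - lc), -300), 300)
    u <- 10^x
    g <- 1 / (1 + u)
    gu <- g^2 * u
    span <- p[2L] - p[1L]
    -sw * cbind(1 - g, g,
                -span * gu * p[4L] * log(10),
                -span * gu * (p[3L] - lc) * log(10))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = bounds$lower, upper = bounds$upper,
                       fn = fn, jac = jac,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 500L)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  c(r0 = unname(p[1L]), rmax = unname(p[2L]), log_ac50 = unname(p[3L]),
    slope = unname(p[4L]), sse = sum(fn(p)^2))
}

.fit_bounds <- function(conc, resp) {
  lo_r <- min(resp) - 150
  hi_r <- max(resp) + 150
  list(lower = c(lo_r, lo_r, log10(min(conc)) - 2, 1e-3),
       upper = c(hi_r, hi_r, log10(max(conc)) + 2, 20))
}

## shared engine behind fit_hill_nls / fit_hill_wnls
.fit_hill <- function(profile, w, weighted) {
  u <- .prof_used(profile)
  if (u$n < 4L) stop("Hill fit requires at least 4 included points")
  cand <- .grid_candidates(u$conc, u$resp, w)
  bounds <- .fit_bounds(u$conc, u$resp)
  ## polish the single best grid node; the linear (R0, RMAX) solve already
  ## decided the response direction at every node, so activators and
  ## inhibitors are covered without dedicated direction starts, and one
  ## polished optimum per fit avoids over-searching pure-noise profiles
  pick <- which.min(cand[, "sse"])
  best <- NULL
  for (k in pick) {
    start <- pmin(pmax(cand[k, c("r0", "rmax", "log_ac50", "slope")],
                       bounds$lower), bounds$upper)
    pol <- .polish_fit(u$conc, u$resp, w, start, bounds)
    if (is.null(pol)) next
    if (is.null(best) || pol[["sse"]] < best[["sse"]] - 1e-12 ||
        (abs(pol[["sse"]] - best[["sse"]]) <= 1e-12 &&
         pol[["slope"]] < best[["slope"]]))
      best <- pol
  }
  if (is.null(best)) {
    # no polish converged: fall back to the best raw grid candidate
    k <- which.min(cand[, "sse"])
    best <- c(cand[k, c("r0", "rmax", "log_ac50", "slope", "sse")])
    converged <- FALSE
  } else converged <- TRUE
  params <- hill_params(best[["r0"]], best[["rmax"]],
                        10^best[["log_ac50"]], max(best[["slope"]], 1e-3))
  structure(list(model_kind = "hill", weighted = weighted, params = params,
                 sse = max(best[["sse"]], 0), n_used = u$n, n_params = 4L,
                 converged = converged,
                 weights = if (weighted) w else NULL,
                 outliers_removed = which(!profile$included)),
            class = "hill_fit")
}

#' Unweighted nonlinear least squares Hill fit
#'
#' Fits the four-parameter Hill model to the included points of a profile by
#' minimizing the residual sum of squares. Candidate starts are generated on
#' a deterministic (log10 AC50, SLOPE) grid with the two linear parameters
#' (R0, RMAX) profiled out in closed form; the best candidate per response
#' direction is then polished by Levenberg-Marquardt
#' (\code{minpack.lm::nls.lm}) under box bounds (AC50 within two decades of
#' the tested range, SLOPE in (0, 20], R0/RMAX within 150\% beyond the data
#' range). Ties are broken toward the shallower slope.
#'
#' @param profile A \code{\link{qhts_profile}} with at least 4 included
#'   points.
#' @return A \code{"hill_fit"} object: fields \code{params}
#'   (\code{\link{hill_params}}), \code{sse}, \code{n_used}, \code{n_params}
#'   (4), \code{converged}, \code{weighted}, \code{outliers_removed}.
#' @export
fit_hill_nls <- function(profile) {
  u <- .prof_used(profile)
  .fit_hill(profile, rep(1, u$n), weighted = FALSE)
}

#' Weighted nonlinear least squares Hill fit
#'
#' As \code{\link{fit_hill_nls}} but minimizing the weighted residual sum of
#' squares with the neighbor-similarity weights, so a single point that
#' disagrees with its concentration-neighbors has less influence on the fit.
#' With all-equal weights the result coincides with the unweighted fit.
#'
#' @inheritParams fit_hill_nls
#' @param weights Weight vector from \code{\link{neighbor_weights}} (one per
#'   included point, summing to n). Defaults to computing them from the
#'   profile.
#' @return A \code{"hill_fit"} object with \code{weighted = TRUE}.
#' @export
fit_hill_wnls <- function(profile, weights = neighbor_weights(profile)) {
  u <- .prof_used(profile)
  if (length(weights) != u$n) stop("one weight per included point required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  .fit_hill(profile, weights, weighted = TRUE)
}

#' Constant (flat-line) null fit
#'
#' Fits the one-parameter no-response model: the (weighted) mean of the
#' included responses. Serves as the null model of the overall F-test
#' against the Hill fit, and must use the same weighting as the Hill fit it
#' is compared with.
#'
#' @inheritParams fit_hill_nls
#' @param weights Optional weight vector (sum n); \code{NULL} for the
#'   unweighted mean.
#' @return A \code{"hill_fit"} object with \code{model_kind = "constant"}
#'   and \code{params} the fitted level.
#' @export
fit_constant <- function(profile, weights = NULL) {
  u <- .prof_used(profile)
  w <- if (is.null(weights)) rep(1, u$n) else weights
  if (length(w) != u$n) stop("one weight per included point required")
  level <- sum(w * u$resp) / sum(w)
  structure(list(model_kind = "constant", weighted = !is.null(weights),
                 params = level, sse = sum(w * (u$resp - level)^2),
                 n_used = u$n, n_params = 1L, converged = TRUE,
                 weights = weights,
                 outliers_removed = which(!profile$included)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$model_kind == "hill") {
    cat(sprintf("%s Hill fit: R0 = %.3g, RMAX = %.3g, AC50 = %.3g uM, SLOPE = %.3g; SSE = %.4g (n = %d)\n",
                if (x$weighted) "WNLS" else "NLS", x$params$r0, x$params$rmax,
                x$params$ac50, x$params$slope, x$sse, x$n_used))
  } else {
    cat(sprintf("%s constant fit: level = %.3g; SSE = %.4g (n = %d)\n",
                if (x$weighted) "weighted" else "unweighted", x$params,
                x$sse, x$n_used))
  }
  invisible(x)
}

#' Overall F-test: Hill model versus flat line
#'
#' Extra-sum-of-squares comparison of the four-parameter Hill fit against
#' the one-parameter constant fit on the same points and weighting:
#' \deqn{F = \frac{(SSE_0 - SSE_1)/3}{SSE_1/(n - 4)}}
#' with p-value from the upper tail of F(3, n - 4). With n = 4 included
#' points (zero residual degrees of freedom) or a zero full-model SSE the
#' test is undefined and flagged, and is treated as non-significant by the
#' classifier.
#'
#' @param full \code{"hill_fit"} of the Hill model.
#' @param null \code{"hill_fit"} of the constant model, same weighting and
#'   included points.
#' @return List of class \code{"f_test"}: \code{f}, \code{df1} (3),
#'   \code{df2}, \code{p}, \code{defined}.
#' @export
overall_f_test <- function(full, null) {
  stopifnot(inherits(full, "hill_fit"), inherits(null, "hill_fit"))
  if (full$model_kind != "hill" || null$model_kind != "constant")
    stop("'full' must be a Hill fit and 'null' a constant fit")
  if (full$n_used != null$n_used || full$weighted != null$weighted)
    stop("full and null fits must share included points and weighting")
  df2 <- full$n_used - 4L
  if (df2 <= 0L || full$sse <= 0 || !full$converged) {
    return(structure(list(f = NA_real_, df1 = 3L, df2 = df2, p = NA_real_,
                          defined = FALSE), class = "f_test"))
  }
  f <- (null$sse - full$sse) / 3 / (full$sse / df2)
  if (!is.finite(f) || f < 0) f <- 0
  structure(list(f = f, df1 = 3L, df2 = df2,
                 p = stats::pf(f, 3, df2, lower.tail = FALSE),
                 defined = TRUE), class = "f_test")
}

#' @export
print.f_test <- function(x, ...) {
  if (!x$defined) cat("overall F-test: undefined (no residual df)\n")
  else cat(sprintf("overall F-test: F(%d, %d) = %.4g, p = %.4g\n",
                   x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' Two-step outlier detection
#'
#' Step 1 fits a robust preliminary Hill curve: the best candidate-grid fit
#' under a soft-L1 loss, refined by BFGS on the same loss, so single
#' aberrant points barely influence it. Step 2 applies a
#' false-discovery-rate outlier test to the residuals: the robust residual
#' scale is the 68.27th percentile of the absolute residuals with a
#' small-sample correction \code{sqrt(n/(n - 4))}, each point gets a
#' two-sided p-value from the t distribution on n - 4 df for
#' \code{|residual|/scale}, and points are flagged by Benjamini-Hochberg at
#' Q = 1\%. Controlling the FDR rather than cutting at a fixed multiple of
#' a 14-point MAD keeps the removal rate on clean noisy profiles near zero
#' (a fixed MAD cut at this sample size removes a large fraction of
#' perfectly ordinary extreme points, which biases the downstream fits and
#' inflates the null rejection rate of the overall F-test). At most
#' \code{ceiling(n/7)} points are removed, never leaving fewer than 4
#' included points, and profiles with fewer than 6 included points are
#' returned unchanged.
#'
#' @param profile A \code{\link{qhts_profile}}.
#' @param q FDR level of the outlier test (default 0.01).
#' @return The profile with its \code{included} mask updated.
#' @export
detect_outliers <- function(profile, q = 0.01) {
  stopifnot(inherits(profile, "qhts_profile"))
  u <- .prof_used(profile)
  if (u$n < 6L) return(profile)
  cand <- .grid_candidates(u$conc, u$resp, rep(1, u$n))
  k <- which.min(cand[, "robust"])
  # refine the best grid node under the same soft-L1 loss so the prefit,
  # not the grid resolution, sets the residual scale
  lc <- log10(u$conc)
  soft_l1 <- function(p) {
    g <- .hill_frac(lc, p[3L], p[4L])
    sum(2 * (sqrt(1 + (u$resp - (p[1L] + (p[2L] - p[1L]) * g))^2) - 1))
  }
  soft_l1_grad <- function(p) {
    g <- .hill_frac(lc, p[3L], p[4L])
    r <- u$resp - (p[1L] + (p[2L] - p[1L]) * g)
    psi <- 2 * r / sqrt(1 + r^2)
    x <- pmin(pmax(p[4L] * (p[3L] - lc), -300), 300)
    uu <- 10^x
    gu <- g^2 * uu
    span <- p[2L] - p[1L]
    J <- cbind(1 - g, g, -span * gu * p[4L] * log(10),
               -span * gu * (p[3L] - lc) * log(10))
    -colSums(psi * J)
  }
  opt <- stats::optim(cand[k, c("r0", "rmax", "log_ac50", "slope")], soft_l1,
                      gr = soft_l1_grad, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  g <- .hill_frac(lc, opt$par[3L], opt$par[4L])
  res <- u$resp - (opt$par[1L] + (opt$par[2L] - opt$par[1L]) * g)
  # robust residual scale: 68.27th percentile of |residuals|, small-sample
  # corrected; floored at 0.1% of the response spread so numerically
  # perfect profiles are never flagged
  scale <- max(stats::quantile(abs(res), 0.6827, names = FALSE) *
                 sqrt(u$n / (u$n - 4)),
               1e-3 * diff(range(u$resp)), 1e-8)
  pvals <- 2 * stats::pt(-abs(res) / scale, df = u$n - 4L)
  bad <- which(stats::p.adjust(pvals, "BH") <= q)
  if (!length(bad)) return(profile)
  cap <- min(ceiling(u$n / 7), u$n - 4L)
  if (cap <= 0L) return(profile)
  if (length(bad) > cap) bad <- bad[order(abs(res[bad]), decreasing = TRUE)[seq_len(cap)]]
  inc <- profile$included
  inc[which(inc)[bad]] <- FALSE
  qhts_profile(profile$substance_id, profile$conc, profile$resp, inc)
}
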