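#' Hill model parameters
#'
#' Container for the four parameters of the Hill concentration-response
#' model \deqn{R(C) = R_0 + \frac{R_{max} - R_0}{1 + (AC_{50}/C)^{SLOPE}}.}
#' Responses are expressed as percent of the positive-control activity and
#' concentrations in micromolar throughout the package.
#'
#' @param r0 Baseline activity (\% of positive control); the response as
#'   concentration approaches zero.
#' @param rmax Maximal activity (\% of positive control); the asymptote as
#'   concentration grows. \code{rmax > r0} describes an activator,
#'   \code{rmax < r0} an inhibitor, \code{rmax == r0} a flat (null) profile.
#' @param ac50 Concentration (uM, > 0) yielding half the maximal response
#'   relative to baseline (EC50 for activators, IC50 for inhibitors).
#' @param slope Hill shape parameter (dimensionless, > 0).
#' @return An object of class \code{"hill_params"}.
#' @examples
#' p <- hill_params(0, 100, 1, 1)
#' hill_response(p, 1)   # midpoint: 50
#' @export
hill_params <- function(r0, rmax, ac50, slope) {
  stopifnot(is.numeric(r0), is.numeric(rmax), is.numeric(ac50),
            is.numeric(slope), length(r0) == 1L, length(rmax) == 1L,
            length(ac50) == 1L, length(slope) == 1L)
  if (!is.finite(ac50) || ac50 <= 0)
    stop("'ac50' must be a positive, finite concentration (uM)")
  if (!is.finite(slope) || slope <= 0)
    stop("'slope' must be positive and finite")
  structure(list(r0 = as.numeric(r0), rmax = as.numeric(rmax),
                 ac50 = as.numeric(ac50), slope = as.numeric(slope)),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("Hill parameters: R0 = %g%%, RMAX = %g%%, AC50 = %g uM, SLOPE = %g\n",
              x$r0, x$rmax, x$ac50, x$slope))
  invisible(x)
}

## fractional occupancy g(C) = 1 / (1 + (AC50/C)^SLOPE), computed in log10
## space; exponent clamped so extreme slopes (used when *simulating* Case 2
## curves with SLOPE up to 100) underflow cleanly to 0/1 instead of NaN.
.hill_frac <- function(log10_conc, log10_ac50, slope) {
  x <- slope * (log10_ac50 - log10_conc)
  x[x > 300] <- 300
  x[x < -300] <- -300
  1 / (1 + 10^x)
}

#' Evaluate the Hill concentration-response model
#'
#' Noiseless mean response at the given concentrations.
#'
#' @param params A \code{\link{hill_params}} object.
#' @param conc Vector of concentrations (uM, all > 0).
#' @return Numeric vector of responses (\% of positive control).
#' @export
hill_response <- function(params, conc) {
  stopifnot(inherits(params, "hill_params"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  g <- .hill_frac(log10(conc), log10(params$ac50), params$slope)
  params$r0 + (params$rmax - params$r0) * g
}

#' Gradient of the Hill model
#'
#' Analytic partial derivatives of the response with respect to
#' (R0, RMAX, AC50, SLOPE), used to supply an exact Jacobian to the
#' least-squares optimizer.
#'
#' @inheritParams hill_response
#' @return A \code{length(conc) x 4} matrix with columns
#'   \code{r0, rmax, ac50, slope}.
#' @export
hill_gradient <- function(params, conc) {
  stopifnot(inherits(params, "hill_params"), is.numeric(conc))
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  la <- log10(params$ac50)
  lc <- log10(conc)
  g <- .hill_frac(lc, la, params$slope)
  u <- 10^pmin(pmax(params$slope * (la - lc), -300), 300)  # (AC50/C)^SLOPE
  span <- params$rmax - params$r0
  d_ac50 <- -span * g^2 * u * params$slope / params$ac50
  d_slope <- -span * g^2 * u * log(params$ac50 / conc)
  out <- cbind(r0 = 1 - g, rmax = g, ac50 = d_ac50, slope = d_slope)
  out[!is.finite(out)] <- 0
  out
}

#' Concentration-response profile for one substance
#'
#' @param substance_id Opaque label for the substance.
#' @param conc Concentrations (uM, strictly positive). Stored sorted
#'   ascending together with the matching responses.
#' @param resp Responses (\% of positive control), same length as
#'   \code{conc}.
#' @param included Logical mask of points currently in use (points failing
#'   outlier detection, or masked out when emulating smaller designs, are
#'   \code{FALSE}).
#' @return An object of class \code{"qhts_profile"}.
#' @export
qhts_profile <- function(substance_id, conc, resp,
                         included = rep(TRUE, length(conc))) {
  if (length(conc) != length(resp) || length(conc) != length(included))
    stop("'conc', 'resp' and 'included' must have equal length")
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("concentrations must be positive and finite")
  if (any(!is.finite(resp)))
    stop("responses must be finite")
  included <- as.logical(included)
  if (anyNA(included)) stop("'included' must be TRUE/FALSE")
  if (!any(included)) stop("profile must retain at least one included point")
  ord <- order(conc)
  structure(list(substance_id = as.character(substance_id)[1L],
                 conc = as.numeric(conc)[ord],
                 resp = as.numeric(resp)[ord],
                 included = included[ord]),
            class = "qhts_profile")
}

#' @export
print.qhts_profile <- function(x, ...) {
  cat(sprintf("qHTS profile '%s': %d points (%d included), %.3g-%.3g uM\n",
              x$substance_id, length(x$conc), sum(x$included),
              min(x$conc), max(x$conc)))
  invisible(x)
}

## included-point views used throughout the fitting/classification code
.prof_used <- function(profile) {
  keep <- profile$included
  list(conc = profile$conc[keep], resp = profile$resp[keep], n = sum(keep))
}
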