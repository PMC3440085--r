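.is_active_call <- function(call) {
  call %in% c("ACTIVE[1]", "ACTIVE[-1]", "ACTIVE[2]", "ACTIVE[-2]")
}

#' Operating characteristics of a set of activity calls
#'
#' Type I error is the fraction of true nulls called ACTIVE[+/-1] or
#' ACTIVE[+/-2]; power the analogous fraction of true actives.
#' INCONCLUSIVE[+/-3] and INACTIVE both count as not-active. Also reports
#' the percentage of active calls made at Stage 1,
#' ACTIVE[1-type] / (ACTIVE[1-type] + ACTIVE[2-type]) x 100, over all
#' substances.
#'
#' @param calls Data frame with columns \code{substance_id} and \code{call}
#'   (from \code{\link{classify_profiles}}), or a character vector of
#'   calls.
#' @param truth Logical vector (or the \code{truth} data frame of a
#'   \code{\link{simulate_dataset}}) marking true actives, aligned with
#'   \code{calls}.
#' @return List of class \code{"operating_characteristics"}: \code{type1},
#'   \code{power}, \code{active1_share} (\%, \code{NaN} when nothing was
#'   called active), \code{n_null}, \code{n_active}.
#' @export
operating_characteristics <- function(calls, truth) {
  call <- if (is.data.frame(calls)) calls$call else as.character(calls)
  act <- if (is.data.frame(truth)) truth$active else as.logical(truth)
  if (length(call) != length(act))
    stop("'calls' and 'truth' must be aligned")
  is_act <- .is_active_call(call)
  n_null <- sum(!act); n_active <- sum(act)
  n1 <- sum(call %in% c("ACTIVE[1]", "ACTIVE[-1]"))
  n2 <- sum(call %in% c("ACTIVE[2]", "ACTIVE[-2]"))
  structure(list(
    type1 = if (n_null) sum(is_act & !act) / n_null else NaN,
    power = if (n_active) sum(is_act & act) / n_active else NaN,
    active1_share = if (n1 + n2) 100 * n1 / (n1 + n2) else NaN,
    n_null = n_null, n_active = n_active),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("type I error = %.4f (%d nulls); power = %.4f (%d actives); ACTIVE*[1] share = %.1f%%\n",
              x$type1, x$n_null, x$power, x$n_active, x$active1_share))
  invisible(x)
}

#' Trapezoid-rule area under a curve
#'
#' @param x,y Coordinates; \code{x} must be sorted nondecreasing. A
#'   two-column matrix/data frame may be passed as \code{x}.
#' @return \eqn{\sum 0.5 (x_{k+1}-x_k)(y_{k+1}+y_k)}.
#' @export
auc_trapezoid <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[, 2]; x <- x[, 1] }
  if (length(x) < 2L) stop("at least 2 points are required")
  if (is.unsorted(x)) stop("'x' must be sorted nondecreasing")
  sum(0.5 * diff(x) * (y[-1] + y[-length(y)]))
}

#' ROC curve of the three-stage algorithm over a significance-level sweep
#'
#' The significance level alpha is the algorithm's only continuous decision
#' threshold, so the ROC curve sweeps it (default: log-spaced from 1e-6 to
#' 0.999) while the detection-limit conditions stay fixed. Profile fits and
#' p-values are computed once; each alpha only re-applies the decision
#' tree. (0,0) and (1,1) anchors are added for the trapezoid AUC — the
#' fixed non-statistical conditions keep the empirical sweep from reaching
#' (1,1) on its own.
#'
#' @param dataset A \code{\link{simulate_dataset}} result (or a list with
#'   \code{profiles} and logical truth via \code{truth$active}).
#' @param alpha_grid Sorted vector of significance levels in (0, 1).
#' @param config \code{\link{classifier_config}} supplying the detection
#'   limits and outlier-detection switch (its \code{alpha} is ignored).
#' @param stats Optional precomputed \code{\link{classify_stats_table}}.
#' @return List of class \code{"roc_curve"}: \code{points} (data frame
#'   \code{alpha}, \code{fpr}, \code{tpr}) and \code{auc}.
#' @export
roc_curve <- function(dataset,
                      alpha_grid = 10^seq(-6, log10(0.999), length.out = 30),
                      config = classifier_config(), stats = NULL) {
  if (any(alpha_grid <= 0) || any(alpha_grid >= 1) || is.unsorted(alpha_grid))
    stop("'alpha_grid' must be sorted values in (0, 1)")
  if (is.null(stats))
    stats <- classify_stats_table(dataset$profiles, config)
  act <- dataset$truth$active
  pts <- t(vapply(alpha_grid, function(a) {
    oc <- operating_characteristics(
      apply_call_tree(stats, a, config$detlim)$call, act)
    c(fpr = oc$type1, tpr = oc$power)
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(alpha = alpha_grid, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  xy <- rbind(c(0, 0), points[order(points$fpr, points$tpr),
                              c("fpr", "tpr")], c(1, 1))
  structure(list(points = points,
                 auc = auc_trapezoid(xy[, 1], xy[, 2])),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC over %d significance levels: AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Single-stage comparator activity calls
#'
#' The one-stage strategies the three-stage algorithm is benchmarked
#' against:
#' \describe{
#'   \item{nls_f / wnls_f}{active iff the overall F-test of the (W)NLS Hill
#'     fit rejects at \code{alpha}; direction from sign(RMAX - R0).}
#'   \item{robust_linreg}{Huber M-estimation (\code{MASS::rlm}, tuning
#'     1.345) of response on log10 concentration; active iff the slope
#'     differs from 0 at \code{alpha} (normal approximation), direction
#'     from the slope sign.}
#'   \item{student_t}{one-sided Student t-tests of the mean response
#'     against +25 and -25; active iff either rejects.}
#'   \item{weighted_t}{as \code{student_t} with the neighbor-similarity
#'     weights.}
#' }
#'
#' @param profile A \code{\link{qhts_profile}}.
#' @param method One of \code{"nls_f"}, \code{"wnls_f"},
#'   \code{"robust_linreg"}, \code{"student_t"}, \code{"weighted_t"}.
#' @param config A \code{\link{classifier_config}} (supplies alpha and the
#'   t-test thresholds via the detection limits).
#' @return List: \code{active} (logical), \code{direction} (+1/-1/0),
#'   \code{p} (the decisive p-value).
#' @export
comparator_call <- function(profile,
                            method = c("nls_f", "wnls_f", "robust_linreg",
                                       "student_t", "weighted_t"),
                            config = classifier_config()) {
  method <- match.arg(method)
  u <- .prof_used(profile)
  alpha <- config$alpha
  if (method %in% c("nls_f", "wnls_f")) {
    if (u$n <= 4L)
      return(list(active = FALSE, direction = 0, p = NA_real_))
    if (method == "nls_f") {
      fit <- fit_hill_nls(profile)
      ft <- overall_f_test(fit, fit_constant(profile))
    } else {
      w <- neighbor_weights(profile)
      fit <- fit_hill_wnls(profile, w)
      ft <- overall_f_test(fit, fit_constant(profile, w))
    }
    hit <- ft$defined && ft$p < alpha
    return(list(active = hit,
                direction = if (hit) sign(fit$params$rmax - fit$params$r0) else 0,
                p = ft$p))
  }
  if (method == "robust_linreg") {
    fit <- tryCatch(
      MASS::rlm(u$resp ~ log10(u$conc), psi = MASS::psi.huber, k = 1.345,
                maxit = 100),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged)
      return(list(active = FALSE, direction = 0, p = NA_real_))
    cf <- summary(fit)$coefficients
    slope <- cf[2, "Value"]; se <- cf[2, "Std. Error"]
    p <- if (!is.finite(se) || se <= 0) (if (abs(slope) > 1e-8) 0 else 1)
         else 2 * stats::pnorm(-abs(slope / se))
    # a slope at numerical zero is flat regardless of its tiny-se z-score
    hit <- is.finite(p) && p < alpha && abs(slope) > 1e-8
    return(list(active = hit, direction = if (hit) sign(slope) else 0,
                p = p))
  }
  # one-sided t-tests against the detection limits
  w <- if (method == "weighted_t") neighbor_weights(profile)
       else rep(1, u$n)
  p_pos <- weighted_t_test(u$resp, w, config$detlim$pos, "greater")
  p_neg <- weighted_t_test(u$resp, w, config$detlim$neg, "less")
  if (p_pos < alpha && (p_pos <= p_neg || p_neg >= alpha))
    return(list(active = TRUE, direction = 1, p = p_pos))
  if (p_neg < alpha)
    return(list(active = TRUE, direction = -1, p = p_neg))
  list(active = FALSE, direction = 0, p = min(p_pos, p_neg))
}

#' Evaluate one simulated configuration end to end
#'
#' Simulates a data set, classifies every profile, and summarizes the
#' operating characteristics; optionally also computes the alpha-sweep
#' AUC from the same fitted statistics.
#'
#' @param config A \code{\link{sim_config}}.
#' @param active_params \code{\link{hill_params}} of the true actives.
#' @param classifier A \code{\link{classifier_config}}.
#' @param auc Also compute the ROC AUC (default \code{FALSE}; reuses the
#'   per-profile fits, so the extra cost is small).
#' @param progress Passed to \code{\link{classify_stats_table}}.
#' @return One-row \code{data.frame}: the true parameters, error setting,
#'   effective n, \code{type1}, \code{power}, \code{active1_share} and
#'   (optionally) \code{auc}.
#' @export
evaluate_configuration <- function(config, active_params,
                                   classifier = classifier_config(),
                                   auc = FALSE, progress = FALSE) {
  ds <- simulate_dataset(config, active_params)
  stats <- classify_stats_table(ds$profiles, classifier, progress = progress)
  calls <- apply_call_tree(stats, classifier$alpha, classifier$detlim)
  oc <- operating_characteristics(calls$call, ds$truth$active)
  out <- data.frame(
    ac50 = active_params$ac50, rmax = active_params$rmax,
    slope = active_params$slope,
    sigma = if (config$error$kind == "constant") config$error$sigma
            else NA_real_,
    error_kind = config$error$kind,
    n = config$n_points - config$points_removed,
    n_null = oc$n_null, n_active = oc$n_active,
    type1 = oc$type1, power = oc$power,
    active1_share = oc$active1_share, stringsAsFactors = FALSE)
  if (auc)
    out$auc <- roc_curve(ds, config = classifier, stats = stats)$auc
  out
}

#' Write an operating-characteristics table
#'
#' @param oc_table Data frame (rows from
#'   \code{\link{evaluate_configuration}}).
#' @param path Output CSV file.
#' @export
write_oc_table <- function(oc_table, path) {
  utils::write.csv(oc_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
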