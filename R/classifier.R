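#' Detection limits from negative-control responses
#'
#' The detection limits bound the response band inside which the normalized
#' signal cannot be distinguished from assay noise. They are set to the
#' negative-control mean plus/minus three sample standard deviations. When
#' no controls are available a band of +/-25\% of the positive control — a
#' typical value for this assay class — is used (see
#' \code{\link{classifier_config}}).
#'
#' @param neg_control_responses Numeric vector (length >= 2) of normalized
#'   negative-control responses.
#' @return List with components \code{pos} and \code{neg} (class
#'   \code{"detection_limits"}).
#' @export
detection_limits_from_controls <- function(neg_control_responses) {
  x <- as.numeric(neg_control_responses)
  if (length(x) < 2L || anyNA(x))
    stop("at least 2 non-missing control responses are required")
  m <- mean(x); s <- stats::sd(x)
  structure(list(pos = m + 3 * s, neg = m - 3 * s),
            class = "detection_limits")
}

.as_detlim <- function(detlim) {
  if (inherits(detlim, "detection_limits")) return(detlim)
  if (is.numeric(detlim) && length(detlim) == 1L && detlim > 0)
    return(structure(list(pos = detlim, neg = -detlim),
                     class = "detection_limits"))
  if (is.numeric(detlim) && length(detlim) == 2L)
    return(structure(list(pos = max(detlim), neg = min(detlim)),
                     class = "detection_limits"))
  stop("'detlim' must be detection_limits, a single magnitude, or c(neg, pos)")
}

#' Classifier configuration
#'
#' @param alpha Significance level for every statistical test
#'   (default 0.05).
#' @param detlim Detection limits: a \code{"detection_limits"} object, a
#'   single magnitude (band +/-detlim), or a length-2 vector. Default
#'   +/-25\% of the positive control.
#' @param run_outlier_detection Run \code{\link{detect_outliers}} before
#'   fitting (default \code{TRUE}).
#' @return List of class \code{"classifier_config"}.
#' @export
classifier_config <- function(alpha = 0.05, detlim = 25,
                              run_outlier_detection = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  dl <- .as_detlim(detlim)
  if (!(dl$neg < dl$pos)) stop("negative limit must lie below positive limit")
  structure(list(alpha = alpha, detlim = dl,
                 run_outlier_detection = isTRUE(run_outlier_detection)),
            class = "classifier_config")
}

#' One-sided weighted t-test against a response threshold
#'
#' Tests whether the weighted mean response exceeds (direction
#' \code{"greater"}) or falls below (direction \code{"less"}) a threshold,
#' using the same neighbor-similarity weights as the WNLS fit so outlying
#' responses do not dominate. With the sum-to-n weight normalization,
#' \eqn{m_w = \sum w_i R_i / \sum w_i},
#' \eqn{s^2_w = \sum w_i (R_i - m_w)^2 / (\sum w_i - 1)},
#' \eqn{t = (m_w - threshold)/(s_w/\sqrt{n})} on n - 1 degrees of freedom.
#' Equal weights recover the ordinary one-sample Student t-test.
#'
#' @param responses Numeric response vector (length >= 2).
#' @param weights Nonnegative weights summing to \code{length(responses)};
#'   defaults to equal weights.
#' @param threshold Response threshold (\% of positive control).
#' @param direction \code{"greater"} or \code{"less"}.
#' @return One-sided p-value. Degenerate zero-variance samples give p = 0
#'   when the weighted mean deviates from the threshold in the tested
#'   direction, otherwise p = 1.
#' @export
weighted_t_test <- function(responses, weights = rep(1, length(responses)),
                            threshold, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  r <- as.numeric(responses)
  n <- length(r)
  if (n < 2L) stop("weighted t-test requires at least 2 responses")
  if (length(weights) != n || any(weights < 0))
    stop("'weights' must be nonnegative, one per response")
  sw <- sum(weights)
  mw <- sum(weights * r) / sw
  s2 <- sum(weights * (r - mw)^2) / (sw - 1)
  dev <- mw - threshold
  if (s2 <= 0) {
    hit <- if (direction == "greater") dev > 0 else dev < 0
    return(if (hit) 0 else 1)
  }
  tstat <- dev / sqrt(s2 / n)
  stats::pt(tstat, df = n - 1, lower.tail = (direction == "less"))
}

## ---------------------------------------------------------------------------
## Per-profile statistics table: every quantity the decision tree consumes.
## Computing this once and sweeping alpha over it afterwards is what makes
## ROC curves and large simulated screens affordable.

.na_fit <- list(r0 = NA_real_, rmax = NA_real_, ac50 = NA_real_,
                slope = NA_real_, sse = NA_real_)

.fit_row <- function(fit) {
  if (is.null(fit)) return(.na_fit)
  list(r0 = fit$params$r0, rmax = fit$params$rmax, ac50 = fit$params$ac50,
       slope = fit$params$slope, sse = fit$sse)
}

#' Compute every stage-level statistic for one profile
#'
#' Runs (optionally) outlier detection, neighbor weights, the NLS and WNLS
#' Hill fits with their matched flat-line fits and overall F-tests, and the
#' weighted t-tests against both detection limits. The result is a one-row
#' data frame of call ingredients; \code{\link{classify}} applies the
#' decision tree to it, and the ROC machinery re-applies the tree at many
#' significance levels without refitting. Profiles with 4 or fewer usable
#' points skip the Hill fits: the overall F-test has no residual degrees of
#' freedom there and only the Stage 2 t-test can ever fire.
#'
#' @inheritParams classify
#' @return One-row \code{data.frame} (columns: masked extremes, F-test
#'   p-values and direction signs per fit, t-test p-values, weighted mean,
#'   fitted parameters, bookkeeping).
#' @export
classify_stats <- function(profile, config = classifier_config()) {
  stopifnot(inherits(profile, "qhts_profile"),
            inherits(config, "classifier_config"))
  if (config$run_outlier_detection) profile <- detect_outliers(profile)
  u <- .prof_used(profile)
  n <- u$n
  low_n <- n < 4L
  w <- if (n >= 2L) neighbor_weights(profile) else rep(1, n)
  wmean <- sum(w * u$resp) / sum(w)
  if (n >= 4L) {   # below 4 points the profile is reported INACTIVE/low_n
    p_t_pos <- weighted_t_test(u$resp, w, config$detlim$pos, "greater")
    p_t_neg <- weighted_t_test(u$resp, w, config$detlim$neg, "less")
  } else {
    p_t_pos <- p_t_neg <- NA_real_
  }
  fit_n <- fit_w <- NULL
  p_f_nls <- p_f_wnls <- NA_real_
  dir_nls <- dir_wnls <- 0
  if (n > 4L) {
    fit_n <- fit_hill_nls(profile)
    fit_w <- fit_hill_wnls(profile, w)
    ft_n <- overall_f_test(fit_n, fit_constant(profile))
    ft_w <- overall_f_test(fit_w, fit_constant(profile, w))
    if (ft_n$defined) p_f_nls <- ft_n$p
    if (ft_w$defined) p_f_wnls <- ft_w$p
    dir_nls <- sign(fit_n$params$rmax - fit_n$params$r0)
    dir_wnls <- sign(fit_w$params$rmax - fit_w$params$r0)
  }
  fn <- .fit_row(fit_n); fw <- .fit_row(fit_w)
  data.frame(substance_id = profile$substance_id, n_used = n,
             low_n = low_n,
             outliers_removed = sum(!profile$included),
             max_r = max(u$resp), min_r = min(u$resp), wmean = wmean,
             p_f_nls = p_f_nls, p_f_wnls = p_f_wnls,
             dir_nls = dir_nls, dir_wnls = dir_wnls,
             p_t_pos = p_t_pos, p_t_neg = p_t_neg,
             nls_r0 = fn$r0, nls_rmax = fn$rmax, nls_ac50 = fn$ac50,
             nls_slope = fn$slope, nls_sse = fn$sse,
             wnls_r0 = fw$r0, wnls_rmax = fw$rmax, wnls_ac50 = fw$ac50,
             wnls_slope = fw$slope, wnls_sse = fw$sse,
             stringsAsFactors = FALSE)
}

#' Apply the three-stage decision tree to a statistics table
#'
#' Vectorized over the rows of a table built by \code{\link{classify_stats}}
#' (or \code{rbind} of several). Stage 1 calls ACTIVE[+/-1] when the masked
#' extreme response clears the detection limit, both overall F-tests reject
#' at \code{alpha}, and both fits agree on direction; Stage 2 calls
#' ACTIVE[+/-2] when the weighted t-test against the detection limit
#' rejects; Stage 3 calls INCONCLUSIVE[+/-3] when the extreme clears the
#' limit and exactly the F-test/direction pair of one fit supports it;
#' everything else is INACTIVE. If activator and inhibitor branches both
#' qualify in one stage, the branch with the larger excess beyond its limit
#' (stages 1/3) or the larger absolute weighted mean (stage 2) wins.
#'
#' @param stats Data frame of call ingredients.
#' @param alpha Significance level.
#' @param detlim Detection limits (as in \code{\link{classifier_config}}).
#' @return Data frame with columns \code{call} (e.g. \code{"ACTIVE[1]"},
#'   \code{"INACTIVE"}), \code{stage} (1, 2, 3 or NA) and
#'   \code{direction} (+1, -1 or 0).
#' @export
apply_call_tree <- function(stats, alpha = 0.05, detlim = 25) {
  dl <- .as_detlim(detlim)
  m <- nrow(stats)
  rej_nls <- !is.na(stats$p_f_nls) & stats$p_f_nls < alpha
  rej_wnls <- !is.na(stats$p_f_wnls) & stats$p_f_wnls < alpha
  above <- stats$max_r > dl$pos
  below <- stats$min_r < dl$neg
  s1_pos <- above & rej_nls & rej_wnls & stats$dir_nls > 0 & stats$dir_wnls > 0
  s1_neg <- below & rej_nls & rej_wnls & stats$dir_nls < 0 & stats$dir_wnls < 0
  excess_pos <- stats$max_r - dl$pos
  excess_neg <- dl$neg - stats$min_r
  pos_wins <- excess_pos >= excess_neg
  s2_pos <- !is.na(stats$p_t_pos) & stats$p_t_pos < alpha
  s2_neg <- !is.na(stats$p_t_neg) & stats$p_t_neg < alpha
  s2_pos_wins <- stats$wmean >= 0
  s3_pos <- above & ((rej_nls & stats$dir_nls > 0) |
                     (rej_wnls & stats$dir_wnls > 0))
  s3_neg <- below & ((rej_nls & stats$dir_nls < 0) |
                     (rej_wnls & stats$dir_wnls < 0))
  call <- rep("INACTIVE", m)
  stage <- rep(NA_integer_, m)
  direction <- rep(0L, m)
  set_call <- function(idx, label, stg, dir) {
    idx <- idx & call == "INACTIVE" & is.na(stage)
    call[idx] <<- label; stage[idx] <<- stg; direction[idx] <<- dir
  }
  # stage order matters: a substance takes the first terminal call
  set_call(s1_pos & (!s1_neg | pos_wins), "ACTIVE[1]", 1L, 1L)
  set_call(s1_neg, "ACTIVE[-1]", 1L, -1L)
  set_call(s2_pos & (!s2_neg | s2_pos_wins), "ACTIVE[2]", 2L, 1L)
  set_call(s2_neg, "ACTIVE[-2]", 2L, -1L)
  set_call(s3_pos & (!s3_neg | pos_wins), "INCONCLUSIVE[3]", 3L, 1L)
  set_call(s3_neg, "INCONCLUSIVE[-3]", 3L, -1L)
  data.frame(call = call, stage = stage, direction = direction,
             stringsAsFactors = FALSE)
}

#' Classify one concentration-response profile
#'
#' Runs the full three-stage algorithm on one profile: outlier detection
#' (when enabled), neighbor weighting, NLS and WNLS Hill fits, the overall
#' F-tests against the flat line, the weighted t-tests against the
#' detection limits, then Stages 1, 2 and 3 in order until a terminal call
#' is reached. Profiles left with fewer than 4 usable points are reported
#' INACTIVE with \code{low_n = TRUE}.
#'
#' @param profile A \code{\link{qhts_profile}}.
#' @param config A \code{\link{classifier_config}}.
#' @return A one-row \code{data.frame} (class \code{"call_record"}): the
#'   call, its stage and direction, every stage-level p-value, the fitted
#'   parameters of both Hill fits, \code{n_used} and
#'   \code{outliers_removed}.
#' @examples
#' grid <- concentration_grid(14)
#' prof <- qhts_profile("ex", grid, hill_response(hill_params(0, 100, 0.1, 1), grid))
#' classify(prof)$call   # "ACTIVE[1]"
#' @export
classify <- function(profile, config = classifier_config()) {
  stats <- classify_stats(profile, config)
  res <- apply_call_tree(stats, config$alpha, config$detlim)
  out <- cbind(res, stats[, setdiff(names(stats), "substance_id")])
  out <- cbind(substance_id = stats$substance_id, out,
               stringsAsFactors = FALSE)
  class(out) <- c("call_record", "data.frame")
  out
}

#' Classify a list of profiles
#'
#' @param profiles List of \code{\link{qhts_profile}} objects.
#' @inheritParams classify
#' @param progress Print a dot every 500 profiles (useful for large
#'   screens).
#' @return A \code{data.frame} with one \code{\link{classify}} row per
#'   profile.
#' @export
classify_profiles <- function(profiles, config = classifier_config(),
                              progress = FALSE) {
  stats <- classify_stats_table(profiles, config, progress = progress)
  res <- apply_call_tree(stats, config$alpha, config$detlim)
  out <- cbind(res, stats[, setdiff(names(stats), c("call", "stage", "direction"))])
  out <- out[, c("substance_id", "call", "stage", "direction",
                 setdiff(names(out), c("substance_id", "call", "stage",
                                       "direction")))]
  rownames(out) <- NULL
  out
}

#' Build the statistics table for a list of profiles
#'
#' @inheritParams classify_profiles
#' @return \code{data.frame}, one \code{\link{classify_stats}} row per
#'   profile.
#' @export
classify_stats_table <- function(profiles, config = classifier_config(),
                                 progress = FALSE) {
  rows <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    rows[[i]] <- classify_stats(profiles[[i]], config)
    if (progress && i %% 500L == 0L) cat(".")
  }
  if (progress) cat("\n")
  do.call(rbind, rows)
}
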