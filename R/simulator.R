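#' Log-spaced assay concentration grid
#'
#' The standard 14-point dilution series of the emulated assay:
#' log10-equally-spaced concentrations from 4.90e-4 to 76.63 uM inclusive.
#'
#' @param n_points Number of concentrations (>= 2; default 14).
#' @param c_min,c_max Range endpoints (uM).
#' @return Numeric vector of concentrations, increasing.
#' @export
concentration_grid <- function(n_points = 14L, c_min = 4.90e-4,
                               c_max = 76.63) {
  if (n_points < 2L) stop("'n_points' must be at least 2")
  10^seq(log10(c_min), log10(c_max), length.out = n_points)
}

#' Residual-error specification
#'
#' Residual errors are drawn as independent N(0, sigma_i^2). Either a
#' constant sigma (in \% of the positive control) or the
#' concentration-linear heteroscedastic model
#' \eqn{\sigma(C_i) = a + b C_i} with the defaults a = 9.7355, b = 0.1146
#' estimated from nuclear-receptor agonist assay noise.
#'
#' @param kind \code{"constant"} or \code{"concentration_linear"}.
#' @param sigma Constant standard deviation (\%), for
#'   \code{kind = "constant"}.
#' @param a,b Intercept and slope of sigma(C), for
#'   \code{kind = "concentration_linear"}.
#' @return List of class \code{"error_spec"}.
#' @export
error_spec <- function(kind = c("constant", "concentration_linear"),
                       sigma = 25, a = 9.7355, b = 0.1146) {
  kind <- match.arg(kind)
  if (kind == "constant" && (!is.numeric(sigma) || sigma < 0))
    stop("'sigma' must be nonnegative")
  structure(list(kind = kind, sigma = sigma, a = a, b = b),
            class = "error_spec")
}

#' Per-concentration residual standard deviation
#'
#' @param error An \code{\link{error_spec}}.
#' @param conc Concentration vector (uM).
#' @return Vector of sigma_i values (\%).
#' @export
error_sigma <- function(error, conc) {
  stopifnot(inherits(error, "error_spec"))
  if (error$kind == "constant") rep(error$sigma, length(conc))
  else error$a + error$b * conc
}

#' Simulate one concentration-response profile
#'
#' Draws \eqn{R_i = hill(C_i) + \epsilon_i} with independent
#' \eqn{\epsilon_i \sim N(0, \sigma_i^2)}. Uses the current R random
#' stream; seed it (or use \code{\link{simulate_dataset}}) for
#' reproducibility.
#'
#' @param params True \code{\link{hill_params}} (a null substance is
#'   encoded as \code{rmax == r0}).
#' @param error An \code{\link{error_spec}}.
#' @param grid Concentration vector (default the 14-point assay grid).
#' @param substance_id Label for the profile.
#' @return A \code{\link{qhts_profile}}.
#' @export
simulate_profile <- function(params, error = error_spec(),
                             grid = concentration_grid(),
                             substance_id = "sim") {
  mu <- hill_response(params, grid)
  s <- error_sigma(error, grid)
  qhts_profile(substance_id, grid, mu + stats::rnorm(length(grid), 0, s))
}

#' Randomly mask points to emulate smaller designs
#'
#' Marks \code{k_remove} points, chosen uniformly without replacement, as
#' excluded, leaving an effective sample size of
#' \code{n_points - k_remove}. Emulates designs with fewer concentrations
#' or points lost to experimental failure.
#'
#' @param profile A \code{\link{qhts_profile}}.
#' @param k_remove Number of points to mask (0 <= k < number of points).
#' @return The profile with an updated \code{included} mask.
#' @export
thin_profile <- function(profile, k_remove) {
  stopifnot(inherits(profile, "qhts_profile"))
  np <- length(profile$conc)
  if (k_remove < 0L || k_remove >= np)
    stop("'k_remove' must be in [0, number of points)")
  if (k_remove == 0L) return(profile)
  drop <- sample.int(np, k_remove)
  inc <- profile$included
  inc[drop] <- FALSE
  qhts_profile(profile$substance_id, profile$conc, profile$resp, inc)
}

#' Simulation configuration for one screening data set
#'
#' Defines one simulated screen: \code{n_active} true actives sharing one
#' Hill parameter configuration plus \code{n_null} true inactives
#' (RMAX = R0 = 0), all observed on the same concentration grid with the
#' same residual-error structure, optionally thinned to a smaller effective
#' sample size. The defaults reproduce the study conditions: 2,000 actives
#' and 8,000 inactives on the 14-point grid.
#'
#' @param error An \code{\link{error_spec}}.
#' @param n_points Points per profile (default 14).
#' @param points_removed Points randomly masked per profile (default 0;
#'   e.g. 10 leaves n = 4).
#' @param n_active,n_null Numbers of true actives and true nulls.
#' @param seed Integer seed making the data set reproducible.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(error = error_spec(), n_points = 14L,
                       points_removed = 0L, n_active = 2000L,
                       n_null = 8000L, seed = 1L) {
  stopifnot(inherits(error, "error_spec"), n_points >= 2L,
            points_removed >= 0L, points_removed < n_points,
            n_active >= 0L, n_null >= 0L)
  structure(list(error = error, n_points = as.integer(n_points),
                 points_removed = as.integer(points_removed),
                 n_active = as.integer(n_active),
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a labeled screening data set
#'
#' Generates \code{config$n_active} profiles from \code{active_params} and
#' \code{config$n_null} null profiles (RMAX = R0 = 0, drawn through the
#' identical noise model), applies the configured thinning, and records the
#' ground truth per substance. Deterministic given \code{config$seed}: the
#' whole data set is drawn from a single seeded stream.
#'
#' @param config A \code{\link{sim_config}}.
#' @param active_params \code{\link{hill_params}} of the true actives.
#' @return List of class \code{"sim_dataset"}: \code{profiles} (list of
#'   \code{\link{qhts_profile}}) and \code{truth} (data frame with
#'   \code{substance_id}, \code{active}, \code{r0}, \code{rmax},
#'   \code{ac50}, \code{slope}).
#' @export
simulate_dataset <- function(config, active_params) {
  stopifnot(inherits(config, "sim_config"),
            inherits(active_params, "hill_params"))
  grid <- concentration_grid(config$n_points)
  null_params <- hill_params(0, 0, active_params$ac50, active_params$slope)
  n_tot <- config$n_active + config$n_null
  profiles <- vector("list", n_tot)
  active <- c(rep(TRUE, config$n_active), rep(FALSE, config$n_null))
  ids <- sprintf("%s%05d", ifelse(active, "act", "nul"), seq_len(n_tot))
  set.seed(config$seed)
  for (i in seq_len(n_tot)) {
    p <- simulate_profile(if (active[i]) active_params else null_params,
                          config$error, grid, ids[i])
    if (config$points_removed > 0L)
      p <- thin_profile(p, config$points_removed)
    profiles[[i]] <- p
  }
  truth <- data.frame(
    substance_id = ids, active = active,
    r0 = ifelse(active, active_params$r0, 0),
    rmax = ifelse(active, active_params$rmax, 0),
    ac50 = active_params$ac50, slope = active_params$slope,
    stringsAsFactors = FALSE)
  structure(list(profiles = profiles, truth = truth, config = config,
                 active_params = active_params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated qHTS data set: %d actives + %d nulls, n = %d points (%d masked), seed %d\n",
              x$config$n_active, x$config$n_null, x$config$n_points,
              x$config$points_removed, x$config$seed))
  invisible(x)
}

#' Write a simulated data set to long-format CSV
#'
#' One row per substance-concentration pair, with the ground truth
#' attached; the inverse of \code{\link{read_profiles}} for the profile
#' columns.
#'
#' @param dataset A \code{\link{simulate_dataset}} result.
#' @param path Output file.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  tr <- dataset$truth
  rows <- lapply(seq_along(dataset$profiles), function(i) {
    p <- dataset$profiles[[i]]
    data.frame(substance_id = p$substance_id,
               concentration_uM = p$conc, response_pct = p$resp,
               included = p$included,
               truth_label = if (tr$active[i]) "active" else "null",
               truth_AC50 = tr$ac50[i], truth_RMAX = tr$rmax[i],
               truth_SLOPE = tr$slope[i], stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
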