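test_that("neighbor weights down-weight isolated disagreement and sum to n", {
  p_flat <- qhts_profile("f", 10^(1:5), rep(7, 5))
  expect_equal(neighbor_weights(p_flat), rep(1, 5))
  # isolated spike: d = (0, 0, 50, 100) -> last point gets the least weight
  p <- qhts_profile("s", 10^(1:4), c(0, 0, 0, 100))
  w <- neighbor_weights(p)
  expect_lt(w[4], w[1])
  expect_equal(which.min(w), 4L)
  expect_equal(sum(w), 4, tolerance = 1e-12)
  # normalization holds on arbitrary noisy profiles
  set.seed(1)
  for (i in 1:5) {
    pr <- qhts_profile("r", 10^(1:9), rnorm(9, 0, 40))
    expect_equal(sum(neighbor_weights(pr)), 9, tolerance = 1e-12)
  }
  expect_error(neighbor_weights(qhts_profile("one", 1, 5)), "at least 2")
})

test_that("noiseless Hill data are recovered essentially exactly", {
  for (par in list(c(0, 100, 0.1, 1), c(10, -90, 2, 2), c(0, 40, 0.005, 0.7))) {
    prof <- clean_profile(par[1], par[2], par[3], par[4])
    for (fit in list(fit_hill_nls(prof),
                     fit_hill_wnls(prof))) {
      expect_true(fit$converged)
      expect_lt(fit$sse, 1e-6)
      expect_lt(abs(fit$params$rmax - par[2]) / abs(par[2]), 1e-3)
      expect_lt(abs(fit$params$ac50 - par[3]) / par[3], 1e-3)
      expect_lt(abs(fit$params$slope - par[4]) / par[4], 1e-3)
    }
  }
})

test_that("equal weights make WNLS coincide with NLS", {
  for (seed in 1:3) {
    prof <- noisy_profile(sigma = 25, seed = seed)
    f1 <- fit_hill_nls(prof)
    f2 <- fit_hill_wnls(prof, rep(1, 14))
    expect_lt(abs(f1$params$r0 - f2$params$r0), 1e-6)
    expect_lt(abs(f1$params$rmax - f2$params$rmax), 1e-6)
    expect_lt(abs(log10(f1$params$ac50) - log10(f2$params$ac50)), 1e-6)
    expect_lt(abs(f1$sse - f2$sse), 1e-6)
  }
})

test_that("fitted SSE matches an independent brute-force minimizer", {
  # oracle: coarse 4-parameter lattice refined by Nelder-Mead (stats::optim),
  # sharing no code with the package's grid-profiling + Levenberg-Marquardt
  oracle_sse <- function(conc, resp) {
    obj <- function(v) {
      g <- 1 / (1 + 10^pmin(pmax(v[4] * (v[3] - log10(conc)), -300), 300))
      sum((resp - (v[1] + (v[2] - v[1]) * g))^2)
    }
    best <- Inf
    for (la in seq(-4, 2.5, by = 0.5))
      for (sl in c(0.3, 1, 3))
        for (span in c(-100, 100)) {
          o <- optim(c(mean(resp), mean(resp) + span, la, sl), obj,
                     control = list(maxit = 2000, reltol = 1e-12))
          best <- min(best, o$value)
        }
    best
  }
  for (seed in c(11, 12)) {
    prof <- noisy_profile(rmax = 80, ac50 = 0.5, sigma = 25, seed = seed)
    fit <- fit_hill_nls(prof)
    expect_lt(fit$sse, oracle_sse(prof$conc, prof$resp) * 1.001)
  }
})

test_that("down-weighting a spike shrinks the fitted response span", {
  prof <- spike_profile()
  f_nls <- fit_hill_nls(prof)
  w <- rep(1e-3, 14); w[1:13] <- (14 - 13 * 1e-3) / 13  # mass on the flat part
  f_w <- fit_hill_wnls(prof, w * 14 / sum(w))
  expect_lt(abs(f_w$params$rmax - f_w$params$r0),
            abs(f_nls$params$rmax - f_nls$params$r0))
})

test_that("constant fit reproduces hand-computed weighted means", {
  prof <- qhts_profile("c", c(1, 10, 100), c(10, 20, 30))
  f <- fit_constant(prof)
  expect_equal(f$params, 20)
  expect_equal(f$sse, 200)
  expect_equal(fit_constant(prof, rep(1, 3))$params, 20)
  # w = (2, 1, 0): level = (2*10 + 1*20)/3
  f2 <- fit_constant(prof, c(2, 1, 0))
  expect_equal(f2$params, 40 / 3)
  expect_equal(f2$sse, 2 * (10 - 40 / 3)^2 + (20 - 40 / 3)^2)
})

test_that("hill fit never loses to the nested constant fit", {
  set.seed(3)
  for (i in 1:6) {
    prof <- noisy_profile(rmax = sample(c(0, 50, 100), 1), sigma = 30,
                          seed = 100 + i)
    expect_lte(fit_hill_nls(prof)$sse, fit_constant(prof)$sse + 1e-6)
    w <- neighbor_weights(prof)
    expect_lte(fit_hill_wnls(prof, w)$sse, fit_constant(prof, w)$sse + 1e-6)
  }
  # identically-zero responses: both models are exact
  z <- flat_profile(0)
  expect_lte(fit_hill_nls(z)$sse, fit_constant(z)$sse + 1e-12)
  expect_equal(fit_constant(z)$sse, 0)
})

test_that("overall F-test follows the closed form and flags degenerate df", {
  mk <- function(sse, n, kind) {
    structure(list(model_kind = kind, weighted = FALSE, params = NULL,
                   sse = sse, n_used = n,
                   n_params = if (kind == "hill") 4L else 1L,
                   converged = TRUE, weights = NULL,
                   outliers_removed = integer()), class = "hill_fit")
  }
  # F = [(1000 - 100)/3] / [100/10] = 30 on (3, 10)
  ft <- overall_f_test(mk(100, 14, "hill"), mk(1000, 14, "constant"))
  expect_equal(ft$f, 30)
  expect_equal(ft$p, pf(30, 3, 10, lower.tail = FALSE))
  # no improvement: F clamps to 0, p = 1
  ft0 <- overall_f_test(mk(500, 14, "hill"), mk(500, 14, "constant"))
  expect_equal(ft0$f, 0)
  expect_equal(ft0$p, 1)
  # n = 4: undefined, never significant
  ft4 <- overall_f_test(mk(10, 4, "hill"), mk(100, 4, "constant"))
  expect_false(ft4$defined)
  expect_true(is.na(ft4$p))
  expect_error(overall_f_test(mk(10, 14, "hill"), mk(100, 12, "constant")),
               "share")
})

test_that("negating responses mirrors the fit and preserves SSE and F", {
  prof <- noisy_profile(rmax = 70, sigma = 20, seed = 9)
  neg <- negate_profile(prof)
  f1 <- fit_hill_nls(prof); f2 <- fit_hill_nls(neg)
  expect_equal(f2$params$r0, -f1$params$r0, tolerance = 1e-5)
  expect_equal(f2$params$rmax, -f1$params$rmax, tolerance = 1e-5)
  expect_equal(f2$sse, f1$sse, tolerance = 1e-6)
  p1 <- overall_f_test(f1, fit_constant(prof))$p
  p2 <- overall_f_test(f2, fit_constant(neg))$p
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("AC50 is recovered to within 0.2 log10 units under 10% noise", {
  set.seed(77)
  errs <- replicate(200, {
    prof <- simulate_profile(hill_params(0, 100, 0.1, 1),
                             error_spec(sigma = 10))
    abs(log10(fit_hill_nls(prof)$params$ac50) - log10(0.1))
  })
  expect_lt(median(errs), 0.2)
})

test_that("outlier detection flags planted spikes and nothing else", {
  clean <- clean_profile()
  expect_equal(detect_outliers(clean)$included, rep(TRUE, 14))
  # one response replaced by +500%: exactly that point goes
  spiked <- clean
  r <- spiked$resp; r[8] <- 500
  spiked <- qhts_profile("spiked", spiked$conc, r)
  out <- detect_outliers(spiked)
  expect_equal(which(!out$included), 8L)
  # below 6 points the mask is untouched
  small <- qhts_profile("s5", 10^(1:5), c(0, 0, 0, 0, 300))
  expect_equal(detect_outliers(small)$included, rep(TRUE, 5))
  # removals are capped at ceiling(n/7)
  r2 <- clean$resp; r2[c(3, 7, 11)] <- c(400, -400, 400)
  many <- qhts_profile("many", clean$conc, r2)
  expect_lte(sum(!detect_outliers(many)$included), 2)
})
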