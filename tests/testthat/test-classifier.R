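test_that("detection limits are mean +/- 3 SD of the negative controls", {
  dl <- detection_limits_from_controls(c(0, 0, 0))
  expect_equal(dl$pos, 0); expect_equal(dl$neg, 0)
  dl2 <- detection_limits_from_controls(c(-10, 10))
  expect_equal(dl2$pos, 3 * sd(c(-10, 10)))
  expect_equal(dl2$neg, -dl2$pos)
  expect_error(detection_limits_from_controls(5), "at least 2")
  # assay default when no controls are supplied
  expect_equal(classifier_config()$detlim$pos, 25)
  expect_equal(classifier_config()$detlim$neg, -25)
})

test_that("weighted t-test reduces to Student's t with equal weights", {
  r <- c(30, 35, 40, 45)
  p <- weighted_t_test(r, rep(1, 4), 25, "greater")
  expect_equal(p, t.test(r, mu = 25, alternative = "greater")$p.value)
  # hand arithmetic: t = (37.5 - 25)/(s/2), df = 3
  expect_equal(p, pt((37.5 - 25) / (sd(r) / 2), 3, lower.tail = FALSE))
  p_less <- weighted_t_test(r, rep(1, 4), 25, "less")
  expect_equal(p_less, t.test(r, mu = 25, alternative = "less")$p.value)
})

test_that("weighted t-test handles degenerate zero-variance samples", {
  expect_equal(weighted_t_test(rep(100, 5), rep(1, 5), 25, "greater"), 0)
  expect_equal(weighted_t_test(rep(100, 5), rep(1, 5), 25, "less"), 1)
  expect_equal(weighted_t_test(rep(25, 5), rep(1, 5), 25, "greater"), 1)
})

test_that("weighted t-test uses the stated weighted moments", {
  r <- c(10, 50, 20, 80)
  w <- c(2, 0.5, 1, 0.5)  # sums to 4
  mw <- sum(w * r) / 4
  s2 <- sum(w * (r - mw)^2) / 3
  expect_equal(weighted_t_test(r, w, 25, "greater"),
               pt((mw - 25) / sqrt(s2 / 4), 3, lower.tail = FALSE))
})

test_that("textbook profiles land in the expected terminal calls", {
  cfg <- classifier_config()
  expect_equal(classify(clean_profile(rmax = 100, ac50 = 0.1), cfg)$call,
               "ACTIVE[1]")
  expect_equal(classify(clean_profile(rmax = -100, ac50 = 0.1), cfg)$call,
               "ACTIVE[-1]")
  expect_equal(classify(flat_profile(0, sigma = 1), cfg)$call, "INACTIVE")
  # plateaued responder: no concentration-response, mean far above the limit
  expect_equal(classify(flat_profile(100, sigma = 3), cfg)$call, "ACTIVE[2]")
  expect_equal(classify(flat_profile(-100, sigma = 3), cfg)$call, "ACTIVE[-2]")
})

test_that("single-spike curves are inconclusive, not active", {
  cfg <- classifier_config(run_outlier_detection = FALSE)
  prof <- spike_profile()
  rec <- classify(prof, cfg)
  # NLS chases the spike (F rejects); WNLS down-weights it (F does not)
  expect_lt(rec$p_f_nls, 0.05)
  expect_gte(rec$p_f_wnls, 0.05)
  expect_equal(rec$call, "INCONCLUSIVE[3]")
  expect_equal(classify(negate_profile(prof), cfg)$call, "INCONCLUSIVE[-3]")
})

test_that("every profile gets exactly one call and stages fire in order", {
  set.seed(21)
  cfg <- classifier_config()
  profs <- c(
    lapply(1:6, function(i) noisy_profile(rmax = sample(c(-100, 0, 100), 1),
                                          sigma = 25, seed = 300 + i)),
    list(flat_profile(100, 3), spike_profile(), clean_profile())
  )
  calls <- classify_profiles(profs, cfg)
  expect_equal(nrow(calls), length(profs))
  expect_true(all(calls$call %in% c("ACTIVE[1]", "ACTIVE[-1]", "ACTIVE[2]",
                                    "ACTIVE[-2]", "INCONCLUSIVE[3]",
                                    "INCONCLUSIVE[-3]", "INACTIVE")))
  expect_true(all(is.na(calls$stage) == (calls$call == "INACTIVE")))
})

test_that("negating all responses mirrors every call", {
  flip <- c("ACTIVE[1]" = "ACTIVE[-1]", "ACTIVE[-1]" = "ACTIVE[1]",
            "ACTIVE[2]" = "ACTIVE[-2]", "ACTIVE[-2]" = "ACTIVE[2]",
            "INCONCLUSIVE[3]" = "INCONCLUSIVE[-3]",
            "INCONCLUSIVE[-3]" = "INCONCLUSIVE[3]",
            "INACTIVE" = "INACTIVE")
  cfg <- classifier_config()
  for (i in 1:8) {
    prof <- noisy_profile(rmax = sample(c(-100, -50, 0, 50, 100), 1),
                          ac50 = sample(c(0.001, 0.1, 10), 1),
                          sigma = 25, seed = 400 + i)
    a <- classify(prof, cfg)$call
    b <- classify(negate_profile(prof), cfg)$call
    expect_equal(b, unname(flip[a]), info = sprintf("seed %d", 400 + i))
  }
})

test_that("ACTIVE[1] calls are monotone in the significance level", {
  cfg <- classifier_config()
  profs <- lapply(1:12, function(i)
    noisy_profile(rmax = sample(c(0, 50), 1), sigma = 25, seed = 500 + i))
  stats <- classify_stats_table(profs, cfg)
  a_small <- apply_call_tree(stats, 0.01, 25)$call == "ACTIVE[1]"
  a_large <- apply_call_tree(stats, 0.2, 25)$call %in%
    c("ACTIVE[1]", "ACTIVE[2]")  # at larger alpha stage 1 can only grow
  s1_large <- apply_call_tree(stats, 0.2, 25)$call == "ACTIVE[1]"
  expect_true(all(!a_small | s1_large))
})

test_that("four usable points can never yield stage 1 or 3 calls", {
  set.seed(61)
  for (i in 1:10) {
    prof <- noisy_profile(rmax = 100, ac50 = 0.001, sigma = 25,
                          seed = 600 + i)
    prof <- thin_profile(prof, 10)
    rec <- classify(prof)
    expect_true(rec$call %in% c("ACTIVE[2]", "ACTIVE[-2]", "INACTIVE"))
  }
})

test_that("profiles with fewer than 4 usable points are inactive-flagged", {
  prof <- qhts_profile("tiny", 10^(1:3), c(100, 100, 100))
  rec <- classify(prof)
  expect_equal(rec$call, "INACTIVE")
  expect_true(rec$low_n)
})
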