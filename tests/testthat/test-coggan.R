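test_that("build_power_series lays out work and rest blocks at 1 Hz", {
  plan <- session_plan(2, 15, 15, rest_power = 100, work_power = 400)
  s <- build_power_series(plan)
  expect_equal(nrow(s), 45)
  expect_equal(s$power_w, c(rep(400, 15), rep(100, 15), rep(400, 15)))

  plan <- session_plan(1, 60, 0, rest_power = 0, work_power = 300)
  expect_equal(build_power_series(plan)$power_w, rep(300, 60))

  plan <- session_plan(2, 10, 5, rest_power = 100, work_power = 400)  # 25 s
  expect_error(build_power_series(plan), class = "hiitsim_series_too_short_error")
})

test_that("normalized_power follows the four-step rolling-window algorithm", {
  # constant series: every window mean equals the constant
  expect_equal(normalized_power(rep(300, 30)), 300)
  expect_equal(normalized_power(rep(300, 3600)), 300)
  expect_equal(normalized_power(rep(123.4, 77)), 123.4)

  # step series against the literal window-loop oracle
  p <- c(rep(400, 30), rep(200, 30))
  expect_equal(normalized_power(p), np_bruteforce(p))
  expect_gt(normalized_power(p), mean(p))  # ~317 W vs the 300 W mean
  expect_equal(round(np_bruteforce(p), 1), 316.6)

  set.seed(11)
  for (i in 1:10) {
    p <- runif(sample(30:240, 1), 0, 600)
    expect_equal(normalized_power(p), np_bruteforce(p))
    # power-mean inequality over the quantities actually averaged: NP is the
    # quartic mean of the 30-s window means, so it dominates their arithmetic
    # mean (the full-series mean is incomparable in general because edge
    # samples enter fewer fully contained windows)
    wm <- vapply(seq_len(length(p) - 29), function(i) mean(p[i:(i + 29)]),
                 numeric(1))
    expect_gte(normalized_power(p), mean(wm))
  }

  expect_error(normalized_power(rep(300, 29)),
               class = "hiitsim_series_too_short_error")
  expect_error(normalized_power(c(rep(300, 40), -5)),
               class = "hiitsim_validation_error")
})

test_that("NP is monotone non-decreasing in any single sample", {
  set.seed(3)
  p <- runif(60, 100, 500)
  for (i in c(1, 17, 60)) {
    bumped <- p
    bumped[i] <- bumped[i] + 50
    expect_gte(normalized_power(bumped), normalized_power(p))
  }
})

test_that("intensity factor and TSS match their defining ratios", {
  expect_equal(intensity_factor(264, 264), 1)
  expect_equal(intensity_factor(132, 264), 0.5)
  expect_equal(intensity_factor(281 * 1.1, 281), 1.1)
  expect_error(intensity_factor(300, 0), class = "hiitsim_domain_error")

  # one hour at threshold scores exactly 1 on the unscaled definition
  expect_equal(tss(3600, pn = 281, ftp = 281), 1)
  expect_equal(tss(1800, pn = 281, ftp = 281), 0.5)
  expect_equal(tss(3600, pn = 2 * 281, ftp = 281), 4)
  expect_equal(tss(3600, pn = 281, ftp = 281, scale_100 = TRUE), 100)

  # maximal TSS substitutes the duration-best power for NP
  expect_equal(tss_max(3600, pmax_t = 281, ftp = 281), 1)
  expect_equal(tss_max(300, pmax_t = 375, ftp = 227), (375 / 227)^2 * 300 / 3600)
  expect_equal(round(tss_max(300, 375, 227), 4), 0.2274)
  expect_equal(tss_max(7200, pmax_t = 281, ftp = 281), 2)

  # TSS meets the maximal TSS exactly when NP reaches the duration-best power
  expect_equal(tss(600, 350, 280), tss_max(600, 350, 280))
  expect_lt(tss(600, 349, 280), tss_max(600, 350, 280))
})

test_that("coggan_metrics summarises a series consistently", {
  m <- coggan_metrics(rep(264, 3600), ftp = 264)
  expect_equal(m$pn_w, 264)
  expect_equal(m$if_, 1)
  expect_equal(m$tss, 1)
  expect_gte(m$pn_w, m$mean_power_w)
})

test_that("the window-count NP used by the solver equals brute-force NP", {
  set.seed(5)
  for (i in 1:15) {
    plan <- random_plan(rest_power = 150, cp = 300)
    plan$work_power <- runif(1, 300, 900)
    counts <- hiitsim:::work_window_counts(plan)
    fast <- hiitsim:::np_from_counts(counts, plan$work_power, plan$rest_power)
    expect_equal(fast, np_bruteforce(build_power_series(plan)$power_w))
  }
})

test_that("solver: a single continuous bout solves to the duration-best power", {
  # for a constant series NP = P, so the root is pmax(work_s) identically and
  # the session is classified possible (ratio exactly 100%)
  tt <- bundled_profiles("time_trialist")
  plan <- session_plan(1, 300, 0, rest_power = 0)
  expect_equal(solve_power_coggan(plan, tt), pmax_power(tt, 300), tolerance = 1e-5)
  rec <- classify_session(plan, tt, "coggan_modified")
  expect_equal(rec$ratio_pct, 100, tolerance = 1e-3)
  expect_false(rec$impossible)
})

test_that("solver drives session NP to the duration-maximal power within tol", {
  tt <- bundled_profiles("time_trialist")
  for (plan in list(session_plan(2, 15, 300, rest_power = 191),
                    session_plan(6, 45, 90, rest_power = 191),
                    session_plan(12, 30, 30, rest_power = 191))) {
    p_star <- solve_power_coggan(plan, tt, tol = 1e-3)
    plan$work_power <- p_star
    np <- np_bruteforce(build_power_series(plan)$power_w)
    expect_equal(np, pmax_power(tt, plan$total_s), tolerance = 1e-3)
  }
})

test_that("solver tolerance bounds the NP mismatch proportionally", {
  tt <- bundled_profiles("time_trialist")
  plan <- session_plan(4, 60, 120, rest_power = 191)
  for (tol in c(1e-1, 1e-3)) {
    p_star <- solve_power_coggan(plan, tt, tol = tol)
    plan2 <- plan
    plan2$work_power <- p_star
    np <- normalized_power(build_power_series(plan2))
    expect_lt(abs(np - pmax_power(tt, plan$total_s)), tol)
  }
})

test_that("solver rejects unreachable targets and out-of-range durations", {
  tt <- bundled_profiles("time_trialist")
  # rest power above the duration-best power: NP already exceeds the target
  plan <- session_plan(2, 60, 60, rest_power = 500)
  expect_error(solve_power_coggan(plan, tt), class = "hiitsim_no_solution_error")
  # session longer than the profile's last node
  plan <- session_plan(10, 300, 3000, rest_power = 191)
  expect_error(solve_power_coggan(plan, tt), class = "hiitsim_range_error")
})
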