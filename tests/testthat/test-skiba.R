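test_that("depletion above CP is linear in the power surplus", {
  expect_equal(wbal_deplete(21500, 431, 304, 10), 21500 - (431 - 304) * 10)
  expect_equal(wbal_deplete(21500, 431, 304, 10), 20230)
  # riding exactly at CP neither drains nor restores
  expect_equal(wbal_deplete(5000, 300, 300, 1e6), 5000)
  # the balance may go negative inside a step; callers detect the crossing
  expect_equal(wbal_deplete(1000, 404, 304, 20), -1000)
  expect_error(wbal_deplete(1000, 250, 304, 10), class = "hiitsim_contract_error")
  expect_error(wbal_deplete(1000, 404, 304, 0), class = "hiitsim_contract_error")
})

test_that("reconstitution decays the deficit exponentially toward W'", {
  expected <- 21500 - (21500 - 10000) * exp((191 - 304) * 60 / 21500)
  expect_equal(wbal_recover(10000, 21500, 191, 304, 60), expected)
  expect_equal(round(expected), 13110)
  # a full reserve is a fixed point
  expect_equal(wbal_recover(21500, 21500, 150, 304, 3600), 21500)
  # long recovery approaches the full reserve from below
  w <- wbal_recover(5000, 21500, 303, 304, 2e5)
  expect_lt(w, 21500)
  expect_equal(w, 21500, tolerance = 1e-4)
  # strictly increasing in dt, never exceeding wprime
  dts <- seq(10, 600, by = 10)
  ws <- wbal_recover(8000, 21500, 191, 304, dts)
  expect_true(all(diff(ws) > 0))
  expect_true(all(ws <= 21500))
  expect_error(wbal_recover(1000, 21500, 304, 304, 10),
               class = "hiitsim_contract_error")
})

test_that("simulate_wbal reaches exhaustion exactly when the closed form says so", {
  # single bout at P = cp + wprime / t exhausts at t
  plan <- session_plan(1, 60, 0, rest_power = 0, work_power = 304 + 21500 / 60)
  traj <- simulate_wbal(plan, cp = 304, wprime = 21500)
  expect_equal(attr(traj, "exhaustion_time"), 60)
  expect_equal(traj$wbal_j[1], 21500)
  expect_equal(traj$wbal_j[nrow(traj)], 0)

  # mid-step crossing is located by linear interpolation
  plan <- session_plan(1, 100, 0, rest_power = 0, work_power = 304 + 21500 / 50.5)
  traj <- simulate_wbal(plan, cp = 304, wprime = 21500)
  expect_equal(attr(traj, "exhaustion_time"), 50.5)
})

test_that("simulated balance at the solved intensity depletes W' at session end", {
  tt <- bundled_profiles("time_trialist")
  for (plan in list(session_plan(2, 15, 300, rest_power = 191),
                    session_plan(5, 60, 60, rest_power = 191),
                    session_plan(10, 120, 45, rest_power = 191))) {
    p_star <- solve_power_skiba(plan, cp = tt$cp, wprime = tt$wprime)
    plan$work_power <- p_star
    traj <- simulate_wbal(plan, cp = tt$cp, wprime = tt$wprime)
    end_wbal <- traj$wbal_j[nrow(traj)]
    te <- attr(traj, "exhaustion_time")
    expect_true(abs(end_wbal) < 1)
    expect_true(is.na(te) || abs(te - plan$total_s) < 1)
    expect_true(all(traj$wbal_j <= tt$wprime + 1e-9))
  }
})

test_that("barely supra-CP work with generous rest never exhausts", {
  plan <- session_plan(3, 30, 1800, rest_power = 191, work_power = 304.5)
  traj <- simulate_wbal(plan, cp = 304, wprime = 21500)
  expect_true(is.na(attr(traj, "exhaustion_time")))
  expect_gt(traj$wbal_j[nrow(traj)], 21500 * 0.99)
})

test_that("simulate_wbal enforces its model domain", {
  plan <- session_plan(2, 60, 60, rest_power = 310, work_power = 400)
  expect_error(simulate_wbal(plan, cp = 304, wprime = 21500),
               class = "hiitsim_model_domain_error")
  plan <- session_plan(2, 60, 60, rest_power = 191, work_power = 300)
  expect_error(simulate_wbal(plan, cp = 304, wprime = 21500),
               class = "hiitsim_model_domain_error")
})

test_that("closed-form exhaustion power matches its published-arithmetic value", {
  plan <- session_plan(2, 15, 300, rest_power = 191)
  lambda <- exp((191 - 304) * 300 / 21500)
  expected <- 304 + 21500 * (1 - lambda) / (15 * (1 - lambda^2))
  expect_equal(solve_power_skiba(plan, 304, 21500), expected)
  expect_equal(round(expected), 1492)
})

test_that("closed form reduces to the continuous CP relation in its limits", {
  # single repetition: P* = cp + wprime / work_s
  plan <- session_plan(1, 120, 0, rest_power = 0)
  expect_equal(solve_power_skiba(plan, 304, 21500), 304 + 21500 / 120)
  # vanishing rest: P* -> cp + wprime / (n * work_s)
  plan <- session_plan(4, 60, 1e-9, rest_power = 191)
  expect_equal(solve_power_skiba(plan, 304, 21500),
               304 + 21500 / (4 * 60), tolerance = 1e-6)
})

test_that("closed form and bisection-on-simulation agree on random plans", {
  set.seed(7)
  for (i in 1:50) {
    plan <- random_plan(rest_power = 191, cp = 304)
    a <- solve_power_skiba(plan, 304, 21500)
    b <- solve_power_skiba(plan, 304, 21500, method = "bisection")
    expect_lt(abs(a - b), 0.01)
  }
})

test_that("exhaustion power responds monotonically to the plan parameters", {
  base <- list(n = 4, work = 60, rest = 120)
  p_of <- function(n = base$n, work = base$work, rest = base$rest) {
    solve_power_skiba(session_plan(n, work, rest, rest_power = 191), 304, 21500)
  }
  # longer rest -> more W' restored -> higher work power needed
  expect_true(all(diff(sapply(seq(30, 300, 30), function(r) p_of(rest = r))) > 0))
  # more repetitions or longer work intervals -> lower sustainable surplus
  expect_true(all(diff(sapply(2:10, function(n) p_of(n = n))) < 0))
  expect_true(all(diff(sapply(seq(30, 300, 30), function(w) p_of(work = w))) < 0))
})
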