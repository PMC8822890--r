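# Shared fixtures built in code.

# Profile whose nodes follow the hyperbolic law P = wprime / t + cp exactly.
hyperbolic_profile <- function(cp = 250, wprime = 20000,
                               durations = c(60, 120, 180, 240, 300, 600, 900),
                               name = "hyperbolic") {
  athlete_profile(
    name,
    nodes = data.frame(duration_s = durations, power_w = wprime / durations + cp),
    cp = cp, wprime = wprime
  )
}

# Random valid synthetic profile parameters for property tests.
random_profile <- function() {
  generate_profile(
    map = runif(1, 250, 450),
    endurance_slope = runif(1, -14, -4),
    wprime_syn = runif(1, 10000, 35000)
  )
}

# Random session plan with integer-second segments (so 1-Hz stepping is exact).
random_plan <- function(rest_power, cp) {
  session_plan(
    n_reps = sample(2:6, 1),
    work_s = sample(seq(15, 120, by = 15), 1),
    rest_s = sample(seq(15, 300, by = 15), 1),
    rest_power = rest_power
  )
}

# Brute-force Normalized Power: literal four-step algorithm with an explicit
# window loop. Independent of the package's cumulative-sum implementation.
np_bruteforce <- function(p) {
  n <- length(p)
  stopifnot(n >= 30)
  means4 <- vapply(seq_len(n - 29), function(i) mean(p[i:(i + 29)])^4, numeric(1))
  mean(means4)^0.25
}
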