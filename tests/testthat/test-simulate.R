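test_that("simulation is seed-deterministic and conserves components", {
  b1 <- generate_synthetic_bird("feedback", seed = 9, n_days_feedback = 3,
                                renditions_per_day = c(300, 400))
  b2 <- generate_synthetic_bird("feedback", seed = 9, n_days_feedback = 3,
                                renditions_per_day = c(300, 400))
  expect_identical(b1$trajectory$pitch, b2$trajectory$pitch)
  expect_identical(b1$trajectory$threshold, b2$trajectory$threshold)
  # ground-truth components sum exactly to pitch
  tt <- b1$truth
  expect_equal(b1$config$repertoire$p_star + tt$eps + tt$b + tt$c + tt$d +
                 tt$o, b1$trajectory$pitch, tolerance = 1e-12)
})

test_that("threshold policies compute the documented updates", {
  expect_equal(threshold_update(threshold_policy("daily_quantile", q = 0.5),
                                list(prev_day_pitches = 1:5)), 3)
  # linear-interpolation quantile convention
  expect_equal(threshold_update(threshold_policy("daily_quantile", q = 0.8),
                                list(prev_day_pitches = 1:10)), 8.2)
  expect_equal(threshold_update(threshold_policy("running_median"),
                                list(recent_pitches = 1:25)),
               median(6:25))
  expect_error(threshold_update(threshold_policy("daily_quantile"),
                                list(prev_day_pitches = numeric(0))),
               "empty")
  # human_auto holds the threshold while the escape rate is in band
  pol <- threshold_policy("human_auto")
  expect_equal(threshold_update(pol, list(recent_pitches = 1:20,
                                          recent_escape_rate = 0.5,
                                          current = 42)), 42)
  expect_equal(threshold_update(pol, list(recent_pitches = 1:20,
                                          recent_escape_rate = 0.9,
                                          current = 42)), median(1:20))
})

test_that("learning moves pitch in the escape direction; alpha = 0 does not", {
  bird <- generate_synthetic_bird("feedback", seed = 17,
                                  n_days_feedback = 10,
                                  renditions_per_day = c(500, 700))
  fb <- bird$trajectory[!is.na(bird$trajectory$threshold), ]
  days <- sort(unique(fb$day))
  first <- mean(fb$pitch[fb$day == days[1]])
  last <- mean(fb$pitch[fb$day == days[length(days)]])
  expect_gt(last - first, 10)  # contingency low: escape is up
  expect_gt(daily_improvement(bird$trajectory), 0)
  # smoothed trajectory rises monotonically at day resolution
  dm <- vapply(days, function(d) mean(fb$pitch[fb$day == d]), numeric(1))
  expect_gt(mean(diff(dm) > 0), 0.7)
  # alpha = 0: no drift beyond repertoire fluctuations
  b0 <- make_bird(seed = 18, alpha = 0, n_days_baseline = 2,
                  n_days_feedback = 8, renditions_per_day = c(500, 700))
  fb0 <- b0$trajectory[!is.na(b0$trajectory$threshold), ]
  days0 <- sort(unique(fb0$day))
  dm0 <- vapply(days0, function(d) mean(fb0$pitch[fb0$day == d]),
                numeric(1))
  expect_lt(abs(dm0[length(dm0)] - dm0[1]), 10)
})

test_that("daily improvement measures morning-to-morning shifts", {
  # constructed +4 Hz/day staircase
  per <- 120L
  pitch <- rep(1000 + 4 * (0:3), each = per) + rnorm(480, 0, 1e-9)
  thr <- rep(995, 480)
  tr <- pitch_trajectory(day = rep(0:3, each = per),
                         h = rep(seq(0.3, 0.8, length.out = per), 4),
                         pitch = pitch, hit = pitch < thr, threshold = thr,
                         contingency = "low")
  expect_equal(daily_improvement(tr), 4, tolerance = 1e-6)
  # identical mornings: zero improvement
  tr0 <- tr; tr0$pitch <- rep(tr$pitch[1:per], 4)
  tr0$hit <- tr0$pitch < tr0$threshold
  expect_equal(daily_improvement(tr0), 0, tolerance = 1e-6)
  expect_error(daily_improvement(tr[1:per, ]), "2 feedback days")
})

test_that("optimal hit probability is 1/2 for symmetric exploration", {
  q_gauss <- optimal_hit_probability("gaussian")
  expect_equal(as.numeric(q_gauss), 0.5, tolerance = 1e-3)
  # any symmetric unimodal density: logistic
  q_logis <- optimal_hit_probability(list(d = stats::dlogis,
                                          q = stats::qlogis))
  expect_equal(as.numeric(q_logis), 0.5, tolerance = 1e-3)
  # right-skewed exploration: optimum at the CDF value of the mean-zero
  # point, P(X < 0) for X = LN(0, 0.5) - exp(0.125) = pnorm(0.25)
  mu <- exp(0.125)
  q_skew <- optimal_hit_probability(list(
    d = function(x) stats::dlnorm(x + mu, 0, 0.5),
    q = function(p) stats::qlnorm(p, 0, 0.5) - mu))
  expect_equal(as.numeric(q_skew), pnorm(0.25), tolerance = 2e-3)
  expect_false(abs(q_skew - 0.5) < 0.05)
})

test_that("policy comparison uses common random numbers", {
  cfgs <- lapply(1:3, function(b) {
    bird <- make_bird(seed = 900 + b, n_days_baseline = 1,
                      n_days_feedback = 5,
                      renditions_per_day = c(400, 500))
    bird$config
  })
  pols <- list(median_daily = threshold_policy("daily_quantile", q = 0.5),
               far_fixed = threshold_policy("fixed", value = 400))
  tab <- compare_policies(cfgs, pols, seed = 1)
  # a never-crossed threshold produces no improvement
  expect_lt(mean(abs(tab$far_fixed)), 1.5)
  expect_gt(mean(tab$median_daily), mean(tab$far_fixed))
  # rerunning reproduces the same numbers (common random numbers)
  tab2 <- compare_policies(cfgs, pols, seed = 1)
  expect_identical(tab, tab2)
})

test_that("presets produce the advertised structures", {
  b <- generate_synthetic_bird("baseline_only", seed = 2,
                               renditions_per_day = c(300, 400))
  expect_true(all(is.na(b$trajectory$threshold)))
  # bias is a reward-free leaky noise accumulator at baseline
  # (stationary SD sqrt(sigma_eta2 / (2 delta)) ~ 4 Hz)
  expect_lt(max(abs(b$truth$b)), 20)
  lp <- generate_synthetic_bird("lesion_pair", seed = 3,
                                renditions_per_day = c(300, 400))
  expect_true(all(lp$post$truth$eps == 0))
  expect_lt(var(lp$post$trajectory$pitch), var(lp$pre$trajectory$pitch))
})
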