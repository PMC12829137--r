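test_that("reward maps and the pitch learning equation are exact", {
  expect_equal(reward_map(TRUE, c(0, -1)), -1)
  expect_equal(reward_map(FALSE, c(0, -1)), 0)
  expect_equal(reward_map(TRUE, c(1, -1)), -1)
  expect_equal(reward_map(c(FALSE, TRUE), c(1, 0)), c(1, 0))
  # reward-free leak, direct substitution, identity limit
  expect_equal(bias_update(10, 0, 5, 0.003, 0.2, 0), 8)
  expect_equal(bias_update(0, -1, 2, 0.003, 3e-4, 0), -0.006)
  expect_equal(bias_update(7, -1, 2, 0, 1e-12, 0), 7, tolerance = 1e-9)
})

test_that("variant increments reduce to the basic rule where they should", {
  v_basic <- model_variant("latent_basic")
  v_eff <- model_variant("efference_copy")
  v_pe <- model_variant("pitch_error")
  expect_equal(variant_increment(v_basic, R_prev = -1, eps_prev = 2,
                                 alpha = 0.01), -0.02)
  # efference copy with V = 0 equals the basic rule
  expect_equal(variant_increment(v_eff, R_prev = -1, eps_prev = 2,
                                 V_prev = 0, alpha = 0.01),
               variant_increment(v_basic, R_prev = -1, eps_prev = 2,
                                 alpha = 0.01))
  # pitch error with mean-centered reward gives zero increment
  expect_equal(variant_increment(v_pe, R_prev = -0.4, Rbar_prev = -0.4,
                                 p_prev = 1010, p_star = 1000,
                                 alpha = 0.01), 0)
  expect_equal(v_pe$W, 20L)
})

test_that("baseline system has the documented structure", {
  tr <- toy_traj(T = 80)
  nodes <- equal_count_nodes(tr, N_D = 6)
  rp <- repertoire_params(p_star = 1000, nodes = nodes,
                          D = c(1, 2, 0, -1, 1, -2, -1), x = 2, N_h = 5,
                          O = c(2, 1, 0, -1, -2), tau = 0.02,
                          sigma_innov2 = 0.3)
  ssm <- assemble_baseline_ssm(rp, tr, sigma_eps2 = 25)
  expect_equal(ssm$n, 2)
  expect_equal(ssm$H, c(1, 1))
  expect_equal(dim(ssm$U), c(80, 6 + 1 + 5))
  expect_equal(ssm$qdiag, c(0.3, 25))
  expect_equal(ssm$A[1, 1, 5], 1 - 0.02)
  # with all fluctuations zero the model reduces to p_t = p* + eps_t
  rp0 <- repertoire_params(p_star = 1000, nodes = nodes, D = rep(0, 7),
                           x = 2, N_h = 5, O = rep(0, 5), tau = 1,
                           sigma_innov2 = 0)
  ssm0 <- assemble_baseline_ssm(rp0, tr, sigma_eps2 = 25)
  set.seed(1)
  q <- matrix(rnorm(2 * 80, 0, rep(sqrt(ssm0$qdiag), 80)), 2, 80)
  sim <- simulate_ssm(ssm0, q = q, g = rep(0, 80))
  expect_equal(drop(sim$y), 1000 + q[2, ], tolerance = 1e-10)
})

test_that("assembled systems reproduce the scalar recursions path-exactly", {
  # feedback system vs direct iteration of the learning + noise equations
  tr <- toy_traj(T = 60)
  nodes <- equal_count_nodes(tr, N_D = 3)
  rp <- repertoire_params(p_star = 1000, nodes = nodes,
                          D = c(1, -1, 2, 0), x = 2, N_h = 3,
                          O = c(1.5, 0, -1.5), tau = 0.05,
                          sigma_innov2 = 0.4)
  lrn <- learner_params(alpha = 0.01, delta = 0.001, sigma_eps2 = 16,
                        sigma_eta2 = 0.01)
  set.seed(11)
  rewards <- sample(c(0, -1), 60, replace = TRUE)
  ssm <- assemble_feedback_ssm(rp, lrn, tr, rewards)
  set.seed(12)
  q <- matrix(rnorm(3 * 60, 0, rep(sqrt(ssm$qdiag), 60)), 3, 60)
  sim <- simulate_ssm(ssm, q = q, g = rep(0, 60))
  # scalar recursions with the same draws
  ev <- evaluate_repertoire(rp, tr)
  m <- ev$total - 1000 + rp$p_star  # p* + d + o
  b <- cc <- eps <- numeric(60)
  b[1] <- q[1, 1]; cc[1] <- q[2, 1]; eps[1] <- q[3, 1]
  Rprev <- c(0, rewards[-60])
  for (t in 2:60) {
    b[t] <- bias_update(b[t - 1], Rprev[t], eps[t - 1], lrn$alpha,
                        lrn$delta, q[1, t])
    cc[t] <- (1 - rp$noise$tau) * cc[t - 1] + q[2, t]
    eps[t] <- q[3, t]
  }
  p_scalar <- eps + b + cc + m
  expect_equal(drop(sim$y), p_scalar, tolerance = 1e-10)
  expect_equal(sim$x[1, ], b, tolerance = 1e-10)
  expect_equal(sim$x[2, ], cc, tolerance = 1e-10)
  # with R identically zero the bias is a pure leaky noise accumulator
  ssm0 <- assemble_feedback_ssm(rp, lrn, tr, rep(0, 60))
  sim0 <- simulate_ssm(ssm0, q = q, g = rep(0, 60))
  b0 <- stats::filter(q[1, ], 1 - lrn$delta, method = "recursive",
                      init = 0)
  expect_equal(sim0$x[1, ], as.numeric(b0), tolerance = 1e-10)
  expect_equal(ssm$n, 3)
})

test_that("bias under zero reward reaches its stationary variance", {
  delta <- 0.05; s_eta <- 1
  b <- stats::filter(rnorm(2e5, 0, 1), 1 - delta, method = "recursive")
  sv <- s_eta / (1 - (1 - delta)^2)
  se <- sv * sqrt(2 * (1 + (1 - delta)) / (delta * 2e5))
  set.seed(5)
  b <- stats::filter(rnorm(2e5, 0, sqrt(s_eta)), 1 - delta,
                     method = "recursive")
  expect_lt(abs(var(as.numeric(b)) - sv), 5 * se)
})
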