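# Synthetic-bird builder for tests that need parameters differing from
# the preset defaults (e.g. varying exploration SD across birds). Mirrors
# generate_synthetic_bird(): schedule drawn first, true circadian nodes
# at its equal-count quantiles.
make_bird <- function(seed, sigma_eps2 = 100, alpha = 0.003, delta = 3e-4,
                      sigma_eta2 = 1e-4, n_days_baseline = 3L,
                      n_days_feedback = 0L,
                      renditions_per_day = c(300, 1500),
                      exploration = "gaussian",
                      policy = threshold_policy("daily_quantile")) {
  lrn <- learner_params(alpha = alpha, delta = delta,
                        sigma_eps2 = sigma_eps2, sigma_eta2 = sigma_eta2)
  cfg <- simulation_config(latentRL:::default_repertoire(), lrn,
                           n_days_baseline = n_days_baseline,
                           n_days_feedback = n_days_feedback,
                           renditions_per_day = renditions_per_day,
                           exploration = exploration)
  set.seed(seed)
  sched <- latentRL:::generate_schedule(cfg)
  cfg$schedule <- sched
  cfg$repertoire <- latentRL:::default_repertoire(schedule = sched)
  sim <- simulate_experiment(cfg, policy, n_reps = 1L, seed = seed)
  list(trajectory = sim$trajectory, truth = sim$truth, config = cfg)
}

# small deterministic baseline-like trajectory for structural tests
toy_traj <- function(T = 60L, days = 2L, pitch = NULL, seed = 42L) {
  set.seed(seed)
  per <- T %/% days
  day <- rep(seq_len(days) - 1L, each = per)[1:T]
  h <- as.numeric(unlist(lapply(seq_len(days), function(d)
    sort(stats::runif(per, 0.3, 0.9)))))[1:T]
  if (is.null(pitch)) pitch <- 1000 + stats::rnorm(T, 0, 5)
  pitch_trajectory(day = day, h = h, pitch = pitch)
}
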