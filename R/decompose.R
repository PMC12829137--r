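#' Fit the baseline model
#'
#' Stage one of the two-stage pipeline: on baseline data (no feedback)
#' the bias is clamped at zero and the repertoire parameters — target
#' pitch, circadian coefficients, history offsets, colored-noise leak and
#' innovation variance — are fitted together with the exploration
#' variance by EM on the baseline state-space model. The per-rendition
#' decomposition is extracted from the smoothed states and disturbances.
#'
#' @param traj baseline `pitch_trajectory` (no thresholds).
#' @param N_D number of circadian periods (default 6).
#' @param x history horizon in seconds (default 2).
#' @param N_h history quantization ceiling (default 5); automatically
#'   reduced to (max observed count) + 1 for birds that never reach it.
#' @param node_method circadian node placement, see [equal_count_nodes()].
#' @param tol,max_iter EM controls, see [em_fit()].
#' @param G fixed observation variance.
#' @return an object of class `baseline_fit`: `repertoire`
#'   ([repertoire_params()]), `sigma_eps2` (baseline exploration variance
#'   in Hz^2), `sigma_eps_pct` (exploration SD in % of `p*`),
#'   `decomposition` (data.frame with `pitch, eps_hat, b_hat, c_hat,
#'   d_hat, o_hat, residual`), `loglik`, `loglik_trace`, `bic`,
#'   `converged`, `n_iter`, `center`, `N_D`, `x`, `N_h`.
#' @export
fit_baseline <- function(traj, N_D = 6L, x = 2, N_h = 5L,
                         node_method = "equal_count",
                         tol = 1e-6, max_iter = 500L, G = 1e-4) {
  validate_trajectory(traj)
  if (any(!is.na(traj$threshold)))
    stop("baseline fit requires a threshold-free trajectory; use ",
         "split_baseline_feedback() first")
  T <- nrow(traj)
  if (T < N_D) stop("fewer renditions than circadian bins")
  nh_raw <- history_counts(traj, x = x, N_h = 10000L)
  N_h_eff <- as.integer(min(N_h, max(nh_raw) + 1L))
  nodes <- equal_count_nodes(traj, N_D = N_D, method = node_method)
  U <- baseline_inputs(traj, nodes, x = x, N_h = N_h_eff)
  center <- mean(traj$pitch)
  yc <- traj$pitch - center
  fit <- em_fit(baseline_template(yc, U, G = G), tol = tol,
                max_iter = max_iter)
  beta <- fit$params$beta$value
  nC <- N_D + 1L
  betaC <- beta[seq_len(nC)]
  betaO <- beta[nC + seq_len(N_h_eff)]
  Uc <- U[, seq_len(nC), drop = FALSE]
  Uo <- U[, nC + seq_len(N_h_eff), drop = FALSE]
  dbar <- mean(drop(Uc %*% betaC))
  obar <- mean(drop(Uo %*% betaO))
  rep <- repertoire_params(
    p_star = center + dbar + obar,
    nodes = nodes, D = betaC - dbar,
    x = x, N_h = N_h_eff, O = betaO - obar,
    tau = 1 - fit$params$phi_tau$value,
    sigma_innov2 = fit$params$sigma_innov2$value)
  m <- drop(U %*% beta)
  xs <- fit$smooth$x_smooth
  decomp <- data.frame(
    day = traj$day, h = traj$h, pitch = traj$pitch,
    eps_hat = xs[2, ] - m,
    b_hat = 0,
    c_hat = xs[1, ],
    d_hat = drop(Uc %*% (betaC - dbar)),
    o_hat = drop(Uo %*% (betaO - obar)))
  decomp$residual <- decomp$pitch - rep$p_star - decomp$eps_hat -
    decomp$c_hat - decomp$d_hat - decomp$o_hat
  k <- 3L + nC + N_h_eff - 1L
  structure(list(
    repertoire = rep,
    sigma_eps2 = fit$params$sigma_eps2$value,
    sigma_eps_pct = 100 * sqrt(fit$params$sigma_eps2$value) / rep$p_star,
    decomposition = decomp,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    bic = bic(fit$loglik, k, T),
    converged = fit$converged, n_iter = fit$n_iter,
    center = center, N_D = N_D, x = x, N_h = N_h_eff, G = G),
    class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf(paste0("<baseline_fit> T = %d, p* = %.1f Hz, sigma_eps = %.2f Hz ",
                     "(%.2f%% of p*), tau = %.4g\n"),
              nrow(x$decomposition), x$repertoire$p_star,
              sqrt(x$sigma_eps2), x$sigma_eps_pct, x$repertoire$noise$tau))
  cat(sprintf("  loglik = %.2f (BIC %.1f) after %d EM iteration(s)\n",
              x$loglik, x$bic, x$n_iter))
  invisible(x)
}

#' Fit the feedback (reinforcement) model
#'
#' Stage two: with the repertoire frozen at the baseline estimates, the
#' learning parameters `alpha` and `delta` and the variances
#' `sigma_eps2` (re-estimated for the self-consistency check) and
#' `sigma_eta2` are fitted by EM on the feedback state-space model. For
#' the `classical`, `efference_copy` and `pitch_error` variants the
#' repertoire is reduced to `V_t = p*` during this fit.
#'
#' If the feedback data contain more than one contiguous contingency
#' block (the white-noise zone was reversed), each block is fitted
#' separately and a list of fits is returned.
#'
#' @param traj feedback `pitch_trajectory` (thresholds throughout).
#' @param baseline a `baseline_fit` (or bare [repertoire_params()], in
#'   which case the centering constant is taken as `p*`).
#' @param variant a [model_variant()].
#' @param reward_convention length-2 numeric `c(escape, hit)`.
#' @param tol,max_iter EM controls.
#' @param G fixed observation variance.
#' @return an object of class `feedback_fit`: `learner`
#'   ([learner_params()]), `sigma_eps2`, `sigma_eps_pct`,
#'   `decomposition`, `loglik`, `loglik_trace`, `converged`, `n_iter`,
#'   `variant`, `alpha_warning`.
#' @export
fit_feedback <- function(traj, baseline,
                         variant = model_variant("latent_basic"),
                         reward_convention = c(0, -1),
                         tol = 1e-6, max_iter = 500L, G = 1e-4) {
  validate_trajectory(traj)
  if (any(is.na(traj$threshold)))
    stop("feedback fit requires thresholds throughout; missing baseline fit ",
         "or unsplit trajectory")
  if (inherits(baseline, "baseline_fit")) {
    rep <- baseline$repertoire; center <- baseline$center
  } else if (inherits(baseline, "repertoire_params")) {
    rep <- baseline; center <- rep$p_star
  } else stop("baseline must be a baseline_fit or repertoire_params")
  cont <- traj$contingency
  if (length(unique(cont[!is.na(cont)])) > 1) {
    blocks <- split(seq_len(nrow(traj)), cumsum(c(1, diff(as.integer(
      factor(cont))) != 0)))
    return(lapply(blocks, function(idx) {
      sub <- traj[idx, , drop = FALSE]
      attr(sub, "meta") <- trajectory_meta(traj)
      class(sub) <- class(traj)
      fit_feedback(sub, baseline, variant, reward_convention, tol,
                   max_iter, G)
    }))
  }
  T <- nrow(traj)
  rewards <- reward_map(traj$hit, reward_convention)
  yc <- traj$pitch - center
  if (variant$name == "latent_basic") {
    # deterministic repertoire input p* + d_t + o_t (circadian weight 0
    # outside the baseline node span, but the p* level always present)
    W <- circadian_weights(traj$h, rep$circadian$nodes)
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    d_det <- drop(W %*% rep$circadian$D)
    nh <- history_counts(traj, x = rep$history$x, N_h = rep$history$N_h)
    o_det <- rep$history$O[1L + nh]
    m <- (rep$p_star - center) + d_det + o_det
    tmpl <- feedback_template(yc, m, rewards, tau = rep$noise$tau,
                              sigma_innov2 = rep$noise$sigma_innov2,
                              variant = variant, G = G,
                              escape_reward = reward_convention[1])
  } else {
    m <- rep$p_star - center
    tmpl <- feedback_template(yc, m, rewards, variant = variant, G = G,
                              escape_reward = reward_convention[1])
  }
  fit <- em_fit(tmpl, tol = tol, max_iter = max_iter)
  learner <- learner_params(
    alpha = fit$params$alpha$value,
    delta = fit$params$delta$value,
    sigma_eps2 = fit$params$sigma_eps2$value,
    sigma_eta2 = fit$params$sigma_eta2$value,
    reward_convention = reward_convention)
  xs <- fit$smooth$x_smooth
  iw <- nrow(xs)
  mfull <- rep_len(m, T)
  if (variant$name == "latent_basic") {
    d_hat <- d_det; o_hat <- o_det
    c_hat <- xs[2, ]
  } else {
    d_hat <- rep(0, T); o_hat <- rep(0, T); c_hat <- rep(0, T)
  }
  decomp <- data.frame(
    day = traj$day, h = traj$h, pitch = traj$pitch,
    eps_hat = xs[iw, ] - mfull,
    b_hat = xs[1, ],
    c_hat = c_hat, d_hat = d_hat, o_hat = o_hat)
  decomp$residual <- decomp$pitch - (center + mfull) - decomp$eps_hat -
    decomp$b_hat - decomp$c_hat
  structure(list(
    learner = learner,
    sigma_eps2 = learner$sigma_eps2,
    sigma_eps_pct = 100 * sqrt(learner$sigma_eps2) / rep$p_star,
    decomposition = decomp,
    loglik = fit$loglik, loglik_trace = fit$loglik_trace,
    converged = fit$converged, n_iter = fit$n_iter,
    variant = variant$name, alpha_warning = fit$alpha_warning,
    repertoire = rep, center = center, G = G),
    class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf(paste0("<feedback_fit:%s> T = %d, alpha = %.4g, delta = %.4g, ",
                     "sigma_eps = %.2f Hz (%.2f%% of p*)\n"),
              x$variant, nrow(x$decomposition), x$learner$alpha,
              x$learner$delta, sqrt(x$sigma_eps2), x$sigma_eps_pct))
  cat(sprintf("  loglik = %.2f after %d EM iteration(s)\n", x$loglik, x$n_iter))
  invisible(x)
}

#' Exploration fraction of baseline pitch variance
#'
#' The share `f = sigma_eps^2 / var(baseline pitch)` of total baseline
#' pitch variability attributed to motor exploration.
#'
#' @param sigma_eps2 best-fit exploration variance (Hz^2).
#' @param baseline_pitch_var total baseline pitch variance (Hz^2).
#' @return scalar fraction `f`.
#' @export
exploration_fraction <- function(sigma_eps2, baseline_pitch_var) {
  stopifnot(baseline_pitch_var > 0)
  sigma_eps2 / baseline_pitch_var
}

#' Short-window exploration estimates
#'
#' Estimates the exploration SD from short stretches of consecutive
#' renditions. For windows of at most 20 renditions the momentary pitch
#' variability (plain SD across the window) is used as the proxy; for
#' longer windows a reduced model (constant level plus colored noise plus
#' exploration) is fitted to each window by EM.
#'
#' @param traj a `pitch_trajectory`.
#' @param window window length in renditions (>= 2); windows are
#'   non-overlapping.
#' @return data.frame with columns `start`, `end`, `sigma_eps`
#'   (Hz per window).
#' @export
short_window_exploration <- function(traj, window = 20L) {
  T <- nrow(traj)
  stopifnot(window >= 2)
  if (window > T) stop("window longer than the trajectory")
  starts <- seq(1L, T - window + 1L, by = window)
  est <- vapply(starts, function(s) {
    yy <- traj$pitch[s:(s + window - 1L)]
    if (window <= 20L) return(stats::sd(yy))
    fit <- em_fit(baseline_template(yy - mean(yy),
                                    matrix(1, window, 1)),
                  tol = 1e-5, max_iter = 200L)
    sqrt(fit$params$sigma_eps2$value)
  }, numeric(1))
  data.frame(start = starts, end = starts + window - 1L, sigma_eps = est)
}

#' Predicted effect of removing the exploration channel
#'
#' Motor-pathway (LMAN-like) lesions are modeled as deleting the
#' exploration channel; the predicted post-lesion pitch variance is the
#' total pitch variance minus the fitted exploration variance, with the
#' non-reinforced repertoire components retained.
#'
#' @param decomp a `baseline_fit`.
#' @return list with `predicted_var` (Hz^2), `total_var`, `sigma_eps2`,
#'   and `components` (variance of each retained/removed component).
#' @export
predict_lesion_effect <- function(decomp) {
  stopifnot(inherits(decomp, "baseline_fit"))
  d <- decomp$decomposition
  total <- stats::var(d$pitch)
  pred <- total - decomp$sigma_eps2
  if (pred < 0) {
    warning("exploration variance exceeds total pitch variance; clipping at 0")
    pred <- 0
  }
  list(predicted_var = pred, total_var = total,
       sigma_eps2 = decomp$sigma_eps2,
       components = c(exploration_removed = decomp$sigma_eps2,
                      colored = stats::var(d$c_hat),
                      circadian = stats::var(d$d_hat),
                      history = stats::var(d$o_hat)))
}

#' Select the history-model horizon and quantization by BIC
#'
#' Fits the baseline model over a candidate grid of history horizons and
#' quantization ceilings and returns the pair minimizing the BIC,
#' together with the full table for audit. Failed candidate fits are
#' recorded as `NA` and excluded from the argmin with a warning.
#'
#' @param traj baseline `pitch_trajectory`.
#' @param candidate_x candidate horizons in seconds
#'   (default `c(1, 2, 3, 5, 10, 60)`).
#' @param candidate_N_h candidate ceilings (default `c(3, 5, 8)`).
#' @param fitter fitting function, by default [fit_baseline()]; it is
#'   called as `fitter(traj, x = , N_h = , ...)` and must return an
#'   object with a `bic` field.
#' @param ... passed to `fitter`.
#' @return list with `x`, `N_h` (the argmin pair) and `table`
#'   (data.frame of `x`, `N_h`, `bic`).
#' @export
select_history_model <- function(traj, candidate_x = c(1, 2, 3, 5, 10, 60),
                                 candidate_N_h = c(3, 5, 8),
                                 fitter = fit_baseline, ...) {
  grid <- expand.grid(x = candidate_x, N_h = candidate_N_h)
  grid$bic <- vapply(seq_len(nrow(grid)), function(i) {
    out <- tryCatch(fitter(traj, x = grid$x[i], N_h = grid$N_h[i], ...)$bic,
                    error = function(e) NA_real_)
    out
  }, numeric(1))
  if (anyNA(grid$bic))
    warning(sum(is.na(grid$bic)), " candidate fit(s) failed; excluded")
  if (all(is.na(grid$bic))) stop("all candidate history fits failed")
  best <- which.min(grid$bic)
  list(x = grid$x[best], N_h = grid$N_h[best], table = grid)
}
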