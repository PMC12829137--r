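#' Learner parameters
#'
#' Parameters of the latent reinforcement learner. The learner injects iid
#' Gaussian exploration into pitch and accumulates a pitch bias by a leaky
#' correlation of exploration with reward (the pitch learning equation):
#' `b_t = (1 - delta) b_{t-1} + alpha R_{t-1} eps_{t-1} + eta_t`.
#'
#' @param alpha learning rate (>= 0).
#' @param delta bias leak per rendition, strictly in `(0, 1)`.
#' @param sigma_eps2 exploration variance in Hz^2.
#' @param sigma_eta2 bias-noise variance in Hz^2 (the small auxiliary
#'   noise that makes the bias a proper stochastic state).
#' @param reward_convention length-2 numeric `c(escape, hit)`; one of
#'   `c(0, -1)` (default), `c(1, 0)`, `c(1, -1)`.
#' @return an object of class `learner_params`.
#' @export
learner_params <- function(alpha, delta, sigma_eps2, sigma_eta2 = 0.01,
                           reward_convention = c(0, -1)) {
  stopifnot(alpha >= 0, delta > 0, delta < 1,
            sigma_eps2 >= 0, sigma_eta2 >= 0,
            length(reward_convention) == 2)
  structure(list(alpha = alpha, delta = delta, sigma_eps2 = sigma_eps2,
                 sigma_eta2 = sigma_eta2,
                 reward_convention = as.numeric(reward_convention)),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf(paste0("<learner_params> alpha = %.4g, delta = %.4g, ",
                     "sigma_eps = %.3g Hz, sigma_eta = %.3g Hz, reward (escape, hit) = (%g, %g)\n"),
              x$alpha, x$delta, sqrt(x$sigma_eps2), sqrt(x$sigma_eta2),
              x$reward_convention[1], x$reward_convention[2]))
  invisible(x)
}

#' Model variant
#'
#' The supported bias-learning rules: `latent_basic` (the default latent
#' reinforcement-learning rule `alpha R eps` on top of the full
#' repertoire), `classical` (same rule but with the repertoire reduced to
#' the target pitch, `V_t = p*`), `efference_copy` (`alpha R (eps + V)`),
#' and `pitch_error` (`alpha (R - Rbar) (p - p*)` with `Rbar` the running
#' mean reward over the preceding `W` renditions).
#'
#' @param name one of `"latent_basic"`, `"classical"`, `"efference_copy"`,
#'   `"pitch_error"`.
#' @param W running-mean reward window for `pitch_error` (default 20).
#' @return an object of class `model_variant`.
#' @export
model_variant <- function(name = c("latent_basic", "classical",
                                   "efference_copy", "pitch_error"),
                          W = 20L) {
  name <- match.arg(name)
  stopifnot(W >= 1)
  structure(list(name = name, W = as.integer(W)), class = "model_variant")
}

#' Map hit flags to rewards
#'
#' @param hit logical vector; `TRUE` when the rendition triggered white
#'   noise.
#' @param convention length-2 numeric `c(escape, hit)`.
#' @return numeric reward vector.
#' @export
reward_map <- function(hit, convention = c(0, -1)) {
  stopifnot(length(convention) == 2)
  ifelse(hit, convention[2], convention[1])
}

#' One step of the pitch learning equation
#'
#' `b_t = (1 - delta) b_prev + alpha * R_prev * eps_prev + eta`.
#'
#' @param b_prev previous bias (Hz).
#' @param R_prev previous reward.
#' @param eps_prev previous exploration (Hz).
#' @param alpha learning rate.
#' @param delta bias leak.
#' @param eta bias noise draw (Hz).
#' @return the updated bias `b_t`.
#' @export
bias_update <- function(b_prev, R_prev, eps_prev, alpha, delta, eta = 0) {
  (1 - delta) * b_prev + alpha * R_prev * eps_prev + eta
}

#' Learning term of a model variant
#'
#' Returns only the reward-driven bias increment; the leak `(1 - delta) b`
#' and the noise `eta` are shared across variants (see [bias_update()]).
#'
#' @param variant a [model_variant()].
#' @param R_prev previous reward.
#' @param Rbar_prev running-mean reward over the preceding `W` renditions
#'   (used by `pitch_error` only; with fewer than `W` prior renditions the
#'   mean over the available history).
#' @param eps_prev previous exploration (Hz).
#' @param V_prev previous repertoire value (Hz; `efference_copy` only).
#' @param p_prev previous pitch (Hz; `pitch_error` only).
#' @param p_star target pitch (Hz; `pitch_error` only).
#' @param alpha learning rate.
#' @return the bias increment in Hz.
#' @export
variant_increment <- function(variant, R_prev, Rbar_prev = 0, eps_prev = 0,
                              V_prev = 0, p_prev = 0, p_star = 0, alpha) {
  switch(variant$name,
    latent_basic = ,
    classical = alpha * R_prev * eps_prev,
    efference_copy = alpha * R_prev * (eps_prev + V_prev),
    pitch_error = alpha * (R_prev - Rbar_prev) * (p_prev - p_star)
  )
}

# running mean of rewards over the preceding W renditions (excluding t);
# for t <= W the mean over the available history, 0 at t = 1
running_reward_mean <- function(R, W = 20L) {
  T <- length(R)
  cs <- c(0, cumsum(R))
  t <- seq_len(T)
  lo <- pmax(t - W, 1L)
  n <- t - lo
  out <- ifelse(n > 0, (cs[t] - cs[lo]) / n, 0)
  out
}
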