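#' @title State-space assembly for the latent pitch models
#' @description
#' The pitch models are linear Gaussian state-space systems
#' `y_t = H' x_t + g_t`, `x_t = A_t x_{t-1} + a_t + q_t` with scalar
#' observation, diagonal process covariance, fixed small observation
#' variance `G`, and known input offsets `a_t` built from the circadian
#' weights, history indicators and (during feedback) the reward sequence.
#' An assembled system is a list of class `latent_ssm` with fields
#' `y, A, a, qdiag, H, G, mu1, P1, labels` directly consumable by
#' [kalman_filter()].
#' @name latent_ssm
NULL

new_latent_ssm <- function(y, A, a, qdiag, H, G, mu1, P1, labels,
                           extra = list()) {
  T <- length(y); n <- length(H)
  stopifnot(dim(A)[1] == n, dim(A)[2] == n, dim(A)[3] == T,
            nrow(a) == n, ncol(a) == T,
            length(qdiag) == n, length(mu1) == n,
            nrow(P1) == n, ncol(P1) == n,
            all(qdiag >= 0), G > 0)
  structure(c(list(y = y, A = A, a = a, qdiag = qdiag, H = H, G = G,
                   mu1 = mu1, P1 = P1, labels = labels, n = n, T = T),
              extra),
            class = "latent_ssm")
}

#' @export
print.latent_ssm <- function(x, ...) {
  cat(sprintf("<latent_ssm> states [%s], T = %d, G = %g\n",
              paste(x$labels, collapse = ", "), x$T, x$G))
  invisible(x)
}

# design matrix of the structural regression row: circadian hat weights
# stacked with history indicator columns, dimension T x (N_D + 1 + N_h)
baseline_inputs <- function(traj, nodes, x = 2, N_h = 5L) {
  W <- circadian_weights(traj$h, nodes)
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  nh <- history_counts(traj, x = x, N_h = N_h)
  Ind <- matrix(0, nrow(traj), N_h)
  Ind[cbind(seq_len(nrow(traj)), 1L + nh)] <- 1
  cbind(W, Ind)
}

#' Assemble the baseline state-space model
#'
#' Baseline (no feedback, reward identically zero, bias clamped at zero):
#' state `x_t = [c_t, p* + d_t + o_t (+ eps_t)]`, observation row
#' `H = [1, 1]`, process covariance `diag(sigma_innov2, sigma_eps2)`. The
#' structural coefficients `(p* + D_j)` and `O_k` multiply the known input
#' vector of circadian weights and history indicators (dimension
#' `N_D + 1 + N_h`), entering the second state as a deterministic offset.
#'
#' @param rep a [repertoire_params()] object.
#' @param traj the baseline `pitch_trajectory`.
#' @param sigma_eps2 exploration variance in Hz^2.
#' @param G fixed observation variance (default `1e-4` Hz^2).
#' @return a `latent_ssm` (see [latent_ssm]).
#' @export
assemble_baseline_ssm <- function(rep, traj, sigma_eps2, G = 1e-4) {
  T <- nrow(traj)
  U <- baseline_inputs(traj, rep$circadian$nodes, x = rep$history$x,
                       N_h = rep$history$N_h)
  beta <- c(rep$p_star + rep$circadian$D, rep$history$O)
  if (ncol(U) != length(beta)) stop("input/coefficient dimension mismatch")
  m <- drop(U %*% beta)
  phi <- 1 - rep$noise$tau
  A <- array(0, c(2, 2, T)); A[1, 1, ] <- phi
  a <- rbind(rep(0, T), m)
  s_in <- rep$noise$sigma_innov2
  cvar <- if (phi < 1) s_in / (1 - phi^2) else s_in * T
  new_latent_ssm(y = traj$pitch, A = A, a = a,
                 qdiag = c(s_in, sigma_eps2), H = c(1, 1), G = G,
                 mu1 = c(0, m[1]), P1 = diag(c(cvar, sigma_eps2)),
                 labels = c("c", "w"),
                 extra = list(U = U, m = m, kind = "baseline"))
}

#' Assemble the feedback (reinforcement) state-space model
#'
#' During white-noise feedback the bias becomes an active state. For the
#' basic latent model the state is `x_t = [b_t, c_t, w_t]` with
#' `w_t = p* + d_t + o_t + eps_t`; the repertoire parameters are frozen at
#' their baseline estimates and enter through the deterministic input
#' `m_t = p* + d_t + o_t`, whose lagged value lets the transition recover
#' `eps_{t-1} = w_{t-1} - m_{t-1}` for the reward-dependent bias update
#' `alpha R_{t-1} eps_{t-1}`. For the `classical` family the colored-noise
#' state is dropped and `m_t = p*`.
#'
#' @param rep frozen [repertoire_params()] from the baseline fit.
#' @param learner a [learner_params()] object.
#' @param traj the feedback `pitch_trajectory`.
#' @param rewards numeric reward sequence `R_1 ... R_T`; the reward
#'   preceding the first feedback rendition is taken as the escape value.
#' @param variant a [model_variant()] (default `latent_basic`).
#' @param G fixed observation variance (default `1e-4` Hz^2).
#' @return a `latent_ssm` (see [latent_ssm]).
#' @export
assemble_feedback_ssm <- function(rep, learner, traj, rewards,
                                  variant = model_variant("latent_basic"),
                                  G = 1e-4) {
  T <- nrow(traj)
  stopifnot(length(rewards) == T)
  conv <- learner$reward_convention
  Rprev <- c(conv[1], rewards[-T])   # R_{t-1}, with R_0 = escape value
  alpha <- learner$alpha
  phid <- 1 - learner$delta
  if (variant$name == "latent_basic") {
    W <- circadian_weights(traj$h, rep$circadian$nodes)
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    nh <- history_counts(traj, x = rep$history$x, N_h = rep$history$N_h)
    m <- rep$p_star + drop(W %*% rep$circadian$D) + rep$history$O[1L + nh]
    phi <- 1 - rep$noise$tau
    s_in <- rep$noise$sigma_innov2
    A <- array(0, c(3, 3, T))
    A[1, 1, ] <- phid
    A[1, 3, ] <- alpha * Rprev
    A[2, 2, ] <- phi
    a <- rbind(-alpha * Rprev * c(m[1], m[-T]), rep(0, T), m)
    bvar <- learner$sigma_eta2 / max(1 - phid^2, 1e-12)
    cvar <- if (phi < 1) s_in / (1 - phi^2) else s_in * T
    return(new_latent_ssm(
      y = traj$pitch, A = A, a = a,
      qdiag = c(learner$sigma_eta2, s_in, learner$sigma_eps2),
      H = c(1, 1, 1), G = G,
      mu1 = c(0, 0, m[1]), P1 = diag(c(bvar, cvar, learner$sigma_eps2)),
      labels = c("b", "c", "w"),
      extra = list(m = m, rewards = rewards, Rprev = Rprev,
                   kind = "feedback", variant = variant$name)))
  }
  # classical family: V_t = p*, state [b_t, w_t] with w_t = p* + eps_t
  m <- rep(rep$p_star, T)
  A <- array(0, c(2, 2, T))
  A[1, 1, ] <- phid
  a <- rbind(rep(0, T), m)
  z <- NULL
  if (variant$name %in% c("classical", "efference_copy")) {
    A[1, 2, ] <- alpha * Rprev
    if (variant$name == "classical")
      a[1, ] <- -alpha * Rprev * m
    # efference copy: increment alpha R (eps + V) = alpha R w, no offset
  } else if (variant$name == "pitch_error") {
    Rbar <- running_reward_mean(Rprev, W = variant$W)
    perr <- c(0, traj$pitch[-T]) - rep$p_star
    z <- (Rprev - Rbar) * perr
    z[1] <- 0
    a[1, ] <- alpha * z
  } else stop("unknown variant: ", variant$name)
  bvar <- learner$sigma_eta2 / max(1 - phid^2, 1e-12)
  new_latent_ssm(
    y = traj$pitch, A = A, a = a,
    qdiag = c(learner$sigma_eta2, learner$sigma_eps2),
    H = c(1, 1), G = G,
    mu1 = c(0, m[1]), P1 = diag(c(bvar, learner$sigma_eps2)),
    labels = c("b", "w"),
    extra = list(m = m, rewards = rewards, Rprev = Rprev, z = z,
                 kind = "feedback", variant = variant$name))
}

#' Simulate one sample path from an assembled system
#'
#' Iterates the assembled recursions with Gaussian draws (or supplied
#' disturbance draws), returning states and observations. Used to
#' cross-check the state-space construction against the scalar
#' recursions.
#'
#' @param ssm a `latent_ssm`.
#' @param seed optional seed.
#' @param q optional `n x T` matrix of process-noise draws (overrides
#'   random generation).
#' @param g optional length-`T` vector of observation-noise draws.
#' @param x1 optional initial state (default: the prior mean `mu1` plus
#'   the `q[, 1]` draw).
#' @return list with `x` (`n x T` states) and `y` (observations).
#' @export
simulate_ssm <- function(ssm, seed = NULL, q = NULL, g = NULL, x1 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ssm$n; T <- ssm$T
  if (is.null(q))
    q <- matrix(stats::rnorm(n * T, 0, rep(sqrt(ssm$qdiag), T)), n, T)
  if (is.null(g)) g <- stats::rnorm(T, 0, sqrt(ssm$G))
  x <- matrix(0, n, T)
  x[, 1] <- if (is.null(x1)) ssm$mu1 + q[, 1] else x1
  for (t in seq_len(T)[-1])
    x[, t] <- ssm$A[, , t] %*% x[, t - 1] + ssm$a[, t] + q[, t]
  list(x = x, y = drop(crossprod(ssm$H, x)) + g)
}
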