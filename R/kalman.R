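#' Kalman filter for an assembled pitch model
#'
#' Standard forward recursion for the time-varying linear Gaussian system
#' (see [latent_ssm]), returning per-rendition predicted and filtered
#' state moments, innovations, and the exact Gaussian log-likelihood.
#'
#' @param ssm a `latent_ssm` from [assemble_baseline_ssm()] or
#'   [assemble_feedback_ssm()].
#' @param y observation series (default: the series stored in `ssm`).
#' @return an object of class `kalman_filter_result` with fields
#'   `loglik`, `x_pred`, `x_filt`, `P_pred`, `P_filt`, `innov`,
#'   `innov_var`.
#' @export
kalman_filter <- function(ssm, y = ssm$y) {
  stopifnot(inherits(ssm, "latent_ssm"), length(y) == ssm$T,
            all(is.finite(y)))
  res <- kalman_core(y, ssm$A, ssm$a, ssm$qdiag, ssm$H, ssm$G,
                     ssm$mu1, ssm$P1, FALSE)
  if (!is.finite(res$loglik)) stop("non-finite log-likelihood")
  res$y <- y
  class(res) <- "kalman_filter_result"
  res
}

#' Fixed-interval (RTS) smoother
#'
#' Backward pass producing smoothed state means/covariances, lag-one
#' smoothed cross-covariances, and smoothed disturbance means for every
#' process-noise channel — in particular the exploration channel, whose
#' smoothed disturbance is the per-rendition exploration estimate.
#'
#' @param filter_result a `kalman_filter_result` (only its observation
#'   series is reused; the smoothing pass is recomputed).
#' @param ssm the `latent_ssm` the filter was run on.
#' @return an object of class `kalman_smooth_result` with fields
#'   `x_smooth` (`n x T`), `P_smooth` (`n x n x T`), `V_lag1`
#'   (`n x n x T`; slice `t` holds `Cov(x_t, x_{t-1} | y)`), `qhat`
#'   (`n x T` smoothed disturbances, first column `NA`), and `loglik`.
#' @export
rts_smooth <- function(filter_result, ssm) {
  y <- if (inherits(filter_result, "kalman_filter_result"))
    filter_result$y else ssm$y
  res <- kalman_core(y, ssm$A, ssm$a, ssm$qdiag, ssm$H, ssm$G,
                     ssm$mu1, ssm$P1, TRUE)
  T <- ssm$T
  qhat <- matrix(NA_real_, ssm$n, T)
  if (T > 1) {
    idx <- 2:T
    pred <- vapply(idx, function(t)
      drop(ssm$A[, , t] %*% res$x_smooth[, t - 1]) + ssm$a[, t],
      numeric(ssm$n))
    qhat[, idx] <- res$x_smooth[, idx, drop = FALSE] - pred
  }
  out <- list(x_smooth = res$x_smooth, P_smooth = res$P_smooth,
              V_lag1 = res$V_lag1, qhat = qhat, loglik = res$loglik,
              x_filt = res$x_filt, P_filt = res$P_filt)
  class(out) <- "kalman_smooth_result"
  out
}

#' Bayesian information criterion
#'
#' `BIC = k log(n) - 2 loglik`; lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of free parameters.
#' @param n_obs number of observations.
#' @return scalar BIC.
#' @export
bic <- function(loglik, k_params, n_obs) {
  stopifnot(n_obs >= 1)
  k_params * log(n_obs) - 2 * loglik
}

# ---------------------------------------------------------------------------
# EM templates and engines
# ---------------------------------------------------------------------------

#' EM templates for the pitch models
#'
#' An EM template packages the observations and the known, fixed
#' structure of one of the two fitting stages. `baseline_template` holds
#' the design matrix of circadian weights and history indicators;
#' `feedback_template` holds the deterministic repertoire values,
#' rewards, and the frozen colored-noise parameters.
#'
#' @param y observation series (pitch, Hz; any centering is the caller's
#'   responsibility).
#' @param U `T x p` design matrix of the structural regression row.
#' @param G fixed observation variance.
#' @param m deterministic repertoire series `p* + d_t + o_t` (feedback).
#' @param rewards reward series `R_1 ... R_T` (feedback).
#' @param tau,sigma_innov2 frozen colored-noise parameters (feedback,
#'   `latent_basic` only).
#' @param variant a [model_variant()] (feedback).
#' @param z observed bias regressor for the `pitch_error` variant.
#' @param escape_reward reward value on escape trials (used for the
#'   reward preceding the first feedback rendition).
#' @return a template list consumed by [em_fit()].
#' @name em_templates
NULL

#' @rdname em_templates
#' @export
baseline_template <- function(y, U, G = 1e-4) {
  stopifnot(nrow(U) == length(y))
  list(kind = "baseline", y = y, U = U, G = G)
}

#' @rdname em_templates
#' @export
feedback_template <- function(y, m, rewards, tau = NULL, sigma_innov2 = NULL,
                              variant = model_variant("latent_basic"),
                              z = NULL, G = 1e-4, escape_reward = 0) {
  stopifnot(length(m) %in% c(1L, length(y)), length(rewards) == length(y))
  if (variant$name == "latent_basic" &&
      (is.null(tau) || is.null(sigma_innov2)))
    stop("latent_basic feedback template needs frozen tau and sigma_innov2")
  list(kind = "feedback", y = y, m = rep_len(m, length(y)),
       rewards = rewards, tau = tau, sigma_innov2 = sigma_innov2,
       variant = variant, z = z, G = G, escape_reward = escape_reward)
}

#' Fit free parameters by expectation maximization
#'
#' E-step: fixed-interval smoothing with lag-one cross-covariances.
#' M-step: closed-form expected-complete-data updates — a minimum-norm
#' least-squares update for the structural coefficients, ratio updates
#' for the leak parameters (clamped to their admissible intervals, with
#' conditional re-maximization when a constraint binds), and residual
#' moment updates for the variances. The prior at the first rendition is
#' held fixed across iterations so the likelihood trace is
#' non-decreasing.
#'
#' @param template a [baseline_template()] or [feedback_template()].
#' @param free_params character vector naming the parameters to update;
#'   `NULL` (default) frees the standard set of the template
#'   (baseline: `phi_tau`, `sigma_innov2`, `beta`, `sigma_eps2`;
#'   feedback: `delta`, `alpha`, `sigma_eta2`, `sigma_eps2`). An empty
#'   vector evaluates the likelihood at `init` without iterating.
#' @param init named list of initial values; missing entries take the
#'   package defaults.
#' @param tol relative log-likelihood change for convergence
#'   (default `1e-6`).
#' @param max_iter iteration cap (default 500).
#' @param seed optional seed (only used by multi-start restarts).
#' @param restarts number of random restarts (default 1, i.e. none).
#' @return an object of class `em_fit` with fields `params` (named list,
#'   each with `value` and `free` flag), `loglik_trace`, `converged`,
#'   `n_iter`, `smooth` (final E-step), `ssm` (final assembled system),
#'   and `seed`.
#' @export
em_fit <- function(template, free_params = NULL, init = list(),
                   tol = 1e-6, max_iter = 500L, seed = NULL,
                   restarts = 1L) {
  fitter <- switch(template$kind,
                   baseline = em_baseline_engine,
                   feedback = em_feedback_engine,
                   stop("unknown template kind: ", template$kind))
  if (restarts <= 1L)
    return(fitter(template, free_params, init, tol, max_iter, seed))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    ir <- init
    ir$jitter <- stats::runif(1, 0.5, 2)
    fit <- fitter(template, free_params, ir, tol, max_iter, seed)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

# expected second-moment sums used by both engines; all sums over t >= 2
em_moments <- function(sm, i, j = i) {
  T <- ncol(sm$x_smooth)
  xs_i <- sm$x_smooth[i, ]; xs_j <- sm$x_smooth[j, ]
  list(
    S11 = sum(sm$P_smooth[i, j, 2:T]) + sum(xs_i[2:T] * xs_j[2:T]),
    S00 = sum(sm$P_smooth[i, j, 1:(T - 1)]) + sum(xs_i[1:(T - 1)] * xs_j[1:(T - 1)]),
    S10 = sum(sm$V_lag1[i, j, 2:T]) + sum(xs_i[2:T] * xs_j[1:(T - 1)])
  )
}

em_baseline_engine <- function(template, free_params, init, tol, max_iter,
                               seed) {
  y <- template$y; U <- template$U; G <- template$G
  T <- length(y); p <- ncol(U)
  defaults <- c("phi_tau", "sigma_innov2", "beta", "sigma_eps2")
  free <- if (is.null(free_params)) defaults else intersect(free_params, defaults)
  vy <- stats::var(y)
  UtU <- crossprod(U)
  # minimum-norm LS via pseudoinverse: hat weights and history indicators
  # are each partitions of unity, giving one exact collinearity
  pinv_UtU <- {
    s <- svd(UtU)
    keep <- s$d > max(s$d) * 1e-10
    s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  }
  jit <- if (is.null(init$jitter)) 1 else init$jitter
  beta <- if (!is.null(init$beta)) init$beta else
    drop(pinv_UtU %*% crossprod(U, y))
  phi <- if (!is.null(init$phi_tau)) init$phi_tau else 0.99
  s_eps <- jit * (if (!is.null(init$sigma_eps2)) init$sigma_eps2 else 0.5 * vy)
  s_in <- jit * (if (!is.null(init$sigma_innov2)) init$sigma_innov2 else
    0.25 * vy * (1 - phi^2))
  # fixed prior: diffuse, data-scaled; constant across iterations
  mu1 <- c(0, drop(U[1, ] %*% beta))
  P1 <- diag(c(10 * vy + s_in, 10 * vy + s_eps))
  build <- function() {
    m <- drop(U %*% beta)
    A <- array(0, c(2, 2, T)); A[1, 1, ] <- phi
    new_latent_ssm(y = y, A = A, a = rbind(rep(0, T), m),
                   qdiag = c(s_in, s_eps), H = c(1, 1), G = G,
                   mu1 = mu1, P1 = P1, labels = c("c", "w"),
                   extra = list(U = U, m = m, kind = "baseline"))
  }
  trace <- numeric(0); converged <- FALSE; sm <- NULL; ssm <- NULL
  will_polish <- setequal(free, defaults)
  tol_em <- if (will_polish) max(tol, 1e-5) else tol
  n_iter <- if (length(free) == 0) 1L else max_iter
  for (it in seq_len(n_iter)) {
    ssm <- build()
    sm <- rts_smooth(NULL, ssm)
    trace <- c(trace, sm$loglik)
    if (length(free) == 0) break
    if (it > 1) {
      dll <- trace[it] - trace[it - 1]
      if (dll < -1e-8 * max(1, abs(trace[it - 1])))
        stop("EM log-likelihood decreased at iteration ", it)
      if (abs(dll) < tol_em * abs(trace[it - 1])) { converged <- TRUE; break }
    }
    mc <- em_moments(sm, 1)
    if ("phi_tau" %in% free)
      phi <- min(max(mc$S10 / mc$S00, 0), 1 - 1e-10)
    if ("sigma_innov2" %in% free)
      s_in <- max((mc$S11 - 2 * phi * mc$S10 + phi^2 * mc$S00) / (T - 1), 1e-12)
    if ("beta" %in% free) {
      U2 <- U[2:T, , drop = FALSE]
      beta <- drop({
        s <- svd(crossprod(U2))
        keep <- s$d > max(s$d) * 1e-10
        pinv <- s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
        pinv %*% crossprod(U2, sm$x_smooth[2, 2:T])
      })
    }
    if ("sigma_eps2" %in% free) {
      resid2 <- sm$x_smooth[2, 2:T] - drop(U[2:T, , drop = FALSE] %*% beta)
      s_eps <- max((sum(sm$P_smooth[2, 2, 2:T]) + sum(resid2^2)) / (T - 1), 1e-12)
    }
  }
  # polish the noise parameters by direct likelihood maximization with the
  # structural coefficients held at the EM solution (EM creeps on the
  # (tau, sigma_innov2) ridge; see the feedback engine)
  if (will_polish) {
    obj <- function(th) {
      phi <<- stats::plogis(th[1])
      s_in <<- exp(th[2])
      s_eps <<- exp(th[3])
      s <- build()
      ll <- tryCatch(
        kalman_loglik(s$y, s$A, s$a, s$qdiag, s$H, s$G, s$mu1, s$P1),
        error = function(e) -Inf)
      if (!is.finite(ll)) 1e12 else -ll
    }
    th0 <- c(stats::qlogis(min(max(phi, 1e-6), 1 - 1e-6)),
             log(s_in), log(s_eps))
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-9))
    obj(opt$par)
    ssm <- build()
    sm <- rts_smooth(NULL, ssm)
    trace <- c(trace, sm$loglik)
  }
  structure(list(
    params = list(
      phi_tau = list(value = phi, free = "phi_tau" %in% free),
      sigma_innov2 = list(value = s_in, free = "sigma_innov2" %in% free),
      beta = list(value = beta, free = "beta" %in% free),
      sigma_eps2 = list(value = s_eps, free = "sigma_eps2" %in% free)),
    loglik = trace[length(trace)], loglik_trace = trace,
    converged = converged, n_iter = length(trace), smooth = sm, ssm = ssm,
    seed = seed), class = "em_fit")
}

em_feedback_engine <- function(template, free_params, init, tol, max_iter,
                               seed) {
  y <- template$y; m <- template$m; G <- template$G
  variant <- template$variant
  T <- length(y)
  latent3 <- variant$name == "latent_basic"
  Rprev <- c(template$escape_reward, template$rewards[-T])
  defaults <- c("delta", "alpha", "sigma_eta2", "sigma_eps2")
  free <- if (is.null(free_params)) defaults else intersect(free_params, defaults)
  vy <- stats::var(y)
  jit <- if (is.null(init$jitter)) 1 else init$jitter
  alpha <- if (!is.null(init$alpha)) init$alpha else 1e-3
  delta <- if (!is.null(init$delta)) init$delta else 1e-4
  s_eps <- jit * (if (!is.null(init$sigma_eps2)) init$sigma_eps2 else 0.5 * vy)
  s_eta <- jit * (if (!is.null(init$sigma_eta2)) init$sigma_eta2 else 0.01)
  # observed bias regressor (pitch_error); zero placeholder otherwise
  z_obs <- if (variant$name == "pitch_error") {
    if (!is.null(template$z)) template$z else {
      Rbar <- running_reward_mean(Rprev, W = variant$W)
      zz <- (Rprev - Rbar) * (c(0, y[-T]) - m[1]); zz[1] <- 0; zz
    }
  } else NULL
  # fixed prior from the initial guess (kept constant for EM monotonicity)
  phid0 <- 1 - delta
  bvar0 <- s_eta / max(1 - phid0^2, 1e-12)
  if (latent3) {
    phi <- 1 - template$tau; s_in <- template$sigma_innov2
    cvar <- if (phi < 1) s_in / (1 - phi^2) else s_in * T
    mu1 <- c(0, 0, m[1]); P1 <- diag(c(bvar0, cvar, s_eps))
    iw <- 3L
  } else {
    mu1 <- c(0, m[1]); P1 <- diag(c(bvar0, s_eps))
    iw <- 2L
  }
  build <- function() {
    phid <- 1 - delta
    if (latent3) {
      A <- array(0, c(3, 3, T))
      A[1, 1, ] <- phid; A[1, 3, ] <- alpha * Rprev; A[2, 2, ] <- phi
      a <- rbind(-alpha * Rprev * c(m[1], m[-T]), rep(0, T), m)
      qd <- c(s_eta, s_in, s_eps)
      lab <- c("b", "c", "w")
    } else {
      A <- array(0, c(2, 2, T)); A[1, 1, ] <- phid
      a <- rbind(rep(0, T), m)
      if (variant$name == "classical") {
        A[1, 2, ] <- alpha * Rprev; a[1, ] <- -alpha * Rprev * m
      } else if (variant$name == "efference_copy") {
        A[1, 2, ] <- alpha * Rprev
      } else {
        a[1, ] <- alpha * z_obs
      }
      qd <- c(s_eta, s_eps)
      lab <- c("b", "w")
    }
    new_latent_ssm(y = y, A = A, a = a, qdiag = qd, H = rep(1, length(lab)),
                   G = G, mu1 = mu1, P1 = P1, labels = lab,
                   extra = list(m = m, Rprev = Rprev, kind = "feedback",
                                variant = variant$name))
  }
  trace <- numeric(0); converged <- FALSE; sm <- NULL; ssm <- NULL
  alpha_flag <- NULL
  will_polish <- setequal(free, defaults)
  tol_em <- if (will_polish) max(tol, 1e-5) else tol
  n_iter <- if (length(free) == 0) 1L else max_iter
  for (it in seq_len(n_iter)) {
    ssm <- build()
    sm <- rts_smooth(NULL, ssm)
    trace <- c(trace, sm$loglik)
    if (length(free) == 0) break
    if (it > 1) {
      dll <- trace[it] - trace[it - 1]
      if (dll < -1e-8 * max(1, abs(trace[it - 1])))
        stop("EM log-likelihood decreased at iteration ", it)
      if (abs(dll) < tol_em * abs(trace[it - 1])) { converged <- TRUE; break }
    }
    xs <- sm$x_smooth; Ps <- sm$P_smooth; V <- sm$V_lag1
    i2 <- 2:T; i1 <- 1:(T - 1)
    mb <- em_moments(sm, 1)
    # bias regressor z_t: latent R_{t-1} (w_{t-1} - kappa_{t-1}) or observed
    if (variant$name == "pitch_error") {
      z <- z_obs[i2]
      Szz <- sum(z^2)
      Sbz0 <- sum(z * xs[1, i1])
      Sbz1 <- sum(z * xs[1, i2])
    } else {
      kap <- if (variant$name == "efference_copy") 0 else c(m[1], m[-T])
      kap1 <- if (length(kap) == 1) 0 else kap[i2]
      r2 <- Rprev[i2]
      wdev <- xs[iw, i1] - kap1
      Szz <- sum(r2^2 * (Ps[iw, iw, i1] + wdev^2))
      Sbz0 <- sum(r2 * (Ps[1, iw, i1] + xs[1, i1] * wdev))
      Sbz1 <- sum(r2 * (V[1, iw, i2] + xs[1, i2] * wdev))
    }
    # joint (1-delta, alpha) update with box constraints
    phid <- 1 - delta
    if (Szz > 1e-12 * max(1, mb$S00)) {
      Mm <- matrix(c(mb$S00, Sbz0, Sbz0, Szz), 2, 2)
      vv <- c(mb$S10, Sbz1)
      th <- tryCatch(solve(Mm, vv), error = function(e) c(phid, alpha))
      if ("delta" %in% free) phid <- min(max(th[1], 1e-10), 1 - 1e-10)
      if ("alpha" %in% free)
        alpha <- max((Sbz1 - phid * Sbz0) / Szz, 0)
      if ("delta" %in% free)
        phid <- min(max((mb$S10 - alpha * Sbz0) / mb$S00, 1e-10), 1 - 1e-10)
    } else {
      if ("alpha" %in% free && is.null(alpha_flag)) {
        alpha_flag <- "alpha unidentifiable: no reward variation in feedback data"
        warning(alpha_flag)
      }
      if ("delta" %in% free)
        phid <- min(max(mb$S10 / mb$S00, 1e-10), 1 - 1e-10)
    }
    delta <- 1 - phid
    if ("sigma_eta2" %in% free) {
      quad <- mb$S11 - 2 * (phid * mb$S10 + alpha * Sbz1) +
        phid^2 * mb$S00 + 2 * phid * alpha * Sbz0 + alpha^2 * Szz
      s_eta <- max(quad / (T - 1), 1e-12)
    }
    if ("sigma_eps2" %in% free) {
      rw <- xs[iw, i2] - m[i2]
      s_eps <- max((sum(Ps[iw, iw, i2]) + sum(rw^2)) / (T - 1), 1e-12)
    }
  }
  # EM crawls along a likelihood ridge in (alpha, delta); polish the
  # converged EM solution by direct maximization of the exact filter
  # likelihood (Nelder-Mead from the EM point, so the likelihood can
  # only improve)
  if (will_polish && is.null(alpha_flag) && alpha > 0) {
    obj <- function(th) {
      delta <<- min(max(exp(th[1]), 1e-10), 1 - 1e-10)
      alpha <<- exp(th[2])
      s_eta <<- exp(th[3])
      s_eps <<- exp(th[4])
      s <- build()
      ll <- tryCatch(
        kalman_loglik(s$y, s$A, s$a, s$qdiag, s$H, s$G, s$mu1, s$P1),
        error = function(e) -Inf)
      if (!is.finite(ll)) 1e12 else -ll
    }
    th0 <- log(c(delta, alpha, s_eta, s_eps))
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9))
    obj(opt$par)  # leave parameters at the optimum
    ssm <- build()
    sm <- rts_smooth(NULL, ssm)
    trace <- c(trace, sm$loglik)
  }
  structure(list(
    params = list(
      alpha = list(value = alpha, free = "alpha" %in% free),
      delta = list(value = delta, free = "delta" %in% free),
      sigma_eta2 = list(value = s_eta, free = "sigma_eta2" %in% free),
      sigma_eps2 = list(value = s_eps, free = "sigma_eps2" %in% free)),
    loglik = trace[length(trace)], loglik_trace = trace,
    converged = converged, n_iter = length(trace), smooth = sm, ssm = ssm,
    alpha_warning = alpha_flag, seed = seed), class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  vals <- vapply(x$params, function(p)
    if (length(p$value) == 1) sprintf("%.5g", p$value) else
      paste0("[", length(p$value), " coefs]"), character(1))
  cat(sprintf("<em_fit> loglik = %.3f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (x$converged) " (converged)" else ""))
  cat(" ", paste(names(vals), vals, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
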