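# Brute-force joint-Gaussian log-density of the observations implied by a
# latent_ssm: assembles the full T x T observation covariance from the
# state recursions and evaluates the density directly. Independent of the
# filtering recursions it is used to check.
bf_loglik <- function(ssm) {
  T <- ssm$T; n <- ssm$n
  mu_x <- matrix(0, n, T)
  mu_x[, 1] <- ssm$mu1
  # cross[[s]] holds Cov(x_s, x_t) for the current t
  cross <- vector("list", T)
  Ptt <- vector("list", T)
  Ptt[[1]] <- ssm$P1
  Q <- diag(ssm$qdiag, n)
  Sy <- matrix(0, T, T)
  H <- ssm$H
  cross[[1]] <- Ptt[[1]]
  Sy[1, 1] <- drop(t(H) %*% Ptt[[1]] %*% H) + ssm$G
  if (T > 1) for (t in 2:T) {
    At <- matrix(ssm$A[, , t], n, n)
    mu_x[, t] <- At %*% mu_x[, t - 1] + ssm$a[, t]
    Ptt[[t]] <- At %*% Ptt[[t - 1]] %*% t(At) + Q
    for (s in 1:(t - 1)) {
      cst <- if (s == t - 1) Ptt[[s]] %*% t(At) else cross[[s]] %*% t(At)
      cross[[s]] <- cst
      Sy[s, t] <- Sy[t, s] <- drop(t(H) %*% cst %*% H)
    }
    Sy[t, t] <- drop(t(H) %*% Ptt[[t]] %*% H) + ssm$G
  }
  mu_y <- drop(crossprod(H, mu_x))
  R <- chol(Sy)
  z <- backsolve(R, ssm$y - mu_y, transpose = TRUE)
  -0.5 * (T * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# random stable time-varying system with simulated observations
random_ssm <- function(seed, T = 40L, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(1:3, 1)
  A <- array(stats::runif(n * n * T, -0.9, 0.9) / n, c(n, n, T))
  a <- matrix(stats::rnorm(n * T, 0, 0.3), n, T)
  qdiag <- stats::runif(n, 0.1, 1)
  H <- stats::runif(n, 0.5, 1.5)
  G <- stats::runif(1, 0.05, 0.5)
  mu1 <- stats::rnorm(n)
  P1 <- diag(stats::runif(n, 0.2, 1), n)
  ssm <- latentRL:::new_latent_ssm(y = numeric(T), A = A, a = a,
                                   qdiag = qdiag, H = H, G = G,
                                   mu1 = mu1, P1 = P1,
                                   labels = paste0("x", seq_len(n)))
  sim <- simulate_ssm(ssm, seed = seed + 1000)
  ssm$y <- sim$y
  ssm
}
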