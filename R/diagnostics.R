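#' Mutual average information profile
#'
#' Mutual information between a series and its lag-k copy over 50
#' log-spaced integer lags from 1 to 1000 (deduplicated; lags exceeding
#' half the series length are dropped with a warning). The estimator is
#' an equal-frequency histogram on rank-transformed pairs with
#' `ceiling(T^(1/3))` bins per axis, which makes the profile invariant
#' under monotone (hence affine) transforms of the series. The
#' white-noise reference level is the mean MAI of `n_ref` freshly drawn
#' Gaussian iid series of the same length, evaluated over the same lags;
#' its spread across surrogates and lags gives the whiteness band.
#'
#' @param series numeric series.
#' @param n_ref number of Gaussian surrogate series (default 3).
#' @param seed optional seed for the surrogates.
#' @param lags integer lags (default: 50 log-spaced over `[1, 1000]`).
#' @param bins histogram bins per axis (default `ceiling(T^(1/3))`).
#' @return an object of class `mai_profile`: `lags`, `mai` (raw, nats),
#'   `reference` (scalar), `reference_sd`, `surrogate_mai`
#'   (matrix lags x n_ref).
#' @export
mai_profile <- function(series, n_ref = 3L, seed = NULL, lags = NULL,
                        bins = NULL) {
  T <- length(series)
  if (is.null(lags))
    lags <- unique(round(10^seq(0, 3, length.out = 50)))
  drop <- lags > T / 2
  if (any(drop)) {
    warning(sum(drop), " lag(s) exceeding T/2 dropped")
    lags <- lags[!drop]
  }
  if (length(lags) == 0) stop("series too short for any requested lag")
  if (is.null(bins)) bins <- ceiling(T^(1 / 3))
  if (stats::sd(series) == 0) {
    mai <- rep(0, length(lags))
  } else {
    mai <- vapply(lags, function(k) mi_hist(series[1:(T - k)],
                                            series[(1 + k):T], bins),
                  numeric(1))
  }
  if (!is.null(seed)) set.seed(seed)
  sur <- vapply(seq_len(n_ref), function(i) {
    w <- stats::rnorm(T)
    vapply(lags, function(k) mi_hist(w[1:(T - k)], w[(1 + k):T], bins),
           numeric(1))
  }, numeric(length(lags)))
  sur <- matrix(sur, nrow = length(lags))
  structure(list(lags = lags, mai = mai,
                 reference = mean(sur), reference_sd = stats::sd(sur),
                 surrogate_mai = sur, bins = bins, T = T),
            class = "mai_profile")
}

# histogram MI (nats) on rank-transformed pairs with equal-frequency bins
mi_hist <- function(x, y, bins) {
  n <- length(x)
  ix <- ceiling(rank(x, ties.method = "first") * bins / n)
  iy <- ceiling(rank(y, ties.method = "first") * bins / n)
  joint <- tabulate((ix - 1L) * bins + iy, nbins = bins * bins) / n
  px <- tabulate(ix, nbins = bins) / n
  py <- tabulate(iy, nbins = bins) / n
  pxy <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / t(pxy)[nz]))
}

#' Normalize an MAI profile
#'
#' Affine map sending the white-noise reference level to 0 and the
#' anchor's raw lag-1 MAI to 1. The anchor is by convention the MAI
#' profile of the original pitch series, so that successive residual
#' stages of the decomposition can be compared on one scale.
#'
#' @param profile an [mai_profile()] to normalize.
#' @param anchor an [mai_profile()] supplying the lag-1 value (default:
#'   `profile` itself).
#' @return the profile with fields `normalized` (per lag) and
#'   `degenerate` (TRUE when the anchor lag-1 value does not exceed the
#'   reference, in which case the raw profile is returned unscaled).
#' @export
normalize_mai <- function(profile, anchor = profile) {
  a1 <- anchor$mai[which(anchor$lags == 1L)[1]]
  ref <- profile$reference
  if (!is.finite(a1) || a1 <= ref) {
    warning("anchor lag-1 MAI does not exceed the white-noise reference; ",
            "returning raw profile")
    profile$normalized <- profile$mai
    profile$degenerate <- TRUE
    return(profile)
  }
  profile$normalized <- (profile$mai - ref) / (a1 - ref)
  profile$degenerate <- FALSE
  profile
}

#' Whiteness check against the surrogate band
#'
#' TRUE when the raw MAI at every lag lies within `n_sd` standard
#' deviations of the white-noise surrogate reference.
#'
#' @param profile an [mai_profile()].
#' @param n_sd band half-width in surrogate SDs (default 3).
#' @return logical scalar with attribute `n_violations`.
#' @export
mai_whiteness <- function(profile, n_sd = 3) {
  dev <- abs(profile$mai - profile$reference)
  viol <- sum(dev > n_sd * profile$reference_sd)
  structure(viol == 0, n_violations = viol)
}

#' Self-consistency check of estimated explorations
#'
#' The model is self-consistent when the estimated explorations look like
#' ideal exploration: iid (flat MAI profile within the white-noise
#' surrogate band at every lag) and Gaussian (skewness and excess
#' kurtosis within `n_sd` analytic standard errors of zero). Both
#' components are reported; `pass` requires both.
#'
#' @param eps_hat estimated exploration series.
#' @param n_ref surrogate series for the MAI reference (default 3).
#' @param seed seed for the surrogates.
#' @param n_sd band half-width (default 3).
#' @return list of class `self_consistency` with `pass`, `whiteness`
#'   (logical, with violation count attribute), `gaussian` (logical),
#'   `z_skew`, `z_kurt`, and the underlying `mai` profile.
#' @export
self_consistency <- function(eps_hat, n_ref = 3L, seed = NULL, n_sd = 3) {
  pr <- mai_profile(eps_hat, n_ref = n_ref, seed = seed)
  white <- mai_whiteness(pr, n_sd = n_sd)
  T <- length(eps_hat)
  z <- (eps_hat - mean(eps_hat)) / stats::sd(eps_hat)
  z_skew <- mean(z^3) / sqrt(6 / T)
  z_kurt <- (mean(z^4) - 3) / sqrt(24 / T)
  gaussian <- abs(z_skew) < n_sd && abs(z_kurt) < n_sd
  structure(list(pass = isTRUE(white) && gaussian, whiteness = white,
                 gaussian = gaussian, z_skew = z_skew, z_kurt = z_kurt,
                 mai = pr),
            class = "self_consistency")
}

#' @export
print.self_consistency <- function(x, ...) {
  cat(sprintf(paste0("<self_consistency> %s (whiteness: %s, %d band ",
                     "violation(s); gaussian: %s, z_skew = %.1f, ",
                     "z_kurt = %.1f)\n"),
              if (x$pass) "PASS" else "FAIL",
              if (isTRUE(x$whiteness)) "ok" else "violated",
              attr(x$whiteness, "n_violations"),
              if (x$gaussian) "ok" else "violated", x$z_skew, x$z_kurt))
  invisible(x)
}

#' Mean squared second derivative of the bias trajectory
#'
#' Smoothness metric for the estimated pitch bias: per day the bias is
#' resampled (linear interpolation) to `resample_n` uniformly spaced
#' points, the discrete second difference is taken, and its mean square
#' is averaged across days. Smooth (policy-gradient-like) bias
#' trajectories give small values; noisy bias estimates give large ones.
#'
#' @param bias_series per-rendition bias estimates.
#' @param day_index day index per rendition.
#' @param resample_n resampled points per day (default 1000).
#' @return scalar MS2D; days with fewer than 3 renditions are skipped
#'   with a warning.
#' @export
ms2d <- function(bias_series, day_index, resample_n = 1000L) {
  stopifnot(length(bias_series) == length(day_index))
  days <- unique(day_index)
  vals <- c()
  skipped <- 0L
  for (d in days) {
    b <- bias_series[day_index == d]
    if (length(b) < 3) { skipped <- skipped + 1L; next }
    z <- stats::approx(seq_along(b), b, n = resample_n)$y
    vals <- c(vals, mean(diff(z, differences = 2)^2))
  }
  if (skipped > 0) warning(skipped, " day(s) with < 3 renditions skipped")
  if (length(vals) == 0) stop("no day with >= 3 renditions")
  mean(vals)
}

#' RMSE between running-average-smoothed trajectories
#'
#' Both series are smoothed by a running average over the last `window`
#' renditions (partial windows at the start) before taking the RMS
#' difference; used to score simulated against observed trajectories.
#'
#' @param sim_traj,obs_traj numeric series (or `pitch_trajectory`s) of
#'   equal length.
#' @param window running-average window (default 50).
#' @return scalar RMSE in Hz.
#' @export
smoothed_rmse <- function(sim_traj, obs_traj, window = 50L) {
  s <- if (is.data.frame(sim_traj)) sim_traj$pitch else sim_traj
  o <- if (is.data.frame(obs_traj)) obs_traj$pitch else obs_traj
  if (length(s) != length(o)) stop("trajectories differ in length")
  sqrt(mean((running_mean(s, window) - running_mean(o, window))^2))
}

# trailing running mean over the last `window` values (partial at start)
running_mean <- function(x, window) {
  cs <- cumsum(x)
  t <- seq_along(x)
  lo <- pmax(t - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (t - lo)
}

#' Normalized final pitch
#'
#' The mean pitch on the last feedback day expressed on a scale where
#' the threshold on the first feedback day is 0 and the threshold on the
#' last feedback day is 1; a value near 1 means the learned shift tracked
#' the full threshold excursion.
#'
#' @param traj feedback `pitch_trajectory`.
#' @param first_day_threshold,last_day_threshold thresholds in Hz;
#'   defaults are the mean thresholds on the first/last feedback day.
#' @return scalar normalized pitch.
#' @export
normalized_final_pitch <- function(traj, first_day_threshold = NULL,
                                   last_day_threshold = NULL) {
  fb <- traj[!is.na(traj$threshold), , drop = FALSE]
  if (nrow(fb) == 0) stop("no feedback renditions")
  days <- sort(unique(fb$day))
  if (is.null(first_day_threshold))
    first_day_threshold <- mean(fb$threshold[fb$day == days[1]])
  if (is.null(last_day_threshold))
    last_day_threshold <- mean(fb$threshold[fb$day == days[length(days)]])
  if (first_day_threshold == last_day_threshold)
    stop("equal first- and last-day thresholds; normalization undefined")
  last_mean <- mean(fb$pitch[fb$day == days[length(days)]])
  (last_mean - first_day_threshold) /
    (last_day_threshold - first_day_threshold)
}

#' Standardized mean difference (d-prime)
#'
#' `(mean(a) - mean(b)) / pooled SD` (Cohen's d with the pooled standard
#' deviation).
#'
#' @param sample_a,sample_b numeric samples with at least 2 points each.
#' @return scalar effect size.
#' @export
dprime <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  na <- length(sample_a); nb <- length(sample_b)
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled SD")
  (mean(sample_a) - mean(sample_b)) / sqrt(sp2)
}

#' Sample autocorrelation
#'
#' Biased sample autocorrelation with lag 0 equal to 1 (thin wrapper
#' around [stats::acf()]).
#'
#' @param series numeric series.
#' @param max_lag maximum lag (`< length(series)`).
#' @return numeric vector of autocorrelations at lags `0:max_lag`.
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(length(series) > max_lag)
  drop(stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}
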