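#' Detect pitch steps
#'
#' A step (abrupt pitch discontinuity) at rendition `i` is flagged when
#' the mean of the `n_s` pitches before `i` and the mean of the `n_s`
#' pitches from `i` onward differ by more than a fraction `theta` of the
#' local mean over the surrounding `2 n_s + 1` renditions:
#' `|p_l - p_r| > theta * p_m` with `p_l = mean(p[i-n_s, i))`,
#' `p_r = mean(p[i, i+n_s))`, `p_m = mean(p[i-n_s, i+n_s])`. Indices
#' within `n_s` of either end are ignored (session-boundary
#' discontinuities are deliberately excluded). The criterion is relative
#' to the local mean, so detection is invariant to rescaling the series.
#'
#' @param series pitch series (Hz).
#' @param n_s window length (default 20).
#' @param theta relative threshold (default 0.05).
#' @param wn_flags optional logical vector: was white noise delivered on
#'   each rendition. When given, each event records whether any of the
#'   `n_s` renditions preceding it experienced white noise.
#' @return data.frame of class `step_events` with columns `index`,
#'   `left_mean`, `right_mean`, `local_mean`, `size`, `direction`,
#'   `wn_preceded`.
#' @export
detect_steps <- function(series, n_s = 20L, theta = 0.05, wn_flags = NULL) {
  T <- length(series)
  if (T <= 2 * n_s) stop("series too short for window ", n_s)
  cs <- cumsum(series)
  msum <- function(from, to) cs[to] - c(0, cs)[from]
  idx <- (n_s + 1L):(T - n_s)
  left <- msum(idx - n_s, idx - 1L) / n_s
  right <- msum(idx, idx + n_s - 1L) / n_s
  local <- msum(idx - n_s, idx + n_s) / (2 * n_s + 1)
  size <- abs(left - right)
  keep <- size > theta * local
  events <- data.frame(index = idx[keep],
                       left_mean = left[keep], right_mean = right[keep],
                       local_mean = local[keep], size = size[keep],
                       direction = sign(right[keep] - left[keep]))
  events$wn_preceded <- if (!is.null(wn_flags)) {
    stopifnot(length(wn_flags) == T)
    vapply(events$index,
           function(i) any(wn_flags[max(1, i - n_s):(i - 1)], na.rm = TRUE),
           logical(1))
  } else rep(NA, nrow(events))
  class(events) <- c("step_events", "data.frame")
  events
}

#' Iteratively remove pitch steps
#'
#' Detects steps, removes the largest one by shifting all renditions from
#' its index onward so the discontinuity closes (the signed step size is
#' added, restoring continuity between the flanking window means), and
#' repeats until no step remains. Events are returned in removal order;
#' ties in magnitude are broken by the earliest index. Applying the
#' procedure to its own output is the identity.
#'
#' @param series pitch series (Hz).
#' @param n_s,theta see [detect_steps()].
#' @param wn_flags optional per-rendition white-noise flags, recorded on
#'   each removed event.
#' @return list with `corrected` (series with all steps removed) and
#'   `events` (`step_events` in removal order).
#' @export
remove_steps_iterative <- function(series, n_s = 20L, theta = 0.05,
                                   wn_flags = NULL) {
  corrected <- series
  removed <- NULL
  for (iter in seq_len(length(series))) {
    ev <- detect_steps(corrected, n_s = n_s, theta = theta,
                       wn_flags = wn_flags)
    if (nrow(ev) == 0) break
    top <- ev[order(-ev$size, ev$index)[1], , drop = FALSE]
    i <- top$index
    corrected[i:length(corrected)] <-
      corrected[i:length(corrected)] + (top$left_mean - top$right_mean)
    removed <- rbind(removed, top)
    if (iter == length(series))
      stop("step removal failed to terminate")
  }
  if (is.null(removed)) {
    removed <- detect_steps(series, n_s = n_s, theta = theta,
                            wn_flags = wn_flags)[0, , drop = FALSE]
  }
  rownames(removed) <- NULL
  class(removed) <- c("step_events", "data.frame")
  list(corrected = corrected, events = removed)
}

#' Equality-of-proportions Z-test for step/white-noise contingency
#'
#' Compares the rate of steps preceded by recent white-noise experience,
#' `r_A = nD_WN / T`, with the chance rate `r_C = nWN / T` (the fraction
#' of renditions preceded by white noise), using
#' `Z = (r_A - r_C) / sqrt(r (1 - r) (1/T + 1/n_D))` with the pooled
#' rate r equal to `(nD_WN + nWN) / (n_D + T)`. `|Z| > 1.96` indicates a
#' significantly white-noise-contingent stepping rate.
#'
#' @param events a `step_events` data.frame (with `wn_preceded` filled,
#'   or recomputed from `wn_flags`).
#' @param wn_flags logical per-rendition white-noise delivery flags.
#' @param T number of renditions in the session.
#' @param n_s window used to define "preceded by" (default 20).
#' @return list of class `step_test` with `r_A`, `r_C`, `r`, `Z`,
#'   `significant`, `n_D`, `nD_WN`, `nWN`, `T`.
#' @export
step_rate_ztest <- function(events, wn_flags, T = length(wn_flags),
                            n_s = 20L) {
  n_D <- nrow(events)
  if (n_D == 0) stop("no steps: Z statistic undefined")
  stopifnot(T >= 1)
  preceded <- vapply(seq_len(T), function(i)
    i > 1 && any(wn_flags[max(1, i - n_s):(i - 1)], na.rm = TRUE),
    logical(1))
  wn_prec <- if (all(is.na(events$wn_preceded))) preceded[events$index]
             else events$wn_preceded
  nD_WN <- sum(wn_prec)
  nWN <- sum(preceded)
  r_A <- nD_WN / T
  r_C <- nWN / T
  r <- (nD_WN + nWN) / (n_D + T)
  Z <- (r_A - r_C) / sqrt(r * (1 - r) * (1 / T + 1 / n_D))
  structure(list(r_A = r_A, r_C = r_C, r = r, Z = Z,
                 significant = abs(Z) > 1.96,
                 n_D = n_D, nD_WN = nD_WN, nWN = nWN, T = T),
            class = "step_test")
}

#' @export
print.step_test <- function(x, ...) {
  cat(sprintf(paste0("<step_test> Z = %.2f (%ssignificant at |Z| > 1.96)\n",
                     "  %d steps, %d WN-preceded; rates r_A = %.4f vs ",
                     "chance r_C = %.4f over T = %d renditions\n"),
              x$Z, if (x$significant) "" else "not ", x$n_D, x$nD_WN,
              x$r_A, x$r_C, x$T))
  invisible(x)
}
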