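#' Equal-count circadian nodes
#'
#' Divides the singing day into `N_D` periods such that, pooled across all
#' days, each period contains the same (within one) number of renditions.
#' Because birds sing more in the morning this yields narrower bins early
#' in the day. The first node is the earliest observed time-of-day
#' fraction and the last node lies just above the latest, so every
#' rendition falls inside the node span.
#'
#' @param traj a `pitch_trajectory` (or anything with an `h` column).
#' @param N_D number of daytime periods (default 6).
#' @param method `"equal_count"` (default) or `"equal_width"` bins.
#' @return numeric vector of `N_D + 1` strictly increasing nodes in
#'   `[0, 1)`.
#' @export
equal_count_nodes <- function(traj, N_D = 6L, method = c("equal_count", "equal_width")) {
  method <- match.arg(method)
  h <- traj$h
  stopifnot(N_D >= 1)
  if (length(h) < N_D) stop("fewer renditions (", length(h),
                            ") than circadian bins (", N_D, ")")
  eps <- 1e-9
  if (method == "equal_width") {
    nodes <- seq(min(h), max(h) + eps, length.out = N_D + 1L)
  } else {
    sh <- sort(h)
    Tn <- length(sh)
    interior <- if (N_D > 1)
      sh[floor((1:(N_D - 1)) * Tn / N_D) + 1L] else numeric(0)
    nodes <- c(sh[1], interior, sh[Tn] + eps)
  }
  if (any(diff(nodes) <= 0))
    stop("degenerate circadian nodes (ties in time-of-day); reduce N_D")
  nodes
}

#' Piecewise-linear circadian hat weights
#'
#' Evaluates the hat-function basis on the circadian nodes at a
#' time-of-day fraction `h`: at most two adjacent weights are non-zero,
#' they sum to one for `h` inside the node span `[H_1, H_{N_D+1})`, and
#' all weights are zero outside it.
#'
#' @param h time-of-day fraction(s).
#' @param nodes node vector from [equal_count_nodes()].
#' @return if `h` is scalar, a weight vector of length `length(nodes)`;
#'   otherwise a `length(h) x length(nodes)` matrix of weights.
#' @export
circadian_weights <- function(h, nodes) {
  m <- length(nodes)
  W <- matrix(0, length(h), m)
  j <- findInterval(h, nodes)           # 0 if below H_1, m if >= H_m
  inside <- j >= 1L & j <= m - 1L
  if (any(inside)) {
    ji <- j[inside]
    frac <- (h[inside] - nodes[ji]) / (nodes[ji + 1L] - nodes[ji])
    W[cbind(which(inside), ji)] <- 1 - frac
    W[cbind(which(inside), ji + 1L)] <- frac
  }
  if (length(h) == 1L) drop(W) else W
}

#' Repertoire parameter bundle
#'
#' The non-reinforced ("other") behavioral components of the pitch
#' repertoire: target pitch, colored noise, circadian basis, history
#' offsets. Circadian coefficients and history offsets are stored with
#' zero rendition-weighted average; the overall level lives in `p_star`.
#'
#' @param p_star target pitch in Hz (> 0).
#' @param nodes circadian node vector (length `N_D + 1`).
#' @param D circadian coefficients in Hz (length `N_D + 1`).
#' @param x history horizon in seconds.
#' @param N_h history quantization ceiling.
#' @param O history offsets in Hz (length `N_h`), indexed by
#'   `1 + n_h(t)`.
#' @param tau colored-noise leak per rendition in `(0, 1]`.
#' @param sigma_innov2 colored-noise innovation variance in Hz^2.
#' @return an object of class `repertoire_params`.
#' @export
repertoire_params <- function(p_star, nodes, D, x = 2, N_h = length(O), O,
                              tau, sigma_innov2) {
  stopifnot(p_star > 0, length(D) == length(nodes),
            length(O) == N_h, N_h >= 1,
            tau > 0, tau <= 1, sigma_innov2 >= 0,
            all(is.finite(D)), all(is.finite(O)))
  structure(list(p_star = p_star,
                 circadian = list(nodes = nodes, D = D),
                 history = list(x = x, N_h = as.integer(N_h), O = O),
                 noise = list(tau = tau, sigma_innov2 = sigma_innov2)),
            class = "repertoire_params")
}

#' @export
print.repertoire_params <- function(x, ...) {
  cat(sprintf("<repertoire_params> p* = %.2f Hz, tau = %.4g, sigma_innov2 = %.4g Hz^2\n",
              x$p_star, x$noise$tau, x$noise$sigma_innov2))
  cat("  circadian D (Hz):", paste(sprintf("%.2f", x$circadian$D), collapse = " "), "\n")
  cat(sprintf("  history (x = %g s, N_h = %d) O (Hz): %s\n", x$history$x,
              x$history$N_h, paste(sprintf("%.2f", x$history$O), collapse = " ")))
  invisible(x)
}

#' Evaluate the repertoire components along a trajectory
#'
#' Deterministic evaluation of `p* + d_t + o_t` (optionally plus a
#' supplied colored-noise path). Renditions with time-of-day outside the
#' circadian node span contribute a zero circadian offset.
#'
#' @param params a [repertoire_params()] object.
#' @param traj a `pitch_trajectory`.
#' @param colored_path optional numeric series `c_t` to add.
#' @return a `data.frame` with columns `d`, `o`, `total`
#'   (`= p_star + d + o [+ c]`), and `c` if supplied.
#' @export
evaluate_repertoire <- function(params, traj, colored_path = NULL) {
  W <- circadian_weights(traj$h, params$circadian$nodes)
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  d <- drop(W %*% params$circadian$D)
  nh <- history_counts(traj, x = params$history$x, N_h = params$history$N_h)
  o <- params$history$O[1L + nh]
  total <- params$p_star + d + o
  out <- data.frame(d = d, o = o)
  if (!is.null(colored_path)) {
    stopifnot(length(colored_path) == nrow(traj))
    out$c <- colored_path
    total <- total + colored_path
  }
  out$total <- total
  out
}

#' Sample a colored-noise path
#'
#' The slow pitch drift obeys the leaky random walk
#' `c_t = (1 - tau) c_{t-1} + e_t` with iid Gaussian innovations
#' `e_t ~ N(0, sigma_innov2)`, started from `c_0 = 0` and applied once per
#' rendition. Its autocorrelation decays as `(1 - tau)^k`, distinguishing
#' it from white exploration noise.
#'
#' @param params list with `tau` and `sigma_innov2` (e.g. the `noise`
#'   field of [repertoire_params()]).
#' @param T number of renditions.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector `c_1 ... c_T`.
#' @export
sample_colored_noise <- function(params, T, seed = NULL) {
  stopifnot(T >= 1)
  if (is.null(params$tau) || params$tau <= 0 || params$tau > 1)
    stop("tau must lie in (0, 1]")
  if (is.null(params$sigma_innov2) || params$sigma_innov2 < 0)
    stop("sigma_innov2 must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  innov <- stats::rnorm(T, 0, sqrt(params$sigma_innov2))
  as.numeric(stats::filter(innov, 1 - params$tau, method = "recursive"))
}
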