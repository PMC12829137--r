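#' Write a fitted-parameter bundle to JSON
#'
#' Serializes a `baseline_fit` or `feedback_fit` (every fitted parameter
#' with its fixed/free status, plus fit metadata: log-likelihood,
#' iterations, convergence) to a JSON file re-readable by
#' [read_parameter_bundle()].
#'
#' @param fit a `baseline_fit` or `feedback_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_parameter_bundle <- function(fit, path) {
  if (inherits(fit, "baseline_fit")) {
    rep <- fit$repertoire
    obj <- list(
      kind = "baseline",
      p_star = rep$p_star,
      circadian = list(nodes = rep$circadian$nodes, D = rep$circadian$D),
      history = list(x = rep$history$x, N_h = rep$history$N_h,
                     O = rep$history$O),
      noise = list(tau = rep$noise$tau,
                   sigma_innov2 = rep$noise$sigma_innov2),
      sigma_eps2 = fit$sigma_eps2,
      free = c("tau", "sigma_innov2", "p_star", "D", "O", "sigma_eps2"),
      fixed = list(G = fit$G),
      fit = list(loglik = fit$loglik, bic = fit$bic, n_iter = fit$n_iter,
                 converged = fit$converged, center = fit$center))
  } else if (inherits(fit, "feedback_fit")) {
    l <- fit$learner
    obj <- list(
      kind = "feedback", variant = fit$variant,
      alpha = l$alpha, delta = l$delta,
      sigma_eps2 = l$sigma_eps2, sigma_eta2 = l$sigma_eta2,
      reward_convention = l$reward_convention,
      free = c("alpha", "delta", "sigma_eps2", "sigma_eta2"),
      fixed = list(G = fit$G, p_star = fit$repertoire$p_star,
                   tau = fit$repertoire$noise$tau,
                   sigma_innov2 = fit$repertoire$noise$sigma_innov2),
      fit = list(loglik = fit$loglik, n_iter = fit$n_iter,
                 converged = fit$converged, center = fit$center))
  } else stop("fit must be a baseline_fit or feedback_fit")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted-parameter bundle
#'
#' @param path JSON path written by [write_parameter_bundle()].
#' @return for baseline bundles, a list with `repertoire`
#'   ([repertoire_params()]), `sigma_eps2` and `fit` metadata; for
#'   feedback bundles a list with `learner` ([learner_params()]),
#'   `variant` and `fit` metadata.
#' @export
read_parameter_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "baseline") {
    list(repertoire = repertoire_params(
           p_star = obj$p_star,
           nodes = obj$circadian$nodes, D = obj$circadian$D,
           x = obj$history$x, N_h = obj$history$N_h, O = obj$history$O,
           tau = obj$noise$tau, sigma_innov2 = obj$noise$sigma_innov2),
         sigma_eps2 = obj$sigma_eps2, fit = obj$fit, kind = obj$kind)
  } else {
    list(learner = learner_params(
           alpha = obj$alpha, delta = obj$delta,
           sigma_eps2 = obj$sigma_eps2, sigma_eta2 = obj$sigma_eta2,
           reward_convention = obj$reward_convention),
         variant = obj$variant, fit = obj$fit, kind = obj$kind)
  }
}
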