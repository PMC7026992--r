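# Predict observation-level concentrations: one solve per subject at the
# union of observation times, then pick the right analyte column.
predict_observations <- function(params, schedule, time_h, analyte) {
  ut <- sort(unique(time_h))
  prof <- solve_profile(params, schedule, ut)
  idx <- match(time_h, ut)
  ifelse(analyte == "plasma", prof$c_plasma[idx], prof$c_elf[idx])
}

#' Subject-level log-likelihood
#'
#' Gaussian log-likelihood of one subject's concentration observations given
#' a structural parameter vector. Each observation's SD is
#' `gamma * sd_assay(prediction)` per the [error_model()]; predictions come
#' from [solve_profile()]. Below-LOQ observations are excluded (the default
#' censoring policy) or included at `LOQ/2` upstream; this function expects
#' non-censored rows.
#'
#' @param params a [structural_params()] vector (or coercible).
#' @param observations data frame with columns `time_h`, `analyte`
#'   (`"plasma"` or `"elf"`), `value_mg_L`, and optionally `bloq` (rows with
#'   `bloq == 1` are dropped).
#' @param schedule the subject's [infusion_schedule()].
#' @param error an [error_model()].
#' @param gamma optional override of `error$gamma`.
#' @return Log-likelihood (scalar).
#' @export
subject_loglik <- function(params, observations, schedule, error,
                           gamma = NULL) {
  if (is.null(gamma)) gamma <- error$gamma
  obs <- drop_bloq(observations)
  if (nrow(obs) == 0L) {
    stop("no quantifiable observations for this subject", call. = FALSE)
  }
  pred <- predict_observations(params, schedule, obs$time_h, obs$analyte)
  sdv <- gamma * assay_sd_obs(error, obs$analyte, pred)
  sum(dnorm(obs$value_mg_L, mean = pred, sd = sdv, log = TRUE))
}

drop_bloq <- function(observations) {
  if ("bloq" %in% names(observations)) {
    observations[!(observations$bloq %in% c(1, TRUE)), , drop = FALSE]
  } else {
    observations
  }
}

#' MAP-Bayesian individual estimation over a discrete prior
#'
#' Given a nonparametric population model (discrete support points with
#' prior weights), the posterior weight of support point k for one subject
#' is proportional to `prior_weight_k * exp(loglik_k)`. Computed with a
#' log-sum-exp guard; returns the posterior weights and the maximum
#' a posteriori support point.
#'
#' @param prior a `pop_model` (see [npag_fit()]) or any list with elements
#'   `support` (data frame of parameter vectors) and `weights`.
#' @param observations,schedule,error as in [subject_loglik()].
#' @return List with `params` (MAP `structural_params`), `weights`
#'   (posterior over support points), `logliks` (per-point log-likelihood),
#'   and `map_index`.
#' @export
map_estimate <- function(prior, observations, schedule, error) {
  support <- prior$support
  w <- prior$weights
  stopifnot(nrow(support) >= 1L, length(w) == nrow(support))
  ll <- vapply(seq_len(nrow(support)), function(k) {
    subject_loglik(as_structural_params(support[k, , drop = FALSE]),
                   observations, schedule, error)
  }, numeric(1))
  logpost <- log(w) + ll
  m <- max(logpost)
  if (!is.finite(m)) {
    stop("all support-point likelihoods underflowed; rescale with ",
         "log-sum-exp or widen the prior support", call. = FALSE)
  }
  post <- exp(logpost - m)
  post <- post / sum(post)
  k <- which.max(post)
  list(params = as_structural_params(support[k, , drop = FALSE]),
       weights = post, logliks = ll, map_index = k)
}
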