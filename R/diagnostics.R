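#' Bias and imprecision of model predictions
#'
#' Bias is the mean prediction error `mean(pred - obs)` (mg/L); imprecision
#' is the bias-adjusted mean squared prediction error
#' `mean((pred - obs)^2) - bias^2` (mg^2/L^2).
#'
#' @param observed,predicted equal-length numeric vectors (length >= 1).
#' @return Named vector `c(bias, imprecision)`.
#' @examples
#' bias_imprecision(c(1, 2, 3), c(2, 3, 4))  # bias 1, imprecision 0
#' @export
bias_imprecision <- function(observed, predicted) {
  if (!length(observed) || length(observed) != length(predicted)) {
    stop("observed and predicted must be non-empty and of equal length",
         call. = FALSE)
  }
  e <- predicted - observed
  bias <- mean(e)
  c(bias = bias, imprecision = mean(e^2) - bias^2)
}

#' Observed-versus-predicted regression
#'
#' Ordinary least squares of observed on predicted concentrations; for a
#' well-calibrated model the intercept is ~0, the slope ~1 and R^2 high.
#'
#' @param observed,predicted numeric vectors, length >= 3.
#' @return Named vector `c(intercept, slope, r_squared)`.
#' @export
obs_pred_regression <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L) {
    stop("need >= 3 observed/predicted pairs", call. = FALSE)
  }
  if (stats::var(predicted) < .Machine$double.eps) {
    stop("predicted values have zero variance; regression is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(observed ~ predicted)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((observed - mean(observed))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  c(intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]), r_squared = r2)
}

# Draw n parameter vectors from a pop_model by weighted resampling of its
# support points. Returns an n x 7 matrix.
sample_pop_model <- function(model, n) {
  idx <- sample.int(nrow(model$support), n, replace = TRUE,
                    prob = model$weights)
  as.matrix(model$support)[idx, , drop = FALSE]
}

#' Visual predictive check
#'
#' Simulates `n_sim` virtual subjects from a fitted population model under a
#' template schedule (parameters resampled from the support by weight,
#' residual noise per the error model) and returns the 5th, 50th and 95th
#' percentiles of the simulated concentrations per time point. With
#' well-estimated random effects, about 90% of observed data are expected
#' to lie inside the 5th-95th band; use [vpc_coverage()] to quantify this.
#'
#' @param model a `pop_model` from [npag_fit()].
#' @param schedule template [infusion_schedule()].
#' @param times evaluation grid, h.
#' @param n_sim number of simulated subjects (>= 100).
#' @param seed RNG seed.
#' @param analyte `"plasma"` or `"elf"`.
#' @param noise add residual (assay x gamma) noise? Default `TRUE`.
#' @return An object of class `vpc_bands`: data frame with columns `time_h`,
#'   `p5`, `p50`, `p95`, plus the simulation matrix in attribute `"sims"`.
#' @export
vpc <- function(model, schedule, times, n_sim = 1000, seed = NULL,
                analyte = c("plasma", "elf"), noise = TRUE) {
  analyte <- match.arg(analyte)
  if (n_sim < 100) stop("n_sim must be >= 100", call. = FALSE)
  with_seed(seed, {
    pars <- sample_pop_model(model, n_sim)
    sims <- matrix(NA_real_, nrow = length(times), ncol = n_sim)
    for (i in seq_len(n_sim)) {
      prof <- solve_profile(as_structural_params(pars[i, ]), schedule, times)
      ci <- if (analyte == "plasma") prof$c_plasma else prof$c_elf
      if (noise) {
        sdv <- model$gamma * assay_sd(model$error, analyte, ci)
        ci <- pmax(ci + rnorm(length(ci), 0, sdv), 0)
      }
      sims[, i] <- ci
    }
    bands <- data.frame(
      time_h = times,
      p5 = apply(sims, 1, quantile, probs = 0.05),
      p50 = apply(sims, 1, quantile, probs = 0.50),
      p95 = apply(sims, 1, quantile, probs = 0.95)
    )
    attr(bands, "sims") <- sims
    class(bands) <- c("vpc_bands", "data.frame")
    bands
  })
}

#' @rdname vpc
#' @param bands a `vpc_bands` object.
#' @param obs_times,obs_values observed sampling times and concentrations;
#'   each observation is compared to the band at the nearest grid time.
#' @return `vpc_coverage()`: fraction of observations inside the 5th-95th
#'   percentile band.
#' @export
vpc_coverage <- function(bands, obs_times, obs_values) {
  idx <- vapply(obs_times, function(t) which.min(abs(bands$time_h - t)),
                integer(1))
  inside <- obs_values >= bands$p5[idx] & obs_values <= bands$p95[idx]
  mean(inside)
}

#' Normalized prediction distribution errors
#'
#' For each observation, simulates `n_sim` replicates under the population
#' model (parameters resampled from the support, residual noise per the
#' error model), ranks the observation among its replicates, maps the rank
#' to a uniform score `(rank + 0.5) / (n_sim + 1)`, and transforms it to a
#' standard-normal quantile. Under a correct model the NPDE sample is
#' approximately N(0, 1). No decorrelation step is applied (rank-based
#' variant); with one ELF observation per subject the within-subject
#' correlation is weakly identifiable.
#'
#' @param model a `pop_model`.
#' @param observations data frame with `subject_id`, `time_h`, `analyte`,
#'   `value_mg_L` (optional `bloq`; censored rows are dropped).
#' @param dosing as in [npag_fit()].
#' @param n_sim simulated replicates per observation (>= 500).
#' @param seed RNG seed.
#' @return The observation data frame with an `npde` column appended.
#' @export
npde <- function(model, observations, dosing, n_sim = 1000, seed = NULL) {
  if (n_sim < 500) stop("n_sim must be >= 500", call. = FALSE)
  with_seed(seed, {
    subjects <- build_subjects(observations, dosing)
    rows <- list()
    for (s in subjects) {
      pars <- sample_pop_model(model, n_sim)
      nobs <- nrow(s$obs)
      sims <- matrix(NA_real_, nrow = nobs, ncol = n_sim)
      for (i in seq_len(n_sim)) {
        pred <- predict_observations(as_structural_params(pars[i, ]),
                                     s$schedule, s$obs$time_h, s$obs$analyte)
        sdv <- model$gamma * assay_sd_obs(model$error, s$obs$analyte, pred)
        sims[, i] <- pred + rnorm(nobs, 0, sdv)
      }
      rank <- rowSums(sims < s$obs$value_mg_L)
      pde <- (rank + 0.5) / (n_sim + 1)
      out <- s$obs
      out$npde <- qnorm(pde)
      rows[[length(rows) + 1L]] <- out
    }
    do.call(rbind, rows)
  })
}
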