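# Shared fixtures: small parameter sets, schedules and toy datasets built
# in code at test time.

med_params <- function() reference_medians()

# single 15-min 2 g loading dose
ld_only <- function() infusion_schedule(0, 0.25, 2000)

# contiguous maintenance infusions (dose mg per 8 h), no loading dose
plain_ci <- function(dose_mg, horizon = 72) {
  k <- seq_len(ceiling(horizon / 8)) - 1
  infusion_schedule(8 * k, rep(8, length(k)), rep(dose_mg, length(k)))
}

# random positive parameter draws around the reference, for property loops
random_params <- function(n, seed = 1) {
  ref <- reference_parameters()
  with_seed_test(seed, {
    lapply(seq_len(n), function(i) {
      x <- ref$median * exp(stats::rnorm(7, 0, 0.3))
      as_structural_params(stats::setNames(x, ref$parameter))
    })
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(code)
}

# tiny two-subject dataset simulated exactly (no noise) from `params`
toy_dataset <- function(params = med_params(),
                        times = c(0.5, 1, 2, 4, 6, 8),
                        schedule = regimen_preset("2g_ld_1g_q8h_ci",
                                                  horizon_h = 8.25)) {
  prof <- solve_profile(params, schedule, times)
  obs <- do.call(rbind, lapply(1:2, function(id) {
    rbind(
      data.frame(subject_id = id, time_h = times, analyte = "plasma",
                 value_mg_L = prof$c_plasma, bloq = 0L),
      data.frame(subject_id = id, time_h = 6, analyte = "elf",
                 value_mg_L = prof$c_elf[times == 6], bloq = 0L)
    )
  }))
  list(observations = obs, schedule = schedule, params = params)
}

# weighted resampling of a pop_model's support, for oracle computations
sample_pop_model_for_test <- function(model, n, seed = NULL) {
  draw <- function() {
    idx <- sample.int(nrow(model$support), n, replace = TRUE,
                      prob = model$weights)
    as.matrix(model$support)[idx, , drop = FALSE]
  }
  if (is.null(seed)) draw() else with_seed_test(seed, draw())
}

# small hand-built population model for diagnostics tests
toy_pop_model <- function(n_points = 5, seed = 99, gamma = 1) {
  pars <- sample_population(population_sampler(), n_points, seed = seed)
  structure(list(support = as.data.frame(pars),
                 weights = rep(1 / n_points, n_points),
                 gamma = gamma, loglik = NA_real_,
                 error = error_model(), n_subjects = n_points,
                 n_obs = NA_integer_),
            class = "pop_model")
}
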