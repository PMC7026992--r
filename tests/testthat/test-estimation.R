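# Likelihood, MAP estimation, population fitting and fit diagnostics.

test_that("subject_loglik matches a brute-force density sum", {
  toy <- toy_dataset()
  obs <- toy$observations[toy$observations$subject_id == 1, ][1:3, ]
  em <- error_model()
  ll <- subject_loglik(toy$params, obs, toy$schedule, em)
  # independent oracle: explicit normal densities at the same predictions
  prof <- solve_profile(toy$params, toy$schedule, sort(unique(obs$time_h)))
  pred <- prof$c_plasma[match(obs$time_h, sort(unique(obs$time_h)))]
  sdv <- 0.25 + 0.15 * pred
  oracle <- sum(log(1 / (sqrt(2 * pi) * sdv) *
                      exp(-(obs$value_mg_L - pred)^2 / (2 * sdv^2))))
  expect_equal(ll, oracle, tolerance = 1e-10)
  # zero residuals: loglik is minus the sum of log(sqrt(2 pi) sd)
  expect_equal(ll, -sum(log(sqrt(2 * pi) * sdv)), tolerance = 1e-8)
  # doubling gamma lowers the log-likelihood of perfectly fitting data
  expect_lt(subject_loglik(toy$params, obs, toy$schedule, em, gamma = 2),
            ll)
})

test_that("map_estimate reproduces hand-computed Bayes ratios", {
  toy <- toy_dataset()
  obs1 <- toy$observations[toy$observations$subject_id == 1, ][3, ]
  em <- error_model()
  truth <- unclass(toy$params)
  other <- truth * 1.6
  prior <- list(support = rbind(as.data.frame(t(truth)),
                                as.data.frame(t(other))),
                weights = c(0.3, 0.7))
  est <- map_estimate(prior, obs1, toy$schedule, em)
  ll1 <- subject_loglik(as_structural_params(truth), obs1, toy$schedule, em)
  ll2 <- subject_loglik(as_structural_params(other), obs1, toy$schedule, em)
  w1 <- 0.3 * exp(ll1) / (0.3 * exp(ll1) + 0.7 * exp(ll2))
  expect_equal(est$weights, c(w1, 1 - w1), tolerance = 1e-12)
  expect_equal(unclass(est$params), truth)
  # single support point: returned with weight 1
  single <- list(support = as.data.frame(t(truth)), weights = 1)
  est1 <- map_estimate(single, obs1, toy$schedule, em)
  expect_equal(est1$weights, 1)
})

test_that("bias_imprecision follows its defining formula", {
  expect_equal(bias_imprecision(c(1, 2, 3), c(1, 2, 3)),
               c(bias = 0, imprecision = 0))
  expect_equal(bias_imprecision(c(1, 2, 3), c(2, 3, 4)),
               c(bias = 1, imprecision = 0))
  with_seed_test(3, {
    o <- rnorm(50, 10, 2); p <- o + rnorm(50, 0.5, 1)
    bi <- bias_imprecision(o, p)
    e <- p - o
    expect_equal(unname(bi["bias"]), mean(e), tolerance = 1e-12)
    expect_equal(unname(bi["imprecision"]), mean(e^2) - mean(e)^2,
                 tolerance = 1e-12)
  })
  expect_error(bias_imprecision(numeric(0), numeric(0)), "non-empty")
})

test_that("obs_pred_regression matches the normal equations", {
  o <- c(1, 2, 3, 5); p <- c(1.2, 1.9, 3.3, 4.6)
  r <- obs_pred_regression(o, p)
  X <- cbind(1, p)
  beta <- solve(t(X) %*% X, t(X) %*% o)
  expect_equal(unname(r["intercept"]), beta[1], tolerance = 1e-12)
  expect_equal(unname(r["slope"]), beta[2], tolerance = 1e-12)
  perfect <- obs_pred_regression(p, p)
  expect_equal(unname(perfect), c(0, 1, 1), tolerance = 1e-10)
  doubled <- obs_pred_regression(2 * p, p)
  expect_equal(unname(doubled["slope"]), 2, tolerance = 1e-10)
  expect_error(obs_pred_regression(o, rep(1, 4)), "degenerate")
  expect_error(obs_pred_regression(1:2, 1:2), ">= 3")
})

test_that("npag_fit with bounds collapsed to a point degenerates to the
           likelihood at that point", {
  toy <- toy_dataset()
  p <- unclass(toy$params)
  bounds <- data.frame(parameter = names(p), lower = p, upper = p)
  fit <- suppressWarnings(
    npag_fit(toy$observations, toy$schedule, bounds = bounds, seed = 1,
             n_init = 20, max_cycles = 2, fit_gamma = FALSE))
  expect_equal(nrow(fit$support), 1L)
  expect_equal(fit$weights, 1)
  em <- error_model()
  ll_direct <- sum(sapply(1:2, function(id) {
    subject_loglik(toy$params,
                   toy$observations[toy$observations$subject_id == id, ],
                   toy$schedule, em)
  }))
  expect_equal(fit$loglik, ll_direct, tolerance = 1e-8)
})

test_that("EM weight updates never decrease the mixture log-likelihood", {
  toy <- toy_dataset()
  fit <- suppressWarnings(
    npag_fit(toy$observations, toy$schedule, seed = 2, n_init = 60,
             max_cycles = 2, fit_gamma = FALSE, refine_maxit = 30))
  expect_gt(length(fit$em_traces), 1L)
  for (tr in fit$em_traces) expect_true(all(diff(tr) >= -1e-6))
})

test_that("noise-free self-simulated data yield a dominant, well-fitting
           support point and clean diagnostics", {
  # 4 identical subjects, rich sampling during the transient, no noise
  p <- med_params()
  sched <- regimen_preset("2g_ld_1g_q8h_ci", horizon_h = 8.25)
  times <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
  prof <- solve_profile(p, sched, times)
  obs <- do.call(rbind, lapply(1:4, function(id) {
    rbind(data.frame(subject_id = id, time_h = times, analyte = "plasma",
                     value_mg_L = prof$c_plasma, bloq = 0L),
          data.frame(subject_id = id, time_h = c(2, 4, 6), analyte = "elf",
                     value_mg_L = prof$c_elf[match(c(2, 4, 6), times)],
                     bloq = 0L))
  }))
  fit <- npag_fit(obs, sched, seed = 3, n_init = 100, max_cycles = 3,
                  fit_gamma = FALSE, refine_maxit = 300)
  k <- which.max(fit$weights)
  expect_gt(fit$weights[k], 0.5)
  best <- as_structural_params(fit$support[k, ])
  # the dominant point reproduces the noise-free observations closely
  # (a simplex search in 7 dimensions stops short of the exact optimum,
  # so the check is close-fit, not exact recovery)
  pfit <- solve_profile(best, sched, times)
  expect_lt(max(abs(pfit$c_plasma - prof$c_plasma) / prof$c_plasma), 0.10)
  expect_equal(best[["CL"]], p[["CL"]], tolerance = 0.10)
  # diagnostics on the (near-perfect) self fit
  pred <- c(pfit$c_plasma, pfit$c_elf[match(c(2, 4, 6), times)])
  obs1 <- c(prof$c_plasma, prof$c_elf[match(c(2, 4, 6), times)])
  bi <- bias_imprecision(obs1, pred)
  expect_lt(abs(bi["bias"]), 1)
  reg <- obs_pred_regression(obs1, pred)
  expect_equal(unname(reg["slope"]), 1, tolerance = 0.10)
  expect_gt(reg["r_squared"], 0.98)
})

test_that("vpc percentile bands match a sort-based oracle and collapse for
           a degenerate model", {
  m <- toy_pop_model(n_points = 4, seed = 12)
  sched <- regimen_preset("2g_ld_1g_q8h_ci", horizon_h = 24.25)
  bands <- vpc(m, sched, times = c(6, 12, 24), n_sim = 200, seed = 5)
  sims <- attr(bands, "sims")
  for (i in 1:3) {
    expect_equal(bands$p5[i], unname(quantile(sims[i, ], 0.05)))
    expect_equal(bands$p50[i], unname(quantile(sims[i, ], 0.5)))
    expect_equal(bands$p95[i], unname(quantile(sims[i, ], 0.95)))
  }
  expect_true(all(bands$p5 <= bands$p50 & bands$p50 <= bands$p95))
  # degenerate model without noise: all three bands equal the single profile
  m1 <- m; m1$support <- as.data.frame(t(unclass(med_params())))
  m1$weights <- 1
  b1 <- vpc(m1, sched, times = c(6, 12, 24), n_sim = 100, seed = 5,
            noise = FALSE)
  prof <- solve_profile(med_params(), sched, c(6, 12, 24))
  expect_equal(b1$p5, prof$c_plasma, tolerance = 1e-10)
  expect_equal(b1$p95, prof$c_plasma, tolerance = 1e-10)
})

test_that("npde is centered, finite at the floor, and ~N(0,1) under the
           null", {
  m <- toy_pop_model(n_points = 8, seed = 31)
  sched <- regimen_preset("2g_ld_1g_q8h_ci", horizon_h = 56.25)
  # observation equal to the simulation median -> NPDE ~ 0
  pars <- sample_pop_model_for_test(m, 500, seed = 8)
  preds <- sapply(seq_len(nrow(pars)), function(i) {
    solve_profile(as_structural_params(pars[i, ]), sched, 48)$c_plasma
  })
  med_obs <- data.frame(subject_id = 1, time_h = 48, analyte = "plasma",
                        value_mg_L = median(preds), bloq = 0L)
  r <- npde(m, med_obs, sched, n_sim = 500, seed = 8)
  expect_lt(abs(r$npde), 0.3)
  # observation below all replicates stays finite
  low_obs <- med_obs; low_obs$value_mg_L <- 1e-6
  r2 <- npde(m, low_obs, sched, n_sim = 500, seed = 8)
  expect_true(is.finite(r2$npde))
  expect_equal(r2$npde, qnorm(0.5 / 501), tolerance = 1e-10)
  # under the null (data simulated from the model) npde ~ N(0, 1)
  n_obs <- 60
  null_obs <- with_seed_test(77, {
    pars <- sample_pop_model_for_test(m, n_obs, seed = NULL)
    do.call(rbind, lapply(seq_len(n_obs), function(i) {
      pr <- solve_profile(as_structural_params(pars[i, ]), sched,
                          c(49.5, 54))
      pred <- pr$c_plasma[2]
      sdv <- m$gamma * (0.25 + 0.15 * pred)
      data.frame(subject_id = i, time_h = 54, analyte = "plasma",
                 value_mg_L = pred + rnorm(1, 0, sdv), bloq = 0L)
    }))
  })
  rn <- npde(m, null_obs, sched, n_sim = 600, seed = 9)
  se_mean <- 1 / sqrt(n_obs)
  se_var <- sqrt(2 / (n_obs - 1))
  expect_lt(abs(mean(rn$npde)), 3 * se_mean)
  expect_lt(abs(var(rn$npde) - 1), 3 * se_var)
})
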