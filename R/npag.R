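# Nonparametric population estimation.
#
# The population distribution is a discrete mixture of support points
# (parameter vectors) with weights. Fitting alternates:
#   1. candidate support from low-discrepancy (Latin hypercube) sampling
#      within the search bounds;
#   2. EM optimization of the mixture weights for fixed points, which is
#      monotone in the total log-likelihood;
#   3. adaptive refinement: each subject's posterior-mode point is polished
#      by a local search of its own likelihood, and the polished points are
#      added to the support; low-weight points are dropped;
#   4. a 1-D golden-section search for the multiplicative process-noise
#      term gamma, interleaved with the weight updates.
#
# For speed, per-(design, point) predictions are cached once: with
# sd_i(k) the assay SD at the prediction and q_jk the standardized squared
# residual sum, the subject-point log-likelihood at any gamma is
#   L_jk(gamma) = -n log(gamma) - sum_i log sd_i(k) - n/2 log(2 pi)
#                 - q_jk / (2 gamma^2),
# so the gamma search costs no additional model solves.

#' Default parameter search bounds
#'
#' Mean +/- 4 SD of the packaged population reference (the published
#' analysis does not state its search ranges), floored below at one-tenth
#' of the population mean. The floor matters: mean - 4 SD is negative for
#' some rate constants, and a near-zero floor would admit
#' quasi-irreversible deep-compartment modes (equilibration half-times of
#' hundreds of hours) that are physiologically implausible for meropenem
#' yet, with single-occasion near-steady-state sampling, almost
#' indistinguishable from genuine elimination — corrupting the fitted
#' clearance distribution. One-tenth of the mean excludes those time
#' scales while keeping essentially every plausible individual (under the
#' published dispersion, < 0.3% of subjects fall below it for any
#' parameter).
#'
#' @param ref reference table as from [reference_parameters()].
#' @param k half-width in SD units.
#' @return Data frame with columns `parameter`, `lower`, `upper`.
#' @export
default_bounds <- function(ref = reference_parameters(), k = 4) {
  data.frame(parameter = ref$parameter,
             lower = pmax(ref$mean - k * ref$sd, ref$mean / 10),
             upper = ref$mean + k * ref$sd)
}

#' Fit a nonparametric population model
#'
#' Estimates a discrete support-point/weight mixture over the structural
#' parameters from multi-subject concentration data, in the spirit of
#' nonparametric adaptive-grid (NPAG) estimation: low-discrepancy
#' initialization of candidate points, EM weight optimization (monotone in
#' the mixture log-likelihood), adaptive refinement of high-posterior
#' points by per-subject local search, pruning of negligible-weight points,
#' and interleaved 1-D optimization of the multiplicative error term gamma.
#'
#' @param observations data frame with columns `subject_id`, `time_h`,
#'   `analyte` (`"plasma"`/`"elf"`), `value_mg_L`, optional `bloq`
#'   (below-LOQ rows are excluded from the likelihood).
#' @param dosing data frame with columns `subject_id`, `start_h`,
#'   `duration_h`, `amount_mg`, or a single [infusion_schedule()] shared by
#'   all subjects, or a named list of schedules keyed by subject id.
#' @param error an [error_model()].
#' @param bounds search bounds as from [default_bounds()].
#' @param seed RNG seed (required: initialization is stochastic).
#' @param n_init number of initial Latin-hypercube support candidates.
#' @param max_cycles maximum refinement cycles.
#' @param em_tol log-likelihood convergence tolerance for the EM weight
#'   updates and for cycle-to-cycle improvement.
#' @param drop_tol support points with weight below this are pruned.
#' @param fit_gamma optimize gamma in `[1, 10]` (golden-section on the
#'   profile likelihood)? If `FALSE`, `error$gamma` is kept fixed.
#' @param refine_maxit iterations for each per-subject local polish.
#' @return An object of class `pop_model`: list with `support` (data frame,
#'   one row per point), `weights`, `gamma`, `loglik`, `em_traces` (list of
#'   per-run EM log-likelihood traces, each monotone non-decreasing),
#'   `cycles`, `converged`, `error`, `bounds`.
#' @export
npag_fit <- function(observations, dosing, error = error_model(),
                     bounds = default_bounds(), seed = NULL,
                     n_init = 200, max_cycles = 5, em_tol = 1e-4,
                     drop_tol = 1e-6, fit_gamma = TRUE,
                     refine_maxit = 80) {
  with_seed(seed, {
    subjects <- build_subjects(observations, dosing)
    if (length(subjects) < 2L) {
      stop("population fitting needs at least 2 subjects", call. = FALSE)
    }
    npar <- sum(vapply(subjects, function(s) nrow(s$obs), numeric(1)))
    if (any(vapply(subjects, function(s) nrow(s$obs), numeric(1)) <
            length(param_names()))) {
      warning("some subjects have fewer observations than parameters; ",
              "individual parameters are only partially identifiable",
              call. = FALSE)
    }

    lower <- bounds$lower[match(param_names(), bounds$parameter)]
    upper <- bounds$upper[match(param_names(), bounds$parameter)]
    stopifnot(all(is.finite(lower)), all(is.finite(upper)),
              all(lower > 0), all(upper >= lower))

    # initial support: Latin hypercube in the box
    H <- lhs::randomLHS(n_init, length(lower))
    pts <- sweep(sweep(H, 2, upper - lower, "*"), 2, lower, "+")
    colnames(pts) <- param_names()
    pts <- dedupe_points(pts)

    cache <- new_likelihood_cache(subjects, error)
    cache <- cache_add_points(cache, pts)

    gamma <- error$gamma
    traces <- list()
    em <- em_weights(cache, gamma, em_tol = em_tol)
    w <- em$w
    traces[[length(traces) + 1L]] <- em$trace
    if (fit_gamma) {
      gamma <- optimize_gamma(cache, w, c(1, 10))
      em <- em_weights(cache, gamma, w0 = w, em_tol = em_tol)
      w <- em$w; traces[[length(traces) + 1L]] <- em$trace
    }
    ll <- mixture_loglik(cache, w, gamma)

    cycles <- 0L
    converged <- FALSE
    for (cyc in seq_len(max_cycles)) {
      cycles <- cyc
      cand <- refine_candidates(cache, w, gamma, lower, upper,
                                maxit = refine_maxit)
      if (!is.null(cand) && nrow(cand)) {
        keep <- !duplicated_points(cand, cache$points)
        if (any(keep)) {
          cache <- cache_add_points(cache, cand[keep, , drop = FALSE])
          w <- c(w, rep(0, sum(keep)))
          w[w == 0] <- 1e-8
          w <- w / sum(w)
        }
      }
      em <- em_weights(cache, gamma, w0 = w, em_tol = em_tol)
      w <- em$w; traces[[length(traces) + 1L]] <- em$trace
      if (fit_gamma) {
        gamma <- optimize_gamma(cache, w, c(1, 10))
        em <- em_weights(cache, gamma, w0 = w, em_tol = em_tol)
        w <- em$w; traces[[length(traces) + 1L]] <- em$trace
      }
      # prune negligible points (always keep the heaviest)
      keep <- w >= drop_tol
      keep[which.max(w)] <- TRUE
      if (!all(keep)) {
        cache <- cache_subset_points(cache, keep)
        w <- w[keep] / sum(w[keep])
      }
      ll_new <- mixture_loglik(cache, w, gamma)
      if (ll_new - ll < em_tol && cyc >= 2L) {
        ll <- max(ll, ll_new)
        converged <- TRUE
        break
      }
      ll <- ll_new
    }

    support <- as.data.frame(cache$points)
    structure(list(support = support, weights = w, gamma = gamma,
                   loglik = ll, em_traces = traces, cycles = cycles,
                   converged = converged, error = error,
                   bounds = data.frame(parameter = param_names(),
                                       lower = lower, upper = upper),
                   n_subjects = length(subjects), n_obs = npar),
              class = "pop_model")
  })
}

#' @export
print.pop_model <- function(x, ...) {
  cat("<pop_model> ", nrow(x$support), " support point(s), ",
      x$n_subjects, " subjects, ", x$n_obs, " observations\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 8),
      ", gamma ", format(x$gamma, digits = 4),
      ", cycles ", x$cycles,
      if (isTRUE(x$converged)) " (converged)" else " (not converged)",
      "\n", sep = "")
  print(pop_summary(x))
  invisible(x)
}

#' Weighted summary of a fitted population model
#'
#' Weighted median, mean and SD of each structural parameter over the
#' support points.
#'
#' @param model a `pop_model`.
#' @return Data frame with columns `parameter`, `median`, `mean`, `sd`.
#' @export
pop_summary <- function(model) {
  s <- as.matrix(model$support)
  w <- model$weights
  data.frame(
    parameter = colnames(s),
    median = apply(s, 2, weighted_quantile, w = w, p = 0.5),
    mean = as.numeric(crossprod(w, s)),
    sd = vapply(seq_len(ncol(s)), function(j) {
      mu <- sum(w * s[, j])
      sqrt(max(sum(w * (s[, j] - mu)^2), 0))
    }, numeric(1)),
    row.names = NULL
  )
}

#' @rdname pop_summary
#' @return `pop_median()`: named vector of weighted parameter medians.
#' @export
pop_median <- function(model) {
  s <- pop_summary(model)
  setNames(s$median, s$parameter)
}

weighted_quantile <- function(x, w, p = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  x[which(cw >= p)[1]]
}

# ---- internal machinery -----------------------------------------------

build_subjects <- function(observations, dosing) {
  need <- c("subject_id", "time_h", "analyte", "value_mg_L")
  miss <- setdiff(need, names(observations))
  if (length(miss)) {
    stop("observations are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ids <- unique(observations$subject_id)
  get_schedule <- function(id) {
    if (inherits(dosing, "infusion_schedule")) return(dosing)
    if (is.list(dosing) && !is.data.frame(dosing)) {
      sc <- dosing[[as.character(id)]]
      if (is.null(sc)) stop("no schedule for subject ", id, call. = FALSE)
      return(sc)
    }
    rows <- dosing[dosing$subject_id == id, , drop = FALSE]
    if (!nrow(rows)) stop("no dosing rows for subject ", id, call. = FALSE)
    infusion_schedule(rows$start_h, rows$duration_h, rows$amount_mg)
  }
  lapply(ids, function(id) {
    obs <- drop_bloq(observations[observations$subject_id == id, ,
                                  drop = FALSE])
    obs <- obs[order(obs$time_h, obs$analyte), , drop = FALSE]
    if (!nrow(obs)) {
      stop("subject ", id, " has no quantifiable observations",
           call. = FALSE)
    }
    sched <- get_schedule(id)
    key <- paste(c(format(unlist(sched$events), digits = 15),
                   format(obs$time_h, digits = 15), obs$analyte),
                 collapse = "|")
    list(id = id, obs = obs, schedule = sched, design_key = key)
  })
}

# Cache layout:
#   points: K x 7 matrix
#   designs: list keyed by design_key: list(schedule, time_h, analyte,
#            pred (n x K), logsd (n x K sum -> A: K), sd (n x K))
#   subjects: list(id, design_key, values)
new_likelihood_cache <- function(subjects, error) {
  designs <- list()
  for (s in subjects) {
    if (is.null(designs[[s$design_key]])) {
      designs[[s$design_key]] <- list(schedule = s$schedule,
                                      time_h = s$obs$time_h,
                                      analyte = s$obs$analyte,
                                      pred = NULL, sd = NULL)
    }
  }
  list(points = NULL, designs = designs, subjects = subjects, error = error)
}

cache_add_points <- function(cache, pts) {
  pts <- as.matrix(pts)
  for (key in names(cache$designs)) {
    d <- cache$designs[[key]]
    newpred <- vapply(seq_len(nrow(pts)), function(k) {
      predict_observations(as_structural_params(pts[k, ]), d$schedule,
                           d$time_h, d$analyte)
    }, numeric(length(d$time_h)))
    newpred <- matrix(newpred, nrow = length(d$time_h))
    newsd <- matrix(assay_sd_obs(cache$error, rep(d$analyte, ncol(newpred)),
                                 as.vector(newpred)),
                    nrow = nrow(newpred))
    d$pred <- cbind(d$pred, newpred)
    d$sd <- cbind(d$sd, newsd)
    cache$designs[[key]] <- d
  }
  cache$points <- rbind(cache$points, pts)
  cache
}

cache_subset_points <- function(cache, keep) {
  for (key in names(cache$designs)) {
    d <- cache$designs[[key]]
    d$pred <- d$pred[, keep, drop = FALSE]
    d$sd <- d$sd[, keep, drop = FALSE]
    cache$designs[[key]] <- d
  }
  cache$points <- cache$points[keep, , drop = FALSE]
  cache
}

# J x K log-likelihood matrix at a given gamma, from cached predictions.
loglik_matrix <- function(cache, gamma) {
  K <- nrow(cache$points)
  L <- matrix(NA_real_, nrow = length(cache$subjects), ncol = K)
  for (j in seq_along(cache$subjects)) {
    s <- cache$subjects[[j]]
    d <- cache$designs[[s$design_key]]
    v <- s$obs$value_mg_L
    n <- length(v)
    q <- colSums(((v - d$pred) / d$sd)^2)
    A <- colSums(log(d$sd))
    L[j, ] <- -n * log(gamma) - A - n / 2 * log(2 * pi) - q / (2 * gamma^2)
  }
  L
}

logsumexp_rows <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

mixture_loglik <- function(cache, w, gamma) {
  L <- loglik_matrix(cache, gamma)
  lw <- sweep(L, 2, log(w), "+")
  sum(logsumexp_rows(lw))
}

# EM for the mixture weights with fixed support and gamma. Monotone in the
# total log-likelihood; `trace` records it per iteration.
em_weights <- function(cache, gamma, w0 = NULL, em_tol = 1e-4,
                       max_iter = 500) {
  L <- loglik_matrix(cache, gamma)
  K <- ncol(L)
  w <- if (is.null(w0)) rep(1 / K, K) else pmax(w0, 1e-300) / sum(pmax(w0, 1e-300))
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, log(w), "+")
    lj <- logsumexp_rows(lw)
    ll <- sum(lj)
    trace <- c(trace, ll)
    resp <- exp(lw - lj)
    w <- colMeans(resp)
    w <- w / sum(w)
    if (ll - ll_old < em_tol && it > 1L) break
    ll_old <- ll
  }
  list(w = w, trace = trace)
}

# Golden-section maximization of the mixture log-likelihood over gamma.
optimize_gamma <- function(cache, w, interval = c(1, 10), tol = 1e-3) {
  f <- function(g) mixture_loglik(cache, w, g)
  opt <- stats::optimize(f, interval = interval, maximum = TRUE, tol = tol)
  # the boundary gamma = 1 is a common solution; keep it if better
  if (f(interval[1]) >= opt$objective) interval[1] else opt$maximum
}

# Per-subject polish by Nelder-Mead on log-parameters (box-constrained by
# penalty). Two starts per subject: the current posterior-mode support
# point, and a data-informed point whose clearance comes from the
# steady-state approximation rate/mean(plasma) — this keeps the plausible
# elimination mode in play when the sampling window is flat (near steady
# state, a very slowly equilibrating deep-compartment mode can mimic the
# same concentrations and trap a single-start search).
refine_candidates <- function(cache, w, gamma, lower, upper, maxit = 80) {
  L <- loglik_matrix(cache, gamma)
  lw <- sweep(L, 2, log(w), "+")
  mid <- (lower + upper) / 2
  out <- NULL
  for (j in seq_along(cache$subjects)) {
    s <- cache$subjects[[j]]
    obj <- function(lx) {
      x <- exp(lx)
      if (any(x < lower) || any(x > upper)) return(1e10)
      -subject_loglik(as_structural_params(setNames(x, param_names())),
                      s$obs, s$schedule, cache$error, gamma = gamma)
    }
    starts <- list(log(cache$points[which.max(lw[j, ]), ]))
    cl_ss <- css_clearance_guess(s)
    if (is.finite(cl_ss) && refine_extra_start(lw[j, ], cache, cl_ss)) {
      guess <- mid
      names(guess) <- param_names()
      guess["CL"] <- min(max(cl_ss, lower[1]), upper[1])
      starts <- c(starts, list(log(guess)))
    }
    for (x0 in starts) {
      fit <- tryCatch({
        f1 <- optim(x0, obj, method = "Nelder-Mead",
                    control = list(maxit = maxit, reltol = 1e-6))
        # one restart: a fresh simplex around the interim optimum helps
        # Nelder-Mead out of premature collapse in 7 dimensions
        optim(f1$par, obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8))
      }, error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e9) {
        out <- rbind(out, exp(fit$par))
      }
    }
  }
  if (!is.null(out)) colnames(out) <- param_names()
  out
}

# Use the extra data-informed start only when the subject's current
# posterior-mode clearance disagrees with the steady-state heuristic by
# more than 30% — the cheap single start suffices otherwise.
refine_extra_start <- function(lw_row, cache, cl_ss) {
  cl_mode <- cache$points[which.max(lw_row), "CL"]
  abs(cl_mode - cl_ss) / cl_ss > 0.3
}

# Steady-state clearance heuristic: mean infusion rate over the 8 h before
# the last plasma sample divided by the mean plasma concentration.
css_clearance_guess <- function(s) {
  pl <- s$obs$analyte == "plasma"
  if (!any(pl)) return(NA_real_)
  tmax <- max(s$obs$time_h[pl])
  rbar <- mean(infusion_rate(s$schedule,
                             seq(max(tmax - 8, 0), tmax, by = 0.25)))
  cbar <- mean(s$obs$value_mg_L[pl])
  if (rbar <= 0 || cbar <= 0) return(NA_real_)
  rbar / cbar
}

dedupe_points <- function(pts) {
  key <- apply(signif(pts, 6), 1, paste, collapse = "|")
  pts[!duplicated(key), , drop = FALSE]
}

duplicated_points <- function(new, existing) {
  if (is.null(existing)) return(rep(FALSE, nrow(new)))
  keyn <- apply(signif(new, 6), 1, paste, collapse = "|")
  keye <- apply(signif(existing, 6), 1, paste, collapse = "|")
  keyn %in% keye | duplicated(keyn)
}
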