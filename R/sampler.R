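#' Virtual-population parameter samplers
#'
#' A sampler describes how Monte Carlo parameter vectors are drawn for
#' dosing simulations.
#'
#' `mode = "parametric"` draws each parameter from an independent log-normal
#' distribution whose moments match a published mean/SD summary (by default
#' the packaged reference table), truncated at mean +/- `truncation` SD on
#' the natural scale (re-drawing out-of-range values). Log-normals guarantee
#' positivity; joint correlations are not published and are therefore not
#' imposed.
#'
#' `mode = "nonparametric"` resamples the support points of a fitted
#' `pop_model` according to their weights.
#'
#' `mode = "degenerate"` returns the reference means exactly (useful for
#' deterministic checks).
#'
#' @param mode `"parametric"`, `"nonparametric"` or `"degenerate"`.
#' @param ref reference table as from [reference_parameters()] (parametric
#'   and degenerate modes).
#' @param model a `pop_model` (nonparametric mode).
#' @param truncation truncation half-width in SD units (natural scale).
#' @param stratified use per-parameter Latin-hypercube stratified
#'   inverse-CDF draws in parametric mode (default). Stratification keeps
#'   the joint distribution (independent permutations per parameter) while
#'   reducing the Monte Carlo error of population summaries; set `FALSE`
#'   for plain independent draws.
#' @return An object of class `population_sampler`.
#' @examples
#' s <- population_sampler()
#' draws <- sample_population(s, 5, seed = 1)
#' @export
population_sampler <- function(mode = c("parametric", "nonparametric",
                                        "degenerate"),
                               ref = reference_parameters(), model = NULL,
                               truncation = 4, stratified = TRUE) {
  mode <- match.arg(mode)
  if (mode == "nonparametric" && !inherits(model, "pop_model")) {
    stop("nonparametric mode needs a fitted `pop_model`", call. = FALSE)
  }
  structure(list(mode = mode, ref = ref, model = model,
                 truncation = truncation, stratified = stratified),
            class = "population_sampler")
}

#' @rdname population_sampler
#' @param sampler a `population_sampler`.
#' @param n number of parameter vectors to draw (>= 1).
#' @param seed RNG seed; identical `(seed, n)` give identical draws.
#' @return `sample_population()`: an `n` x 7 matrix with columns
#'   `CL, V, K12, K21, K13, K31, V_ELF`; every row satisfies the structural
#'   parameter invariants.
#' @export
sample_population <- function(sampler, n, seed = NULL) {
  stopifnot(inherits(sampler, "population_sampler"), n >= 1)
  with_seed(seed, {
    out <- switch(sampler$mode,
      degenerate = matrix(rep(sampler$ref$mean, each = n), nrow = n,
                          dimnames = list(NULL, sampler$ref$parameter)),
      nonparametric = sample_pop_model(sampler$model, n),
      parametric = sample_lognormal_matched(sampler$ref, n,
                                            sampler$truncation,
                                            sampler$stratified)
    )
    colnames(out) <- param_names()
    out
  })
}

# Independent truncated log-normals, moment-matched per parameter. The
# truncation window is mean +/- k*sd on the natural scale (lower bound
# floored at a small positive value). Because truncating a skewed
# log-normal shifts its moments (for the most dispersed rate constant the
# plain-lognormal SD would be ~16% off after truncation), (mu, sigma) are
# calibrated so that the *truncated* distribution reproduces the target
# mean and SD; the closed-form truncated-lognormal moments
#   E[X^k | a<X<b] = e^{k mu + k^2 sigma^2/2} *
#     [Phi((log b - mu - k sigma^2)/sigma) - Phi((log a - mu - k sigma^2)/sigma)] /
#     [Phi((log b - mu)/sigma) - Phi((log a - mu)/sigma)]
# make the calibration a cheap 2-D optimization. Rejected draws are
# redrawn.
sample_lognormal_matched <- function(ref, n, truncation = 4,
                                     stratified = TRUE) {
  p <- nrow(ref)
  out <- matrix(NA_real_, nrow = n, ncol = p,
                dimnames = list(NULL, ref$parameter))
  for (j in seq_len(p)) {
    m <- ref$mean[j]; s <- ref$sd[j]
    lo <- max(m - truncation * s, 1e-3)
    hi <- m + truncation * s
    par <- calibrate_trunc_lnorm(m, s, lo, hi)
    pa <- stats::plnorm(lo, par$mu, par$sigma)
    pb <- stats::plnorm(hi, par$mu, par$sigma)
    if (pb - pa < 1e-6) {
      stop("truncation bounds leave no probability mass for ",
           ref$parameter[j], call. = FALSE)
    }
    # inverse-CDF sampling of the truncated distribution; by default the
    # uniforms are Latin-hypercube stratified per parameter (independent
    # random permutations keep the joint distribution independent), which
    # trims the Monte Carlo error of population summaries at no cost
    u <- if (stratified) (sample.int(n) - 1 + runif(n)) / n else runif(n)
    out[, j] <- stats::qlnorm(pa + u * (pb - pa), par$mu, par$sigma)
  }
  out
}

trunc_lnorm_moment <- function(k, mu, sigma, a, b) {
  za <- (log(a) - mu) / sigma
  zb <- (log(b) - mu) / sigma
  denom <- stats::pnorm(zb) - stats::pnorm(za)
  exp(k * mu + k^2 * sigma^2 / 2) *
    (stats::pnorm(zb - k * sigma) - stats::pnorm(za - k * sigma)) / denom
}

# Find (mu, sigma) of a lognormal such that, truncated to [a, b], it has
# mean m and SD s. Starts from the untruncated moment match.
calibrate_trunc_lnorm <- function(m, s, a, b) {
  sigma0 <- sqrt(log(1 + (s / m)^2))
  mu0 <- log(m) - sigma0^2 / 2
  obj <- function(theta) {
    mu <- theta[1]; sigma <- exp(theta[2])
    m1 <- trunc_lnorm_moment(1, mu, sigma, a, b)
    m2 <- trunc_lnorm_moment(2, mu, sigma, a, b)
    v <- m2 - m1^2
    if (!is.finite(m1) || !is.finite(v) || v <= 0) return(1e10)
    (m1 / m - 1)^2 + (sqrt(v) / s - 1)^2
  }
  fit <- optim(c(mu0, log(sigma0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-8) {
    # truncation too tight to reproduce the target moments exactly;
    # fall back to the untruncated match
    return(list(mu = mu0, sigma = sigma0))
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}
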