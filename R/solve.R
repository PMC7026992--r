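# Structural model: amounts A1 (central), A2 (peripheral), A3 (ELF).
#   dA1/dt = R(t) - (CL/V + K12 + K13) A1 + K21 A2 + K31 A3
#   dA2/dt = K12 A1 - K21 A2
#   dA3/dt = K13 A1 - K31 A3
# c_plasma = A1/V (total), c_elf = A3/V_ELF.

rate_matrix <- function(p) {
  matrix(c(-(p[["CL"]] / p[["V"]] + p[["K12"]] + p[["K13"]]),
           p[["K21"]], p[["K31"]],
           p[["K12"]], -p[["K21"]], 0,
           p[["K13"]], 0, -p[["K31"]]),
         nrow = 3, byrow = TRUE)
}

#' Solve plasma and ELF concentration-time profiles
#'
#' Solves the three-compartment linear model (zero-order infusion input into
#' the central compartment, first-order clearance, first-order exchange with
#' a peripheral and an ELF compartment) for an arbitrary infusion schedule,
#' starting drug-naive (all amounts zero at `t = 0`).
#'
#' `method = "analytic"` uses the exact closed-form solution per constant-rate
#' segment via the eigendecomposition of the (constant) rate matrix; it falls
#' back to adaptive numerical integration when the eigensystem is
#' near-degenerate or ill-conditioned. `method = "ode"` forces numerical
#' integration (deSolve, relative tolerance 1e-10), integrating segment by
#' segment so that rate discontinuities are handled exactly; it serves as an
#' independent check of the analytic path.
#'
#' @param params a [structural_params()] vector (or coercible).
#' @param schedule an [infusion_schedule()].
#' @param times strictly increasing evaluation grid, h, within
#'   `[0, horizon]`.
#' @param method `"analytic"` (default) or `"ode"`.
#' @return An object of class `concentration_profile`: list with `times`,
#'   `c_plasma` (mg/L), `c_elf` (mg/L), and the amount matrix `amounts`
#'   (mg, one row per time).
#' @examples
#' prof <- solve_profile(reference_medians(),
#'                       regimen_preset("2g_ld_2g_q8h_ci"),
#'                       times = seq(0, 72, by = 0.5))
#' @export
solve_profile <- function(params, schedule, times,
                          method = c("analytic", "ode")) {
  method <- match.arg(method)
  p <- as_structural_params(params)
  stopifnot(inherits(schedule, "infusion_schedule"))
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  segs <- rate_segments(schedule, tmax = max(times))
  amounts <- if (method == "analytic") {
    solve_amounts_analytic(p, segs, times)
  } else {
    solve_amounts_ode(p, segs, times)
  }
  if (is.null(amounts)) amounts <- solve_amounts_ode(p, segs, times)
  # clamp roundoff-negative amounts
  amounts[amounts < 0 & amounts > -1e-6] <- 0
  new_profile(times, amounts, p)
}

new_profile <- function(times, amounts, p) {
  structure(list(times = times,
                 c_plasma = amounts[, 1] / p[["V"]],
                 c_elf = amounts[, 3] / p[["V_ELF"]],
                 amounts = amounts,
                 params = p),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat("<concentration_profile> ", length(x$times), " time points over [",
      min(x$times), ", ", max(x$times), "] h\n", sep = "")
  cat("  c_plasma range: ", signif(min(x$c_plasma), 4), " - ",
      signif(max(x$c_plasma), 4), " mg/L\n", sep = "")
  cat("  c_elf    range: ", signif(min(x$c_elf), 4), " - ",
      signif(max(x$c_elf), 4), " mg/L\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(time_h = x$times, c_plasma_mg_L = x$c_plasma,
             c_elf_mg_L = x$c_elf)
}

# Closed-form per-segment solution. Returns NULL if the eigensystem is
# unusable (degenerate/ill-conditioned), signalling the ode fallback.
solve_amounts_analytic <- function(p, segs, times) {
  M <- rate_matrix(p)
  eg <- eigen(M)
  lam <- eg$values
  P <- eg$vectors
  # degenerate eigenvalues or singular M (e.g. CL = 0) -> fallback
  scale <- max(Mod(lam))
  if (scale == 0) return(NULL)
  dmin <- min(abs(outer(lam, lam, "-")[lower.tri(diag(3))]))
  # near-zero eigenvalues (negligible clearance) make -M^{-1} b cancel
  # catastrophically; hand those to the numeric integrator
  if (dmin / scale < 1e-7 || min(Mod(lam)) / scale < 1e-8) return(NULL)
  Pinv <- tryCatch(solve(P), error = function(e) NULL)
  pcond <- tryCatch(rcond(P), error = function(e) 1)
  if (is.null(Pinv) || pcond < 1e-10) return(NULL)
  minv_e1 <- tryCatch(solve(M, c(1, 0, 0)), error = function(e) NULL)
  if (is.null(minv_e1)) return(NULL)

  A0 <- c(0, 0, 0)
  out <- matrix(NA_real_, nrow = length(times), ncol = 3)
  if (times[1] == 0) out[1, ] <- 0
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$t0[i]; t1 <- segs$t1[i]; r <- segs$rate[i]
    Ap <- -r * minv_e1                      # particular (steady-forcing) state
    cvec <- Pinv %*% (A0 - Ap)
    last <- i == nrow(segs)
    idx <- which(times > t0 & (times < t1 | (times == t1 & !last) |
                                 (last & times <= t1 + 1e-12)))
    if (length(idx)) {
      tau <- times[idx] - t0
      E <- exp(outer(tau, lam))             # n x 3, possibly complex
      Ec <- E * matrix(cvec, nrow = length(tau), ncol = 3, byrow = TRUE)
      out[idx, ] <- Re(Ec %*% t(P)) +
        matrix(Re(Ap), nrow = length(tau), ncol = 3, byrow = TRUE)
    }
    A0 <- Re(P %*% (cvec * exp(lam * (t1 - t0)))) + Re(Ap)
    A0 <- as.numeric(A0)
  }
  # times exactly at interior breakpoints were computed in the segment they
  # terminate; any time beyond the last breakpoint keeps the final state
  beyond <- which(times > segs$t1[nrow(segs)] + 1e-12)
  for (j in beyond) out[j, ] <- A0
  out
}

solve_amounts_ode <- function(p, segs, times) {
  M <- rate_matrix(p)
  deriv <- function(t, A, parms) list(M %*% A + c(parms$r, 0, 0))
  A0 <- c(0, 0, 0)
  out <- matrix(NA_real_, nrow = length(times), ncol = 3)
  if (times[1] == 0) out[1, ] <- 0
  for (i in seq_len(nrow(segs))) {
    t0 <- segs$t0[i]; t1 <- segs$t1[i]; r <- segs$rate[i]
    last <- i == nrow(segs)
    idx <- which(times > t0 & (times < t1 | (times == t1 & !last) |
                                 (last & times <= t1 + 1e-12)))
    tt <- sort(unique(c(t0, times[idx], t1)))
    sol <- deSolve::lsoda(y = A0, times = tt, func = deriv,
                          parms = list(r = r), rtol = 1e-10, atol = 1e-10)
    if (length(idx)) {
      out[idx, ] <- sol[match(times[idx], sol[, 1]), 2:4, drop = FALSE]
    }
    A0 <- as.numeric(sol[nrow(sol), 2:4])
  }
  beyond <- which(times > segs$t1[nrow(segs)] + 1e-12)
  for (j in beyond) out[j, ] <- A0
  out
}

#' Steady-state concentrations under a constant infusion rate
#'
#' Closed-form limit of the model under continuous infusion: the plasma
#' steady state is `rate / CL`, and the ELF steady state follows from the
#' flux balance `A3 * K31 = A1 * K13`, giving
#' `css_elf = css_plasma * (V * K13) / (K31 * V_ELF)`.
#'
#' @param params a [structural_params()] vector (or coercible).
#' @param rate constant infusion rate, mg/h (>= 0).
#' @return Named numeric vector `c(css_plasma, css_elf)` in mg/L.
#' @examples
#' steady_state(reference_medians(), rate = 250)
#' @export
steady_state <- function(params, rate) {
  p <- as_structural_params(params)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  css_p <- rate / p[["CL"]]
  css_e <- css_p * (p[["V"]] * p[["K13"]]) / (p[["K31"]] * p[["V_ELF"]])
  c(css_plasma = unname(css_p), css_elf = unname(css_e))
}

#' Model-implied steady-state ELF/plasma penetration ratio
#'
#' Under continuous infusion the ELF:plasma concentration (and AUC) ratio at
#' steady state is the closed form `(V * K13) / (K31 * V_ELF)`, independent
#' of the infusion rate.
#'
#' @param params a [structural_params()] vector (or coercible).
#' @return Penetration ratio in percent.
#' @examples
#' steady_state_penetration(reference_medians())  # ~37.8%
#' @export
steady_state_penetration <- function(params) {
  p <- as_structural_params(params)
  100 * (p[["V"]] * p[["K13"]]) / (p[["K31"]] * p[["V_ELF"]])
}
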