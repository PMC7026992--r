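#' Residual error model
#'
#' Observations are weighted by the inverse of the estimated assay variance.
#' Each analyte has a linear assay-SD polynomial `sd(c) = c0 + c1 * c`
#' (evaluated at the model prediction), and process noise beyond the assay is
#' modeled by `gamma`, a multiplicative inflation of the assay SD, so the
#' residual SD of an observation is `gamma * sd_assay(pred)`.
#'
#' @param plasma,elf length-2 numeric `c(intercept, proportional)` SD
#'   polynomials for the plasma and ELF analytes, mg/L. Defaults are
#'   `LOQ/2 + 0.15 c` anchored to the assays' reported <= 15% precision
#'   (plasma LOQ 0.5 mg/L; ELF values derive from the BAL assay, LOQ
#'   0.03 mg/L).
#' @param gamma multiplicative process-noise scalar, >= 1 at initialization.
#' @return An object of class `error_model`.
#' @examples
#' error_model()
#' @export
error_model <- function(plasma = c(0.25, 0.15), elf = c(0.015, 0.15),
                        gamma = 1) {
  stopifnot(length(plasma) == 2L, length(elf) == 2L,
            plasma[1] > 0, elf[1] > 0, plasma[2] >= 0, elf[2] >= 0,
            gamma >= 1)
  structure(list(plasma = plasma, elf = elf, gamma = gamma),
            class = "error_model")
}

# Assay SD at (predicted) concentration c for a given analyte, without gamma.
assay_sd <- function(error, analyte, conc) {
  coefs <- switch(analyte,
                  plasma = error$plasma,
                  elf = error$elf,
                  stop("unknown analyte '", analyte, "'", call. = FALSE))
  pmax(coefs[1] + coefs[2] * pmax(conc, 0), 1e-6)
}

# Vectorized over a data frame of observations with columns analyte + pred.
assay_sd_obs <- function(error, analyte, conc) {
  out <- numeric(length(conc))
  for (a in unique(analyte)) {
    idx <- analyte == a
    out[idx] <- assay_sd(error, a, conc[idx])
  }
  out
}
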