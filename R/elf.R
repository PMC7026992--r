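#' Assay specification
#'
#' Describes one bioanalytical assay: its limit of quantification (LOQ),
#' linear range, and a linear error-SD polynomial
#' `sd(c) = intercept + proportional * c` used to weight observations in the
#' population fit.
#'
#' Packaged defaults (see [default_assays()]) reflect a validated HPLC assay
#' for meropenem with LOQ 0.5 mg/L in plasma and 0.03 mg/L in BAL fluid, and
#' an enzymatic urea assay with LOQ 3 mg/dL in serum and 0.078 mg/dL in BAL.
#' The SD polynomial defaults to `LOQ/2 + 0.15 * c`, anchoring the
#' proportional term to the assay's reported <= 15% precision.
#'
#' @param analyte analyte label, e.g. `"plasma"`.
#' @param loq limit of quantification (assay units).
#' @param range linear range, length-2 numeric.
#' @param sd_intercept,sd_proportional error-SD polynomial coefficients.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(analyte, loq, range = c(loq, Inf),
                       sd_intercept = loq / 2, sd_proportional = 0.15) {
  stopifnot(loq > 0, sd_proportional >= 0)
  structure(list(analyte = analyte, loq = loq, range = range,
                 sd_intercept = sd_intercept,
                 sd_proportional = sd_proportional),
            class = "assay_spec")
}

#' @rdname assay_spec
#' @return `default_assays()`: named list of the four packaged assay specs
#'   (`plasma`, `bal`, `urea_serum`, `urea_bal`).
#' @export
default_assays <- function() {
  list(
    plasma     = assay_spec("plasma", loq = 0.5, range = c(0.5, 80)),
    bal        = assay_spec("bal", loq = 0.03, range = c(0.03, 1)),
    urea_serum = assay_spec("urea_serum", loq = 3),
    urea_bal   = assay_spec("urea_bal", loq = 0.078)
  )
}

#' Flag a measurement below the limit of quantification
#'
#' The boundary is inclusive: a value exactly at the LOQ counts as
#' quantifiable, matching assay-validation convention.
#'
#' @param value measured value(s) (>= 0).
#' @param spec an [assay_spec()].
#' @return A data frame with columns `value` and `bloq` (logical).
#' @examples
#' censor_loq(c(0.4, 0.5), default_assays()$plasma)
#' @export
censor_loq <- function(value, spec) {
  stopifnot(inherits(spec, "assay_spec"))
  if (any(value < 0)) stop("value must be >= 0", call. = FALSE)
  data.frame(value = value, bloq = value < spec$loq)
}

#' Urea-dilution correction of a BAL measurement
#'
#' Bronchoalveolar lavage recovers epithelial lining fluid diluted by an
#' unknown factor of instilled saline. Because urea equilibrates freely
#' between blood and ELF, the serum/BAL urea ratio estimates that dilution,
#' giving the corrected ELF drug concentration
#' `MER_ELF = MER_BAL * Urea_SER / Urea_BAL`.
#'
#' Measurements below the LOQ do not stop the calculation: the corrected
#' value is still returned, but carries a `censored` flag so downstream
#' analyses can exclude or substitute it explicitly.
#'
#' @param mer_bal meropenem concentration in BAL supernatant, mg/L.
#' @param urea_ser serum urea, mg/dL.
#' @param urea_bal BAL urea, mg/dL (> 0).
#' @param assays named list of [assay_spec()]s with elements `bal`,
#'   `urea_serum`, `urea_bal` (default [default_assays()]).
#' @return A data frame with columns `elf_mg_L`, `censored` (TRUE if any
#'   analyte was below its LOQ) and per-analyte `bloq_*` flags. Vectorized
#'   over samples.
#' @examples
#' correct_elf(0.5, 40, 1.0)  # 20 mg/L
#' @export
correct_elf <- function(mer_bal, urea_ser, urea_bal,
                        assays = default_assays()) {
  n <- max(length(mer_bal), length(urea_ser), length(urea_bal))
  mer_bal <- rep_len(mer_bal, n)
  urea_ser <- rep_len(urea_ser, n)
  urea_bal <- rep_len(urea_bal, n)
  if (any(mer_bal < 0) || any(urea_ser < 0)) {
    stop("measured concentrations must be >= 0", call. = FALSE)
  }
  if (any(urea_bal <= 0)) {
    stop("urea_bal must be > 0 for the dilution correction", call. = FALSE)
  }
  bloq_mer <- censor_loq(mer_bal, assays$bal)$bloq
  bloq_ser <- censor_loq(urea_ser, assays$urea_serum)$bloq
  bloq_bal <- censor_loq(urea_bal, assays$urea_bal)$bloq
  data.frame(
    elf_mg_L = mer_bal * urea_ser / urea_bal,
    censored = bloq_mer | bloq_ser | bloq_bal,
    bloq_mer_bal = bloq_mer,
    bloq_urea_ser = bloq_ser,
    bloq_urea_bal = bloq_bal
  )
}

#' Apply the urea-dilution correction to a BAL table
#'
#' @param bal data frame with columns `subject_id`, `mer_bal_mg_L`,
#'   `urea_ser_mg_dL`, `urea_bal_mg_dL` (as written by [generate_trial()] or
#'   read from a BAL CSV).
#' @param assays named list of [assay_spec()]s.
#' @return The input with `elf_mg_L` and censoring-flag columns appended.
#' @export
correct_bal_table <- function(bal, assays = default_assays()) {
  need <- c("subject_id", "mer_bal_mg_L", "urea_ser_mg_dL", "urea_bal_mg_dL")
  miss <- setdiff(need, names(bal))
  if (length(miss)) {
    stop("BAL table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cbind(bal, correct_elf(bal$mer_bal_mg_L, bal$urea_ser_mg_dL,
                         bal$urea_bal_mg_dL, assays = assays))
}
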