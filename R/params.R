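#' Structural pharmacokinetic parameters
#'
#' Constructs and validates the parameter vector of the three-compartment
#' meropenem model: clearance `CL` (L/h) from the central compartment,
#' central volume `V` (L), first-order intercompartmental rate constants
#' `K12`, `K21` (central <-> peripheral, 1/h) and `K13`, `K31`
#' (central <-> ELF, 1/h), and the ELF compartment volume `V_ELF` (L).
#' Compartment 3 is the epithelial lining fluid, so `A3 / V_ELF` is the
#' predicted lung concentration; compartment 2 is a non-observed peripheral
#' distribution space.
#'
#' @param CL clearance, L/h.
#' @param V central volume of distribution, L.
#' @param K12,K21 central <-> peripheral rate constants, 1/h.
#' @param K13,K31 central <-> ELF rate constants, 1/h.
#' @param V_ELF ELF compartment volume, L.
#' @return A named numeric vector of class `structural_params`.
#' @examples
#' p <- structural_params(CL = 11.2, V = 10.1, K12 = 26.7, K21 = 7.6,
#'                        K13 = 18.5, K31 = 25.6, V_ELF = 19.4)
#' @export
structural_params <- function(CL, V, K12, K21, K13, K31, V_ELF) {
  p <- c(CL = CL, V = V, K12 = K12, K21 = K21, K13 = K13, K31 = K31,
         V_ELF = V_ELF)
  validate_params(p)
  class(p) <- "structural_params"
  p
}

#' @rdname structural_params
#' @param x object to coerce: a named numeric vector, single-row data frame,
#'   or list with the seven parameter names.
#' @export
as_structural_params <- function(x) {
  if (inherits(x, "structural_params")) return(x)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(x[param_names()])
  }
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) && length(x) == 7L) names(x) <- param_names()
  p <- as.numeric(x[param_names()])
  names(p) <- param_names()
  validate_params(p)
  class(p) <- "structural_params"
  p
}

param_names <- function() c("CL", "V", "K12", "K21", "K13", "K31", "V_ELF")

validate_params <- function(p) {
  if (anyNA(p) || any(!is.finite(p)) || any(p <= 0)) {
    stop("invalid parameters: all of ", paste(param_names(), collapse = ", "),
         " must be strictly positive and finite", call. = FALSE)
  }
  invisible(p)
}

#' Published population parameter reference set
#'
#' Returns the packaged population summary of the meropenem
#' continuous-infusion model: median, mean, standard deviation and 95%
#' credibility limits for each structural parameter, as estimated in a
#' 31-patient nosocomial-pneumonia study (two arms, 1 g/8 h and 2 g/8 h by
#' continuous infusion). These values parameterize the default Monte Carlo
#' samplers and the synthetic-trial generator. An internal checksum guards
#' against accidental edits of the packaged table.
#'
#' @return A data frame with columns `parameter`, `unit`, `median`, `mean`,
#'   `sd`, `ci95_lower`, `ci95_upper`.
#' @examples
#' reference_parameters()
#' @export
reference_parameters <- function() {
  ref <- data.frame(
    parameter  = param_names(),
    unit       = c("L/h", "L", "1/h", "1/h", "1/h", "1/h", "L"),
    median     = c(11.219, 10.143, 26.696, 7.601, 18.539, 25.614, 19.424),
    mean       = c(12.464, 12.500, 22.987, 11.721, 17.317, 24.451, 25.319),
    sd         = c(5.570, 6.929, 8.072, 9.730, 5.611, 5.892, 10.735),
    ci95_lower = c(8.539, 8.385, 23.706, 3.853, 13.124, 23.575, 19.321),
    ci95_upper = c(15.589, 17.194, 27.897, 21.014, 21.815, 28.602, 28.525),
    stringsAsFactors = FALSE
  )
  checksum <- sum(ref$median) + sum(ref$mean) + sum(ref$sd) +
    sum(ref$ci95_lower) + sum(ref$ci95_upper)
  if (abs(checksum - 559.673) > 1e-9) {
    stop("reference parameter table failed its checksum", call. = FALSE)
  }
  ref
}

#' Median reference parameter vector
#'
#' Convenience accessor: the population medians of [reference_parameters()]
#' as a `structural_params` vector.
#'
#' @return A `structural_params` vector.
#' @export
reference_medians <- function() {
  ref <- reference_parameters()
  as_structural_params(setNames(ref$median, ref$parameter))
}
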