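# CSV interchange schemas:
#   observations: subject_id, time_h, analyte {plasma, elf}, value_mg_L,
#                 bloq {0, 1}
#   dosing:       subject_id, start_h, duration_h, amount_mg
#   BAL:          subject_id, mer_bal_mg_L, urea_ser_mg_dL, urea_bal_mg_dL

read_validated_csv <- function(path, need, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(need, c("analyte", "subject_id"))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop(what, " file ", path, ": non-numeric value in column '", col,
           "', row ", bad[1], call. = FALSE)
    }
  }
  df
}

#' Read observation, dosing and BAL tables
#'
#' Column-validated CSV readers for the package's interchange formats.
#' `read_observations()` expects `subject_id, time_h, analyte, value_mg_L`
#' (optional `bloq`); `read_dosing()` expects
#' `subject_id, start_h, duration_h, amount_mg`; `read_bal()` expects
#' `subject_id, mer_bal_mg_L, urea_ser_mg_dL, urea_bal_mg_dL`.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_observations <- function(path) {
  df <- read_validated_csv(path, c("subject_id", "time_h", "analyte",
                                   "value_mg_L"), "observation")
  if (!"bloq" %in% names(df)) df$bloq <- 0L
  bad <- which(!df$analyte %in% c("plasma", "elf"))
  if (length(bad)) {
    stop("observation file ", path, ": unknown analyte '",
         df$analyte[bad[1]], "' in row ", bad[1], call. = FALSE)
  }
  df
}

#' @rdname read_observations
#' @export
read_dosing <- function(path) {
  read_validated_csv(path, c("subject_id", "start_h", "duration_h",
                             "amount_mg"), "dosing")
}

#' @rdname read_observations
#' @export
read_bal <- function(path) {
  read_validated_csv(path, c("subject_id", "mer_bal_mg_L",
                             "urea_ser_mg_dL", "urea_bal_mg_dL"), "BAL")
}

#' Serialize a fitted population model to JSON
#'
#' Writes support points, weights, gamma, log-likelihood and the error
#' model; [read_fit_json()] restores a `pop_model` usable by the samplers
#' and diagnostics.
#'
#' @param model a `pop_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(model, path) {
  payload <- list(
    support = model$support, weights = model$weights, gamma = model$gamma,
    loglik = model$loglik, cycles = model$cycles,
    converged = model$converged,
    error = list(plasma = model$error$plasma, elf = model$error$elf,
                 gamma = model$error$gamma),
    n_subjects = model$n_subjects, n_obs = model$n_obs,
    package_version = as.character(utils::packageVersion("merelf"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(support = as.data.frame(x$support), weights = x$weights,
                 gamma = x$gamma, loglik = x$loglik, cycles = x$cycles,
                 converged = x$converged,
                 error = error_model(plasma = x$error$plasma,
                                     elf = x$error$elf,
                                     gamma = max(1, x$error$gamma)),
                 n_subjects = x$n_subjects, n_obs = x$n_obs),
            class = "pop_model")
}
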