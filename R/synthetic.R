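#' Synthetic trial design
#'
#' Describes a virtual two-arm continuous-infusion study mirroring the
#' sampling layout of the clinical trial the model derives from: 16 + 15
#' subjects randomized to 1 g/8 h or 2 g/8 h maintenance infusions after a
#' 2 g/15-min loading dose; five plasma samples on day 3 (pre-infusion,
#' then 1.5, 3, 6 and 8 h after the day-3 infusion start, i.e. 48, 49.5,
#' 51, 54 and 56 h after treatment start, the pre-infusion sample being the
#' 48-h trough) and one ELF sample at 6 h (54 h) obtained by BAL with an
#' unknown dilution.
#'
#' The BAL dilution factor is drawn log-uniformly on `dilution_range`
#' (BAL dilutes ELF by one to two orders of magnitude); serum urea is drawn
#' log-normally with the given median and CV. Meropenem analytes carry
#' multiplicative log-normal assay noise with SD `assay_cv`; urea analytes
#' use `urea_cv` (default 0: enzymatic urea assays are much more precise
#' than HPLC and would otherwise dominate the corrected-ELF error budget).
#'
#' @param n_per_arm subjects per arm, length 2.
#' @param regimens length-2 list of regimens (schedules or preset names).
#' @param plasma_times_h plasma sampling times, h after treatment start.
#' @param elf_time_h ELF sampling time, h.
#' @param assay_cv multiplicative assay noise SD (log scale) for meropenem.
#' @param urea_cv same for the urea analytes.
#' @param dilution_range BAL dilution-factor range (log-uniform draw).
#' @param urea_ser_median,urea_ser_cv serum urea distribution, mg/dL.
#' @param assays named list of [assay_spec()]s for LOQ censoring.
#' @param horizon_h simulated horizon, h.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = c(16, 15),
                         regimens = list("2g_ld_1g_q8h_ci",
                                         "2g_ld_2g_q8h_ci"),
                         plasma_times_h = c(48, 49.5, 51, 54, 56),
                         elf_time_h = 54,
                         assay_cv = 0.15, urea_cv = 0,
                         dilution_range = c(10, 100),
                         urea_ser_median = 40, urea_ser_cv = 0.4,
                         assays = default_assays(), horizon_h = 72) {
  stopifnot(length(n_per_arm) == 2L, all(n_per_arm >= 1),
            length(regimens) == 2L, assay_cv >= 0, urea_cv >= 0,
            dilution_range[1] >= 1, dilution_range[2] >= dilution_range[1],
            max(plasma_times_h, elf_time_h) <= horizon_h)
  structure(list(n_per_arm = n_per_arm, regimens = regimens,
                 plasma_times_h = plasma_times_h, elf_time_h = elf_time_h,
                 assay_cv = assay_cv, urea_cv = urea_cv,
                 dilution_range = dilution_range,
                 urea_ser_median = urea_ser_median,
                 urea_ser_cv = urea_ser_cv, assays = assays,
                 horizon_h = horizon_h),
            class = "trial_design")
}

#' Generate a synthetic trial dataset
#'
#' For each virtual subject: draw true structural parameters from the
#' sampler, solve the profile under the arm's regimen, read plasma
#' concentrations at the design's sampling times and the true ELF
#' concentration at the BAL time; draw a BAL dilution factor `D` and serum
#' urea, emit `mer_bal = ELF/D` and `urea_bal = urea_ser/D`; apply
#' multiplicative log-normal assay noise per analyte and LOQ censoring.
#' The observation table contains the plasma rows and one ELF row per
#' subject whose value is the urea-corrected BAL measurement, ready for
#' [npag_fit()].
#'
#' @param design a [trial_design()].
#' @param sampler a [population_sampler()] for the true parameters.
#' @param seed RNG seed; a fixed seed reproduces the dataset exactly.
#' @return An object of class `synthetic_trial`: list with data frames
#'   `truth` (true parameters per subject), `dosing`, `observations`,
#'   `bal`, and the `design`.
#' @examples
#' \donttest{
#' trial <- generate_trial(trial_design(), population_sampler(), seed = 1)
#' }
#' @export
generate_trial <- function(design, sampler = population_sampler(),
                           seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  with_seed(seed, {
    n_total <- sum(design$n_per_arm)
    arm <- rep(1:2, design$n_per_arm)
    pars <- sample_population(sampler, n_total)
    scheds <- lapply(design$regimens, as_regimen,
                     horizon_h = design$horizon_h)

    mnoise <- function(x, cv) {
      if (cv <= 0) return(x)
      x * exp(rnorm(length(x), 0, cv))
    }

    truth <- data.frame(subject_id = seq_len(n_total), arm = arm, pars)
    dosing <- do.call(rbind, lapply(seq_len(n_total), function(i) {
      ev <- scheds[[arm[i]]]$events
      data.frame(subject_id = i, ev)
    }))

    obs_rows <- list(); bal_rows <- list()
    for (i in seq_len(n_total)) {
      prof <- solve_profile(as_structural_params(pars[i, ]), scheds[[arm[i]]],
                            sort(unique(c(design$plasma_times_h,
                                          design$elf_time_h))))
      cp <- stats::approx(prof$times, prof$c_plasma,
                          xout = design$plasma_times_h)$y
      ce <- stats::approx(prof$times, prof$c_elf,
                          xout = design$elf_time_h)$y

      cp_obs <- mnoise(cp, design$assay_cv)
      pl <- censor_loq(cp_obs, design$assays$plasma)
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        subject_id = i, time_h = design$plasma_times_h, analyte = "plasma",
        value_mg_L = pl$value, bloq = as.integer(pl$bloq))

      # BAL triple: ELF diluted by D, urea serum diluted identically
      D <- exp(runif(1, log(design$dilution_range[1]),
                     log(design$dilution_range[2])))
      urea_ser_true <- stats::rlnorm(1, log(design$urea_ser_median),
                                     sqrt(log(1 + design$urea_ser_cv^2)))
      mer_bal <- mnoise(ce / D, design$assay_cv)
      urea_ser <- mnoise(urea_ser_true, design$urea_cv)
      urea_bal <- mnoise(urea_ser_true / D, design$urea_cv)
      corr <- correct_elf(mer_bal, urea_ser, urea_bal,
                          assays = design$assays)
      bal_rows[[length(bal_rows) + 1L]] <- data.frame(
        subject_id = i, mer_bal_mg_L = mer_bal,
        urea_ser_mg_dL = urea_ser, urea_bal_mg_dL = urea_bal,
        dilution_true = D, elf_true_mg_L = ce)
      obs_rows[[length(obs_rows) + 1L]] <- data.frame(
        subject_id = i, time_h = design$elf_time_h, analyte = "elf",
        value_mg_L = corr$elf_mg_L, bloq = as.integer(corr$censored))
    }

    structure(list(truth = truth,
                   dosing = dosing,
                   observations = do.call(rbind, obs_rows),
                   bal = do.call(rbind, bal_rows),
                   design = design),
              class = "synthetic_trial")
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial> ", nrow(x$truth), " subjects (",
      paste(x$design$n_per_arm, collapse = " + "), "), ",
      nrow(x$observations), " observations (",
      sum(x$observations$analyte == "plasma"), " plasma, ",
      sum(x$observations$analyte == "elf"), " ELF)\n", sep = "")
  invisible(x)
}

#' Write a synthetic trial to CSV files
#'
#' Writes `dosing.csv`, `obs.csv`, `bal.csv`, `truth.csv` and `design.json`
#' into `dir`. Existing files are not overwritten unless `overwrite = TRUE`.
#'
#' @param trial a `synthetic_trial`.
#' @param dir output directory (created if missing).
#' @param overwrite allow overwriting existing files?
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir, overwrite = FALSE) {
  stopifnot(inherits(trial, "synthetic_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(dosing = "dosing.csv", observations = "obs.csv",
             bal = "bal.csv", truth = "truth.csv")
  for (nm in names(files)) {
    path <- file.path(dir, files[[nm]])
    if (file.exists(path) && !overwrite) {
      stop("refusing to overwrite ", path, call. = FALSE)
    }
    write.csv(trial[[nm]], path, row.names = FALSE)
  }
  dj <- trial$design
  dj$assays <- lapply(dj$assays, unclass)
  dj$regimens <- lapply(dj$regimens, function(r) {
    if (inherits(r, "infusion_schedule")) unclass(r) else r
  })
  jsonlite::write_json(unclass(dj), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
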