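#' Infusion schedules
#'
#' An infusion schedule is an ordered set of zero-order infusion events,
#' each defined by a start time (h), a duration (h) and an amount (mg).
#' Overlapping events are allowed; their rates add. Back-to-back events with
#' equal rates are equivalent to one continuous infusion.
#'
#' @param start_h numeric vector of event start times, h.
#' @param duration_h numeric vector of event durations, h (> 0).
#' @param amount_mg numeric vector of infused amounts, mg (>= 0).
#' @param horizon_h total simulated horizon, h; defaults to the end of the
#'   last event.
#' @return An object of class `infusion_schedule`: a list with a data frame
#'   `events` (sorted by start time) and scalar `horizon`.
#' @examples
#' # 2 g loading dose over 15 min, then 1 g over 8 h every 8 h for 72 h
#' sched <- infusion_schedule(
#'   start_h    = c(0, 0.25 + 8 * 0:8),
#'   duration_h = c(0.25, rep(8, 9)),
#'   amount_mg  = c(2000, rep(1000, 9))
#' )
#' infusion_rate(sched, c(0.1, 4))
#' @export
infusion_schedule <- function(start_h, duration_h, amount_mg,
                              horizon_h = NULL) {
  n <- length(start_h)
  if (length(duration_h) != n || length(amount_mg) != n) {
    stop("start_h, duration_h and amount_mg must have equal length",
         call. = FALSE)
  }
  if (n == 0L) {
    events <- data.frame(start_h = numeric(), duration_h = numeric(),
                         amount_mg = numeric())
    horizon <- if (is.null(horizon_h)) 0 else horizon_h
  } else {
    if (any(!is.finite(start_h)) || any(start_h < 0)) {
      stop("event start times must be finite and >= 0", call. = FALSE)
    }
    if (any(!is.finite(duration_h)) || any(duration_h <= 0)) {
      stop("event durations must be finite and > 0", call. = FALSE)
    }
    if (any(!is.finite(amount_mg)) || any(amount_mg < 0)) {
      stop("event amounts must be finite and >= 0", call. = FALSE)
    }
    ord <- order(start_h, duration_h)
    events <- data.frame(start_h = start_h[ord], duration_h = duration_h[ord],
                         amount_mg = amount_mg[ord])
    horizon <- if (is.null(horizon_h)) max(events$start_h + events$duration_h)
               else horizon_h
  }
  structure(list(events = events, horizon = horizon),
            class = "infusion_schedule")
}

#' @export
print.infusion_schedule <- function(x, ...) {
  cat("<infusion_schedule> ", nrow(x$events), " event(s), horizon ",
      x$horizon, " h\n", sep = "")
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}

#' Instantaneous infusion rate
#'
#' Piecewise-constant input rate implied by a schedule: the sum of
#' `amount/duration` over all events whose half-open window
#' `[start, start + duration)` contains `t`.
#'
#' @param schedule an [infusion_schedule()].
#' @param t time(s), h (>= 0); vectorized.
#' @return Rate(s) in mg/h.
#' @export
infusion_rate <- function(schedule, t) {
  stopifnot(inherits(schedule, "infusion_schedule"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  ev <- schedule$events
  if (nrow(ev) == 0L) return(numeric(length(t)))
  vapply(t, function(ti) {
    active <- ti >= ev$start_h & ti < ev$start_h + ev$duration_h
    sum(ev$amount_mg[active] / ev$duration_h[active])
  }, numeric(1))
}

# Segment table: breakpoints and constant rate per segment covering
# [0, max(horizon, tmax)]. Rates are evaluated on half-open segments.
rate_segments <- function(schedule, tmax = NULL) {
  ev <- schedule$events
  end <- max(schedule$horizon, tmax, 0)
  brk <- sort(unique(c(0, ev$start_h, ev$start_h + ev$duration_h, end)))
  brk <- brk[brk <= end + 1e-12]
  if (length(brk) < 2L) brk <- c(0, max(end, 1))
  mids <- (brk[-length(brk)] + brk[-1]) / 2
  data.frame(t0 = brk[-length(brk)], t1 = brk[-1],
             rate = infusion_rate(schedule, mids))
}

#' Packaged dosing-regimen presets
#'
#' Named presets for the regimens examined in the continuous-infusion (CI)
#' meropenem study and its dose-exploration simulations. Loading-dose (LD)
#' regimens give 2 or 3 g over 15 min, immediately followed by contiguous
#' 8-h maintenance infusions; extended-infusion (EI) presets infuse the dose
#' over the first 4 h of every 8-h interval; plain CI presets infuse the
#' dose over the full interval with no loading dose.
#'
#' @param name one of `"2g_ld_1g_q8h_ci"`, `"2g_ld_2g_q8h_ci"`,
#'   `"3g_ld_3g_q8h_ci"`, `"1g_q8h_ci"`, `"2g_q8h_ci"`, `"4g_q8h_ci"`,
#'   `"8g_q8h_ci"`, `"1g_q8h_ei4"`, `"2g_q8h_ei4"`, `"3g_q8h_ei4"`.
#' @param horizon_h simulated horizon, h (default 72; intervals are repeated
#'   to cover it).
#' @return An [infusion_schedule()].
#' @examples
#' regimen_preset("2g_ld_2g_q8h_ci")
#' @export
regimen_preset <- function(name, horizon_h = 72) {
  presets <- regimen_presets()
  if (!name %in% names(presets)) {
    stop("unknown regimen preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]](horizon_h)
}

#' @rdname regimen_preset
#' @export
regimen_preset_names <- function() names(regimen_presets())

regimen_presets <- function() {
  ci_ld <- function(ld_mg, maint_mg) function(horizon_h) {
    k <- seq_len(ceiling((horizon_h - 0.25) / 8)) - 1
    infusion_schedule(
      start_h    = c(0, 0.25 + 8 * k),
      duration_h = c(0.25, rep(8, length(k))),
      amount_mg  = c(ld_mg, rep(maint_mg, length(k)))
    )
  }
  ci <- function(maint_mg) function(horizon_h) {
    k <- seq_len(ceiling(horizon_h / 8)) - 1
    infusion_schedule(start_h = 8 * k, duration_h = rep(8, length(k)),
                      amount_mg = rep(maint_mg, length(k)))
  }
  ei4 <- function(dose_mg) function(horizon_h) {
    k <- seq_len(ceiling(horizon_h / 8)) - 1
    infusion_schedule(start_h = 8 * k, duration_h = rep(4, length(k)),
                      amount_mg = rep(dose_mg, length(k)),
                      horizon_h = 8 * length(k))
  }
  list(
    "2g_ld_1g_q8h_ci" = ci_ld(2000, 1000),
    "2g_ld_2g_q8h_ci" = ci_ld(2000, 2000),
    "3g_ld_3g_q8h_ci" = ci_ld(3000, 3000),
    "1g_q8h_ci" = ci(1000),
    "2g_q8h_ci" = ci(2000),
    "4g_q8h_ci" = ci(4000),
    "8g_q8h_ci" = ci(8000),
    "1g_q8h_ei4" = ei4(1000),
    "2g_q8h_ei4" = ei4(2000),
    "3g_q8h_ei4" = ei4(3000)
  )
}

#' Read a regimen from a CSV file
#'
#' The file must have columns `start_h`, `duration_h`, `amount_mg`
#' (one row per infusion event).
#'
#' @param path CSV file path.
#' @param horizon_h optional horizon override, h.
#' @return An [infusion_schedule()].
#' @export
read_regimen <- function(path, horizon_h = NULL) {
  df <- read.csv(path)
  need <- c("start_h", "duration_h", "amount_mg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("regimen file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  infusion_schedule(df$start_h, df$duration_h, df$amount_mg,
                    horizon_h = horizon_h)
}
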