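#' Trapezoidal area under the curve
#'
#' Standard linear trapezoid over a concentration-time grid.
#'
#' @param values concentrations, mg/L.
#' @param times increasing time grid, h, same length as `values`.
#' @return AUC in mg*h/L.
#' @examples
#' auc_trapezoid(c(10, 10), c(0, 24))  # 240
#' @export
auc_trapezoid <- function(values, times) {
  if (length(values) != length(times)) {
    stop("values and times must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) return(0)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2)
}

#' Daily-average AUC
#'
#' Normalizes a cumulative AUC to a 24-h exposure: divide by the total time
#' in hours and multiply by 24.
#'
#' @param cumulative_auc cumulative AUC, mg*h/L.
#' @param total_time_h total observation time, h (> 0).
#' @return AUC_0-24 in mg*h/L.
#' @examples
#' daily_average_auc(720, 72)  # 240
#' @export
daily_average_auc <- function(cumulative_auc, total_time_h) {
  if (any(total_time_h <= 0)) stop("total_time_h must be > 0", call. = FALSE)
  cumulative_auc / total_time_h * 24
}

#' ELF/plasma penetration ratio
#'
#' The lung partitioning of a drug expressed as the percentage ratio of the
#' ELF AUC to the plasma AUC over the same window.
#'
#' @param auc_elf ELF AUC, mg*h/L.
#' @param auc_plasma plasma AUC, mg*h/L (> 0).
#' @return Ratio in percent.
#' @examples
#' penetration_ratio(84.1, 287.6)  # ~29.2%
#' @export
penetration_ratio <- function(auc_elf, auc_plasma) {
  if (any(auc_plasma <= 0)) {
    stop("auc_plasma must be > 0 for a defined ratio", call. = FALSE)
  }
  100 * auc_elf / auc_plasma
}

# AUC of a profile restricted to [from, to], interpolating the endpoints.
auc_window <- function(profile, from, to, site = c("plasma", "elf")) {
  site <- match.arg(site)
  vals <- if (site == "plasma") profile$c_plasma else profile$c_elf
  tt <- profile$times
  if (from < min(tt) - 1e-9 || to > max(tt) + 1e-9 || from >= to) {
    stop("AUC window must lie within the profile", call. = FALSE)
  }
  inside <- tt > from & tt < to
  t2 <- c(from, tt[inside], to)
  v2 <- c(stats::approx(tt, vals, xout = from)$y, vals[inside],
          stats::approx(tt, vals, xout = to)$y)
  auc_trapezoid(v2, t2)
}
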