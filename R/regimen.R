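#' Construct and validate a dosing regimen
#'
#' A regimen is a drug, a dose (mg per administration), a dosing interval
#' tau (h), an infusion duration (h) and an administration mode. Continuous
#' infusions are represented over a 24 h reference window with
#' `interval_h = infusion_h = 24` and `dose_mg` equal to the total daily
#' dose. Units are fixed throughout the package: hours, mg, L, mg/L.
#'
#' @param drug Drug name.
#' @param dose_mg Dose per administration, mg (> 0).
#' @param interval_h Dosing interval tau, h (> 0).
#' @param infusion_h Infusion duration, h (0 < infusion_h <= interval_h).
#' @param mode One of "intermittent", "extended", "continuous"; if `NULL`
#'   it is classified from the infusion duration (see
#'   [classify_infusion_mode()]).
#' @return A list of class `"regimen"`.
#' @export
#' @examples
#' regimen("cefepime", 2000, 8, 0.5)
regimen <- function(drug, dose_mg, interval_h, infusion_h, mode = NULL) {
  stopifnot(length(drug) == 1L, is.numeric(dose_mg), is.numeric(interval_h),
            is.numeric(infusion_h))
  if (dose_mg <= 0) stop("dose must be > 0", call. = FALSE)
  if (interval_h <= 0) stop("dosing interval must be > 0", call. = FALSE)
  if (infusion_h <= 0 || infusion_h > interval_h) {
    stop("infusion duration must satisfy 0 < infusion_h <= interval_h",
         call. = FALSE)
  }
  if (is.null(mode)) {
    mode <- classify_infusion_mode(infusion_h, interval_h)
  }
  mode <- match.arg(mode, c("intermittent", "extended", "continuous"))
  if (mode == "continuous" && infusion_h != interval_h) {
    stop("continuous mode requires infusion_h == interval_h (24 h window)",
         call. = FALSE)
  }
  structure(list(drug = drug, dose_mg = dose_mg, interval_h = interval_h,
                 infusion_h = infusion_h, mode = mode),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s %g mg q%gh, %g h infusion (%s)\n",
              x$drug, x$dose_mg, x$interval_h, x$infusion_h, x$mode))
  invisible(x)
}

#' Classify an infusion as intermittent, extended or continuous
#'
#' Intermittent when the infusion runs no longer than the cut (default 1 h,
#' the typical short 30-min infusion falls here), extended when longer but
#' shorter than the dosing interval, continuous when it spans the interval.
#' The 1 h cut is a convention, hence configurable.
#'
#' @param infusion_h,interval_h Infusion duration and dosing interval, h.
#' @param intermittent_cut_h Longest infusion still called intermittent.
#' @return Character vector of modes.
#' @export
classify_infusion_mode <- function(infusion_h, interval_h,
                                   intermittent_cut_h = 1) {
  ifelse(infusion_h >= interval_h, "continuous",
         ifelse(infusion_h <= intermittent_cut_h, "intermittent", "extended"))
}

#' Total daily dose of a regimen, mg/day
#' @param reg A `regimen`, or a data frame with `dose_mg` and `interval_h`.
#' @return Numeric, mg per 24 h.
#' @export
daily_dose <- function(reg) {
  if (inherits(reg, "regimen")) reg$dose_mg * 24 / reg$interval_h
  else reg$dose_mg * 24 / reg$interval_h
}

#' A timed total plasma concentration sample
#'
#' @param time_after_dose_start_h Time since the start of the infusion, h.
#' @param total_conc_mg_L Total plasma concentration, mg/L (> 0).
#' @param kind One of "peak", "trough", "random".
#' @return A list of class `"conc_sample"`.
#' @export
conc_sample <- function(time_after_dose_start_h, total_conc_mg_L,
                        kind = c("peak", "trough", "random")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time_after_dose_start_h), is.numeric(total_conc_mg_L))
  if (total_conc_mg_L <= 0) {
    stop("concentration must be > 0", call. = FALSE)
  }
  structure(list(time_after_dose_start_h = time_after_dose_start_h,
                 total_conc_mg_L = total_conc_mg_L, kind = kind),
            class = "conc_sample")
}
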