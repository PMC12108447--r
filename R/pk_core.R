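#' First-order elimination rate from two elimination-phase samples
#'
#' With both samples drawn after the end of the infusion within the same
#' dosing interval, log-linear decline gives
#' ke = ln(C1/C2) / (t2 - t1), and half-life = ln(2)/ke.
#'
#' @param s1,s2 [conc_sample()] objects (or lists with
#'   `time_after_dose_start_h`, `total_conc_mg_L`), with `s2` later than
#'   `s1`.
#' @return List with `ke_per_h` and `half_life_h`.
#' @export
#' @examples
#' estimate_elimination_rate(conc_sample(2, 40, "peak"),
#'                           conc_sample(8, 10, "trough"))
estimate_elimination_rate <- function(s1, s2) {
  t1 <- s1$time_after_dose_start_h; c1 <- s1$total_conc_mg_L
  t2 <- s2$time_after_dose_start_h; c2 <- s2$total_conc_mg_L
  if (t2 <= t1) {
    stop("second sample must be drawn after the first (t2 > t1)",
         call. = FALSE)
  }
  if (c1 <= c2) {
    stop("no elimination signal: concentrations rising or flat ",
         sprintf("(C1 = %g, C2 = %g mg/L); ke cannot be estimated",
                 c1, c2), call. = FALSE)
  }
  ke <- log(c1 / c2) / (t2 - t1)
  list(ke_per_h = ke, half_life_h = log(2) / ke)
}

#' Steady-state concentrations from CL, V and a regimen
#'
#' One-compartment, first-order elimination, zero-order infusion at steady
#' state. Vectorized over all arguments. For intermittent/extended infusions
#' the end-of-infusion maximum is
#' Cmax_ss = dose (1 - e^(-ke Tinf)) / (Tinf CL (1 - e^(-ke tau)))
#' and Cmin_ss = Cmax_ss e^(-ke (tau - Tinf)). For continuous infusions both
#' equal the plateau Css = rate / CL.
#'
#' @param cl Clearance, L/h. @param v Volume of distribution, L.
#' @param dose_mg,interval_h,infusion_h Regimen fields (continuous rows use
#'   interval_h = infusion_h).
#' @return List of vectors `ke`, `cmax`, `cmin` (total mg/L).
#' @export
steady_state_conc <- function(cl, v, dose_mg, interval_h, infusion_h) {
  n <- max(length(cl), length(v), length(dose_mg), length(interval_h),
           length(infusion_h))
  cl <- rep_len(cl, n); v <- rep_len(v, n)
  dose_mg <- rep_len(dose_mg, n)
  interval_h <- rep_len(interval_h, n); infusion_h <- rep_len(infusion_h, n)
  ke <- cl / v
  cont <- infusion_h >= interval_h
  cmax <- ifelse(
    cont,
    dose_mg / (interval_h * cl),
    dose_mg * (1 - exp(-ke * infusion_h)) /
      (infusion_h * cl * (1 - exp(-ke * interval_h)))
  )
  cmin <- ifelse(cont, cmax, cmax * exp(-ke * (interval_h - infusion_h)))
  list(ke = ke, cmax = cmax, cmin = cmin)
}

#' Reconstruct individual steady-state kinetics from a peak/trough pair
#'
#' ke comes from the log-linear decline between peak and trough; the
#' end-of-infusion maximum is back-extrapolated from the measured peak,
#' Cmax_ss = C_peak e^(ke (t_peak - Tinf)); the interval-end minimum is the
#' measured trough extrapolated forward to tau if drawn earlier. Clearance
#' then follows from the steady-state infusion equation and V = CL/ke.
#' Steady state is assumed (sampling typically occurs several half-lives
#' into therapy).
#'
#' @param reg A [regimen()]. @param peak,trough [conc_sample()] objects;
#'   the peak must be drawn after the end of the infusion, the trough no
#'   later than tau.
#' @return List of class `"pk_estimate"`: `ke_per_h`, `half_life_h`,
#'   `cl_L_h`, `v_L`, `cmax_ss_total`, `cmin_ss_total`.
#' @export
#' @examples
#' reg <- regimen("cefepime", 2000, 8, 0.5)
#' reconstruct_profile(reg, conc_sample(1.5, 60, "peak"),
#'                     conc_sample(8, 12, "trough"))
reconstruct_profile <- function(reg, peak, trough) {
  stopifnot(inherits(reg, "regimen"))
  if (reg$mode == "continuous") {
    stop("peak/trough reconstruction applies to intermittent/extended ",
         "infusions; use continuous_attainment() for continuous mode",
         call. = FALSE)
  }
  if (peak$time_after_dose_start_h < reg$infusion_h) {
    stop("peak drawn before the end of the infusion", call. = FALSE)
  }
  if (trough$time_after_dose_start_h > reg$interval_h) {
    stop("trough drawn after the end of the dosing interval", call. = FALSE)
  }
  est <- estimate_elimination_rate(peak, trough)
  ke <- est$ke_per_h
  cmax <- peak$total_conc_mg_L *
    exp(ke * (peak$time_after_dose_start_h - reg$infusion_h))
  cmin <- trough$total_conc_mg_L *
    exp(-ke * (reg$interval_h - trough$time_after_dose_start_h))
  cl <- reg$dose_mg * (1 - exp(-ke * reg$infusion_h)) /
    (reg$infusion_h * cmax * (1 - exp(-ke * reg$interval_h)))
  if (!is.finite(cl) || cl <= 0) {
    stop("non-physical clearance estimate (CL <= 0)", call. = FALSE)
  }
  structure(list(ke_per_h = ke, half_life_h = est$half_life_h,
                 cl_L_h = cl, v_L = cl / ke,
                 cmax_ss_total = cmax, cmin_ss_total = cmin),
            class = "pk_estimate")
}

#' @export
print.pk_estimate <- function(x, ...) {
  cat(sprintf(paste0("<pk_estimate> ke %.4f /h (t1/2 %.2f h), CL %.2f L/h, ",
                     "V %.1f L, Cmax_ss %.1f, Cmin_ss %.2f mg/L (total)\n"),
              x$ke_per_h, x$half_life_h, x$cl_L_h, x$v_L,
              x$cmax_ss_total, x$cmin_ss_total))
  invisible(x)
}

#' Closed-form time above a threshold over one steady-state interval
#'
#' Internal vectorized kernel, free-concentration scale. The steady-state
#' profile is piecewise monotone: during the infusion
#' C(t) = A + (Cmin - A) e^(-ke t) with A chosen so C(Tinf) = Cmax (rising),
#' and after it C(t) = Cmax e^(-ke (t - Tinf)) (falling). Each phase
#' contributes at most one threshold crossing, found with a logarithm.
#' Returns the percentage of tau spent strictly above `thr`; boundary
#' contact (Cmin == thr) counts as attained (measure-zero convention).
#'
#' @param ke Elimination rate, 1/h. @param cmax,cmin Free steady-state
#'   max/min, mg/L. @param tau,tinf Interval and infusion duration, h.
#' @param thr Free-concentration threshold, mg/L (> 0).
#' @return Percent of the interval above `thr`, in `[0, 100]`.
#' @keywords internal
ss_percent_above <- function(ke, cmax, cmin, tau, tinf, thr) {
  n <- max(length(ke), length(cmax), length(cmin), length(tau),
           length(tinf), length(thr))
  ke <- rep_len(ke, n); cmax <- rep_len(cmax, n); cmin <- rep_len(cmin, n)
  tau <- rep_len(tau, n); tinf <- rep_len(tinf, n); thr <- rep_len(thr, n)

  # continuous: flat profile at cmax (== cmin)
  cont <- tinf >= tau

  # elimination phase, duration tau - tinf, falls cmax -> cmin
  elim_dur <- pmax(tau - tinf, 0)
  above_elim <- ifelse(cmin >= thr, elim_dur,
                ifelse(cmax <= thr, 0,
                       pmin(log(cmax / thr) / ke, elim_dur)))

  # infusion phase, duration tinf, rises cmin -> cmax towards asymptote A
  ek <- exp(-ke * tinf)
  A <- (cmax - cmin * ek) / (1 - ek)
  crossing <- !cont & cmin < thr & thr < cmax        # rows with a crossing
  ratio <- rep_len(1, n)
  ratio[crossing] <- (A[crossing] - cmin[crossing]) / (A[crossing] - thr[crossing])
  t_cross <- log(ratio) / ke
  above_inf <- ifelse(cmin >= thr, tinf,
               ifelse(cmax <= thr, 0, pmax(tinf - t_cross, 0)))

  pct <- ifelse(cont,
                ifelse(cmax > thr, 100, 0),  # flat profile: strict step
                100 * (above_elim + above_inf) / tau)
  pmin(pmax(pct, 0), 100)
}

#' Percent of the dosing interval with free concentration above a threshold
#'
#' fT>threshold for one TDM occasion, from the reconstructed steady-state
#' profile, after free-fraction correction for the drug.
#'
#' @param pk A `pk_estimate` (total-concentration scale).
#' @param reg The [regimen()] the estimate refers to.
#' @param drug Drug name (for the unbound fraction) or a one-row subset of
#'   [drug_profiles()].
#' @param threshold_mg_L Free-concentration threshold, mg/L (> 0).
#' @param profiles Drug profile table.
#' @return Percent of the interval, in `[0, 100]`.
#' @export
fraction_time_above <- function(pk, reg, drug, threshold_mg_L,
                                profiles = drug_profiles()) {
  stopifnot(threshold_mg_L > 0)
  fu <- fraction_unbound(drug, profiles)
  ss_percent_above(pk$ke_per_h, fu * pk$cmax_ss_total, fu * pk$cmin_ss_total,
                   reg$interval_h, reg$infusion_h, threshold_mg_L)
}

#' PK/PD target attainment for one TDM occasion
#'
#' Computes fT above h x MIC for each requested multiplier h and the free
#' trough to MIC ratio fCmin/MIC.
#'
#' @inheritParams fraction_time_above
#' @param mic MIC, mg/L (> 0).
#' @param multipliers MIC multipliers, default 1:5.
#' @return List of class `"target_attainment"`: `ft_above` (named percent
#'   vector, one entry per multiplier) and `fcmin_over_mic`.
#' @export
target_attainment <- function(pk, reg, drug, mic, multipliers = 1:5,
                              profiles = drug_profiles()) {
  if (!is.numeric(mic) || mic <= 0) stop("invalid MIC (must be > 0)",
                                         call. = FALSE)
  ft <- vapply(multipliers, function(h) {
    fraction_time_above(pk, reg, drug, h * mic, profiles)
  }, numeric(1))
  names(ft) <- paste0("x", multipliers)
  fu <- fraction_unbound(drug, profiles)
  structure(list(ft_above = ft,
                 fcmin_over_mic = fu * pk$cmin_ss_total / mic),
            class = "target_attainment")
}

#' @export
print.target_attainment <- function(x, ...) {
  cat("<target_attainment> fT>hxMIC (%):",
      paste(sprintf("%s=%.1f", names(x$ft_above), x$ft_above),
            collapse = " "),
      sprintf("| fCmin/MIC = %.2f\n", x$fcmin_over_mic))
  invisible(x)
}

#' Target attainment for a continuous infusion from random samples
#'
#' The plateau Css is the arithmetic mean of the sampled total
#' concentrations; the flat free profile is either entirely above or
#' entirely below each threshold, so fT>hxMIC is the step 100 x
#' I(free Css > h MIC), and fCmin/MIC = free Css / MIC.
#'
#' @param samples List of [conc_sample()]s (>= 1, kind "random").
#' @param drug Drug name. @param mic MIC, mg/L (> 0).
#' @param multipliers MIC multipliers, default 1:5.
#' @param profiles Drug profile table.
#' @return A `"target_attainment"` object.
#' @export
continuous_attainment <- function(samples, drug, mic, multipliers = 1:5,
                                  profiles = drug_profiles()) {
  if (length(samples) == 0L) stop("at least one random sample is required",
                                  call. = FALSE)
  if (!is.numeric(mic) || mic <= 0) stop("invalid MIC (must be > 0)",
                                         call. = FALSE)
  css <- mean(vapply(samples, function(s) s$total_conc_mg_L, numeric(1)))
  fcss <- free_concentration(css, drug, profiles)
  ft <- ifelse(fcss > multipliers * mic, 100, 0)
  names(ft) <- paste0("x", multipliers)
  structure(list(ft_above = ft, fcmin_over_mic = fcss / mic),
            class = "target_attainment")
}

#' Evaluate the steady-state free-concentration profile on a time grid
#'
#' Mostly a diagnostic/plotting aid; also serves as the numerical
#' counterpart of the closed-form crossing-time computation.
#'
#' @inheritParams fraction_time_above
#' @param times Times within one interval, h (0 to tau).
#' @return Free concentrations, mg/L, at `times`.
#' @export
ss_free_profile <- function(pk, reg, drug, times,
                            profiles = drug_profiles()) {
  fu <- fraction_unbound(drug, profiles)
  ke <- pk$ke_per_h
  cmax <- fu * pk$cmax_ss_total
  cmin <- fu * pk$cmin_ss_total
  tinf <- reg$infusion_h
  if (reg$mode == "continuous") return(rep(cmax, length(times)))
  ek <- exp(-ke * tinf)
  A <- (cmax - cmin * ek) / (1 - ek)
  ifelse(times <= tinf,
         A + (cmin - A) * exp(-ke * times),
         cmax * exp(-ke * (times - tinf)))
}
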