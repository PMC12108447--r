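#' Classify a therapy change as increase, no change or decrease
#'
#' A therapy increase is an increase in daily dose, dosing frequency and/or
#' infusion duration; a decrease is a decrease in any of them. Changes whose
#' components move in opposite directions (e.g. dose up, frequency down) are
#' resolved by comparing predicted target attainment of the two regimens at
#' the episode's MIC: exposure is the axis the definitions track. When the
#' fT comparison ties (commonly both 100%), the predicted free trough breaks
#' the tie before declaring no change.
#'
#' @param old,new [regimen()] objects for the same drug.
#' @param pk A `pk_estimate` (needed only for mixed-direction changes).
#' @param drug,mic,target_multiplier,profiles Attainment context for the
#'   mixed-direction comparison; `mic` may be numeric or an `effective_mic`.
#' @return List of class `"change_classification"`: `ordinal_code`
#'   (-1/0/+1), `label` ("decrease"/"no_change"/"increase"), `reasons`.
#' @export
#' @examples
#' classify_change(regimen("cefepime", 1000, 8, 0.5),
#'                 regimen("cefepime", 2000, 8, 0.5))
classify_change <- function(old, new, pk = NULL, drug = old$drug, mic = NULL,
                            target_multiplier = 1,
                            profiles = drug_profiles()) {
  stopifnot(inherits(old, "regimen"), inherits(new, "regimen"))
  if (old$drug != new$drug) {
    stop("drug switch (", old$drug, " -> ", new$drug,
         ") is outside the increase/decrease coding", call. = FALSE)
  }
  comp <- c(
    daily_dose        = sign(daily_dose(new) - daily_dose(old)),
    frequency         = sign(24 / new$interval_h - 24 / old$interval_h),
    infusion_duration = sign(new$infusion_h - old$infusion_h)
  )
  up <- names(comp)[comp > 0]
  down <- names(comp)[comp < 0]
  code <- if (length(up) && !length(down)) 1L
          else if (length(down) && !length(up)) -1L
          else if (!length(up) && !length(down)) 0L
          else NA_integer_
  reasons <- c(up, down)
  if (is.na(code)) {  # mixed directions: compare predicted exposure
    if (is.null(pk) || is.null(mic)) {
      stop("mixed-direction change (", paste(up, collapse = "/"), " up, ",
           paste(down, collapse = "/"),
           " down): supply pk and mic to resolve by predicted attainment",
           call. = FALSE)
    }
    micv <- if (is.list(mic)) mic$value else mic
    fu <- fraction_unbound(drug, profiles)
    thr <- target_multiplier * micv
    pred <- function(reg) {
      ss <- steady_state_conc(pk$cl_L_h, pk$v_L, reg$dose_mg,
                              reg$interval_h, reg$infusion_h)
      c(ft = ss_percent_above(ss$ke, fu * ss$cmax, fu * ss$cmin,
                              reg$interval_h, reg$infusion_h, thr),
        fcmin = fu * ss$cmin)
    }
    po <- pred(old); pn <- pred(new)
    d <- if (pn[["ft"]] != po[["ft"]]) pn[["ft"]] - po[["ft"]]
         else pn[["fcmin"]] - po[["fcmin"]]
    code <- as.integer(sign(d))
    reasons <- c(reasons, "mixed_resolved_by_predicted_attainment")
    if (code == 0L) reasons <- character(0)
  }
  structure(list(
    ordinal_code = code,
    label = c("decrease", "no_change", "increase")[code + 2L],
    reasons = reasons
  ), class = "change_classification")
}

#' @export
print.change_classification <- function(x, ...) {
  cat(sprintf("<change_classification> %s (%+d)%s\n", x$label,
              x$ordinal_code,
              if (length(x$reasons))
                paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

# Predicted fT>thr (%) and free Cmin for every (patient, candidate) pair.
# cl, v: patient vectors; menu: candidate data frame; fu, thr_free: patient
# vectors. Returns n x m matrices. Linear kinetics: the reconstructed CL/V
# determine every candidate's steady-state profile in closed form.
# Rows with v = NA are evaluated only against continuous candidates.
menu_attainment_matrix <- function(cl, v, fu, thr_free, menu) {
  n <- length(cl); m <- nrow(menu)
  ft <- matrix(NA_real_, n, m)
  fcmin <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    cont <- menu$infusion_h[j] >= menu$interval_h[j]
    ok <- if (cont) rep(TRUE, n) else !is.na(v)
    if (!any(ok)) next
    vj <- ifelse(is.na(v), 1, v)  # placeholder; continuous path ignores ke
    ss <- steady_state_conc(cl, vj, menu$dose_mg[j], menu$interval_h[j],
                            menu$infusion_h[j])
    ftj <- ss_percent_above(ss$ke, fu * ss$cmax, fu * ss$cmin,
                            menu$interval_h[j], menu$infusion_h[j], thr_free)
    ft[ok, j] <- ftj[ok]
    fcmin[ok, j] <- (fu * ss$cmin)[ok]
  }
  list(ft = ft, fcmin = fcmin)
}

# Vectorized candidate selection. Returns an integer vector of menu row
# indices plus a best_effort flag. Choice rule: among candidates with 100%
# predicted fT>target, lowest total daily dose, then fewest administrations
# per day, then shortest infusion; if none attains, the maximal-attainment
# candidate, tie-broken towards the highest predicted free trough (the
# exposure axis), flagged best-effort.
select_regimen_idx <- function(ft, menu, fcmin = ft) {
  dd <- menu$dose_mg * 24 / menu$interval_h
  npd <- 24 / menu$interval_h
  attain <- ft >= 100 - 1e-9
  rank_attain <- order(dd, npd, menu$infusion_h)          # cheapest first
  pos_attain <- match(seq_len(nrow(menu)), rank_attain)
  best <- integer(nrow(ft))
  best_effort <- logical(nrow(ft))
  ftx <- ft
  ftx[is.na(ftx)] <- -Inf
  for (i in seq_len(nrow(ft))) {
    cand <- which(attain[i, ])
    if (length(cand)) {
      best[i] <- cand[which.min(pos_attain[cand])]
    } else {
      avail <- which(is.finite(ftx[i, ]))
      o <- avail[order(-ftx[i, avail], -fcmin[i, avail], dd[avail],
                       npd[avail], menu$infusion_h[avail])]
      best[i] <- o[1L]
      best_effort[i] <- TRUE
    }
  }
  list(idx = best, best_effort = best_effort)
}

#' Recommend the minimal regimen achieving the PK/PD target
#'
#' Predicts steady-state attainment for every candidate in the dose menu
#' from the reconstructed clearance and volume (linear kinetics) and returns
#' the candidate with the lowest total daily dose — tie-broken by fewest
#' administrations per day, then shortest infusion — whose predicted
#' fT>target_multiplier x MIC is 100%. If no candidate attains, the
#' maximal-attainment candidate is returned flagged `best_effort`.
#'
#' @param pk A `pk_estimate` (uses `cl_L_h` and `v_L`).
#' @param drug Drug name. @param mic Numeric MIC (mg/L) or `effective_mic`.
#' @param target_multiplier MIC multiplier targeted at 100% fT, in 1..4
#'   (clinician's choice; default 1).
#' @param menu Candidate regimens, as [default_dose_menu()] rows.
#' @param profiles Drug profile table.
#' @return A [regimen()] with attributes `best_effort` (logical) and
#'   `predicted_ft` (percent).
#' @export
recommend_regimen <- function(pk, drug, mic, target_multiplier = 1,
                              menu = default_dose_menu(drug),
                              profiles = drug_profiles()) {
  if (nrow(menu) == 0L) stop("empty dose menu", call. = FALSE)
  micv <- if (is.list(mic)) mic$value else mic
  stopifnot(is.numeric(micv), micv > 0)
  fu <- fraction_unbound(drug, profiles)
  v <- if (is.null(pk$v_L)) NA_real_ else pk$v_L
  att <- menu_attainment_matrix(pk$cl_L_h, v, fu,
                                target_multiplier * micv, menu)
  sel <- select_regimen_idx(att$ft, menu, att$fcmin)
  j <- sel$idx[1L]
  out <- regimen(drug, menu$dose_mg[j], menu$interval_h[j],
                 menu$infusion_h[j], menu$mode[j])
  attr(out, "best_effort") <- sel$best_effort[1L]
  attr(out, "predicted_ft") <- att$ft[1L, j]
  out
}
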