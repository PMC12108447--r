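#' Write a cohort to the delimited-text exchange schemas
#'
#' Emits `episodes.csv`, `samples.csv` (one row per timed concentration,
#' carrying the regimen under which it was drawn) and `isolates.csv` into
#' `dir`. UTF-8, "." decimal separator, empty fields for missing values;
#' times in hours except `days_to_tdm` and `los_days` (days).
#'
#' @param cohort A `"tdm_cohort"`. @param dir Output directory (created if
#'   absent).
#' @return Invisibly, the written file paths.
#' @export
write_cohort_csvs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tdm_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ep <- cohort$episodes
  reg <- ep[, c("episode_id", "drug", "dose_mg", "interval_h", "infusion_h",
                "mode")]
  samples <- dplyr::left_join(cohort$samples, reg, by = "episode_id")
  samples <- samples[, c("episode_id", "drug", "dose_mg", "interval_h",
                         "infusion_h", "mode", "occasion", "sample_kind",
                         "time_after_dose_start_h", "total_conc_mg_L")]
  paths <- file.path(dir, c("episodes.csv", "samples.csv", "isolates.csv"))
  readr::write_csv(ep, paths[1], progress = FALSE)
  readr::write_csv(samples, paths[2], progress = FALSE)
  readr::write_csv(cohort$isolates, paths[3], progress = FALSE)
  invisible(paths)
}

read_checked_csv <- function(path, required) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read the sample, episode or isolate tables
#'
#' Thin readers that validate the required columns of each schema.
#' @param path CSV path.
#' @return A tibble.
#' @export
read_samples_csv <- function(path) {
  read_checked_csv(path, c("episode_id", "drug", "dose_mg", "interval_h",
                           "infusion_h", "mode", "sample_kind",
                           "time_after_dose_start_h", "total_conc_mg_L"))
}

#' @rdname read_samples_csv
#' @export
read_episodes_csv <- function(path) {
  read_checked_csv(path, c("episode_id", "drug", "mic_mg_L"))
}

#' @rdname read_samples_csv
#' @export
read_isolates_csv <- function(path) {
  read_checked_csv(path, c("episode_id", "organism", "mic_mg_L"))
}

#' Per-occasion PK/PD attainment report
#'
#' For every (episode, occasion) in the sample table: intermittent/extended
#' occasions are reconstructed from the earliest complete peak/trough pair
#' (earliest peak, then the first trough drawn after it); continuous
#' occasions use the mean of the random samples. Occasions that cannot be
#' resolved (missing pair, rising concentrations) are emitted with a
#' `status` message rather than dropped.
#'
#' @param samples Sample table in the [read_samples_csv()] schema (an
#'   `occasion` column defaults to 1).
#' @param mics Tibble `episode_id`, `mic_mg_L`.
#' @param profiles Drug profile table.
#' @return Tibble: episode_id, occasion, status, ke_per_h, half_life_h,
#'   fCmax, fCmin, fT_above_MIC_pct, fT_above_4xMIC_pct, fCmin_over_MIC.
#' @export
attainment_report <- function(samples, mics, profiles = drug_profiles()) {
  if (is.null(samples[["occasion"]])) samples$occasion <- 1L
  keys <- unique(samples[, c("episode_id", "occasion")])
  mic_of <- stats::setNames(mics$mic_mg_L, mics$episode_id)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- samples[samples$episode_id == keys$episode_id[i] &
                   samples$occasion == keys$occasion[i], ]
    out <- tibble::tibble(
      episode_id = keys$episode_id[i], occasion = keys$occasion[i],
      status = "ok", ke_per_h = NA_real_, half_life_h = NA_real_,
      fCmax = NA_real_, fCmin = NA_real_, fT_above_MIC_pct = NA_real_,
      fT_above_4xMIC_pct = NA_real_, fCmin_over_MIC = NA_real_)
    mic <- unname(mic_of[as.character(keys$episode_id[i])])
    if (is.na(mic)) {
      out$status <- "no MIC for episode"
      return(out)
    }
    drug <- s$drug[1]
    res <- tryCatch({
      fu <- fraction_unbound(drug, profiles)
      if (s$mode[1] == "continuous") {
        rs <- s[s$sample_kind == "random", ]
        if (nrow(rs) == 0L) stop("no random samples for continuous infusion")
        att <- continuous_attainment(
          lapply(seq_len(nrow(rs)), function(j)
            conc_sample(rs$time_after_dose_start_h[j],
                        rs$total_conc_mg_L[j], "random")),
          drug, mic, profiles = profiles)
        css <- mean(rs$total_conc_mg_L)
        list(ke = NA_real_, thalf = NA_real_, fcmax = fu * css,
             fcmin = fu * css, att = att)
      } else {
        reg <- regimen(drug, s$dose_mg[1], s$interval_h[1], s$infusion_h[1],
                       s$mode[1])
        pk <- s[s$sample_kind == "peak", ]
        tr <- s[s$sample_kind == "trough", ]
        if (nrow(pk) == 0L || nrow(tr) == 0L) {
          stop("no complete peak/trough pair (trough-only or peak-only ",
               "occasions cannot be resolved)")
        }
        pk <- pk[order(pk$time_after_dose_start_h), ][1, ]
        tr <- tr[tr$time_after_dose_start_h >
                   pk$time_after_dose_start_h, , drop = FALSE]
        if (nrow(tr) == 0L) stop("no trough after the earliest peak")
        tr <- tr[order(tr$time_after_dose_start_h), ][1, ]
        est <- reconstruct_profile(
          reg,
          conc_sample(pk$time_after_dose_start_h, pk$total_conc_mg_L,
                      "peak"),
          conc_sample(tr$time_after_dose_start_h, tr$total_conc_mg_L,
                      "trough"))
        att <- target_attainment(est, reg, drug, mic, multipliers = c(1, 4),
                                 profiles = profiles)
        list(ke = est$ke_per_h, thalf = est$half_life_h,
             fcmax = fu * est$cmax_ss_total, fcmin = fu * est$cmin_ss_total,
             att = att)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status <- conditionMessage(res)
    } else {
      out$ke_per_h <- res$ke
      out$half_life_h <- res$thalf
      out$fCmax <- res$fcmax
      out$fCmin <- res$fcmin
      out$fT_above_MIC_pct <- res$att$ft_above[["x1"]]
      out$fT_above_4xMIC_pct <- res$att$ft_above[["x4"]]
      out$fCmin_over_MIC <- res$att$fcmin_over_mic
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Change-log table for a cohort
#'
#' One row per episode: old and applied regimen, ordinal change code and
#' label, best-effort flag and predicted attainment at the clinician target.
#'
#' @param cohort A `"tdm_cohort"`.
#' @return A tibble.
#' @export
change_log <- function(cohort) {
  ep <- cohort$episodes
  tibble::tibble(
    episode_id = ep$episode_id, drug = ep$drug,
    old_dose_mg = ep$dose_mg, old_interval_h = ep$interval_h,
    old_infusion_h = ep$infusion_h,
    new_dose_mg = ep$new_dose_mg, new_interval_h = ep$new_interval_h,
    new_infusion_h = ep$new_infusion_h,
    ordinal_code = ep$ordinal_code, change = as.character(ep$change),
    target_multiplier = ep$target_multiplier,
    ft_target_pct = ep$ft_target_pct, best_effort = ep$best_effort
  )
}
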