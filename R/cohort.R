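#' Fit log-normal parameters to printed quantiles
#'
#' Least-squares fit of `log(q) ~ qnorm(p)`: the intercept is `meanlog`, the
#' slope `sdlog`. Used to turn a printed median and IQR (which is asymmetric
#' around the median on the natural scale) into a log-normal sampling
#' distribution.
#'
#' @param q Quantile values (> 0). @param p Their probabilities.
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
#' @examples
#' fit_lognormal_quantiles(c(1.7, 2.7, 4.7))  # sdlog approx 0.75
fit_lognormal_quantiles <- function(q, p = c(0.25, 0.5, 0.75)) {
  stopifnot(length(q) == length(p), all(q > 0), all(p > 0 & p < 1))
  z <- stats::qnorm(p)
  fit <- stats::lm.fit(cbind(1, z), log(q))
  c(meanlog = unname(fit$coefficients[1]),
    sdlog = unname(fit$coefficients[2]))
}

#' Configuration for the synthetic ICU TDM cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 297
#' infection episodes from 268 patients; age 56 (17) y, weight 82 (32) kg
#' (> 30), 57% male, 14% on RRT, SOFA 6 (4), baseline creatinine 1.26 (1.14)
#' mg/dL (> 0.2); lung-dominant infection sources; a cefepime-dominant drug
#' mix; 91% intermittent infusions; log-normal days-to-first-TDM fitted to
#' median 2.7 (IQR 1.7-4.7); outcome models whose true effects are the
#' published adjusted odds ratios, calibrated to 75% clinical cure and 20%
#' 30-day mortality; survivor hospital length of stay log-normal with group
#' medians ordered increase < no change < decrease around an overall 22 d;
#' censoring horizon 50 d.
#'
#' @param seed Integer seed; mandatory — every draw in [generate_cohort()]
#'   derives from it.
#' @param n_episodes,n_patients Cohort size; episodes beyond `n_patients`
#'   are second infections assigned to random patients.
#' @param ... Named overrides for any default listed in the function body
#'   (validated against the default set).
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed, n_episodes = 297L,
                          n_patients = round(n_episodes * 268 / 297), ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tdm_fit <- fit_lognormal_quantiles(c(1.7, 2.7, 4.7))
  cfg <- list(
    seed = as.integer(seed),
    n_episodes = as.integer(n_episodes),
    n_patients = as.integer(n_patients),
    # covariates
    age_mean = 56, age_sd = 17, age_min = 18, age_max = 100,
    weight_mean = 82, weight_sd = 32, weight_min = 30,
    p_male = 0.57, p_rrt = 0.14,
    sofa_mean = 6, sofa_sd = 4,
    scr_mean = 1.26, scr_sd = 1.14, scr_min = 0.2,
    severity_loading = 0.3,   # shared latent tying SOFA and RRT together
    source_probs = c(lung = 0.44, bacteremia = 0.17, skin = 0.09,
                     intra_abdominal = 0.07, urinary = 0.06, bone = 0.05,
                     endocarditis = 0.04, other = 0.08),
    drug_probs = c(cefepime = 0.42, meropenem = 0.20, piperacillin = 0.14,
                   cefazolin = 0.07, ceftriaxone = 0.06, ampicillin = 0.04,
                   aztreonam = 0.03, oxacillin = 0.04),
    mode_probs = c(intermittent = 0.91, extended = 0.06, continuous = 0.03),
    # PK truth: typical ICU clearance (L/h) and volume (L) per drug at
    # CrCl 100 mL/min and 82 kg (reduced CL / expanded V relative to
    # healthy volunteers, as in septic patients), log-normal
    # between-patient variability
    cl_typical = c(ampicillin = 11.5, aztreonam = 4.5, cefazolin = 3.5,
                   cefepime = 6.5, ceftriaxone = 0.9, meropenem = 10.5,
                   oxacillin = 19.5, piperacillin = 12.5),
    v_typical = c(ampicillin = 24, aztreonam = 16, cefazolin = 13,
                  cefepime = 22, ceftriaxone = 12, meropenem = 20,
                  oxacillin = 24, piperacillin = 22),
    crcl_exponent = 0.75, rrt_cl_factor = 0.35,
    bsv_cl_sdlog = 0.40, bsv_v_sdlog = 0.20,
    conc_noise_sdlog = 0.10,
    # MIC process: per-drug log2 centre/sd of doubling-dilution MICs,
    # capped at the breakpoint (resistant infections were excluded)
    mic_log2_center = c(ampicillin = 1, aztreonam = 1, cefazolin = 0,
                        cefepime = 0, ceftriaxone = 0, meropenem = -2,
                        oxacillin = -1, piperacillin = 2),
    mic_log2_sd = c(ampicillin = 1, aztreonam = 1.5, cefazolin = 1,
                    cefepime = 1.5, ceftriaxone = 1, meropenem = 1.5,
                    oxacillin = 1, piperacillin = 1.5),
    p_breakpoint = 0.27, p_polymicrobial = 0.15,
    # sampling-time process (log-normal fitted to 2.7 d, IQR 1.7-4.7)
    days_tdm_meanlog = tdm_fit[["meanlog"]],
    days_tdm_sdlog = tdm_fit[["sdlog"]],
    # clinician behaviour: stochastic PK/PD target multiplier (1-4x MIC,
    # severity-linked) and probability of acting on a de-escalation
    target_base = 0.8, target_sofa_slope = 0.1, target_sd = 0.7,
    p_deescalate = 0.48,
    # outcome models: true log odds ratios (published adjusted estimates)
    cure_coefs = c(days_to_tdm = log(0.92), increase = log(1.17),
                   decrease = log(1.25)),
    mort_coefs = c(sofa = log(1.14), rrt = log(2.07), age = log(1.05),
                   intra_abdominal = log(4.82), increase = log(0.36),
                   decrease = log(0.67)),
    alpha_cure = NULL, alpha_mort = NULL,   # NULL: calibrate per cohort
    target_cure = 0.75, target_mortality = 0.20,
    # survivor hospital LOS (days), log-normal by change group
    los_median = c(increase = 22 * exp(-0.2), no_change = 22,
                   decrease = 22 * exp(0.2)),
    los_sdlog = 0.85,
    censor_horizon = 50
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_cohort_config(structure(cfg, class = "cohort_config"))
}

validate_cohort_config <- function(cfg) {
  for (blk in c("source_probs", "drug_probs", "mode_probs")) {
    if (abs(sum(cfg[[blk]]) - 1) > 1e-8 || any(cfg[[blk]] < 0)) {
      stop(blk, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  pos <- c("age_sd", "weight_sd", "sofa_sd", "scr_sd", "days_tdm_sdlog",
           "los_sdlog", "censor_horizon")
  bad <- pos[vapply(pos, function(f) any(cfg[[f]] <= 0), logical(1))]
  if (length(bad)) {
    stop("scale parameter(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nn <- c("bsv_cl_sdlog", "bsv_v_sdlog", "conc_noise_sdlog")
  bad <- nn[vapply(nn, function(f) any(cfg[[f]] < 0), logical(1))]
  if (length(bad)) {
    stop("variability parameter(s) must be non-negative: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(cfg$cl_typical > 0), all(cfg$v_typical > 0),
            cfg$p_breakpoint >= 0, cfg$p_breakpoint <= 1,
            cfg$p_deescalate >= 0, cfg$p_deescalate <= 1,
            cfg$target_cure > 0, cfg$target_cure < 1,
            cfg$target_mortality > 0, cfg$target_mortality < 1)
  cfg
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# organisms compatible with a drug = pairs present in the breakpoint table,
# with rough prevalence weights (Pseudomonas-dominant ICU flora)
organism_weights <- function(drug, breakpoints) {
  w <- c("Pseudomonas aeruginosa" = 0.45, "Escherichia coli" = 0.25,
         "Klebsiella pneumoniae" = 0.20, "Staphylococcus aureus" = 0.10,
         "Enterococcus faecalis" = 0.05)
  org <- breakpoints$organism[breakpoints$drug == drug]
  ww <- w[intersect(names(w), org)]
  ww / sum(ww)
}

#' Generate a synthetic ICU TDM cohort
#'
#' Draws covariates, true individual kinetics, an empiric regimen, a first
#' TDM occasion (noisy peak/trough or random samples forward-simulated from
#' the true steady-state profile), an effective MIC (measured isolates or a
#' breakpoint fallback), then derives the therapy-change group by running
#' the adjustment rules against the reconstructed attainment under a
#' stochastic clinician target (1-4x MIC), and finally assigns outcomes
#' from the configured logistic/log-normal models. Deterministic given
#' `config$seed`; the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @param with_outcomes Set `FALSE` to stop before outcome assignment
#'   (used for intercept calibration).
#' @return List of class `"tdm_cohort"` with tibbles `episodes`, `samples`,
#'   `isolates` and the `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1, n_episodes = 40))
#' coh$episodes[1:3, c("drug", "mic_mg_L", "change")]
generate_cohort <- function(config, with_outcomes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  n <- config$n_episodes
  npat <- min(config$n_patients, n)
  profiles <- drug_profiles()
  bp <- default_breakpoints()
  menu_all <- default_dose_menu()
  empiric <- default_empiric_regimens()

  # ---- patients and episode covariates -------------------------------
  pat <- tibble::tibble(
    patient_id = seq_len(npat),
    age = rtruncnorm(npat, config$age_mean, config$age_sd,
                     config$age_min, config$age_max),
    weight_kg = rtruncnorm(npat, config$weight_mean, config$weight_sd,
                           lo = config$weight_min),
    male = stats::runif(npat) < config$p_male
  )
  pid <- c(seq_len(npat),
           sample(npat, n - npat, replace = TRUE))  # second infections
  lam <- config$severity_loading
  z_sev <- stats::rnorm(n)
  sofa <- pmin(24, pmax(0, round(
    config$sofa_mean + config$sofa_sd *
      (lam * z_sev + sqrt(1 - lam^2) * stats::rnorm(n)))))
  rrt <- stats::runif(n) < stats::plogis(stats::qlogis(config$p_rrt) +
                                           lam * z_sev)
  ep <- tibble::tibble(
    episode_id = seq_len(n),
    patient_id = pid,
    age = pat$age[pid], weight_kg = pat$weight_kg[pid], male = pat$male[pid],
    scr_mg_dL = rtruncnorm(n, config$scr_mean, config$scr_sd,
                           lo = config$scr_min),
    sofa = sofa, rrt = rrt,
    source = sample(names(config$source_probs), n, replace = TRUE,
                    prob = config$source_probs),
    drug = sample(names(config$drug_probs), n, replace = TRUE,
                  prob = config$drug_probs)
  )

  # ---- true kinetics --------------------------------------------------
  crcl <- pmin(pmax((140 - ep$age) * ep$weight_kg /
                      (72 * ep$scr_mg_dL) * ifelse(ep$male, 1, 0.85),
                    5), 200)
  cl_typ <- unname(config$cl_typical[ep$drug])
  ep$true_cl_L_h <- ifelse(ep$rrt,
                           cl_typ * config$rrt_cl_factor,
                           cl_typ * (crcl / 100)^config$crcl_exponent) *
    stats::rlnorm(n, 0, config$bsv_cl_sdlog)
  ep$true_v_L <- unname(config$v_typical[ep$drug]) * (ep$weight_kg / 82) *
    stats::rlnorm(n, 0, config$bsv_v_sdlog)

  # ---- initial regimen ------------------------------------------------
  i_emp <- match(ep$drug, empiric$drug)
  ep$dose_mg <- empiric$dose_mg[i_emp]
  ep$interval_h <- empiric$interval_h[i_emp]
  ep$infusion_h <- empiric$infusion_h[i_emp]
  mode_draw <- sample(names(config$mode_probs), n, replace = TRUE,
                      prob = config$mode_probs)
  # extended: stretch the empiric infusion to the drug's longest
  # non-continuous menu infusion (drugs without one stay intermittent)
  ext_len <- vapply(ep$drug, function(d) {
    m <- menu_all[menu_all$drug == d & menu_all$mode != "continuous", ]
    max(m$infusion_h)
  }, numeric(1))
  is_ext <- mode_draw == "extended" & ext_len > 1
  ep$infusion_h[is_ext] <- ext_len[is_ext]
  # continuous: same daily dose over a 24 h window, where the menu offers it
  cont_menu <- menu_all[menu_all$mode == "continuous", ]
  want_cont <- mode_draw == "continuous" & ep$drug %in% cont_menu$drug
  if (any(want_cont)) {
    dd <- ep$dose_mg * 24 / ep$interval_h
    ci <- vapply(which(want_cont), function(i) {
      m <- cont_menu[cont_menu$drug == ep$drug[i], ]
      m$dose_mg[which.min(abs(m$dose_mg - dd[i]))]
    }, numeric(1))
    ep$dose_mg[want_cont] <- ci
    ep$interval_h[want_cont] <- 24
    ep$infusion_h[want_cont] <- 24
  }
  ep$mode <- classify_infusion_mode(ep$infusion_h, ep$interval_h)

  # ---- isolates and effective MIC ------------------------------------
  use_bp <- stats::runif(n) < config$p_breakpoint
  n_iso <- ifelse(use_bp, 0L,
                  1L + (stats::runif(n) < config$p_polymicrobial))
  iso_ep <- rep.int(seq_len(n), n_iso)
  iso_drug <- ep$drug[iso_ep]
  iso_org <- character(length(iso_ep))
  for (d in unique(iso_drug)) {
    w <- organism_weights(d, bp)
    k <- iso_drug == d
    iso_org[k] <- sample(names(w), sum(k), replace = TRUE, prob = w)
  }
  cap <- bp$breakpoint_mg_L[match(paste(iso_drug, iso_org),
                                  paste(bp$drug, bp$organism))]
  mic_draw <- 2^round(stats::rnorm(length(iso_ep),
                                   unname(config$mic_log2_center[iso_drug]),
                                   unname(config$mic_log2_sd[iso_drug])))
  iso_mic <- pmin(pmax(mic_draw, 0.06), cap)
  isolates <- tibble::tibble(episode_id = iso_ep, organism = iso_org,
                             mic_mg_L = iso_mic, site = ep$source[iso_ep])
  # vectorized resolution mirroring effective_mic(): measured max, the
  # cefazolin/MSSA override, or breakpoint fallback
  mic_val <- rep(NA_real_, n); mic_prov <- rep(NA_character_, n)
  mx <- tapply(isolates$mic_mg_L, isolates$episode_id, max)
  mic_val[as.integer(names(mx))] <- mx
  mic_prov[!use_bp] <- "measured_max"
  mssa <- tapply(isolates$organism == "Staphylococcus aureus",
                 isolates$episode_id, any)
  mssa_ids <- as.integer(names(mssa))[mssa]
  mssa_ids <- mssa_ids[ep$drug[mssa_ids] == "cefazolin"]
  mic_val[mssa_ids] <- 2
  mic_prov[mssa_ids] <- "mssa_cefazolin_rule"
  if (any(use_bp)) {
    suspected <- character(sum(use_bp))
    bdrug <- ep$drug[use_bp]
    for (d in unique(bdrug)) {
      w <- organism_weights(d, bp)
      k <- bdrug == d
      suspected[k] <- sample(names(w), sum(k), replace = TRUE, prob = w)
    }
    mic_val[use_bp] <- bp$breakpoint_mg_L[match(paste(bdrug, suspected),
                                                paste(bp$drug, bp$organism))]
    mic_prov[use_bp] <- "breakpoint"
    ep$suspected_pathogen <- NA_character_
    ep$suspected_pathogen[use_bp] <- suspected
  } else {
    ep$suspected_pathogen <- NA_character_
  }
  ep$mic_mg_L <- mic_val
  ep$mic_provenance <- mic_prov

  # ---- first TDM occasion: forward-simulated samples ------------------
  ep$days_to_tdm <- stats::rlnorm(n, config$days_tdm_meanlog,
                                  config$days_tdm_sdlog)
  ss_true <- steady_state_conc(ep$true_cl_L_h, ep$true_v_L, ep$dose_mg,
                               ep$interval_h, ep$infusion_h)
  is_cont <- ep$mode == "continuous"
  t_peak <- ep$infusion_h + 1
  noise <- function(k) stats::rlnorm(k, 0, config$conc_noise_sdlog)
  peak_true <- ss_true$cmax * exp(-ss_true$ke * 1)
  peak_obs <- peak_true * noise(n)
  trough_obs <- ss_true$cmin * noise(n)
  # continuous infusions contribute one or two random plateau samples
  n_rand <- ifelse(is_cont, 1L + (stats::runif(n) < 0.5), 0L)
  rand_ep <- rep.int(seq_len(n), n_rand)
  rand_obs <- ss_true$cmax[rand_ep] * noise(length(rand_ep))
  samples <- dplyr::bind_rows(
    tibble::tibble(episode_id = which(!is_cont), occasion = 1L,
                   sample_kind = "peak",
                   time_after_dose_start_h = t_peak[!is_cont],
                   total_conc_mg_L = peak_obs[!is_cont]),
    tibble::tibble(episode_id = which(!is_cont), occasion = 1L,
                   sample_kind = "trough",
                   time_after_dose_start_h = ep$interval_h[!is_cont],
                   total_conc_mg_L = trough_obs[!is_cont]),
    tibble::tibble(episode_id = rand_ep, occasion = 1L,
                   sample_kind = "random",
                   time_after_dose_start_h =
                     stats::runif(length(rand_ep), 0, 24),
                   total_conc_mg_L = rand_obs)
  ) |> dplyr::arrange(episode_id, time_after_dose_start_h)

  # ---- reconstruction (vectorized mirror of reconstruct_profile) ------
  css_hat <- rep(NA_real_, n)
  if (any(is_cont)) {
    css_hat[is_cont] <- tapply(rand_obs, rand_ep, mean)[
      as.character(which(is_cont))]
  }
  estimable <- !is_cont & peak_obs > trough_obs
  ke_hat <- cmax_hat <- cmin_hat <- cl_hat <- v_hat <- rep(NA_real_, n)
  k <- which(estimable)
  ke_hat[k] <- log(peak_obs[k] / trough_obs[k]) /
    (ep$interval_h[k] - t_peak[k])
  cmax_hat[k] <- peak_obs[k] * exp(ke_hat[k] * 1)
  cmin_hat[k] <- trough_obs[k]
  cl_hat[k] <- ep$dose_mg[k] * (1 - exp(-ke_hat[k] * ep$infusion_h[k])) /
    (ep$infusion_h[k] * cmax_hat[k] * (1 - exp(-ke_hat[k] * ep$interval_h[k])))
  v_hat[k] <- cl_hat[k] / ke_hat[k]
  cl_hat[is_cont] <- ep$dose_mg[is_cont] / (24 * css_hat[is_cont])
  cmax_hat[is_cont] <- cmin_hat[is_cont] <- css_hat[is_cont]
  estimable <- estimable | is_cont
  ep$pk_estimable <- estimable
  ep$ke_hat <- ke_hat; ep$cl_hat <- cl_hat; ep$v_hat <- v_hat

  # ---- attainment of the current regimen ------------------------------
  fu <- fraction_unbound(ep$drug, profiles)
  att_pct <- function(mult) {
    out <- rep(NA_real_, n)
    kk <- which(estimable)
    out[kk] <- ss_percent_above(ke_hat[kk], fu[kk] * cmax_hat[kk],
                                fu[kk] * cmin_hat[kk], ep$interval_h[kk],
                                ep$infusion_h[kk],
                                mult[kk] * ep$mic_mg_L[kk])
    out
  }
  ep$ft_mic_pct <- att_pct(rep(1, n))
  ep$ft_4mic_pct <- att_pct(rep(4, n))
  ep$fcmin_over_mic <- fu * cmin_hat / ep$mic_mg_L
  # clinician's stochastic exposure target, higher with severity
  ep$target_multiplier <- pmin(4, pmax(1, round(
    config$target_base + config$target_sofa_slope * ep$sofa +
      stats::rnorm(n, 0, config$target_sd))))
  ep$ft_target_pct <- att_pct(ep$target_multiplier)

  # ---- recommendation and change group --------------------------------
  new_dose <- ep$dose_mg; new_int <- ep$interval_h; new_inf <- ep$infusion_h
  best_effort <- rep(FALSE, n)
  deesc_roll <- stats::runif(n) < config$p_deescalate
  for (d in unique(ep$drug)) {
    kk <- which(ep$drug == d & estimable)
    if (!length(kk)) next
    mn <- menu_all[menu_all$drug == d, ]
    att <- menu_attainment_matrix(cl_hat[kk], v_hat[kk], fu[kk],
                                  ep$target_multiplier[kk] * ep$mic_mg_L[kk],
                                  mn)
    sel <- select_regimen_idx(att$ft, mn, att$fcmin)
    attains_now <- ep$ft_target_pct[kk] >= 100 - 1e-9
    act <- !attains_now | deesc_roll[kk]  # always act on failure;
    kk_act <- kk[act]                     # de-escalate with probability
    j <- sel$idx[act]
    new_dose[kk_act] <- mn$dose_mg[j]
    new_int[kk_act] <- mn$interval_h[j]
    new_inf[kk_act] <- mn$infusion_h[j]
    best_effort[kk_act] <- sel$best_effort[act]
  }
  ep$new_dose_mg <- new_dose
  ep$new_interval_h <- new_int
  ep$new_infusion_h <- new_inf
  ep$best_effort <- best_effort
  cls <- classify_change_vec(ep, fu)
  ep$ordinal_code <- cls$code
  ep$change <- factor(cls$label,
                      levels = c("decrease", "no_change", "increase"))

  out <- structure(list(episodes = ep, samples = samples,
                        isolates = isolates, config = config),
                   class = "tdm_cohort")
  if (with_outcomes) out <- assign_outcomes(out, config)
  out
}

# vectorized increase/decrease/no-change coding; mixed directions resolved
# by predicted fT at the clinician target, then predicted free trough
classify_change_vec <- function(ep, fu) {
  d_dd <- sign(ep$new_dose_mg * 24 / ep$new_interval_h -
                 ep$dose_mg * 24 / ep$interval_h)
  d_fr <- sign(24 / ep$new_interval_h - 24 / ep$interval_h)
  d_in <- sign(ep$new_infusion_h - ep$infusion_h)
  any_up <- d_dd > 0 | d_fr > 0 | d_in > 0
  any_dn <- d_dd < 0 | d_fr < 0 | d_in < 0
  code <- ifelse(any_up & !any_dn, 1L, ifelse(any_dn & !any_up, -1L, 0L))
  mixed <- which(any_up & any_dn)
  if (length(mixed)) {
    thr <- ep$target_multiplier[mixed] * ep$mic_mg_L[mixed]
    pr <- function(dose, tau, tinf) {
      ss <- steady_state_conc(ep$cl_hat[mixed],
                              ifelse(is.na(ep$v_hat[mixed]), 1,
                                     ep$v_hat[mixed]),
                              dose, tau, tinf)
      list(ft = ss_percent_above(ss$ke, fu[mixed] * ss$cmax,
                                 fu[mixed] * ss$cmin, tau, tinf, thr),
           fcmin = fu[mixed] * ss$cmin)
    }
    po <- pr(ep$dose_mg[mixed], ep$interval_h[mixed], ep$infusion_h[mixed])
    pn <- pr(ep$new_dose_mg[mixed], ep$new_interval_h[mixed],
             ep$new_infusion_h[mixed])
    dlt <- ifelse(pn$ft != po$ft, pn$ft - po$ft, pn$fcmin - po$fcmin)
    code[mixed] <- as.integer(sign(dlt))
  }
  list(code = code,
       label = c("decrease", "no_change", "increase")[code + 2L])
}

#' Assign clinical outcomes to a generated cohort
#'
#' Clinical cure and 30-day mortality are Bernoulli draws from logistic
#' models whose log odds ratios are the configured (published) adjusted
#' effects; hospital length of stay for survivors is log-normal with
#' change-group-specific medians, censored administratively at the horizon.
#' When `config$alpha_cure`/`alpha_mort` are `NULL`, intercepts are
#' calibrated on the cohort's own linear predictors so the expected
#' marginal proportions equal `target_cure`/`target_mortality` exactly.
#' Draws come from the current RNG stream (inside [generate_cohort()] that
#' stream is seeded by `config$seed`).
#'
#' @param cohort A `"tdm_cohort"` (or its `episodes` tibble).
#' @param config A [cohort_config()].
#' @return The cohort with `clinical_cure`, `mortality_30d`, `los_days`,
#'   `censored` filled in on `episodes`.
#' @export
assign_outcomes <- function(cohort, config = cohort$config) {
  ep <- if (inherits(cohort, "tdm_cohort")) cohort$episodes else cohort
  if (is.null(ep$change)) stop("episodes lack a change group", call. = FALSE)
  n <- nrow(ep)
  inc <- ep$change == "increase"
  dec <- ep$change == "decrease"
  eta_cure <- config$cure_coefs[["days_to_tdm"]] * ep$days_to_tdm +
    config$cure_coefs[["increase"]] * inc +
    config$cure_coefs[["decrease"]] * dec
  eta_mort <- config$mort_coefs[["sofa"]] * ep$sofa +
    config$mort_coefs[["rrt"]] * ep$rrt +
    config$mort_coefs[["age"]] * ep$age +
    config$mort_coefs[["intra_abdominal"]] * (ep$source == "intra_abdominal") +
    config$mort_coefs[["increase"]] * inc +
    config$mort_coefs[["decrease"]] * dec
  a_c <- config$alpha_cure %||%
    solve_intercept(eta_cure, config$target_cure)
  a_m <- config$alpha_mort %||%
    solve_intercept(eta_mort, config$target_mortality)
  ep$clinical_cure <- stats::runif(n) < stats::plogis(a_c + eta_cure)
  ep$mortality_30d <- stats::runif(n) < stats::plogis(a_m + eta_mort)
  med <- config$los_median[as.character(ep$change)]
  los <- stats::rlnorm(n, log(med), config$los_sdlog)
  los[ep$mortality_30d] <- NA_real_
  ep$los_days <- los
  ep$censored <- !is.na(los) & los > config$censor_horizon
  if (inherits(cohort, "tdm_cohort")) {
    cohort$episodes <- ep
    cohort
  } else ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# monotone root: mean(plogis(alpha + eta)) = target
solve_intercept <- function(eta, target) {
  if (all(eta == 0)) return(stats::qlogis(target))  # closed form
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target,
                 lower = -40, upper = 40, tol = 1e-10)$root
}

#' Calibrate outcome-model intercepts by Monte Carlo
#'
#' Generates a large pre-outcome cohort under `config` and root-solves the
#' intercepts so the marginal cure and mortality proportions hit the
#' targets over that covariate distribution.
#'
#' @param config A [cohort_config()]. @param target_cure,target_mortality
#'   Marginal proportions in (0, 1).
#' @param n Monte-Carlo cohort size.
#' @return Named vector `c(alpha_cure, alpha_mort)`.
#' @export
calibrate_intercepts <- function(config,
                                 target_cure = config$target_cure,
                                 target_mortality = config$target_mortality,
                                 n = 200000L) {
  stopifnot(target_cure > 0, target_cure < 1,
            target_mortality > 0, target_mortality < 1)
  big <- config
  big$n_episodes <- as.integer(n)
  big$n_patients <- as.integer(round(n * config$n_patients /
                                       config$n_episodes))
  coh <- generate_cohort(big, with_outcomes = FALSE)
  ep <- coh$episodes
  inc <- ep$change == "increase"; dec <- ep$change == "decrease"
  eta_cure <- config$cure_coefs[["days_to_tdm"]] * ep$days_to_tdm +
    config$cure_coefs[["increase"]] * inc +
    config$cure_coefs[["decrease"]] * dec
  eta_mort <- config$mort_coefs[["sofa"]] * ep$sofa +
    config$mort_coefs[["rrt"]] * ep$rrt +
    config$mort_coefs[["age"]] * ep$age +
    config$mort_coefs[["intra_abdominal"]] * (ep$source == "intra_abdominal") +
    config$mort_coefs[["increase"]] * inc +
    config$mort_coefs[["decrease"]] * dec
  c(alpha_cure = solve_intercept(eta_cure, target_cure),
    alpha_mort = solve_intercept(eta_mort, target_mortality))
}

#' @export
print.tdm_cohort <- function(x, ...) {
  ep <- x$episodes
  cat(sprintf("<tdm_cohort> %d episodes / %d patients, seed %d\n",
              nrow(ep), length(unique(ep$patient_id)), x$config$seed))
  if (!is.null(ep$change)) {
    tb <- table(ep$change)
    cat("  change groups:",
        paste(sprintf("%s %.0f%%", names(tb), 100 * tb / sum(tb)),
              collapse = ", "), "\n")
  }
  if (!is.null(ep$clinical_cure)) {
    cat(sprintf("  cure %.0f%%, 30-day mortality %.0f%%\n",
                100 * mean(ep$clinical_cure), 100 * mean(ep$mortality_30d)))
  }
  invisible(x)
}
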