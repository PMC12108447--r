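test_that("the generator is deterministic given the seed", {
  a <- generate_cohort(cohort_config(seed = 5, n_episodes = 150))
  b <- generate_cohort(cohort_config(seed = 5, n_episodes = 150))
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$samples, b$samples)
  expect_identical(a$isolates, b$isolates)
  c2 <- generate_cohort(cohort_config(seed = 6, n_episodes = 150))
  expect_false(identical(a$episodes$age, c2$episodes$age))
  # and leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_cohort(cohort_config(seed = 5,
                                                        n_episodes = 20)))
  expect_identical(runif(1), before)
})

test_that("defaults give 297 episodes from 268 patients with Table-1-like marginals", {
  co <- generate_cohort(cohort_config(seed = 1))
  ep <- co$episodes
  expect_equal(nrow(ep), 297)
  expect_equal(length(unique(ep$patient_id)), 268)
  # binomial tolerances at n = 297
  expect_lt(abs(mean(ep$rrt) - 0.14), 0.06)
  expect_lt(abs(mean(ep$male) - 0.57), 0.09)
  expect_lt(abs(mean(ep$mode == "intermittent") - 0.91), 0.06)
  expect_lt(abs(mean(ep$age) - 56), 3)
  expect_true(all(ep$weight_kg > 30))
  expect_true(all(ep$scr_mg_dL > 0.2))
  expect_true(all(ep$mic_mg_L > 0))
  expect_true(all(ep$mic_provenance %in%
                    c("measured_max", "breakpoint", "mssa_cefazolin_rule")))
})

test_that("different seeds are distributionally equivalent", {
  a <- generate_cohort(cohort_config(seed = 21, n_episodes = 2000),
                       with_outcomes = FALSE)$episodes
  b <- generate_cohort(cohort_config(seed = 22, n_episodes = 2000),
                       with_outcomes = FALSE)$episodes
  for (v in c("age", "weight_kg", "days_to_tdm")) {
    expect_gt(suppressWarnings(ks.test(a[[v]], b[[v]])$p.value), 0.01)
  }
})

test_that("zero variability and noise give exact PK recovery", {
  co <- generate_cohort(cohort_config(seed = 9, n_episodes = 200,
                                      bsv_cl_sdlog = 0, bsv_v_sdlog = 0,
                                      conc_noise_sdlog = 0,
                                      mode_probs = c(intermittent = 1,
                                                     extended = 0,
                                                     continuous = 0)))
  ep <- co$episodes
  expect_true(all(ep$pk_estimable))
  expect_equal(ep$ke_hat, ep$true_cl_L_h / ep$true_v_L, tolerance = 1e-10)
  expect_equal(ep$cl_hat, ep$true_cl_L_h, tolerance = 1e-10)
  expect_equal(ep$v_hat, ep$true_v_L, tolerance = 1e-10)
})

test_that("the generator's MIC resolution agrees with effective_mic()", {
  co <- generate_cohort(cohort_config(seed = 13, n_episodes = 300),
                        with_outcomes = FALSE)
  ep <- co$episodes
  for (i in seq_len(nrow(ep))) {
    iso <- co$isolates[co$isolates$episode_id == ep$episode_id[i], ]
    em <- effective_mic(if (nrow(iso)) iso else NULL, ep$drug[i],
                        ep$suspected_pathogen[i])
    expect_equal(em$value, ep$mic_mg_L[i])
    expect_equal(em$provenance, ep$mic_provenance[i])
  }
})

test_that("intercept calibration matches the closed-form logit when effects vanish", {
  zero <- cohort_config(seed = 2, n_episodes = 400,
                        cure_coefs = c(days_to_tdm = 0, increase = 0,
                                       decrease = 0),
                        mort_coefs = c(sofa = 0, rrt = 0, age = 0,
                                       intra_abdominal = 0, increase = 0,
                                       decrease = 0))
  a <- calibrate_intercepts(zero, target_cure = 0.5,
                            target_mortality = 0.5, n = 500)
  expect_equal(unname(a), c(0, 0))
  b <- calibrate_intercepts(zero, target_cure = 0.75,
                            target_mortality = 0.2, n = 500)
  expect_equal(unname(b[1]), log(3), tolerance = 1e-9)
  expect_equal(unname(b[2]), qlogis(0.2), tolerance = 1e-9)
})

test_that("an intercept-only mortality model reproduces its marginal rate", {
  co <- generate_cohort(cohort_config(
    seed = 31, n_episodes = 8000,
    mort_coefs = c(sofa = 0, rrt = 0, age = 0, intra_abdominal = 0,
                   increase = 0, decrease = 0),
    alpha_mort = qlogis(0.2)))
  expect_lt(abs(mean(co$episodes$mortality_30d) - 0.2), 0.015)
})

test_that("LOS exists for survivors only and censoring flags stays over 50 d", {
  co <- generate_cohort(cohort_config(seed = 4, n_episodes = 2000))
  ep <- co$episodes
  expect_true(all(is.na(ep$los_days[ep$mortality_30d])))
  expect_true(all(ep$los_days[!ep$mortality_30d] > 0))
  expect_identical(ep$censored,
                   !is.na(ep$los_days) & ep$los_days > 50)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(), "mandatory")
  expect_error(cohort_config(seed = 1,
                             mode_probs = c(intermittent = 0.7,
                                            extended = 0.2,
                                            continuous = 0.2)),
               "sum to 1")
  expect_error(cohort_config(seed = 1, sofa_sd = -1), "positive")
  expect_error(cohort_config(seed = 1, bsv_cl_sdlog = -0.1),
               "non-negative")
  expect_error(cohort_config(seed = 1, nonsense = 3), "unknown config")
})

test_that("the days-to-TDM log-normal reproduces the printed quantiles", {
  fit <- fit_lognormal_quantiles(c(1.7, 2.7, 4.7))
  expect_equal(unname(fit["sdlog"]), 0.75, tolerance = 0.01)
  q <- qlnorm(c(0.25, 0.5, 0.75), fit["meanlog"], fit["sdlog"])
  expect_lt(abs(q[2] - 2.7), 0.2)
  expect_lt(abs(q[1] - 1.7), 0.3)
  expect_lt(abs(q[3] - 4.7), 0.3)
})
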