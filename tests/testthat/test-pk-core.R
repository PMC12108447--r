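test_that("elimination rate follows the log-linear decline", {
  est <- estimate_elimination_rate(conc_sample(2, 40, "peak"),
                                   conc_sample(8, 10, "trough"))
  expect_equal(est$ke_per_h, log(4) / 6, tolerance = 1e-12)
  expect_equal(est$half_life_h, log(2) / (log(4) / 6), tolerance = 1e-12)
  # cross-check: solving C1 e^(-ke dt) = C2 numerically
  f <- function(ke) 40 * exp(-ke * 6) - 10
  expect_equal(est$ke_per_h, uniroot(f, c(1e-4, 5), tol = 1e-12)$root,
               tolerance = 1e-8)

  # definition of half-life, any t1/2
  for (thalf in c(0.5, 1, 3, 8)) {
    est <- estimate_elimination_rate(
      conc_sample(2, 40, "peak"), conc_sample(2 + thalf, 20, "trough"))
    expect_equal(est$ke_per_h, log(2) / thalf, tolerance = 1e-12)
  }
})

test_that("flat or rising concentrations are rejected with a diagnostic", {
  expect_error(estimate_elimination_rate(conc_sample(2, 30, "peak"),
                                         conc_sample(8, 30, "trough")),
               "elimination signal")
  expect_error(estimate_elimination_rate(conc_sample(2, 30, "peak"),
                                         conc_sample(8, 45, "trough")),
               "elimination signal")
  expect_error(estimate_elimination_rate(conc_sample(8, 40, "peak"),
                                         conc_sample(2, 10, "trough")),
               "t2 > t1")
})

test_that("profile reconstruction reproduces the measured samples", {
  reg <- regimen("cefepime", 2000, 8, 0.5)
  pk <- reconstruct_profile(reg, conc_sample(1.5, 60, "peak"),
                            conc_sample(8, 12, "trough"))
  expect_equal(pk$ke_per_h, log(5) / 6.5, tolerance = 1e-12)
  expect_equal(pk$cmax_ss_total, 60 * exp(log(5) / 6.5), tolerance = 1e-12)
  expect_equal(pk$cmin_ss_total, 12)

  # forward multi-dose superposition with the recovered CL/V must pass
  # through both measured samples within 0.1 mg/L
  for (tt in c(1.5, 8)) {
    obs <- if (tt == 1.5) 60 else 12
    expect_equal(superpose_conc(pk$cl_L_h, pk$v_L, 2000, 8, 0.5, tt), obs,
                 tolerance = 0.1 / obs)
  }
})

test_that("peak drawn exactly at end of infusion needs no extrapolation", {
  reg <- regimen("cefepime", 2000, 8, 0.5)
  pk <- reconstruct_profile(reg, conc_sample(0.5, 80, "peak"),
                            conc_sample(8, 10, "trough"))
  expect_equal(pk$cmax_ss_total, 80)
  # measured trough equals the predicted decline from Cmax
  expect_equal(pk$cmin_ss_total,
               pk$cmax_ss_total * exp(-pk$ke_per_h * 7.5),
               tolerance = 1e-12)
})

test_that("free concentration applies the published unbound fractions", {
  expect_equal(free_concentration(10, "meropenem"), 9.8)
  expect_equal(free_concentration(100, "ceftriaxone"), 10)
  expect_equal(free_concentration(0, "oxacillin"), 0)
  # linear and order-preserving
  tot <- c(0.5, 1, 5, 20, 80)
  fr <- free_concentration(tot, "piperacillin")
  expect_equal(fr, 0.7 * tot)
  expect_true(all(diff(fr) > 0))
  expect_error(free_concentration(10, "imipenem"), "imipenem")
  expect_error(free_concentration(-1, "meropenem"), ">= 0")
})

test_that("time above threshold handles the never/always cases", {
  reg <- regimen("meropenem", 1000, 8, 0.5)
  pk <- reconstruct_profile(reg, conc_sample(1.5, 30, "peak"),
                            conc_sample(8, 6, "trough"))
  fu <- 0.98
  expect_equal(fraction_time_above(pk, reg, "meropenem",
                                   fu * pk$cmin_ss_total * 0.99), 100)
  expect_equal(fraction_time_above(pk, reg, "meropenem",
                                   fu * pk$cmax_ss_total * 1.01), 0)
})

test_that("closed-form time above matches the dense grid on the cefepime case", {
  reg <- regimen("cefepime", 2000, 8, 0.5)
  pk <- reconstruct_profile(reg, conc_sample(1.5, 60, "peak"),
                            conc_sample(8, 12, "trough"))
  got <- fraction_time_above(pk, reg, "cefepime", 32)  # 4 x MIC of 8
  oracle <- grid_percent_above(pk$ke_per_h, 0.8 * pk$cmax_ss_total,
                               0.8 * pk$cmin_ss_total, 8, 0.5, 32)
  expect_lt(abs(got - oracle), 0.5)
})

test_that("closed form agrees with the grid oracle across random scenarios", {
  sc <- random_pk_scenarios(200, seed = 7)
  got <- tdmattain:::ss_percent_above(sc$ke, sc$cmax, sc$cmin, sc$tau,
                                      sc$tinf, sc$thr)
  oracle <- vapply(seq_len(nrow(sc)), function(i) {
    grid_percent_above(sc$ke[i], sc$cmax[i], sc$cmin[i], sc$tau[i],
                       sc$tinf[i], sc$thr[i])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 0.5)
})

test_that("target attainment: boundary, worked example, monotonicity, scaling", {
  reg <- regimen("cefepime", 2000, 8, 0.5)
  pk <- reconstruct_profile(reg, conc_sample(1.5, 60, "peak"),
                            conc_sample(8, 12, "trough"))
  att <- target_attainment(pk, reg, "cefepime", 8)
  expect_equal(att$fcmin_over_mic, 0.8 * 12 / 8)  # 1.2
  expect_equal(unname(att$ft_above["x1"]), 100)   # fCmin > MIC forces 100%
  expect_true(all(diff(att$ft_above) <= 0))       # non-increasing in h

  # boundary: free Cmin equal to MIC counts as attained
  mic_eq <- 0.8 * pk$cmin_ss_total
  att_eq <- target_attainment(pk, reg, "cefepime", mic_eq)
  expect_equal(att_eq$fcmin_over_mic, 1.0)
  expect_equal(unname(att_eq$ft_above["x1"]), 100)

  # fCmin/MIC halves exactly when the MIC doubles
  att2 <- target_attainment(pk, reg, "cefepime", 16)
  expect_equal(att2$fcmin_over_mic, att$fcmin_over_mic / 2)
  expect_error(target_attainment(pk, reg, "cefepime", -1), "MIC")
})

test_that("continuous-infusion attainment is a step in free Css", {
  # one sample with free Css exactly 2 x MIC: strict threshold at the step
  s <- conc_sample(10, 2 * 16 / 0.7, "random")
  att <- continuous_attainment(list(s), "piperacillin", 16)
  expect_equal(att$fcmin_over_mic, 2.0)
  expect_equal(unname(att$ft_above["x1"]), 100)
  expect_equal(unname(att$ft_above["x2"]), 0)

  att2 <- continuous_attainment(list(conc_sample(4, 30, "random"),
                                     conc_sample(20, 50, "random")),
                                "piperacillin", 16)
  expect_equal(att2$fcmin_over_mic, 0.7 * 40 / 16)
  expect_equal(unname(att2$ft_above["x1"]), 100)

  att3 <- continuous_attainment(list(conc_sample(4, 10, "random")),
                                "piperacillin", 16)
  expect_true(all(att3$ft_above == 0))
  expect_error(continuous_attainment(list(), "piperacillin", 16),
               "at least one")
})

test_that("noise-free peak/trough sampling recovers ke, CL and V within 1%", {
  cases <- list(c(cl = 6, v = 20), c(cl = 12, v = 35), c(cl = 2.5, v = 15))
  for (cs in cases) {
    tau <- 8; tinf <- 0.5; dose <- 2000
    peak <- superpose_conc(cs["cl"], cs["v"], dose, tau, tinf, tinf + 1)
    trough <- superpose_conc(cs["cl"], cs["v"], dose, tau, tinf, tau)
    pk <- reconstruct_profile(regimen("cefepime", dose, tau, tinf),
                              conc_sample(tinf + 1, peak, "peak"),
                              conc_sample(tau, trough, "trough"))
    expect_equal(pk$ke_per_h, unname(cs["cl"] / cs["v"]), tolerance = 0.01)
    expect_equal(pk$cl_L_h, unname(cs["cl"]), tolerance = 0.01)
    expect_equal(pk$v_L, unname(cs["v"]), tolerance = 0.01)
  }
})
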