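make_2x2 <- function() {
  data.frame(
    y = c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80)),
    exposed = c(rep(TRUE, 100), rep(FALSE, 100))
  )
}

random_logit_data <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  beta <- rnorm(p, 0, 0.7)
  y <- runif(n) < plogis(0.2 + drop(X %*% beta))
  data.frame(y = as.numeric(y), X)
}

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  d <- make_2x2()
  fit <- fit_logistic(d, model_spec("y", "exposed"))
  or <- fit$coefficients$or[fit$coefficients$term == "exposedTRUE"]
  expect_equal(or, (10 * 80) / (90 * 20), tolerance = 1e-6)
})

test_that("the Newton fit matches glm to 1e-6 on random datasets", {
  worst <- 0
  for (s in 1:100) {
    d <- random_logit_data(n = 80, p = 3, seed = s)
    fit <- fit_logistic(d, model_spec("y", c("x1", "x2", "x3")))
    ref <- glm(y ~ x1 + x2 + x3, binomial(), data = d)
    worst <- max(worst, max(abs(fit$coefficients$estimate -
                                  unname(coef(ref)))))
  }
  expect_lt(worst, 1e-6)
})

test_that("Wald intervals and p-values follow the reported conventions", {
  d <- random_logit_data(200, 2, seed = 11)
  fit <- fit_logistic(d, model_spec("y", c("x1", "x2")))
  co <- fit$coefficients
  expect_equal(co$or, exp(co$estimate))
  expect_equal(co$ci_low, exp(co$estimate - 1.96 * co$se))
  expect_equal(co$ci_high, exp(co$estimate + 1.96 * co$se))
  expect_equal(co$p_value, 2 * pnorm(-abs(co$estimate / co$se)))
  expect_true(fit$converged)
  expect_lt(fit$max_gradient, 1e-8)
})

test_that("a null model recovers the logit of the event fraction", {
  d <- data.frame(y = c(rep(1, 30), rep(0, 70)), one = 1)
  fit <- fit_logistic(d, model_spec("y", character(0)))
  expect_equal(fit$coefficients$estimate[1], qlogis(0.3), tolerance = 1e-10)
})

test_that("degenerate designs fail loudly", {
  d <- make_2x2()
  d$flat <- 1
  expect_error(fit_logistic(d, model_spec("y", c("exposed", "flat"))),
               "singular design.*flat")
  # perfect separation
  d2 <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                   x = c(rnorm(20, -4), rnorm(20, 4)))
  expect_error(fit_logistic(d2, model_spec("y", "x")), "separat")
  d3 <- data.frame(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(d3, model_spec("y", "x")), "single class")
  expect_error(fit_logistic(make_2x2(), model_spec("y", "missing_col")),
               "missing_col")
})

test_that("survival records drop 30-day deaths and censor at the horizon", {
  ep <- tibble::tibble(
    episode_id = 1:4,
    mortality_30d = c(FALSE, FALSE, TRUE, FALSE),
    los_days = c(60, 22, NA, 50),
    change = c("increase", "decrease", "no_change", "no_change")
  )
  rec <- tte_prepare(ep)
  expect_equal(nrow(rec), 3)           # the death is excluded
  expect_equal(rec$time, c(50, 22, 50))
  expect_equal(rec$event, c(FALSE, TRUE, TRUE))  # 60 d -> censored
  ep$los_days[2] <- NA
  expect_error(tte_prepare(ep), "missing")
})

test_that("product-limit estimate matches the hand computation", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = TRUE, group = "all")
  km <- km_estimate(rec)
  expect_equal(km$survival[km$n_event == 1],
               c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  rec2 <- tibble::tibble(time = c(1, 2, 3), event = FALSE, group = "all")
  km2 <- km_estimate(rec2)
  expect_true(all(km2$survival == 1))
  # no censoring: one minus the empirical CDF at every event time
  set.seed(8)
  tt <- sample(1:40, 25, replace = TRUE)
  km3 <- km_estimate(tibble::tibble(time = tt, event = TRUE))
  ev <- km3$time[km3$n_event > 0]
  expect_equal(km3$survival[km3$n_event > 0],
               vapply(ev, function(x) mean(tt > x), numeric(1)))
})

test_that("log-rank is zero for identical groups and df = groups - 1", {
  tt <- c(3, 6, 6, 10, 14); evs <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  rec <- tibble::tibble(time = rep(tt, 2), event = rep(evs, 2),
                        group = rep(c("a", "b"), each = 5))
  lr <- log_rank(rec)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  rec3 <- tibble::tibble(time = rep(tt, 3), event = rep(evs, 3),
                         group = rep(c("a", "b", "c"), each = 5))
  expect_equal(log_rank(rec3)$df, 2)
  expect_error(log_rank(rec[rec$group == "a", ]), ">= 2")
})

test_that("log-rank p agrees with a permutation reference on small samples", {
  set.seed(15)
  rec <- tibble::tibble(
    time = c(rexp(30, 1 / 8), rexp(30, 1 / 14)),
    event = runif(60) > 0.15,
    group = rep(c("early", "late"), each = 30)
  )
  lr <- log_rank(rec)
  nperm <- 4000
  stat_perm <- replicate(nperm, {
    g <- sample(rec$group)
    survival::survdiff(survival::Surv(rec$time, rec$event) ~ g)$chisq
  })
  p_perm <- mean(stat_perm >= lr$statistic - 1e-12)
  expect_lt(abs(p_perm - lr$p_value), 0.01)
})

test_that("clearly separated survival gives a significant log-rank at n=50/group", {
  set.seed(2)
  rec <- tibble::tibble(
    time = c(runif(50, 1, 10), runif(50, 20, 40)),
    event = TRUE,
    group = rep(c("early", "late"), each = 50)
  )
  lr <- log_rank(rec)
  expect_gt(lr$statistic, 0)
  expect_lt(lr$p_value, 0.05)
})

test_that("the regression table carries univariate and adjusted columns", {
  co <- generate_cohort(cohort_config(seed = 17, n_episodes = 3000))
  tb <- regression_table(co$episodes, mortality_model_spec())
  expect_true(all(c("uni_or", "or", "ci_low", "ci_high", "p_value")
                  %in% names(tb)))
  expect_true(any(grepl("sofa", tb$term)))
  expect_true(any(grepl("change", tb$term)))
})
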