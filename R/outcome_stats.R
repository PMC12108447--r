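#' Specify a logistic outcome model
#'
#' @param outcome Binary outcome column ("clinical_cure" or
#'   "mortality_30d").
#' @param predictors Character vector of predictor columns; factors are
#'   expanded with `reference` as the baseline of the change variable.
#' @param reference Reference level for the regimen-change factor.
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(outcome, predictors, reference = "no_change") {
  structure(list(outcome = outcome, predictors = predictors,
                 reference = reference), class = "model_spec")
}

#' Default multivariable model for clinical cure
#'
#' Days to first TDM (continuous) and regimen change (categorical,
#' reference: no change).
#' @export
cure_model_spec <- function() {
  model_spec("clinical_cure", c("days_to_tdm", "change"))
}

#' Default multivariable model for 30-day mortality
#'
#' SOFA score, RRT, age, intra-abdominal source and regimen change
#' (reference: no change).
#' @export
mortality_model_spec <- function() {
  model_spec("mortality_30d",
             c("sofa", "rrt", "age", "intra_abdominal", "change"))
}

build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(c(spec$outcome, setdiff(spec$predictors,
                                          "intra_abdominal")),
                  names(data))
  if (length(miss)) {
    stop("column(s) missing from data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(data)
  if ("intra_abdominal" %in% spec$predictors &&
      !"intra_abdominal" %in% names(df)) {
    df$intra_abdominal <- df$source == "intra_abdominal"
  }
  if ("change" %in% spec$predictors) {
    df$change <- stats::relevel(factor(df$change), ref = spec$reference)
  }
  y <- df[[spec$outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; model is not estimable",
         call. = FALSE)
  }
  rhs <- if (length(spec$predictors)) {
    paste(spec$predictors, collapse = "+")
  } else "1"
  f <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(f, df)
  list(y = y, X = X)
}

#' Maximum-likelihood logistic regression (Newton / IRLS)
#'
#' Fits by full Newton steps on the log-likelihood to a gradient tolerance
#' of 1e-8 (at most 100 iterations), with Wald standard errors from the
#' observed information. Odds ratios, 95% Wald intervals
#' (`exp(beta +/- 1.96 se)`) and two-sided Wald p-values are reported.
#' Singular designs name the collinear columns; non-convergence (including
#' separation) raises an explicit diagnostic rather than returning silently.
#'
#' @param data Episode data (tibble/data frame).
#' @param spec A [model_spec()].
#' @return List of class `"tdm_logit"`: `coefficients` tibble (term,
#'   estimate, se, or, ci_low, ci_high, p_value), `converged`, `iterations`,
#'   `max_gradient`, `n`.
#' @export
fit_logistic <- function(data, spec) {
  d <- build_design(data, spec)
  y <- d$y; X <- d$X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design: collinear/constant column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- c(stats::qlogis(mean(y)), rep(0, ncol(X) - 1L))
  tol <- 1e-8; maxit <- 100L
  converged <- FALSE; it <- 0L; g_max <- Inf
  while (it < maxit) {
    it <- it + 1L
    p <- stats::plogis(drop(X %*% beta))
    g <- drop(crossprod(X, y - p))
    g_max <- max(abs(g))
    if (g_max < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), .Machine$double.eps)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(beta)) > 50) break  # diverging: separation signature
  }
  if (!converged) {
    stop("logistic fit did not converge after ", it, " iterations ",
         sprintf("(max gradient %.3g)", g_max),
         "; the data may be separated", call. = FALSE)
  }
  p <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (p * (1 - p)), X)
  se <- sqrt(diag(solve(H)))
  if (any(!is.finite(se)) || max(se) > 100) {
    stop("logistic fit is degenerate (a Wald SE exceeds 100 on the ",
         "log-odds scale); a predictor likely separates the outcome",
         call. = FALSE)
  }
  beta <- unname(beta); se <- unname(se)
  z <- beta / se
  res <- tibble::tibble(
    term = colnames(X), estimate = beta, se = se,
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z))
  )
  structure(list(coefficients = res, converged = converged,
                 iterations = it, max_gradient = g_max, n = length(y)),
            class = "tdm_logit")
}

#' @export
print.tdm_logit <- function(x, digits = 3, ...) {
  cat(sprintf("<tdm_logit> n = %d, converged in %d iterations\n",
              x$n, x$iterations))
  print(as.data.frame(x$coefficients), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Univariate screen plus multivariable model, Tables-style layout
#'
#' Fits each predictor alone against the outcome, then the full
#' multivariable spec, and assembles one row per predictor with univariate
#' and adjusted OR (95% CI) and the adjusted p-value — the layout of a
#' standard univariate/multivariable regression table.
#'
#' @param data Episode data. @param spec Multivariable [model_spec()].
#' @param univariate Predictors for the univariate column (default: the
#'   spec's own predictors).
#' @return Tibble: term, or/ci (univariate), aor/ci/p (adjusted).
#' @export
regression_table <- function(data, spec, univariate = spec$predictors) {
  uni <- dplyr::bind_rows(lapply(univariate, function(pr) {
    f <- fit_logistic(data, model_spec(spec$outcome, pr, spec$reference))
    dplyr::filter(f$coefficients, term != "(Intercept)")
  }))
  names(uni) <- paste0("uni_", names(uni))
  multi <- fit_logistic(data, spec)$coefficients
  multi <- dplyr::filter(multi, term != "(Intercept)")
  dplyr::full_join(dplyr::rename(uni, term = "uni_term"), multi,
                   by = "term")
}

#' Prepare survival records for the time-to-discharge analysis
#'
#' Drops 30-day deaths, censors stays longer than the horizon: each
#' remaining episode contributes `time = min(LOS, horizon)` and
#' `event = LOS <= horizon`, with its change-group label.
#'
#' @param episodes Episode data with `mortality_30d`, `los_days`, `change`.
#' @param horizon_days Administrative censoring horizon (default 50).
#' @return Tibble: `episode_id`, `time`, `event`, `group`.
#' @export
tte_prepare <- function(episodes, horizon_days = 50) {
  ep <- episodes[!episodes$mortality_30d, , drop = FALSE]
  if (anyNA(ep$los_days)) {
    stop("length of stay missing for included episode(s)", call. = FALSE)
  }
  tibble::tibble(
    episode_id = ep$episode_id,
    time = pmin(ep$los_days, horizon_days),
    event = ep$los_days <= horizon_days,
    group = as.character(ep$change)
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Right-censored product-limit estimator (via the survival package),
#' evaluated at the event times of each group.
#'
#' @param records Output of [tte_prepare()] (columns `time`, `event`,
#'   optional `group`).
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  grp <- if (!is.null(records[["group"]])) records[["group"]]
         else rep("all", nrow(records))
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ grp)
  s <- summary(fit, censored = TRUE)
  group <- if (is.null(s$strata)) rep("all", length(s$time))
           else sub("^grp=", "", as.character(s$strata))
  tibble::tibble(group = group, time = s$time, n_risk = s$n.risk,
                 n_event = s$n.event, n_censor = s$n.censor,
                 survival = s$surv)
}

#' Log-rank test across change groups
#'
#' Standard observed-minus-expected chi-square over the pooled event times
#' (ties handled by the aggregated-increment formulation). `groups` selects
#' a pairwise comparison (e.g. increase vs decrease); the default compares
#' all groups present.
#'
#' @param records Output of [tte_prepare()].
#' @param groups Optional subset of group labels to compare.
#' @return List of class `"log_rank"`: `statistic`, `df`, `p_value`,
#'   `groups`.
#' @export
log_rank <- function(records, groups = NULL) {
  if (!is.null(groups)) {
    records <- records[records$group %in% groups, , drop = FALSE]
  }
  gl <- unique(records$group)
  if (length(gl) < 2L) stop("log-rank needs >= 2 non-empty groups",
                            call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ records$group)
  df <- length(gl) - 1L
  structure(list(statistic = unname(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 groups = sort(gl)),
            class = "log_rank")
}

#' @export
print.log_rank <- function(x, ...) {
  cat(sprintf("<log_rank> chi-square = %.3f on %d df, p = %.4f (%s)\n",
              x$statistic, x$df, x$p_value,
              paste(x$groups, collapse = " vs ")))
  invisible(x)
}
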