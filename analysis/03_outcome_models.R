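#!/usr/bin/env Rscript
# Stage 3 — outcome regressions and time-to-discharge analysis.
#
# Fits the univariate and multivariable logistic models for clinical cure
# (days to TDM + regimen change) and 30-day mortality (SOFA, RRT, age,
# intra-abdominal source, regimen change; no-change reference), then the
# Kaplan-Meier time-to-discharge analysis excluding 30-day deaths with
# censoring at 50 days. Exits non-zero on non-convergence.
#
# Usage: Rscript analysis/03_outcome_models.R [--outdir results]

suppressPackageStartupMessages(library(tdmattain))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
outdir <- get_arg("--outdir", "results")

episodes <- readr::read_csv(file.path(outdir, "cohort", "episodes.csv"),
                            show_col_types = FALSE)

cure_tb <- regression_table(episodes, cure_model_spec(),
                            univariate = c("sofa", "rrt", "age",
                                           "days_to_tdm", "scr_mg_dL"))
mort_tb <- regression_table(episodes, mortality_model_spec(),
                            univariate = c("sofa", "rrt", "age",
                                           "days_to_tdm", "scr_mg_dL",
                                           "intra_abdominal"))
readr::write_csv(cure_tb, file.path(outdir, "cure_model.csv"))
readr::write_csv(mort_tb, file.path(outdir, "mortality_model.csv"))

fmt <- function(tb) {
  cell <- function(o, lo, hi) ifelse(is.na(o), "-",
                                     sprintf("%.2f (%.2f, %.2f)", o, lo, hi))
  data.frame(term = tb$term,
             univariate = cell(tb$uni_or, tb$uni_ci_low, tb$uni_ci_high),
             adjusted = cell(tb$or, tb$ci_low, tb$ci_high),
             p = ifelse(is.na(tb$p_value), "-",
                        format(signif(tb$p_value, 2))))
}
cat("clinical cure, adjusted:\n"); print(fmt(cure_tb), row.names = FALSE)
cat("30-day mortality, adjusted:\n"); print(fmt(mort_tb), row.names = FALSE)

recs <- tte_prepare(episodes)
km <- km_estimate(recs)
readr::write_csv(km, file.path(outdir, "survival.csv"))
lr_all <- log_rank(recs)
lr_pair <- log_rank(recs, groups = c("increase", "decrease"))
cat(sprintf("log-rank all groups: chi2 = %.2f, p = %.4f\n",
            lr_all$statistic, lr_all$p_value))
cat(sprintf("log-rank increase vs decrease: chi2 = %.2f, p = %.4f\n",
            lr_pair$statistic, lr_pair$p_value))
cat("wrote cure_model.csv, mortality_model.csv, survival.csv ->",
    outdir, "\n")
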