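#!/usr/bin/env Rscript
# Stage 4 — human-readable run summary.
#
# Collates the outputs of stages 1-3 into one printed report: cohort
# marginals, attainment medians, both regression tables and the
# time-to-discharge comparison.
#
# Usage: Rscript analysis/04_report.R [--outdir results]

suppressPackageStartupMessages(library(tdmattain))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
outdir <- get_arg("--outdir", "results")
rd <- function(f) readr::read_csv(file.path(outdir, f),
                                  show_col_types = FALSE)

ep <- rd("cohort/episodes.csv")
att <- rd("attainment.csv")
cure <- rd("cure_model.csv")
mort <- rd("mortality_model.csv")

cat("== cohort ==\n")
cat(sprintf("%d episodes / %d patients | age %.0f (%.0f) | weight %.0f (%.0f) | male %.0f%% | RRT %.0f%%\n",
            nrow(ep), length(unique(ep$patient_id)), mean(ep$age),
            sd(ep$age), mean(ep$weight_kg), sd(ep$weight_kg),
            100 * mean(ep$male), 100 * mean(ep$rrt)))
cat(sprintf("therapy change: %s\n",
            paste(sprintf("%s %.0f%%", names(table(ep$change)),
                          100 * table(ep$change) / nrow(ep)),
                  collapse = ", ")))
cat(sprintf("clinical cure %.0f%% | 30-day mortality %.0f%% | median LOS %.0f d\n",
            100 * mean(ep$clinical_cure), 100 * mean(ep$mortality_30d),
            median(ep$los_days, na.rm = TRUE)))

cat("\n== target attainment (resolved occasions) ==\n")
ok <- att[att$status == "ok", ]
cat(sprintf("median fT>MIC %.0f%% | fT>4xMIC %.0f%% | fCmin/MIC %.1f\n",
            median(ok$fT_above_MIC_pct), median(ok$fT_above_4xMIC_pct),
            median(ok$fCmin_over_MIC)))

fmt <- function(tb) {
  cell <- function(o, lo, hi) ifelse(is.na(o), "-",
                                     sprintf("%.2f (%.2f, %.2f)", o, lo, hi))
  data.frame(term = tb$term,
             univariate = cell(tb$uni_or, tb$uni_ci_low, tb$uni_ci_high),
             adjusted = cell(tb$or, tb$ci_low, tb$ci_high),
             p = ifelse(is.na(tb$p_value), "-",
                        format(signif(tb$p_value, 2))))
}
cat("\n== clinical cure model ==\n"); print(fmt(cure), row.names = FALSE)
cat("\n== 30-day mortality model ==\n"); print(fmt(mort), row.names = FALSE)

recs <- tte_prepare(ep)
med <- vapply(split(recs$time, recs$group), median, numeric(1))
cat("\n== time to discharge (survivors, censored at 50 d) ==\n")
cat(sprintf("median days by group: %s\n",
            paste(sprintf("%s %.0f", names(med), med), collapse = ", ")))
lr <- log_rank(recs)
cat(sprintf("log-rank (all groups): p = %.4f\n", lr$p_value))
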