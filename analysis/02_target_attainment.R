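#!/usr/bin/env Rscript
# Stage 2 — PK/PD target attainment per TDM occasion.
#
# Reads the sample and episode tables written by stage 1, reconstructs each
# occasion's steady-state kinetics from its peak/trough pair (or plateau
# samples for continuous infusions), and writes the attainment report
# (ke, half-life, free Cmax/Cmin, fT>MIC, fT>4xMIC, fCmin/MIC). Occasions
# that cannot be resolved are kept with a status message.
#
# Usage: Rscript analysis/02_target_attainment.R [--outdir results]

suppressPackageStartupMessages(library(tdmattain))
args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
outdir <- get_arg("--outdir", "results")

samples <- read_samples_csv(file.path(outdir, "cohort", "samples.csv"))
episodes <- read_episodes_csv(file.path(outdir, "cohort", "episodes.csv"))

rep <- attainment_report(samples, episodes[, c("episode_id", "mic_mg_L")])
readr::write_csv(rep, file.path(outdir, "attainment.csv"))

ok <- rep[rep$status == "ok", ]
cat(sprintf("attainment computed for %d/%d occasions (%d flagged)\n",
            nrow(ok), nrow(rep), nrow(rep) - nrow(ok)))
by_drug <- merge(ok, episodes[, c("episode_id", "drug")], by = "episode_id")
agg <- aggregate(cbind(fT_above_MIC_pct, fT_above_4xMIC_pct,
                       fCmin_over_MIC) ~ drug, by_drug, median)
cat("median attainment by drug:\n")
print(agg, row.names = FALSE, digits = 3)
cat("wrote attainment.csv ->", outdir, "\n")
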