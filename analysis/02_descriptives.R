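#!/usr/bin/env Rscript
# Stage 2: descriptive epidemiology of the simulated cohort.
#
# Prevalence of any AUD by sex and age band, the four transition-pair
# tallies per age stratum, and the per-covariate contrasts between pairs
# that did and did not change state (these contrasts gate model entry in
# stage 3).

library(audmc)

cohort <- read_panel("results/cohort.csv")
cohort <- combine_covariates(cohort, list(anx_dep = c("anxiety", "depression")))
pairs <- build_transition_pairs(cohort)
strata <- stratify_by_age(pairs)

prev <- prevalence_any_aud(cohort)
cat(sprintf("any AUD during follow-up: %.1f%% of subjects\n",
            100 * attr(prev, "overall")))
print(prev)
write.csv(prev, "results/prevalence_by_sex_age.csv", row.names = FALSE)
png("results/prevalence_by_sex_age.png", width = 800, height = 500)
plot_prevalence(prev)
dev.off()

for (snm in names(strata)) {
  sp <- strata[[snm]]
  cat("\n==", snm, "stratum:", nrow(sp), "pairs ==\n")
  print(tabulate_transitions(sp))
  ct <- contrast_table(sp)
  sig <- ct$covariate[ct$onset_sig | ct$remission_sig]
  cat("covariates contrasting significantly (p < 0.05):",
      paste(sig, collapse = ", "), "\n")
  write.csv(ct, sprintf("results/table1_%s.csv", snm), row.names = FALSE)
}
write_pairs(pairs, "results/transition_pairs.csv")
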