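#!/usr/bin/env Rscript
# The core demonstration: manipulating ONLY mean pellet-eating time between
# two simulated groups (15 s vs 10 s; identical attentional-lapse
# parameters; 5 s ITI) produces a robust group difference in omissions
# after correct trials (OAC) while omissions after incorrect/omission
# trials (OAIO) stay at chance -- eating delays masquerade as attentional
# omissions, and conditioning on no-reward predecessors removes the
# confound. Replicated over independent cohorts.

suppressMessages(library(fivechoice))

SEED <- 20260925
REPS <- 40
dir.create("results", showWarnings = FALSE)

cat("Replicating", REPS, "eating-only cohorts (n = 16 + 16)...\n")
rows <- lapply(seq_len(REPS), function(r) {
  sp <- cohort_preset("eating_only", seed = SEED + r)
  pr <- sd_profile(cohort_sd_sweep(sp))
  data.frame(
    replicate = r,
    oac_p = mixed_anova(pr, dv = "oac", between = "group", within = "sd_s",
                        subject = "mouse_id")$p[1],
    oaio_p = mixed_anova(pr, dv = "oaio", between = "group",
                         within = "sd_s", subject = "mouse_id")$p[1],
    oaio_ext_p = mixed_anova(pr, dv = "oaio_ext", between = "group",
                             within = "sd_s", subject = "mouse_id")$p[1]
  )
})
res <- do.call(rbind, rows)
write.csv(res, "results/dissociation.csv", row.names = FALSE)

cat(sprintf("\nOAC group effect p < 0.01:       %d/%d cohorts (%.0f%%)\n",
            sum(res$oac_p < 0.01), REPS, 100 * mean(res$oac_p < 0.01)))
cat(sprintf("OAIO group effect p > 0.05:      %d/%d cohorts (%.0f%%)\n",
            sum(res$oaio_p > 0.05), REPS, 100 * mean(res$oaio_p > 0.05)))
cat(sprintf("ext. OAIO group effect p > 0.05: %d/%d cohorts (%.0f%%)\n",
            sum(res$oaio_ext_p > 0.05), REPS,
            100 * mean(res$oaio_ext_p > 0.05)))
cat("\nEating time alone drives OAC; OAIO isolates attention from the\n")
cat("motor confound. The extended OAIO definition additionally removes\n")
cat("trials following a (correct, omission) pair, where a very long eating\n")
cat("bout can outlast a whole trial, and retains the null almost fully.\n")
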