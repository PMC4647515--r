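#!/usr/bin/env Rscript
# Fit both treatment-effect models to the simulated trial: the Beta-Binomial
# mixed model (odds ratio, no dichotomization) and the repeated-measures
# linear mixed model (mean difference), with matching covariates.

library(qlor)

trial <- read_trial_csv("results/synthetic_trial.csv")
res <- run_pipeline(trial, models = c("BB", "MD"), seed = 20260930L,
                    out_dir = "results/fits")

cat("Per-domain treatment effects (true subject-specific OR = 1.2):\n\n")
print(res$effects, digits = 4)
cat("\nOR band:", as.character(classify_or(res$effects$or)),
    "| MD band:", as.character(classify_md(res$effects$md)), "\n")
cat("\nThe generator's OR of 1.2 is a constant shift of", round(log(1.2), 3),
    "on the logit scale;\nthe corresponding MD depends on where the score",
    "mass sits on the 0-100 scale.\n")
cat("Wrote results/fits/effects.csv and manifest.json\n")
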