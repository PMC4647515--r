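#!/usr/bin/env Rscript
# Distributional screening that motivates the odds-scale analysis: grid
# scores with floor/ceiling mass reject normality decisively and their
# method-of-moments beta shapes fall below 1 (J/U-shaped mass against a
# boundary), so the mean is a poor effect summary.

library(qlor)

dir.create("results", showWarnings = FALSE)

# a skewed symptom domain (grid mode) and a boundary-inflated continuous one
skewed <- generate_trial(sim_config(seed = 20260930L))
inflated <- generate_trial(sim_config(
  domains = list(list(domain = "DI", n_levels = 3L, mu0 = 0.15, or = 1.2,
                      rho = 0.55, sigma_b = 0.5, p0 = 0.20, p1 = 0.03)),
  seed = 20260931L))

rep_ <- rbind(domain_distribution_report(skewed),
              domain_distribution_report(inflated))
print(rep_, digits = 3)
write.csv(rep_, "results/distribution_report.csv", row.names = FALSE)

cat("\nKS (Lilliefors) p-values below 0.001 reject normality;",
    "\nbeta shapes below 1 flag boundary-piled (J/U-shaped) score mass.\n")
cat("Wrote results/distribution_report.csv\n")
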