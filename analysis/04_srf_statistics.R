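#!/usr/bin/env Rscript
# The main simulated-receptive-field analysis: 800 sRFs (200 per diameter
# in 2.5/5/10/15 deg) over the synthetic dataset, with saliency-driven
# fixations, smooth pursuit and vergence.  Produces per-sRF figure/ground
# summaries, one-sample t-tests with Cohen's D, eccentricity ANOVAs with
# eta^2 and Tukey HSD pairs, figure-faster/more-coherent/nearer
# proportions with binomial CIs, probability-ratio curves with bootstrap
# CIs, and the population-decoding table.

library(figround)

cfg <- run_config(params = scene_gen_params(), n_scenes = 40L,
                  n_per_size = 200L, master_seed = 1L,
                  out_dir = "results/analysis/run_default")
res <- run_pipeline(cfg)

sm <- res$summaries
cat(sprintf("Accepted %d sRFs (%d attempts).\n",
            nrow(sm), res$srf_set$attempts))
cat(sprintf(
  "Figure-ground differences: speed %.2f log[deg/s] (t = %.1f, D = %.2f), circular variance %.3f (D = %.2f), disparity %.2f deg (D = %.2f).\n",
  mean(sm$delta_s, na.rm = TRUE), res$tests$delta_s$statistic,
  res$tests$delta_s$effect_size,
  mean(sm$delta_v, na.rm = TRUE), res$tests$delta_v$effect_size,
  mean(sm$delta_d, na.rm = TRUE), res$tests$delta_d$effect_size))
pr <- res$proportions
cat(sprintf(
  "Figure faster in %.0f%% of sRFs (CI %.0f-%.0f%%), more coherent in %.0f%%, nearer in %.0f%%.\n",
  100 * pr$proportion[1], 100 * pr$ci_lo[1], 100 * pr$ci_hi[1],
  100 * pr$proportion[2], 100 * pr$proportion[3]))
cat(sprintf(
  "Eccentricity dependence: speed eta^2 = %.2f (p = %.2g), coherence eta^2 = %.2f, disparity eta^2 = %.2f.\n",
  res$tests$anova_s$effect_size, res$tests$anova_s$p_value,
  res$tests$anova_v$effect_size, res$tests$anova_d$effect_size))
by_ecc <- aggregate(cbind(delta_s, delta_v, delta_d) ~ diameter, sm, mean)
print(by_ecc)
cat("Tables written under", cfg$out_dir, "\n")
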