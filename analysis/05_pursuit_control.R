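#!/usr/bin/env Rscript
# Stationary-eye control: re-run the sRF motion analyses with the smooth
# pursuit simulation removed (the observer fixates but does not track),
# on the same scenes and sRF placements, and compare the motion
# statistics with the pursuit-on run.

library(figround)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg_on <- run_config(params = scene_gen_params(), n_scenes = 40L,
                     n_per_size = 200L, master_seed = 1L)
ds <- generate_dataset(cfg_on$n_scenes, cfg_on$params, cfg_on$seeds$scenes)

run_one <- function(pursuit) {
  ss <- build_srf_set(ds, n_per_size = cfg_on$n_per_size,
                      sizes = cfg_on$sizes, seed = cfg_on$seeds$srf,
                      pursuit_enabled = pursuit)
  summarize_srf_set(ss, ds)
}
sm_on <- run_one(TRUE)
sm_off <- run_one(FALSE)

cmp <- rbind(
  data.frame(pursuit = "on", fg_proportions(sm_on)),
  data.frame(pursuit = "off", fg_proportions(sm_off)))
write.csv(cmp, file.path(out, "pursuit_control.csv"), row.names = FALSE)

p_on <- fg_proportions(sm_on); p_off <- fg_proportions(sm_off)
cat(sprintf(
  "Figure faster: %.0f%% with pursuit vs %.0f%% with a stationary eye.\n",
  100 * p_on$proportion[1], 100 * p_off$proportion[1]))
cat(sprintf(
  "Figure more coherent: %.0f%% vs %.0f%%.\n",
  100 * p_on$proportion[2], 100 * p_off$proportion[2]))
cat(sprintf(
  "Mean speed difference: %.2f vs %.2f log[deg/s] - pursuit shrinks the figure-ground motion contrast rather than creating it.\n",
  mean(sm_on$delta_s, na.rm = TRUE), mean(sm_off$delta_s, na.rm = TRUE)))
ecc_on <- anova_eta(sm_on$delta_s, factor(sm_on$diameter))
ecc_off <- anova_eta(sm_off$delta_s, factor(sm_off$diameter))
cat(sprintf(
  "Eccentricity dependence of the speed difference: eta^2 = %.2f with pursuit, %.2f without.\n",
  ecc_on$effect_size, ecc_off$effect_size))
cat("In these synthetic scenes the eccentricity effect is carried by gaze:\n")
cat("small sRFs sit close to their fixation, which then often tracks the\n")
cat("same figure and stabilises it; world speeds themselves have no\n")
cat("spatial autocorrelation that receptive-field size could pick up.\n")
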