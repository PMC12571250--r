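# figround

Figure-ground statistics of natural-scene motion and distance at the
scale of MT receptive fields.

## The problem

Differentiating figures (objects, people, animals) from the surrounding
ground is a core visual computation.  Neurons in primate area MT show
response biases when two surfaces share one receptive field — bi-speed
responses are pulled toward the faster component, and many MT neurons
prefer near (crossed) disparities.  Those biases would help segregate
figures *if* figures in natural scenes reliably move faster and more
coherently than their surroundings and sit nearer to the observer.

`figround` tests that premise as a fully synthetic, tested pipeline, for
researchers in natural scene statistics and population coding:

1. **Scene model** (`scene_bundle`, `read_bundle`/`write_bundle`) —
   co-registered speed/direction/distance/label/saliency rasters with an
   annotation-border buffer (5 px Chebyshev) and a strict 0.5 deg/s
   motion-validity threshold; TIFF/PNG/JSON container.
2. **Synthetic scenes** (`generate_scene`, `generate_dataset`) —
   annotated scenes with censored slow ground motion, coherent fast
   horizontally-biased figure motion, a receding ground plane with
   nearer figures, a sky band, and a configurable figure-ground
   log-speed offset that is the generator's recoverable ground truth.
3. **Epoch selection** (`smooth_series`, `select_epochs`) — motion-epoch
   picking (onset / peak / offset) from a mean-speed time series.
4. **Gaze simulation** (`fixation_candidates`, `retinal_motion`,
   `binocular_disparity`, `disparity_map`) — saliency median split,
   smooth pursuit by vector subtraction, and the vergence geometry
   `x_R = s/2 − x`, `x_L = −s/2 − x`,
   `θ_{R,L} = atan(x_fix/z_fix) − atan(x_{R,L}/z)`, `d = θ_L − θ_R`
   (crossed positive), with `s = 6.2 cm`.
5. **sRF sampling** (`build_srf_set`) — circular apertures of 2.5–15°
   with the ≤50% invalid / ≥25% figure / ≥25% ground rules and
   eccentricity-matched fixations.
6. **Statistics** (`summarize_srf_set`, `one_sample_t`, `anova_eta`,
   `tukey_pairs`, `ranksum_r`, `rayleigh_test`, `kuiper_two`,
   `binomial_ci`, `ratio_curve`) — per-sRF figure-ground differences in
   mean log10 retinal speed, direction circular variance and disparity;
   tests, effect sizes, and 50-bin figure/ground probability-ratio
   curves with sRF-level bootstrap CIs.
7. **Population model** (`build_population`, `decode`,
   `run_bispeed_experiment`) — 50 Gaussian log-speed-tuned neurons
   (sd 1 log[deg/s]), three bi-speed combination strategies, and a
   response-weighted-average decoder.

The numbered scripts under `analysis/` run these stages as a narrative
workflow and write tidy tables under `results/analysis/`;
`run_pipeline()` does the same in one call.

## Worked example

```r
library(figround)

p  <- scene_gen_params()                   # default study conditions
ds <- generate_dataset(10, p, seed = 1)    # 10 annotated scenes
ss <- build_srf_set(ds, n_per_size = 50, seed = 2)   # 200 sRFs
sm <- summarize_srf_set(ss, ds)

t_s <- one_sample_t(sm$delta_s)
cat(sprintf("mean delta_s = %.2f log[deg/s] (t(%d) = %.1f, D = %.2f)\n",
            mean(sm$delta_s, na.rm = TRUE), t_s$df, t_s$statistic,
            t_s$effect_size))
fg_proportions(sm)[, c("feature", "proportion", "ci_lo", "ci_hi")]
```

```
mean delta_s = 0.88 log[deg/s] (t(199) = 18.7, D = 1.32)
               feature proportion ci_lo ci_hi
1        figure_faster       0.81  0.74  0.86
2 figure_more_coherent       0.74  0.68  0.80
3        figure_nearer       0.97  0.94  0.99
```

Figure regions move on average ~0.9 log10 units (about 7x) faster than
the ground of the same receptive field, are more directionally coherent
in 74% of sRFs, and are nearer (more positive disparity) in 97% — the
three regularities a fast/coherent/near-biased MT population could
exploit.  The population read-out shows the exploit directly:

```r
pop <- build_population()
head(run_bispeed_experiment(pop, seed = 1), 3)
```

```
  stimulus s_f        s_g scale_factor          strategy    decoded interior
1        1 0.1 0.04327543    0.4327543 prioritize_faster 0.10075275     TRUE
2        1 0.1 0.04327543    0.4327543           average 0.06678335     TRUE
3        1 0.1 0.04327543    0.4327543 prioritize_slower 0.04422798     TRUE
```

Prioritizing the faster component decodes the figure speed (0.101 vs
0.1 deg/s); averaging and slow-prioritizing under-report it.

See `vignettes/figure-ground-statistics.Rmd` for the full model
description, parameter rationale, and limitations.

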