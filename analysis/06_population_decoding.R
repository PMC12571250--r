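#!/usr/bin/env Rscript
# Toy MT population model: 50 neurons with Gaussian log-speed tuning
# (sd = 1 log[deg/s]) respond to bi-speed figure/ground stimuli under
# three combination strategies; a response-weighted-average decoder reads
# out the represented speed for eight example stimuli.

library(figround)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pop <- build_population()
tab <- run_bispeed_experiment(pop, seed = 1)
write.csv(tab, file.path(out, "population_decoding.csv"), row.names = FALSE)

spacing <- diff(pop$preferred)[1]
fast <- tab[tab$strategy == "prioritize_faster", ]
cat(sprintf(
  "Population: %d neurons, preferred speeds %.3g-%.3g deg/s, tuning sd %.0f log[deg/s].\n",
  pop$n, 10^min(pop$preferred), 10^max(pop$preferred), pop$sigma))
cat(sprintf(
  "Prioritize-faster decoding error: max %.4f log units (half lattice spacing = %.3f).\n",
  max(abs(log10(fast$decoded) - log10(fast$s_f))), spacing / 2))
for (strat in unique(tab$strategy)) {
  ti <- tab[tab$strategy == strat, ]
  cat(sprintf("  %-18s decoded/figure speed ratio: %.2f-%.2f\n",
              strat, min(ti$decoded / ti$s_f), max(ti$decoded / ti$s_f)))
}
cat("The fast-speed bias recovers the figure's speed; averaging and\n")
cat("slow-bias strategies under-report it by up to the ground scale factor.\n")
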