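#!/usr/bin/env Rscript
# Generate the synthetic inputs of the analysis: length-at-age records for
# the two focal species drawn from the lognormal VBGM observation model,
# and catch-by-length-class data for the two gears (gillnet on the
# piscivore, trawl on the planktivore).

library(atne)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

species <- list(
  pikeperch = list(vbgm = vbgm_params(87, 0.124, 1.7),
                   gear = selectivity_curve(46.72, 3.44, 10000),
                   classes = 16:73, age_max = 12),
  vendace = list(vbgm = vbgm_params(16, 0.555, 0.9),
                 gear = selectivity_curve(12.21, 1.71, 10000),
                 classes = 4:17, age_max = 8))

for (nm in names(species)) {
  sp <- species[[nm]]
  laa <- gen_length_at_age(sp$vbgm, sigma = 0.1, n = 2000, seed = 42,
                           age_max = sp$age_max)
  write_length_at_age(laa, sprintf("results/data/%s_length_at_age.csv", nm))
  peak <- selectivity_eval(sp$gear, sp$gear$mu)
  catch <- gen_catch_by_length(sp$gear, sp$classes,
                               noise_sd = 0.05 * peak, seed = 43)
  write_catch_by_length(catch, sprintf("results/data/%s_catch.csv", nm))
  cat(sprintf(
    "%s: %d length-at-age records (ages %.2f-%.2f, lengths %.1f-%.1f cm), %d catch classes\n",
    nm, nrow(laa), min(laa$fractional_age), max(laa$fractional_age),
    min(laa$length_cm), max(laa$length_cm), nrow(catch)))
}
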