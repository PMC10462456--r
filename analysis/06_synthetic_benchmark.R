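#!/usr/bin/env Rscript
# Step 6: benchmark the richness estimators on synthetic surveys with known
# pool size. Two regimes: a deep-sampling design where estimators should
# recover S_true, and a survey-like shallow design (defaults emulate the
# duckweed survey's 72 samples, 26% empty, ~4.75 isolates/sample) where
# estimators can only bound observed richness from above.
# Writes results/estimator_benchmark.tsv.

suppressPackageStartupMessages(library(duckweedyeast))
dir.create("results", showWarnings = FALSE)

bench <- function(cfg_fn, seeds) {
  t(vapply(seeds, function(seed) {
    tab <- simulate_survey(cfg_fn(seed))$table
    a <- to_abundance(tab)
    m <- to_incidence(tab, "sample")
    c(sobs = a$S, chao1 = chao1(a)$S_est, jack1 = jackknife1(m)$S_est,
      bootstrap = bootstrap_richness(m)$S_est)
  }, numeric(4)))
}

deep_cfg <- function(seed) survey_config(
  S_true = 20, n_samples = 25,
  abundance_model = list(model = "geometric", k = 0.1),
  isolates_per_sample_mean = 50, p_empty_sample = 0, seed = seed
)
shallow_cfg <- function(seed) survey_config(seed = seed) # survey-like defaults

deep <- bench(deep_cfg, 1:20)
shallow <- bench(shallow_cfg, 1:20)

rows <- rbind(
  data.frame(regime = "deep", S_true = 20, t(colMeans(deep))),
  data.frame(regime = "survey_like", S_true = 70, t(colMeans(shallow)))
)
write.table(rows, "results/estimator_benchmark.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(rows, row.names = FALSE)

cat(sprintf(
  "\nDeep regime: mean estimates within %.1f%% of the true 20-taxon pool.\n",
  100 * max(abs(colMeans(deep)[-1] - 20) / 20)
))
cat("Survey-like regime: estimators exceed mean observed richness but cannot\nreach the configured pool size — the geometric tail is effectively\nunsampleable at this effort, mirroring the real survey's unsaturated curve.\n")
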