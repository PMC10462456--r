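#!/usr/bin/env Rscript
# Step 2: alpha diversity and frequency statistics.
#
# The headline indices use the per-sample deduplicated tally (one strain per
# species per sample), standing in for the survey's exclusion of
# identical-sequence isolates before diversity analysis; the raw strain
# tally is reported alongside. Writes results/diversity.json and
# results/per_taxon_frequencies.tsv.

suppressPackageStartupMessages(library(duckweedyeast))
dir.create("results", showWarnings = FALSE)

survey <- read_survey(duckweed_survey_path(), n_samples_collected = 72)
raw <- to_abundance(survey)
dedup <- to_abundance(survey, dedup = "sample")

for (label in c("raw strain tally", "per-sample deduplicated tally")) {
  a <- if (startsWith(label, "raw")) raw else dedup
  cat(sprintf(
    "%s: S = %d, N = %d | H' = %.2f | E_H = %.2f | 1-D = %.2f\n",
    label, a$S, a$N, round_half_up(shannon(a), 2),
    round_half_up(equitability(a), 2), round_half_up(simpson_unbiased(a), 2)
  ))
}

jsonlite::write_json(
  list(raw_tally = unclass(diversity_report(raw)),
       dedup_tally = unclass(diversity_report(dedup))),
  "results/diversity.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)

ft <- frequency_table(survey)
write.table(ft, "results/per_taxon_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nMost prevalent taxa (relative frequency / frequency of occurrence):\n")
print(head(ft, 5), row.names = FALSE)
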