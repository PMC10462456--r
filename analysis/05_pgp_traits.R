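#!/usr/bin/env Rscript
# Step 5: plant-growth-promotion screening summaries for the three assays:
# IAA production (mg/L), siderophore activity units (AU) on CAS agar, and
# phosphate solubilization efficiency (SE) on Pikovskaya's agar.
# Writes results/trait_summary.json.

suppressPackageStartupMessages(library(duckweedyeast))
dir.create("results", showWarnings = FALSE)

survey <- read_survey(duckweed_survey_path(), n_samples_collected = 72)

traits <- c("iaa", "siderophore_au", "phosphate_se")
summaries <- lapply(setNames(traits, traits),
                    function(tr) summarize_trait(survey, tr))
for (s in summaries) {
  print(s)
  print(s$bins, row.names = FALSE)
}
jsonlite::write_json(lapply(summaries, unclass), "results/trait_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

top <- function(tr) {
  v <- survey[[paste0(tr, "_value")]]
  survey$strain_id[which.max(ifelse(is.na(v), -Inf, v))]
}
cat(sprintf(
  "\nTop producers: IAA %s, siderophore %s, phosphate %s.\n",
  top("iaa"), top("siderophore_au"), top("phosphate_se")
))
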