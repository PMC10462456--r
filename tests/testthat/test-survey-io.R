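write_lines_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f, useBytes = TRUE)
  f
}

header <- paste("strain_id", "sample_id", "host_genus", "phylum",
                "taxon_label", "identity_pct", "iaa_mg_per_l",
                "siderophore_au", "phosphate_se", sep = "\t")

test_that("trait-cell dialect parses into the tri-state model", {
  f <- write_lines_tsv(c(
    header,
    "A-1\tA\tLemna\tAscomycota\tCandida sp.\t99.5\t117.07 ± 1.67\t-\tnd",
    "B-1\tB\tWolffia\tBasidiomycota\tPapiliotrema sp.\t\t0\t1.5\t2.13 ± 0.05",
    "C-1\tC\tother\tunknown\tPichia sp.\t97.2\tnd\t2.55 ± 0.45\t0"
  ))
  s <- read_survey(f, n_samples_collected = 3)
  expect_s3_class(s, "survey_table")
  expect_equal(nrow(s), 3)
  expect_equal(length(unique(s$sample_id)), 3)
  # "a ± b" keeps the mean, stores the SD as metadata
  expect_equal(s$iaa_state[1], "measured")
  expect_equal(s$iaa_value[1], 117.07)
  expect_equal(s$iaa_sd[1], 1.67)
  # "-" is a strain that did not grow on the assay plate
  expect_equal(s$siderophore_au_state[1], "no_growth")
  expect_true(is.na(s$siderophore_au_value[1]))
  # "nd" is an unavailable assay; bare numbers are measured means
  expect_equal(s$phosphate_se_state[1], "not_determined")
  expect_equal(s$iaa_value[2], 0)
  expect_equal(s$iaa_state[2], "measured")
  expect_equal(s$phosphate_se_value[2], 2.13)
  expect_true(is.na(s$identity_pct[2]))
})

test_that("schema and validation errors are specific", {
  f <- write_lines_tsv(c(
    paste("strain_id", "sample_id", "host_genus", "phylum", "taxon_label",
          "identity_pct", "iaa_mg_per_l", "siderophore_au", sep = "\t"),
    "A-1\tA\tLemna\tAscomycota\tCandida sp.\t\t0\t0"
  ))
  expect_error(read_survey(f, 1), "phosphate_se")

  dup <- write_lines_tsv(c(
    header,
    "DW1-1\tDW1\tLemna\tAscomycota\tCandida sp.\t\t0\t0\t0",
    "DW1-1\tDW1\tLemna\tAscomycota\tPichia sp.\t\t0\t0\t0"
  ))
  expect_error(read_survey(dup, 1), "duplicate strain_id.*DW1-1")

  bad_id <- write_lines_tsv(c(
    header,
    "A-1\tA\tLemna\tAscomycota\tCandida sp.\t101\t0\t0\t0"
  ))
  expect_error(read_survey(bad_id, 1), "identity_pct.*row.* 1")

  neg <- write_lines_tsv(c(
    header,
    "A-1\tA\tLemna\tAscomycota\tCandida sp.\t\t-3.5\t0\t0"
  ))
  expect_error(read_survey(neg, 1), "negative iaa_value.*row.* 1")

  few <- write_lines_tsv(c(
    header,
    "A-1\tA\tLemna\tAscomycota\tCandida sp.\t\t0\t0\t0",
    "B-1\tB\tLemna\tAscomycota\tCandida sp.\t\t0\t0\t0"
  ))
  expect_error(read_survey(few, 1), "n_samples_collected")
})

test_that("written surveys re-parse to an identical table", {
  s <- inventory()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_survey(s, f)
  s2 <- read_survey(f, n_samples_collected = 72)
  expect_equal(s2, s)

  sim <- simulate_survey(survey_config(n_samples = 12, seed = 42))$table
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_survey(sim, f2)
  sim2 <- read_survey(f2, n_samples_collected = n_samples_collected(sim))
  expect_equal(sim2, sim, ignore_attr = "row.names")
})

test_that("abundance tallies count strains per taxon and respect scope", {
  s <- inventory()
  a <- to_abundance(s)
  expect_equal(a$S, 58)
  expect_equal(a$N, 252)
  expect_equal(sum(a$counts), nrow(s))

  # counts sum to records in scope for every host-genus subset
  for (g in unique(s$host_genus)) {
    ag <- to_abundance(s, host_genus = g)
    expect_equal(ag$N, sum(s$host_genus == g))
  }
  expect_equal(to_abundance(s, host_genus = "Wolffia")$N, 10)
  expect_error(to_abundance(s, host_genus = "other"), "empty scope")

  one <- tiny_survey("Candida sp.")
  expect_equal(unname(to_abundance(one)$counts), 1L)

  # per-sample dedup counts unique taxon-sample occurrences
  ad <- to_abundance(s, dedup = "sample")
  expect_equal(ad$N, nrow(unique(s[, c("sample_id", "taxon_label")])))
  expect_equal(ad$S, 58)
})

test_that("incidence matrices are binary, occupied, and bounded by abundance", {
  same <- tiny_survey(c("A", "B", "A", "B"), sample = c("s1", "s1", "s2", "s2"))
  m0 <- to_incidence(same)
  expect_equal(unname(m0["s1", ]), unname(m0["s2", ]))

  s <- inventory()
  m <- to_incidence(s, "sample")
  expect_equal(dim(m), c(53, 58))
  expect_true(all(m %in% 0:1))
  expect_true(all(rowSums(m) >= 1))
  expect_equal(sum(m[, "Papiliotrema laurentii"]), 18)

  mg <- to_incidence(s, "host_genus")
  expect_equal(nrow(mg), 4)

  # presence cannot exceed strain count
  a <- to_abundance(s)
  expect_true(all(colSums(m)[names(a$counts)] <= a$counts))
})

test_that("the packaged inventory reflects the published survey structure", {
  s <- inventory()
  expect_equal(n_samples_collected(s), 72)
  # per-genus strain totals: 183/36/23/10 for Lemna/Spirodela/Landotia/Wolffia
  tot <- tapply(s$strain_id, s$host_genus, length)
  expect_equal(as.vector(tot[c("Lemna", "Spirodela", "Landotia", "Wolffia")]),
               c(183, 36, 23, 10))
  # per-genus sample counts: 33/9/8/3
  ns <- tapply(s$sample_id, s$host_genus, function(x) length(unique(x)))
  expect_equal(as.vector(ns[c("Lemna", "Spirodela", "Landotia", "Wolffia")]),
               c(33, 9, 8, 3))
  # 139 ascomycete strains, the two ubiquitous species on all four genera
  expect_equal(sum(s$phylum == "Ascomycota"), 139)
  for (sp in c("Papiliotrema laurentii", "Crinitomyces flavificans")) {
    expect_setequal(unique(s$host_genus[s$taxon_label == sp]),
                    c("Landotia", "Lemna", "Spirodela", "Wolffia"))
  }
})
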