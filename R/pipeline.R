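#' Run the full survey analysis end-to-end
#'
#' Orchestrates every stage over one survey and writes a reproducible report
#' bundle: the alpha-diversity report (both the raw strain tally and the
#' per-sample deduplicated tally used for the headline indices), the
#' per-taxon frequency table, the three richness estimators with their
#' components, the sample-based accumulation curve, the Jaccard distance
#' matrix with its PCoA, the three trait summaries, and a manifest mapping
#' every output file to the stage that produced it. Outputs are TSV/JSON
#' only, carry no timestamps, and are byte-identical across re-runs with the
#' same inputs and seed.
#'
#' @param input A [survey_table], or a path to a survey TSV.
#' @param n_samples_collected Required when `input` is a path.
#' @param out_dir Output directory (created if needed).
#' @param grouping Ordination grouping, `"sample"` (default) or
#'   `"host_genus"`.
#' @param n_permutations Sample orderings for the accumulation curve.
#' @param seed Integer seed for the permutation stream.
#' @param chao1_variant Passed to [chao1()] and [accumulation_curve()].
#' @param rounding `"full"` (full precision, default) or `"display"`
#'   (half-up rounding: indices to 2 dp, percentages to 1 dp).
#' @return The manifest, invisibly (list also written as
#'   `manifest.json`).
#' @export
run_all <- function(input, n_samples_collected = NULL, out_dir,
                    grouping = c("sample", "host_genus"),
                    n_permutations = 100, seed = 1,
                    chao1_variant = c("bias_corrected", "classic"),
                    rounding = c("full", "display")) {
  grouping <- match.arg(grouping)
  chao1_variant <- match.arg(chao1_variant)
  rounding <- match.arg(rounding)
  survey <- if (inherits(input, "survey_table")) {
    input
  } else {
    if (is.null(n_samples_collected)) {
      stop("n_samples_collected is required when reading from a path",
           call. = FALSE)
    }
    read_survey(input, n_samples_collected)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  idx <- if (rounding == "display") function(v) round_half_up(v, 2) else identity
  pct <- if (rounding == "display") function(v) round_half_up(v, 1) else identity
  wjson <- function(obj, file) {
    jsonlite::write_json(obj, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  wtsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # diversity on both tallies; the deduplicated one is the headline route
  a_raw <- to_abundance(survey)
  a_dedup <- to_abundance(survey, dedup = "sample")
  div <- list(
    raw_tally = report_list(diversity_report(a_raw), idx),
    dedup_tally = report_list(diversity_report(a_dedup), idx)
  )
  wjson(div, "diversity.json")

  freq <- frequency_table(survey)
  freq$rf_pct <- pct(freq$rf_pct)
  freq$fo_pct <- pct(freq$fo_pct)
  wtsv(freq, "per_taxon_frequencies.tsv")

  m <- to_incidence(survey, "sample")
  est <- list(
    chao1 = unclass(chao1(a_raw, variant = chao1_variant)),
    jack1 = unclass(jackknife1(m)),
    bootstrap = unclass(bootstrap_richness(m))
  )
  wjson(est, "richness.json")

  curve <- accumulation_curve(survey, n_permutations = n_permutations,
                              seed = seed, chao1_variant = chao1_variant)
  wtsv(curve[, c("t", "sobs_mean", "sobs_sd", "chao1_mean", "jack1_mean",
                 "bootstrap_mean")], "accumulation.tsv")

  ordn <- ordinate_survey(survey, grouping = grouping)
  dmat <- as.data.frame(unclass(ordn$distance))
  wtsv(cbind(group = rownames(dmat), dmat), "jaccard_distance.tsv")
  wtsv(ordn$scores, "ordination.tsv")
  wjson(list(eigenvalues = ordn$ordination$eigenvalues,
             explained = ordn$ordination$explained),
        "ordination_eigenvalues.json")

  traits <- lapply(stats::setNames(SURVEY_TRAITS, SURVEY_TRAITS),
                   function(tr) unclass(summarize_trait(survey, tr)))
  wjson(traits, "trait_summary.json")

  manifest <- list(
    package = "duckweedyeast",
    version = as.character(utils::packageVersion("duckweedyeast")),
    seed = seed,
    n_permutations = n_permutations,
    grouping = grouping,
    chao1_variant = chao1_variant,
    rounding = rounding,
    n_samples_collected = n_samples_collected(survey),
    n_strains = nrow(survey),
    n_taxa = a_raw$S,
    outputs = list(
      diversity.json = "diversity_metrics",
      per_taxon_frequencies.tsv = "diversity_metrics",
      richness.json = "richness_estimators",
      accumulation.tsv = "richness_estimators",
      jaccard_distance.tsv = "ordination",
      ordination.tsv = "ordination",
      ordination_eigenvalues.json = "ordination",
      trait_summary.json = "pgp_traits"
    )
  )
  wjson(manifest, "manifest.json")
  invisible(manifest)
}

report_list <- function(rep, f) {
  list(H_prime = f(rep$H_prime), E_H = f(rep$E_H),
       simpson_1_minus_D = f(rep$simpson_1_minus_D), S = rep$S, N = rep$N)
}
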