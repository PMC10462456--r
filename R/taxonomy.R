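#' Sequence-identity thresholds for rank assignment
#'
#' Threshold set for assigning taxonomic rank from percent identity of the
#' D1/D2 LSU rRNA barcode to the closest type strain. Defaults are the
#' study's calibrated cutoffs: species level at 99.41% (Ascomycota) or
#' 99.51% (Basidiomycota), genus level at 97.11% for either phylum. All
#' comparisons are inclusive (>=): 97.11% identity is genus-level, the band
#' endpoints belong to the band.
#'
#' @param species_asco Species-level cutoff for ascomycetous yeasts (percent).
#' @param species_basidio Species-level cutoff for basidiomycetous yeasts.
#' @param genus_any Genus-level cutoff for either phylum; must be below both
#'   species cutoffs.
#' @return A list of class `threshold_set`.
#' @export
threshold_set <- function(species_asco = 99.41, species_basidio = 99.51,
                          genus_any = 97.11) {
  vals <- c(species_asco = species_asco, species_basidio = species_basidio,
            genus_any = genus_any)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(vals > 100)) {
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  }
  if (genus_any >= species_asco || genus_any >= species_basidio) {
    stop("genus_any must be below both species-level thresholds", call. = FALSE)
  }
  structure(as.list(vals), class = "threshold_set")
}

#' Assign taxonomic rank from sequence identity
#'
#' Applies the inclusive threshold rule per isolate: `species` when the
#' identity meets the phylum-specific species cutoff, otherwise `genus` when
#' it meets the shared genus cutoff, otherwise `unplaced`. Raising the
#' identity can never demote the rank. The reported `threshold_used` is the
#' cutoff the identity was last compared against (the species cutoff for a
#' species call, the genus cutoff otherwise).
#'
#' @param phylum Character vector, `"Ascomycota"` or `"Basidiomycota"` (an
#'   unknown phylum is an error: supply the phylum before ranking).
#' @param identity_pct Numeric vector of percent identities in \[0, 100\].
#' @param thresholds A [threshold_set()].
#' @return Data frame with one row per input: `rank` (ordered factor
#'   `unplaced < genus < species`) and `threshold_used`.
#' @examples
#' assign_rank("Ascomycota", 99.41)$rank    # species (inclusive boundary)
#' assign_rank("Basidiomycota", 99.45)$rank # genus
#' @export
assign_rank <- function(phylum, identity_pct, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  n <- max(length(phylum), length(identity_pct))
  phylum <- rep_len(phylum, n)
  identity_pct <- rep_len(identity_pct, n)
  bad_phy <- !phylum %in% c("Ascomycota", "Basidiomycota")
  if (any(bad_phy)) {
    stop("unknown phylum at position(s) ",
         paste(which(bad_phy), collapse = ", "),
         ": supply the phylum (Ascomycota or Basidiomycota) before ranking",
         call. = FALSE)
  }
  if (any(is.na(identity_pct)) || any(identity_pct < 0 | identity_pct > 100)) {
    stop("identity_pct must lie in [0, 100]", call. = FALSE)
  }
  sp_thr <- ifelse(phylum == "Ascomycota",
                   thresholds$species_asco, thresholds$species_basidio)
  rank <- ifelse(identity_pct >= sp_thr, "species",
                 ifelse(identity_pct >= thresholds$genus_any, "genus",
                        "unplaced"))
  data.frame(
    rank = factor(rank, levels = c("unplaced", "genus", "species"),
                  ordered = TRUE),
    threshold_used = ifelse(rank == "species", sp_thr, thresholds$genus_any)
  )
}
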