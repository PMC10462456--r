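#' Plate-assay activity ratio
#'
#' The dimensionless zone-to-colony diameter ratio used by both plate
#' screens: siderophore activity units (AU) are the orange-halo diameter on
#' Chrome-Azurol S agar over the colony diameter, and phosphate
#' solubilization efficiency (SE) is the clear-zone diameter on Pikovskaya's
#' agar over the colony diameter. An absent zone is not a ratio: the caller
#' records a measured value of 0 instead.
#'
#' @param zone_diam Zone (halo or clear-zone) diameter in mm, > 0.
#' @param colony_diam Colony diameter in mm, > 0.
#' @return `zone_diam / colony_diam` (vectorised).
#' @examples
#' activity_ratio(10, 5) # 2
#' @export
activity_ratio <- function(zone_diam, colony_diam) {
  if (any(!is.finite(colony_diam)) || any(colony_diam <= 0)) {
    stop("colony_diam must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(zone_diam)) || any(zone_diam <= 0)) {
    stop("zone_diam must be strictly positive (record an absent zone as a ",
         "measured value of 0, not a ratio)", call. = FALSE)
  }
  zone_diam / colony_diam
}

# default bin edges per trait, matching the reported screening ranges:
# IAA mg/L in [0,50), [50,100), [100,Inf); AU in [0,2), [2,Inf);
# SE in [0,1), [1,Inf). Left-closed on observed producer values.
default_bin_edges <- function(trait) {
  switch(trait,
    iaa = c(0, 50, 100, Inf),
    siderophore_au = c(0, 2, Inf),
    phosphate_se = c(0, 1, Inf),
    stop("unknown trait: ", trait, call. = FALSE)
  )
}

#' Summarise a plant-growth-promotion trait over a survey
#'
#' A *producer* is a strain whose measured mean value is strictly positive;
#' strains measured at exactly 0 are assayed non-producers, and `no_growth` /
#' `not_determined` strains are excluded from both counts. The four state
#' counts always partition the table. Producers are binned by value into
#' left-closed intervals over `bin_edges`; the reported `min_positive` and
#' `max_value` are over producers only.
#'
#' @param x A [survey_table].
#' @param trait One of `"iaa"`, `"siderophore_au"`, `"phosphate_se"`.
#' @param bin_edges Strictly increasing numeric vector of bin edges
#'   (defaults per trait: 0/50/100/Inf for IAA, 0/2/Inf for AU, 0/1/Inf
#'   for SE).
#' @return A `trait_summary`: list with `trait`, `n_producers`,
#'   `min_positive`, `max_value`, `bins` (data frame of `label`, `count`),
#'   `n_zero`, `n_no_growth`, `n_not_determined`, `n_total`.
#' @examples
#' path <- system.file("extdata", "duckweed_yeast_survey.tsv",
#'                     package = "duckweedyeast")
#' survey <- read_survey(path, n_samples_collected = 72)
#' summarize_trait(survey, "iaa")$n_producers # 178
#' @export
summarize_trait <- function(x, trait, bin_edges = NULL) {
  stopifnot(inherits(x, "survey_table"))
  if (length(trait) != 1L || !trait %in% SURVEY_TRAITS) {
    stop("unknown trait: ", paste(trait, collapse = ", "),
         " (expected one of ", paste(SURVEY_TRAITS, collapse = ", "), ")",
         call. = FALSE)
  }
  bin_edges <- bin_edges %||% default_bin_edges(trait)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing with at least two edges",
         call. = FALSE)
  }
  state <- x[[paste0(trait, "_state")]]
  value <- x[[paste0(trait, "_value")]]
  producer <- state == "measured" & value > 0
  vals <- value[producer]
  labels <- paste0("[", bin_edges[-length(bin_edges)], ",",
                   bin_edges[-1L], ")")
  counts <- if (length(vals) > 0L) {
    as.integer(table(cut(vals, breaks = bin_edges, right = FALSE,
                         include.lowest = FALSE, labels = labels)))
  } else {
    integer(length(labels))
  }
  structure(
    list(
      trait = trait,
      n_producers = sum(producer),
      min_positive = if (length(vals)) min(vals) else NA_real_,
      max_value = if (length(vals)) max(vals) else NA_real_,
      bins = data.frame(label = labels, count = counts,
                        stringsAsFactors = FALSE),
      n_zero = sum(state == "measured" & value == 0),
      n_no_growth = sum(state == "no_growth"),
      n_not_determined = sum(state == "not_determined"),
      n_total = nrow(x)
    ),
    class = "trait_summary"
  )
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf(
    "<trait_summary> %s: %d producers (%.2f-%.2f), %d zero, %d no-growth, %d not determined of %d\n",
    x$trait, x$n_producers, x$min_positive, x$max_value,
    x$n_zero, x$n_no_growth, x$n_not_determined, x$n_total
  ))
  invisible(x)
}

#' Per-strain activity ratios from plate diameters
#'
#' When the optional diameter columns (`halo_diam_mm` / `colony_diam_mm_cas`
#' for the CAS siderophore screen, `clearzone_diam_mm` /
#' `colony_diam_mm_pvk` for the Pikovskaya phosphate screen) are present,
#' computes the per-strain activity ratios for the strains where both
#' diameters of a pair are recorded.
#'
#' @param x A [survey_table] carrying at least one diameter-column pair.
#' @return Data frame with `strain_id` and any of `siderophore_au_ratio`,
#'   `phosphate_se_ratio` (NA where diameters are absent).
#' @export
zone_ratios <- function(x) {
  stopifnot(inherits(x, "survey_table"))
  pairs <- list(
    siderophore_au_ratio = c("halo_diam_mm", "colony_diam_mm_cas"),
    phosphate_se_ratio = c("clearzone_diam_mm", "colony_diam_mm_pvk")
  )
  out <- data.frame(strain_id = x$strain_id, stringsAsFactors = FALSE)
  found <- FALSE
  for (nm in names(pairs)) {
    cols <- pairs[[nm]]
    if (all(cols %in% names(x))) {
      found <- TRUE
      zone <- x[[cols[1L]]]
      colony <- x[[cols[2L]]]
      ok <- !is.na(zone) & !is.na(colony)
      r <- rep(NA_real_, nrow(x))
      if (any(ok)) r[ok] <- activity_ratio(zone[ok], colony[ok])
      out[[nm]] <- r
    }
  }
  if (!found) {
    stop("no plate-diameter column pairs present in this survey", call. = FALSE)
  }
  out
}
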