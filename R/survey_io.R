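#' @name survey_table
#' @title The isolate-survey data model
#'
#' @description
#' A `survey_table` is the single source of truth for a culture-based isolate
#' survey: a validated data frame with one row per isolated strain. Columns:
#'
#' * `strain_id` -- unique strain code (e.g. `"DWEN59-3"`).
#' * `sample_id` -- the environmental sample the strain was isolated from.
#' * `host_genus` -- host plant genus (`Landotia`, `Lemna`, `Spirodela`,
#'   `Wolffia`, or `other`).
#' * `phylum` -- `Ascomycota`, `Basidiomycota`, or `unknown`.
#' * `taxon_label` -- species name or genus-level label such as
#'   `"Candida sp. group 1"`. Taxon identity is the exact label string; no
#'   normalisation is attempted, so distinct labels are distinct taxa.
#' * `identity_pct` -- optional D1/D2 percent identity to the closest type
#'   strain, in \[0, 100\].
#' * per assay trait (`iaa`, `siderophore_au`, `phosphate_se`), three columns:
#'   `<trait>_state` (one of `"measured"`, `"no_growth"`, `"not_determined"`),
#'   `<trait>_value` (non-negative mean, present iff measured), and
#'   `<trait>_sd` (replicate SD metadata, never used by any statistic).
#'
#' A measured value of exactly 0 means "assayed, no activity" and is distinct
#' from both `no_growth` (strain failed to grow on the assay plate) and
#' `not_determined` (assay not available).
#'
#' The number of samples *collected* (including samples that yielded no
#' isolates and therefore have no rows) is carried as the attribute
#' `n_samples_collected`; it is supplied by the caller, never inferred,
#' and is the denominator for frequency of occurrence.
NULL

SURVEY_TRAITS <- c("iaa", "siderophore_au", "phosphate_se")

# TSV column name for each trait
.trait_columns <- c(
  iaa = "iaa_mg_per_l",
  siderophore_au = "siderophore_au",
  phosphate_se = "phosphate_se"
)

REQUIRED_COLUMNS <- c(
  "strain_id", "sample_id", "host_genus", "phylum", "taxon_label",
  "identity_pct", unname(.trait_columns)
)

HOST_GENERA <- c("Landotia", "Lemna", "Spirodela", "Wolffia", "other")
TRAIT_STATES <- c("measured", "no_growth", "not_determined")

# Parse one vector of trait cells in the survey dialect:
#   "nd" -> not_determined, "-" -> no_growth, "a" or "a ± b" -> measured.
# Returns a data.frame with state/value/sd.
parse_trait_cells <- function(cells, column) {
  cells <- trimws(cells)
  state <- rep("measured", length(cells))
  value <- rep(NA_real_, length(cells))
  sdev <- rep(NA_real_, length(cells))
  state[cells == "nd"] <- "not_determined"
  state[cells == "-"] <- "no_growth"
  meas <- state == "measured"
  if (any(meas)) {
    parts <- strsplit(cells[meas], "±", fixed = TRUE)
    a <- suppressWarnings(as.numeric(trimws(vapply(parts, `[`, "", 1L))))
    b <- suppressWarnings(as.numeric(trimws(vapply(
      parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, ""
    ))))
    bad <- is.na(a)
    if (any(bad)) {
      stop(sprintf(
        "column '%s': unparseable trait cell(s) at row(s) %s (expected a number, 'a ± b', 'nd' or '-')",
        column, paste(which(meas)[bad], collapse = ", ")
      ), call. = FALSE)
    }
    value[meas] <- a
    sdev[meas] <- b
  }
  data.frame(state = state, value = value, sd = sdev)
}

# Re-encode state/value/sd triples into the dialect.
format_trait_cells <- function(state, value, sdev) {
  out <- character(length(state))
  out[state == "not_determined"] <- "nd"
  out[state == "no_growth"] <- "-"
  meas <- state == "measured"
  num <- function(x) format(x, trim = TRUE, scientific = FALSE)
  has_sd <- meas & !is.na(sdev)
  out[meas & !has_sd] <- num(value[meas & !has_sd])
  out[has_sd] <- paste(num(value[has_sd]), "±", num(sdev[has_sd]))
  out
}

#' Read an isolate survey table
#'
#' Parses the tab-separated survey format (header row naming the required
#' columns) into a validated [survey_table]. Trait cells follow the survey
#' dialect: `"nd"` becomes `not_determined`, `"-"` becomes `no_growth`, and a
#' numeric cell or `"a ± b"` becomes a `measured` value `a` (the
#' replicate SD `b` is retained as metadata only).
#'
#' @param path Path to the delimited file.
#' @param n_samples_collected Total number of samples collected in the survey,
#'   including samples that yielded no isolates. Must be at least the number
#'   of distinct `sample_id` values in the file.
#' @param sep Field separator; tab by default, use `","` for CSV input.
#' @return A validated [survey_table].
#' @seealso [write_survey()], [to_abundance()], [to_incidence()]
#' @examples
#' path <- system.file("extdata", "duckweed_yeast_survey.tsv",
#'                     package = "duckweedyeast")
#' survey <- read_survey(path, n_samples_collected = 72)
#' nrow(survey) # 252 strains
#' @export
read_survey <- function(path, n_samples_collected, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = sep, colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    strain_id = trimws(raw$strain_id),
    sample_id = trimws(raw$sample_id),
    host_genus = trimws(raw$host_genus),
    phylum = trimws(raw$phylum),
    taxon_label = trimws(raw$taxon_label),
    identity_pct = suppressWarnings(as.numeric(ifelse(
      trimws(raw$identity_pct) == "", NA, trimws(raw$identity_pct)
    ))),
    stringsAsFactors = FALSE
  )
  for (tr in SURVEY_TRAITS) {
    parsed <- parse_trait_cells(raw[[.trait_columns[[tr]]]], .trait_columns[[tr]])
    out[[paste0(tr, "_state")]] <- parsed$state
    out[[paste0(tr, "_value")]] <- parsed$value
    out[[paste0(tr, "_sd")]] <- parsed$sd
  }
  # optional plate-diameter columns pass through as numerics
  optional <- c("halo_diam_mm", "colony_diam_mm_cas",
                "clearzone_diam_mm", "colony_diam_mm_pvk")
  for (col in intersect(optional, names(raw))) {
    out[[col]] <- suppressWarnings(as.numeric(ifelse(
      trimws(raw[[col]]) == "", NA, trimws(raw[[col]])
    )))
  }
  survey_table(out, n_samples_collected = n_samples_collected)
}

#' Construct and validate a survey table
#'
#' Validates the survey invariants (unique non-empty strain IDs, non-empty
#' sample IDs and taxon labels, identity percentages in \[0, 100\], trait
#' values present exactly when measured and non-negative) and attaches the
#' `n_samples_collected` attribute.
#'
#' @param records Data frame of per-isolate records (see [survey_table]).
#' @param n_samples_collected Positive integer, at least the number of
#'   distinct sample IDs.
#' @return The validated `survey_table`.
#' @export
survey_table <- function(records, n_samples_collected) {
  stopifnot(is.data.frame(records))
  n_samples_collected <- as.integer(n_samples_collected)
  if (length(n_samples_collected) != 1L || is.na(n_samples_collected) ||
      n_samples_collected < 1L) {
    stop("n_samples_collected must be a single positive integer", call. = FALSE)
  }
  if (any(records$strain_id == "")) {
    stop("validation error: empty strain_id at row(s) ",
         paste(which(records$strain_id == ""), collapse = ", "), call. = FALSE)
  }
  dup <- unique(records$strain_id[duplicated(records$strain_id)])
  if (length(dup) > 0L) {
    stop("validation error: duplicate strain_id: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(records$sample_id == "")) {
    stop("validation error: empty sample_id at row(s) ",
         paste(which(records$sample_id == ""), collapse = ", "), call. = FALSE)
  }
  if (any(records$taxon_label == "")) {
    stop("validation error: empty taxon_label at row(s) ",
         paste(which(records$taxon_label == ""), collapse = ", "), call. = FALSE)
  }
  bad_genus <- !records$host_genus %in% HOST_GENERA
  if (any(bad_genus)) {
    stop("validation error: unknown host_genus at row(s) ",
         paste(which(bad_genus), collapse = ", "),
         " (expected one of ", paste(HOST_GENERA, collapse = ", "), ")",
         call. = FALSE)
  }
  bad_phy <- !records$phylum %in% c("Ascomycota", "Basidiomycota", "unknown")
  if (any(bad_phy)) {
    stop("validation error: unknown phylum at row(s) ",
         paste(which(bad_phy), collapse = ", "), call. = FALSE)
  }
  id <- records$identity_pct
  bad_id <- !is.na(id) & (id < 0 | id > 100)
  if (any(bad_id)) {
    stop("range error: identity_pct outside [0, 100] at row(s) ",
         paste(which(bad_id), collapse = ", "), call. = FALSE)
  }
  for (tr in SURVEY_TRAITS) {
    st <- records[[paste0(tr, "_state")]]
    v <- records[[paste0(tr, "_value")]]
    if (!all(st %in% TRAIT_STATES)) {
      stop("validation error: invalid ", tr, "_state", call. = FALSE)
    }
    if (any(st == "measured" & is.na(v)) || any(st != "measured" & !is.na(v))) {
      stop("validation error: ", tr,
           "_value must be present exactly when state is 'measured'",
           call. = FALSE)
    }
    bad_v <- st == "measured" & v < 0
    if (any(bad_v)) {
      stop("range error: negative ", tr, "_value at row(s) ",
           paste(which(bad_v), collapse = ", "), call. = FALSE)
    }
  }
  n_samples_observed <- length(unique(records$sample_id))
  if (n_samples_collected < n_samples_observed) {
    stop("n_samples_collected (", n_samples_collected,
         ") is below the number of distinct sample_id values (",
         n_samples_observed, ")", call. = FALSE)
  }
  structure(records,
            n_samples_collected = n_samples_collected,
            class = c("survey_table", "data.frame"))
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf(
    "<survey_table> %d strains | %d taxa | %d samples with isolates of %d collected\n",
    nrow(x), length(unique(x$taxon_label)), length(unique(x$sample_id)),
    attr(x, "n_samples_collected")
  ))
  invisible(x)
}

#' Number of samples collected in a survey
#'
#' @param x A [survey_table].
#' @return Integer count of samples collected (including isolate-free ones).
#' @export
n_samples_collected <- function(x) {
  stopifnot(inherits(x, "survey_table"))
  attr(x, "n_samples_collected")
}

#' Write a survey table
#'
#' Emits the same tab-separated schema that [read_survey()] consumes,
#' re-encoding trait states into the survey dialect, so that a written table
#' re-parses to an identical `survey_table`.
#'
#' @param x A [survey_table].
#' @param path Output file path.
#' @param sep Field separator (tab by default).
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "survey_table"))
  out <- data.frame(
    strain_id = x$strain_id,
    sample_id = x$sample_id,
    host_genus = x$host_genus,
    phylum = x$phylum,
    taxon_label = x$taxon_label,
    identity_pct = ifelse(is.na(x$identity_pct), "",
                          format(x$identity_pct, trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  for (tr in SURVEY_TRAITS) {
    out[[.trait_columns[[tr]]]] <- format_trait_cells(
      x[[paste0(tr, "_state")]], x[[paste0(tr, "_value")]], x[[paste0(tr, "_sd")]]
    )
  }
  optional <- c("halo_diam_mm", "colony_diam_mm_cas",
                "clearzone_diam_mm", "colony_diam_mm_pvk")
  for (col in intersect(optional, names(x))) out[[col]] <- x[[col]]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Tally strains per taxon
#'
#' Collapses a survey to an [abundance_vector]: one count per distinct
#' `taxon_label`. With the default `dedup = "none"` every strain counts once,
#' so the counts sum to the number of records in scope. `dedup = "sample"`
#' instead counts at most one strain per taxon per sample: this is the
#' inventory-level proxy for the survey's stated exclusion of isolates with
#' identical barcode sequences before diversity and richness analysis
#' (conspecific isolates from the same sample are the likeliest sequence
#' duplicates), and is the tally used by the headline diversity report.
#'
#' @param x A [survey_table].
#' @param host_genus Optional host genus to subset to before tallying.
#' @param dedup `"none"` (raw strain counts) or `"sample"` (unique
#'   taxon-sample occurrences).
#' @return An [abundance_vector].
#' @examples
#' path <- system.file("extdata", "duckweed_yeast_survey.tsv",
#'                     package = "duckweedyeast")
#' survey <- read_survey(path, n_samples_collected = 72)
#' a <- to_abundance(survey)
#' a$S # 58 taxa
#' a$N # 252 strains
#' @export
to_abundance <- function(x, host_genus = NULL, dedup = c("none", "sample")) {
  stopifnot(inherits(x, "survey_table"))
  dedup <- match.arg(dedup)
  if (!is.null(host_genus)) {
    keep <- x$host_genus == host_genus
    if (!any(keep)) {
      stop("empty scope: no records with host_genus '", host_genus, "'",
           call. = FALSE)
    }
    x <- x[keep, , drop = FALSE]
  }
  if (dedup == "sample") {
    x <- x[!duplicated(x[, c("sample_id", "taxon_label")]), , drop = FALSE]
  }
  # counts in first-appearance order of taxa
  taxa <- unique(x$taxon_label)
  counts <- vapply(taxa, function(t) sum(x$taxon_label == t), 0L)
  abundance_vector(counts)
}

#' Build a sample-by-taxon (or genus-by-taxon) incidence matrix
#'
#' @param x A [survey_table].
#' @param grouping `"sample"` for one row per sample with isolates, or
#'   `"host_genus"` for one row per host genus with isolates. Rows appear in
#'   first-appearance order; every row has at least one presence.
#' @return An `incidence_matrix`: a 0/1 matrix, rows = groups, cols = taxa.
#' @examples
#' path <- system.file("extdata", "duckweed_yeast_survey.tsv",
#'                     package = "duckweedyeast")
#' survey <- read_survey(path, n_samples_collected = 72)
#' m <- to_incidence(survey)
#' dim(m) # 53 samples x 58 taxa
#' @export
to_incidence <- function(x, grouping = c("sample", "host_genus")) {
  stopifnot(inherits(x, "survey_table"))
  grouping <- match.arg(grouping)
  key <- if (grouping == "sample") x$sample_id else x$host_genus
  groups <- unique(key)
  taxa <- unique(x$taxon_label)
  m <- matrix(0L, nrow = length(groups), ncol = length(taxa),
              dimnames = list(groups, taxa))
  m[cbind(match(key, groups), match(x$taxon_label, taxa))] <- 1L
  incidence_matrix(m)
}

#' Construct a validated incidence matrix
#'
#' @param m A 0/1 matrix with row (group) and column (taxon) names. All-zero
#'   rows or columns are rejected: a group in the matrix must have yielded at
#'   least one taxon and every retained taxon must occur somewhere.
#' @return The matrix with class `incidence_matrix`.
#' @export
incidence_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (!all(m %in% c(0L, 1L))) stop("incidence cells must be 0/1", call. = FALSE)
  if (any(rowSums(m) == 0)) stop("incidence matrix has an all-zero row", call. = FALSE)
  if (any(colSums(m) == 0)) stop("incidence matrix has an all-zero column", call. = FALSE)
  storage.mode(m) <- "integer"
  structure(m, class = c("incidence_matrix", "matrix", "array"))
}

#' Path to the packaged duckweed yeast survey inventory
#'
#' The packaged fixture transcribes the published inventory of 252 yeast
#' strains isolated from 53 duckweed samples (out of 72 collected) in
#' Thailand: strain code, source sample, phylum, taxon label (58 taxa,
#' genus-level isolates kept as their own `sp.`/`sp. group` labels), and the
#' three plant-growth-promotion assays (IAA in mg/L, siderophore AU,
#' phosphate SE) in the `"a ± b"` dialect. Sample IDs are derived from
#' strain codes (code minus the trailing `-<n>`). The `host_genus` column is
#' a *reconstruction*: per-strain host genera are not published, so the 53
#' samples were partitioned to match the published per-genus totals
#' (33/9/8/3 Lemna/Spirodela/Landotia/Wolffia samples carrying 183/36/23/10
#' strains, with the two ubiquitous species present on all four genera).
#' Analyses that do not group by host genus are unaffected by this
#' reconstruction.
#'
#' @return Path to the TSV file.
#' @export
duckweed_survey_path <- function() {
  system.file("extdata", "duckweed_yeast_survey.tsv",
              package = "duckweedyeast", mustWork = TRUE)
}
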