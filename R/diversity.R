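#' Construct an abundance vector
#'
#' An `abundance_vector` holds per-taxon strain counts \eqn{n_i} together
#' with the derived totals used throughout the diversity and richness
#' statistics: \eqn{N = \sum n_i}, the number of taxa \eqn{S}, and the
#' proportions \eqn{P_i = n_i / N}.
#'
#' @param counts Named vector of positive integer counts, one per taxon.
#' @return A list with elements `counts`, `N`, `S`, `P`, of class
#'   `abundance_vector`.
#' @export
abundance_vector <- function(counts) {
  if (length(counts) == 0L) stop("empty abundance vector", call. = FALSE)
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("abundance counts must be named by taxon", call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate taxon names in abundance vector", call. = FALSE)
  }
  n <- as.integer(counts)
  if (any(is.na(n)) || any(n < 1L) || any(abs(counts - n) > 0)) {
    stop("abundance counts must be positive integers", call. = FALSE)
  }
  names(n) <- names(counts)
  structure(
    list(counts = n, N = sum(n), S = length(n), P = n / sum(n)),
    class = "abundance_vector"
  )
}

as_abundance <- function(a) {
  if (inherits(a, "abundance_vector")) a else abundance_vector(a)
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("<abundance_vector> S = %d taxa, N = %d strains\n", x$S, x$N))
  invisible(x)
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H' = -\sum_i P_i \ln P_i} with \eqn{P_i = n_i/N}, natural logarithm.
#' Zero when a single taxon is present; at most \eqn{\ln S}.
#'
#' @param a An [abundance_vector] or named vector of positive counts.
#' @return The index \eqn{H'} in nats.
#' @examples
#' shannon(c(A = 1, B = 1)) # ln 2
#' @export
shannon <- function(a) {
  a <- as_abundance(a)
  p <- a$P
  -sum(p * log(p))
}

#' Shannon equitability (evenness)
#'
#' \eqn{E_H = H' / \ln S}, on \[0, 1\]: 1 is complete evenness among the
#' \eqn{S} taxa. Undefined for a single taxon (\eqn{\ln 1 = 0}).
#'
#' @inheritParams shannon
#' @return The evenness \eqn{E_H}.
#' @export
equitability <- function(a) {
  a <- as_abundance(a)
  if (a$S < 2L) {
    stop("equitability is undefined for a single taxon (ln S = 0)",
         call. = FALSE)
  }
  shannon(a) / log(a$S)
}

#' Unbiased Simpson diversity index
#'
#' The finite-sample form
#' \eqn{1 - D = 1 - \sum_i n_i (n_i - 1) / (N (N - 1))}: the probability
#' that two strains drawn without replacement belong to different taxa.
#' The plug-in \eqn{\sum P_i^2} variant is deliberately not offered.
#'
#' @inheritParams shannon
#' @return `1 - D` on \[0, 1\].
#' @examples
#' simpson_unbiased(c(A = 2, B = 2)) # 2/3
#' @export
simpson_unbiased <- function(a) {
  a <- as_abundance(a)
  if (a$N < 2L) {
    stop("unbiased Simpson requires N >= 2 strains", call. = FALSE)
  }
  n <- a$counts
  1 - sum(n * (n - 1)) / (a$N * (a$N - 1))
}

#' Relative frequency of each taxon
#'
#' \eqn{RF_t = 100 \, n_t / N}: the percentage of all isolated strains
#' belonging to taxon `t`. Values sum to 100 before rounding.
#'
#' @inheritParams shannon
#' @return Named numeric vector of percentages.
#' @export
relative_frequency <- function(a) {
  a <- as_abundance(a)
  100 * a$counts / a$N
}

#' Frequency of occurrence of each taxon
#'
#' \eqn{FO_t = 100 \, s_t / }`total_samples`, where \eqn{s_t} is the number
#' of incidence rows (samples) containing taxon `t`. The denominator is the
#' number of samples *collected*, including those that yielded no isolates
#' and therefore have no incidence row -- not the number of occupied rows.
#'
#' @param m An `incidence_matrix` (see [to_incidence()]), rows = samples.
#' @param total_samples Total samples collected; must be at least `nrow(m)`.
#' @return Named numeric vector of percentages, one per taxon.
#' @export
frequency_of_occurrence <- function(m, total_samples) {
  stopifnot(inherits(m, "incidence_matrix"))
  total_samples <- as.integer(total_samples)
  if (length(total_samples) != 1L || is.na(total_samples) || total_samples < 1L) {
    stop("total_samples must be a single positive integer", call. = FALSE)
  }
  if (total_samples < nrow(m)) {
    stop("total_samples (", total_samples,
         ") is below the number of occupied samples (", nrow(m), ")",
         call. = FALSE)
  }
  100 * colSums(m) / total_samples
}

#' Alpha-diversity report for an abundance tally
#'
#' Bundles the three headline indices with the tally dimensions.
#'
#' @inheritParams shannon
#' @return List with `H_prime`, `E_H`, `simpson_1_minus_D`, `S`, `N`, of
#'   class `diversity_report`.
#' @export
diversity_report <- function(a) {
  a <- as_abundance(a)
  structure(
    list(
      H_prime = shannon(a),
      E_H = if (a$S >= 2L) equitability(a) else NA_real_,
      simpson_1_minus_D = if (a$N >= 2L) simpson_unbiased(a) else NA_real_,
      S = a$S,
      N = a$N
    ),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf(
    "<diversity_report> S = %d, N = %d | H' = %.4f | E_H = %.4f | 1-D = %.4f\n",
    x$S, x$N, x$H_prime, x$E_H, x$simpson_1_minus_D
  ))
  invisible(x)
}

#' Per-taxon frequency table
#'
#' Joins strain counts, relative frequency, sample occupancy and frequency of
#' occurrence into one data frame, ordered by decreasing strain count.
#'
#' @param x A [survey_table].
#' @return Data frame with columns `taxon`, `n`, `rf_pct`,
#'   `occupied_samples`, `fo_pct`.
#' @export
frequency_table <- function(x) {
  stopifnot(inherits(x, "survey_table"))
  a <- to_abundance(x)
  m <- to_incidence(x, "sample")
  rf <- relative_frequency(a)
  fo <- frequency_of_occurrence(m, n_samples_collected(x))
  taxa <- names(a$counts)
  out <- data.frame(
    taxon = taxa,
    n = as.integer(a$counts),
    rf_pct = unname(rf[taxa]),
    occupied_samples = as.integer(colSums(m)[taxa]),
    fo_pct = unname(fo[taxa]),
    stringsAsFactors = FALSE
  )
  out[order(-out$n, out$taxon), , drop = FALSE]
}
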