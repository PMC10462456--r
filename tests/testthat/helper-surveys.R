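# Fixtures built in code: small surveys, enumeration oracles, and the
# packaged inventory.

inventory <- function() {
  read_survey(duckweed_survey_path(), n_samples_collected = 72)
}

# Minimal survey builder: one strain per element of `taxon`. Trait values are
# numeric vectors (NA -> not determined, 0 -> assayed non-producer).
tiny_survey <- function(taxon,
                        sample = paste0("s", seq_along(taxon)),
                        genus = "Lemna", phylum = "Ascomycota",
                        n_collected = length(unique(sample)),
                        iaa = NA_real_, au = NA_real_, se = NA_real_) {
  n <- length(taxon)
  rec <- data.frame(
    strain_id = paste0("st", seq_len(n)),
    sample_id = rep_len(sample, n),
    host_genus = rep_len(genus, n),
    phylum = rep_len(phylum, n),
    taxon_label = taxon,
    identity_pct = NA_real_,
    stringsAsFactors = FALSE
  )
  vals <- list(iaa = rep_len(iaa, n), siderophore_au = rep_len(au, n),
               phosphate_se = rep_len(se, n))
  for (tr in names(vals)) {
    v <- vals[[tr]]
    rec[[paste0(tr, "_state")]] <- ifelse(is.na(v), "not_determined", "measured")
    rec[[paste0(tr, "_value")]] <- v
    rec[[paste0(tr, "_sd")]] <- NA_real_
  }
  survey_table(rec, n_samples_collected = n_collected)
}

# incidence matrix straight from 0/1 rows
inc <- function(..., taxa = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  colnames(m) <- if (is.null(taxa)) LETTERS[seq_len(ncol(m))] else taxa
  incidence_matrix(m)
}

# Independent Simpson oracle: enumerate all ordered pairs of distinct strains
# and count cross-taxon pairs.
oracle_simpson <- function(counts) {
  pop <- rep(seq_along(counts), counts)
  n <- length(pop)
  diff_pairs <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && pop[i] != pop[j]) diff_pairs <- diff_pairs + 1L
    }
  }
  diff_pairs / (n * (n - 1L))
}

# All partitions of n (abundance vectors up to taxon relabelling).
partitions_of <- function(n, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in partitions_of(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

# All compositions of n into exactly s positive parts.
compositions_of <- function(n, s) {
  if (s == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - s + 1L)) {
    for (rest in compositions_of(n - first, s - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# Orthogonal Procrustes residual after centring: how far Y is from X up to
# rotation/reflection (no scaling).
procrustes_residual <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  s <- svd(t(y) %*% x)
  rot <- s$u %*% t(s$v)
  sqrt(sum((y %*% rot - x)^2))
}

named_counts <- function(...) {
  v <- c(...)
  if (is.null(names(v)) || any(names(v) == "")) {
    names(v) <- paste0("t", seq_along(v))
  }
  v
}
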