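#' Chao1 species-richness estimator
#'
#' Abundance-based estimator of total richness from the counts of singleton
#' (\eqn{F_1}) and doubleton (\eqn{F_2}) taxa. The `"classic"` variant is
#' \eqn{S_{obs} + F_1^2 / (2 F_2)}, falling back to
#' \eqn{S_{obs} + F_1 (F_1 - 1) / 2} when no doubletons exist; the
#' `"bias_corrected"` variant (the default, matching the common
#' survey-software default) is
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))}. Both are bounded below by
#' the observed richness.
#'
#' @param a An [abundance_vector] or named vector of positive counts.
#' @param variant `"bias_corrected"` or `"classic"`.
#' @return A `richness_estimate`: list with `estimator`, `S_obs`, `S_est`
#'   and a `components` list (`F1`, `F2`).
#' @examples
#' chao1(c(A = 1, B = 1, C = 2), variant = "classic")$S_est # 5
#' @export
chao1 <- function(a, variant = c("bias_corrected", "classic")) {
  a <- as_abundance(a)
  variant <- match.arg(variant)
  f1 <- sum(a$counts == 1L)
  f2 <- sum(a$counts == 2L)
  add <- if (variant == "classic" && f2 > 0L) {
    f1^2 / (2 * f2)
  } else {
    f1 * (f1 - 1) / (2 * (if (variant == "classic") 1 else f2 + 1))
  }
  richness_estimate("chao1", a$S, a$S + add,
                    components = list(F1 = f1, F2 = f2, variant = variant))
}

#' First-order jackknife richness estimator
#'
#' Incidence-based estimator
#' \eqn{S_{est} = S_{obs} + Q_1 (m - 1) / m}, where \eqn{Q_1} is the number
#' of taxa found in exactly one of the \eqn{m} samples. Undefined on a
#' single sample.
#'
#' @param m An `incidence_matrix` (rows = samples, see [to_incidence()]).
#' @return A `richness_estimate` with components `Q1` and `m`.
#' @export
jackknife1 <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  if (nrow(m) < 2L) {
    stop("first-order jackknife is undefined on fewer than 2 samples",
         call. = FALSE)
  }
  q1 <- sum(colSums(m) == 1L)
  nr <- nrow(m)
  richness_estimate("jack1", ncol(m), ncol(m) + q1 * (nr - 1) / nr,
                    components = list(Q1 = q1, m = nr))
}

#' Analytic bootstrap richness estimator
#'
#' Incidence-based estimator
#' \eqn{S_{est} = S_{obs} + \sum_k (1 - p_k)^m}, where \eqn{p_k} is the
#' fraction of the \eqn{m} samples containing taxon \eqn{k}. Strictly above
#' \eqn{S_{obs}} unless every taxon occurs in every sample.
#'
#' @inheritParams jackknife1
#' @return A `richness_estimate` with components `m` and `sum_term`.
#' @export
bootstrap_richness <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  p <- colSums(m) / nrow(m)
  add <- sum((1 - p)^nrow(m))
  richness_estimate("bootstrap", ncol(m), ncol(m) + add,
                    components = list(m = nrow(m), sum_term = add))
}

richness_estimate <- function(estimator, s_obs, s_est, components) {
  structure(
    list(estimator = estimator, S_obs = as.integer(s_obs), S_est = s_est,
         components = components),
    class = "richness_estimate"
  )
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("<richness_estimate> %s: S_obs = %d, S_est = %.2f\n",
              x$estimator, x$S_obs, x$S_est))
  invisible(x)
}

#' Sample-based species accumulation curve with richness estimators
#'
#' Randomises the order of the samples `n_permutations` times; for each
#' permutation and each prefix length `t = 1..m` it pools the strains of the
#' first `t` samples and computes the observed richness together with the
#' Chao1 (on the pooled abundance tally), first-order jackknife and analytic
#' bootstrap (on the pooled incidence sub-matrix) estimators. The jackknife
#' correction factor \eqn{(m-1)/m} vanishes at \eqn{t = 1}, so the curve is
#' defined from the first sample on. Per-`t` means and standard deviations
#' over permutations are returned; the run is deterministic given `seed`, and
#' the caller's RNG state is left untouched.
#'
#' @param x A [survey_table] with at least two distinct samples.
#' @param n_permutations Number of random sample orderings (default 100).
#' @param seed Integer seed for the permutation stream (required).
#' @param chao1_variant Passed to [chao1()].
#' @return An `accumulation_curve`: a data frame with columns `t`,
#'   `sobs_mean`, `sobs_sd`, `chao1_mean`, `chao1_sd`, `jack1_mean`,
#'   `jack1_sd`, `bootstrap_mean`, `bootstrap_sd`, with attributes
#'   `n_permutations` and `seed`.
#' @export
accumulation_curve <- function(x, n_permutations = 100, seed,
                               chao1_variant = c("bias_corrected", "classic")) {
  stopifnot(inherits(x, "survey_table"))
  chao1_variant <- match.arg(chao1_variant)
  if (missing(seed)) stop("seed is required for the permutation stream",
                          call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  samples <- unique(x$sample_id)
  m <- length(samples)
  if (m < 2L) stop("accumulation curve requires at least 2 samples", call. = FALSE)
  taxa <- unique(x$taxon_label)
  # per-sample strain counts over the common taxon index
  per_sample <- lapply(samples, function(s) {
    tabulate(match(x$taxon_label[x$sample_id == s], taxa), nbins = length(taxa))
  })

  acc <- array(NA_real_, dim = c(n_permutations, m, 4L),
               dimnames = list(NULL, NULL, c("sobs", "chao1", "jack1", "bootstrap")))
  with_seed(seed, {
    for (r in seq_len(n_permutations)) {
      ord <- sample.int(m)
      counts <- numeric(length(taxa))   # pooled strain counts
      occ <- numeric(length(taxa))      # number of pooled samples containing taxon
      for (t in seq_len(m)) {
        cs <- per_sample[[ord[t]]]
        counts <- counts + cs
        occ <- occ + (cs > 0)
        present <- counts > 0
        s_obs <- sum(present)
        f1 <- sum(counts == 1)
        f2 <- sum(counts == 2)
        ch <- if (chao1_variant == "classic" && f2 > 0) {
          s_obs + f1^2 / (2 * f2)
        } else if (chao1_variant == "classic") {
          s_obs + f1 * (f1 - 1) / 2
        } else {
          s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
        }
        q1 <- sum(occ == 1)
        jk <- s_obs + q1 * (t - 1) / t
        bt <- s_obs + sum((1 - occ[present] / t)^t)
        acc[r, t, ] <- c(s_obs, ch, jk, bt)
      }
    }
  })
  out <- data.frame(t = seq_len(m))
  for (k in dimnames(acc)[[3]]) {
    nm <- if (k == "sobs") "sobs" else k
    out[[paste0(nm, "_mean")]] <- apply(acc[, , k, drop = FALSE], 2, mean)
    out[[paste0(nm, "_sd")]] <- apply(acc[, , k, drop = FALSE], 2, stats::sd)
  }
  structure(out, n_permutations = n_permutations, seed = seed,
            class = c("accumulation_curve", "data.frame"))
}
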