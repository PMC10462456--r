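#' Pairwise Jaccard distances between communities
#'
#' For presence/absence rows \eqn{T_i} of an incidence matrix,
#' \eqn{d(i, j) = 1 - |T_i \cap T_j| / |T_i \cup T_j|}: the complement of
#' the Jaccard similarity. Jaccard distance is a metric on non-empty sets
#' (every incidence row has at least one taxon by construction).
#'
#' @param m An `incidence_matrix` (see [to_incidence()]).
#' @return A `distance_matrix`: a symmetric labelled matrix with zero
#'   diagonal and entries in \[0, 1\].
#' @examples
#' m <- incidence_matrix(matrix(c(1, 1, 1, 0, 0, 1, 1, 1), nrow = 2,
#'                              byrow = TRUE,
#'                              dimnames = list(c("s1", "s2"), LETTERS[1:4])))
#' jaccard_distance(m)["s1", "s2"] # 1 - 2/4
#' @export
jaccard_distance <- function(m) {
  stopifnot(inherits(m, "incidence_matrix"))
  mm <- unclass(m)
  storage.mode(mm) <- "double"
  inter <- mm %*% t(mm)
  sizes <- rowSums(mm)
  union <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / union
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Embeds a distance matrix by Gower double-centering: with
#' \eqn{C = I - \mathbf{1}\mathbf{1}^\top / n},
#' \eqn{B = -\tfrac12 C (d \circ d) C} is eigendecomposed and the
#' coordinates on axis \eqn{j} are \eqn{v_j \sqrt{\lambda_j}}. Axes are
#' ordered by decreasing eigenvalue and retained while
#' \eqn{\lambda_j > } `tolerance` \eqn{\cdot \lambda_1}. Negative
#' eigenvalues, which arise because Jaccard distances need not be
#' Euclidean-embeddable, are reported unaltered (no Lingoes/Cailliez
#' correction). Eigenvector signs are fixed so the largest-magnitude
#' coordinate on each axis is positive, making the output reproducible
#' across eigen-solvers. Coordinates are centred: each retained axis has
#' zero column mean.
#'
#' @param d A `distance_matrix` (from [jaccard_distance()]), a [stats::dist],
#'   or a symmetric numeric matrix with zero diagonal.
#' @param tolerance Relative eigenvalue tolerance for axis retention
#'   (default `1e-10`).
#' @return An `ordination_result`: list with `coordinates` (groups x retained
#'   axes, labelled `Axis1`, `Axis2`, ...), `eigenvalues` (all, decreasing,
#'   including negatives), and `explained` (each retained eigenvalue as a
#'   fraction of the positive-eigenvalue sum).
#' @export
pcoa <- function(d, tolerance = 1e-10) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  n <- nrow(d)
  if (n < 2L) stop("PCoA requires at least 2 groups", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  labels <- rownames(d) %||% paste0("g", seq_len(n))
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d * d) %*% cmat
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- eig$values
  if (max(ev) <= tolerance) {
    stop("degenerate configuration: no eigenvalue above tolerance", call. = FALSE)
  }
  keep <- which(ev > tolerance * max(ev))
  coords <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]),
                                                       nrow = length(keep))
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(labels, paste0("Axis", seq_along(keep)))
  structure(
    list(coordinates = coords, eigenvalues = ev,
         explained = ev[keep] / sum(ev[ev > 0])),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf(
    "<ordination_result> %d groups, %d retained axes (%.1f%%, %.1f%% explained)\n",
    nrow(x$coordinates), ncol(x$coordinates),
    100 * x$explained[1], if (length(x$explained) > 1) 100 * x$explained[2] else NA
  ))
  invisible(x)
}

#' Community ordination of a survey
#'
#' Convenience wrapper reproducing the community-similarity analysis:
#' builds the incidence matrix at the requested grouping, computes Jaccard
#' distances, and embeds them by [pcoa()]. The default groups per-sample
#' communities (each labelled by its host genus in the returned data frame);
#' `grouping = "host_genus"` pools communities per host genus instead.
#'
#' @param x A [survey_table].
#' @param grouping `"sample"` or `"host_genus"`.
#' @param tolerance Passed to [pcoa()].
#' @return A list with `distance` (the `distance_matrix`), `ordination`
#'   (the `ordination_result`), and `scores` (data frame of group, retained
#'   axes, and host genus).
#' @export
ordinate_survey <- function(x, grouping = c("sample", "host_genus"),
                            tolerance = 1e-10) {
  stopifnot(inherits(x, "survey_table"))
  grouping <- match.arg(grouping)
  m <- to_incidence(x, grouping)
  d <- jaccard_distance(m)
  ord <- pcoa(d, tolerance = tolerance)
  genus <- if (grouping == "sample") {
    vapply(rownames(m), function(s) x$host_genus[x$sample_id == s][1L], "")
  } else {
    rownames(m)
  }
  scores <- data.frame(group = rownames(ord$coordinates),
                       ord$coordinates,
                       host_genus = unname(genus),
                       stringsAsFactors = FALSE, check.names = FALSE)
  list(distance = d, ordination = ord, scores = scores)
}
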