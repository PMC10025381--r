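# Rogers' (1972) genetic distance on dosage rows.

#' Rogers' distance between two individuals
#'
#' The per-locus Rogers distance between allele-frequency vectors is
#' `sqrt(0.5 * sum_alleles (p_a - p_b)^2)`; with per-individual biallelic
#' frequencies derived from a dosage `d` (frequencies `d` and `1 - d`) this
#' reduces to `|d_a - d_b|`, and the distance is the mean over loci. Loci
#' missing in either row are excluded pairwise; the result lies in
#' `[0, 1]`.
#'
#' @param a,b Dosage vectors on the `[0, 1]` scale over the same marker set.
#' @return The Rogers distance (scalar).
#' @export
rogers_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop_invalid("rogers_distance: no shared non-missing loci")
  mean(sqrt(0.5 * ((a[ok] - b[ok])^2 + ((1 - a[ok]) - (1 - b[ok]))^2)))
}

#' All pairwise Rogers distances
#'
#' @param X Individuals x markers dosage matrix; missing loci are excluded
#'   pairwise (each pair is rescaled to its complete loci).
#' @return A symmetric matrix of Rogers distances.
#' @export
rogers_distance_matrix <- function(X) {
  # Manhattan distance / locus count equals the mean |d_a - d_b|; stats::dist
  # rescales NA-affected pairs to their complete loci, matching the pairwise-
  # complete rule.
  as.matrix(stats::dist(X, method = "manhattan")) / ncol(X)
}

#' Within- and between-environment mean Rogers distances of hybrids
#'
#' For each environment the mean pairwise distance among its hybrids, and
#' for each pair of environments the mean distance over all cross pairs.
#' Because hybrids within an environment typically share one tester while
#' hybrids of two environments involve two testers, between-environment
#' means exceed within-environment means in tester-structured trials.
#'
#' @param hybrid_geno Hybrids x markers dosage matrix
#'   (see [hybrid_dosage_matrix()]).
#' @param env Environment label per hybrid (named by hybrid or in row
#'   order).
#' @return A symmetric environments x environments matrix of mean Rogers
#'   distances; the diagonal holds the within-environment means.
#' @export
pairwise_distance_summary <- function(hybrid_geno, env) {
  if (!is.null(names(env))) env <- env[rownames(hybrid_geno)]
  stopifnot(length(env) == nrow(hybrid_geno))
  if (min(table(env)) < 2L)
    stop_invalid("pairwise_distance_summary: need >= 2 hybrids per environment")
  D <- rogers_distance_matrix(hybrid_geno)
  envs <- sort(unique(env))
  out <- matrix(NA_real_, length(envs), length(envs),
                dimnames = list(envs, envs))
  for (i in seq_along(envs)) {
    for (j in i:length(envs)) {
      di <- D[env == envs[i], env == envs[j], drop = FALSE]
      m <- if (i == j) mean(di[upper.tri(di)]) else mean(di)
      out[i, j] <- out[j, i] <- m
    }
  }
  out
}
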