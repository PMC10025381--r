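# Linkage-disequilibrium decay and principal-component diagnostics.

#' LD decay within a pool, binned by map distance
#'
#' Squared Pearson correlation (r2) of dosages for all intra-chromosome
#' marker pairs, binned by their cM distance. Pairs involving a
#' zero-variance marker are skipped; missing calls are handled with
#' pairwise-complete correlations.
#'
#' @param geno Lines x markers dosage matrix for one pool.
#' @param map Marker map (`marker`, `chrom`, `pos_cM`) covering the columns
#'   of `geno`.
#' @param bin_width_cM Width of the distance bins (default 1 cM).
#' @return A data.frame with `bin_mid` (bin midpoint in cM), `mean_r2` and
#'   `n_pairs`.
#' @export
ld_decay <- function(geno, map, bin_width_cM = 1) {
  map <- map[map$marker %in% colnames(geno), , drop = FALSE]
  dists <- list(); r2s <- list()
  for (c in unique(map$chrom)) {
    mk <- map[map$chrom == c, , drop = FALSE]
    if (nrow(mk) < 2L) next
    sub <- geno[, mk$marker, drop = FALSE]
    keep <- apply(sub, 2L, stats::var, na.rm = TRUE) > 0
    if (sum(keep) < 2L) next
    sub <- sub[, keep, drop = FALSE]
    pos <- mk$pos_cM[keep]
    r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    ut <- upper.tri(r)
    d <- abs(outer(pos, pos, "-"))[ut]
    r2 <- r[ut]^2
    ok <- is.finite(r2)
    dists[[length(dists) + 1L]] <- d[ok]
    r2s[[length(r2s) + 1L]] <- r2[ok]
  }
  if (!length(dists))
    stop_invalid("ld_decay: need >= 2 polymorphic markers on one chromosome")
  d <- unlist(dists); r2 <- unlist(r2s)
  bin <- floor(d / bin_width_cM)
  agg <- tapply(r2, bin, mean)
  data.frame(bin_mid = (as.numeric(names(agg)) + 0.5) * bin_width_cM,
             mean_r2 = as.numeric(agg),
             n_pairs = as.integer(tapply(r2, bin, length)),
             row.names = NULL)
}

#' Mean r2 of marker pairs at a given map distance
#'
#' Convenience accessor for calibration checks: mean r2 over all pairs whose
#' distance lies within `target +- halfwidth` cM.
#'
#' @inheritParams ld_decay
#' @param target Distance of interest in cM (default 5).
#' @param halfwidth Window half-width in cM (default 1).
#' @return Mean r2 (scalar).
#' @export
ld_r2_at <- function(geno, map, target = 5, halfwidth = 1) {
  ld <- ld_decay(geno, map, bin_width_cM = 0.5)
  sel <- ld$bin_mid >= target - halfwidth & ld$bin_mid <= target + halfwidth
  sum(ld$mean_r2[sel] * ld$n_pairs[sel]) / sum(ld$n_pairs[sel])
}

#' Principal-component projection of lines
#'
#' PCA of the centred (not scaled: biallelic dosages are already on a
#' common scale) dosage matrix; a diagnostic for the separation of the
#' heterotic pools.
#'
#' @param geno Imputed lines x markers dosage matrix (no missing values).
#' @param n_pc Number of components to return.
#' @return A data.frame with the line names and PC scores.
#' @export
pca_projection <- function(geno, n_pc = 5) {
  if (nrow(geno) < 2L)
    stop_invalid("pca_projection: need at least two lines")
  if (anyNA(geno))
    stop_invalid("pca_projection: matrix contains missing values; impute first")
  n_pc <- min(n_pc, nrow(geno) - 1L, ncol(geno))
  pc <- stats::prcomp(geno, center = TRUE, scale. = FALSE, rank. = n_pc)
  cbind(data.frame(line = rownames(geno) %||% seq_len(nrow(geno)),
                   stringsAsFactors = FALSE),
        as.data.frame(pc$x[, seq_len(n_pc), drop = FALSE]))
}
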