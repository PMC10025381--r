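# Marker and line quality control on parental-line dosage matrices.
# Dosages are on the haplotype scale: inbred/DH lines carry 0 or 1 (NA for a
# failed call); hybrids carry the mean of their parents (0, 0.5, 1).

#' Per-marker summary statistics
#'
#' For every marker: the number of distinct observed variants, the allele
#' frequencies `f1` (of the allele coded 1) and `f2 = 1 - f1` among
#' non-missing parental calls, the expected heterozygosity
#' `1 - f1^2 - f2^2`, and the call rate across lines.
#'
#' @param geno Lines x markers dosage matrix (raw parental calls, NA =
#'   missing).
#' @return A data.frame with one row per marker.
#' @export
marker_stats <- function(geno) {
  if (!is.matrix(geno) || nrow(geno) == 0L || ncol(geno) == 0L)
    stop_invalid("marker_stats: empty genotype matrix")
  n_variants <- apply(geno, 2L, function(x) length(unique(x[!is.na(x)])))
  f1 <- colMeans(geno, na.rm = TRUE)
  f2 <- 1 - f1
  data.frame(marker = colnames(geno) %||% sprintf("M%04d", seq_len(ncol(geno))),
             n_variants = as.integer(n_variants),
             f1 = f1, f2 = f2,
             exp_het = 1 - f1^2 - f2^2,
             call_rate = colMeans(!is.na(geno)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on biallelic state, expected heterozygosity and call rate
#'
#' Keeps markers that show exactly two variants among the parental lines,
#' have expected heterozygosity `1 - f1^2 - f2^2 >= min_het`, and were
#' called in at least `min_call_rate` of the lines.
#'
#' @param geno Raw lines x markers dosage matrix.
#' @param min_het Minimum expected heterozygosity (default 0.10).
#' @param min_call_rate Minimum marker call rate (default 0.90).
#' @return A list with `kept` (character vector of retained marker names)
#'   and `stats` (the full [marker_stats()] table with a logical `kept`
#'   column).
#' @export
filter_markers <- function(geno, min_het = 0.10, min_call_rate = 0.90) {
  st <- marker_stats(geno)
  st$kept <- st$n_variants == 2L &
    st$exp_het >= min_het &
    st$call_rate >= min_call_rate
  if (!any(st$kept))
    warning("filter_markers: no marker passed the filters")
  list(kept = st$marker[st$kept], stats = st)
}

#' Filter lines on missing-call fraction
#'
#' Keeps lines whose fraction of missing calls over the supplied (already
#' marker-filtered) matrix does not exceed `max_missing`.
#'
#' @param geno Lines x kept-markers dosage matrix.
#' @param max_missing Maximum tolerated missing fraction (default 0.10).
#' @return Character vector of retained line names.
#' @export
filter_lines <- function(geno, max_missing = 0.10) {
  if (!is.matrix(geno) || nrow(geno) == 0L)
    stop_invalid("filter_lines: empty genotype matrix")
  miss <- rowMeans(is.na(geno))
  (rownames(geno) %||% as.character(seq_len(nrow(geno))))[miss <= max_missing]
}

#' Impute missing dosages with within-pool allele-frequency means
#'
#' Each missing call is replaced by the mean dosage of the line's pool at
#' that marker; a marker entirely missing within a pool falls back to the
#' across-pool mean (with a warning).
#'
#' @param geno Filtered lines x markers dosage matrix.
#' @param pools Named character vector mapping line name to pool label
#'   (or an unnamed vector in row order).
#' @return The completed matrix; `attr(, "status") == "imputed"`.
#' @export
impute_missing <- function(geno, pools) {
  if (is.null(names(pools))) {
    stopifnot(length(pools) == nrow(geno))
  } else {
    pools <- pools[rownames(geno)]
    if (anyNA(pools)) stop_invalid("impute_missing: pool label missing for some lines")
  }
  out <- geno
  overall <- colMeans(geno, na.rm = TRUE)
  warned <- FALSE
  for (p in unique(pools)) {
    rows <- which(pools == p)
    sub <- geno[rows, , drop = FALSE]
    pm <- colMeans(sub, na.rm = TRUE)
    empty <- !is.finite(pm)
    if (any(empty)) {
      pm[empty] <- overall[empty]
      warned <- TRUE
    }
    na_idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(na_idx)) out[rows, ][na_idx] <- pm[na_idx[, 2L]]
  }
  if (warned)
    warning("impute_missing: some markers had no calls within a pool; across-pool mean used")
  if (anyNA(out))
    out[is.na(out)] <- overall[which(is.na(out), arr.ind = TRUE)[, 2L]]
  attr(out, "status") <- "imputed"
  out
}

#' Hybrid dosage as the parental mean
#'
#' The expected dosage of the cross of two homozygous parents is the mean
#' of the parental dosages; fractional (imputed) parental dosages are
#' handled by the same formula. Used for distance and PCA diagnostics (the
#' prediction model works on parental rows directly).
#'
#' @param candidate,tester Parental dosage vectors (or matrices of equal
#'   shape) on the `[0, 1]` scale.
#' @return `(candidate + tester) / 2`.
#' @export
hybrid_dosage <- function(candidate, tester) {
  stopifnot(length(candidate) == length(tester))
  (candidate + tester) / 2
}

#' Dosage matrix for all hybrids of a trial layout
#'
#' @param hybrids Hybrid-parent table (columns `hybrid`, `flint_parent`,
#'   `dent_parent`), e.g. `dataset$hybrids`.
#' @param geno Imputed parental lines x markers matrix.
#' @return Hybrids x markers matrix of mean-parent dosages.
#' @export
hybrid_dosage_matrix <- function(hybrids, geno) {
  missing_par <- !(hybrids$flint_parent %in% rownames(geno)) |
    !(hybrids$dent_parent %in% rownames(geno))
  if (any(missing_par)) {
    warning("hybrid_dosage_matrix: dropping ", sum(missing_par),
            " hybrids with ungenotyped parents")
    hybrids <- hybrids[!missing_par, , drop = FALSE]
  }
  out <- hybrid_dosage(geno[hybrids$flint_parent, , drop = FALSE],
                       geno[hybrids$dent_parent, , drop = FALSE])
  rownames(out) <- hybrids$hybrid
  out
}
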