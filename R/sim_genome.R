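# Genome, meiosis and population simulation for the two-pool DH program.
# All functions draw from the ambient R RNG; simulate_dataset() seeds it once
# from the configuration's master_seed so that full datasets are reproducible
# bit for bit.

#' Simulate a linkage map
#'
#' Draws chromosome lengths uniformly from the configured range and places
#' the configured number of markers at uniform random positions, allocating
#' marker counts to chromosomes proportionally to their genetic length
#' (largest-remainder rounding, at least one marker per chromosome).
#'
#' @param config A [sim_config()] object.
#' @return A data.frame (class `genome_map`) with columns `marker`, `chrom`,
#'   `pos_cM`, sorted by chromosome and position; chromosome lengths are kept
#'   in `attr(, "chrom_length")`.
#' @export
simulate_genome_map <- function(config) {
  validate_sim_config(config)
  nc <- config$n_chromosomes
  nm <- config$n_markers
  len <- stats::runif(nc, config$chrom_length_cM[1], config$chrom_length_cM[2])
  counts <- allocate_proportional(nm, len)
  rows <- vector("list", nc)
  for (c in seq_len(nc)) {
    pos <- sort(stats::runif(counts[c], 0, len[c]))
    rows[[c]] <- data.frame(chrom = c, pos_cM = pos)
  }
  map <- do.call(rbind, rows)
  map <- data.frame(marker = sprintf("M%04d", seq_len(nrow(map))),
                    chrom = map$chrom, pos_cM = map$pos_cM,
                    stringsAsFactors = FALSE)
  attr(map, "chrom_length") <- len
  class(map) <- c("genome_map", "data.frame")
  map
}

# Largest-remainder allocation of `n` items proportional to weights `w`,
# with a minimum of one item per class.
allocate_proportional <- function(n, w) {
  k <- length(w)
  if (n < k) stop_invalid("cannot place ", n, " markers on ", k, " chromosomes")
  raw <- (n - k) * w / sum(w)
  base <- floor(raw)
  rem <- n - k - sum(base)
  counts <- base + 1L   # the guaranteed one per chromosome
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

# Extend a marker map with unobserved QTL loci for each trait, at uniform
# random positions (or, in the diagnostic qtl_at_markers mode, designate
# randomly chosen markers themselves as the QTL).  Returns the full locus
# map with `is_marker` and `trait` columns ("" for markers), sorted by
# chromosome and position; the per-trait QTL locus names are kept in
# `attr(, "qtl")`.
add_qtl_loci <- function(map, config) {
  len <- attr(map, "chrom_length")
  rows <- list(data.frame(locus = map$marker, chrom = map$chrom,
                          pos_cM = map$pos_cM, is_marker = TRUE, trait = "",
                          stringsAsFactors = FALSE))
  qtl_of <- list()
  for (tr in config$traits$trait) {
    if (config$qtl_at_markers) {
      at <- sample.int(nrow(map), min(config$n_qtl, nrow(map)))
      qtl_of[[tr]] <- map$marker[at]
      next
    }
    chrom <- sample.int(config$n_chromosomes, config$n_qtl, replace = TRUE,
                        prob = len / sum(len))
    pos <- stats::runif(config$n_qtl, 0, len[chrom])
    ids <- sprintf("QTL_%s_%03d", tr, seq_len(config$n_qtl))
    qtl_of[[tr]] <- ids
    rows[[length(rows) + 1L]] <-
      data.frame(locus = ids, chrom = chrom, pos_cM = pos,
                 is_marker = FALSE, trait = tr, stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, rows)
  loci <- loci[order(loci$chrom, loci$pos_cM), , drop = FALSE]
  rownames(loci) <- NULL
  attr(loci, "chrom_length") <- len
  attr(loci, "qtl") <- qtl_of
  loci
}

#' Simulate one gamete from a heterozygous genome
#'
#' Meiosis under the Haldane (no-interference) model: the number of
#' crossovers per chromosome is Poisson with mean length/100 (one expected
#' crossover per 100 cM) and breakpoints fall uniformly along the
#' chromosome.
#'
#' @param parent A 2 x n_loci matrix of parental haplotypes (rows are the
#'   two homologues), columns ordered as in `map`.
#' @param map A locus map with columns `chrom` and `pos_cM` covering the
#'   parent's columns, with chromosome lengths in `attr(, "chrom_length")`
#'   (falls back to the maximum marker position per chromosome).
#' @return A haplotype vector of length n_loci.
#' @export
make_gamete <- function(parent, map) {
  stopifnot(is.matrix(parent), nrow(parent) == 2L, ncol(parent) == nrow(map))
  out <- numeric(ncol(parent))
  len <- attr(map, "chrom_length")
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    L <- if (!is.null(len)) len[c] else max(map$pos_cM[idx])
    n_co <- stats::rpois(1L, L / 100)
    start <- sample.int(2L, 1L)
    if (n_co == 0L) {
      hap <- rep.int(start, length(idx))
    } else {
      bp <- sort(stats::runif(n_co, 0, L))
      hap <- 1L + (start - 1L + findInterval(map$pos_cM[idx], bp)) %% 2L
    }
    out[idx] <- parent[cbind(hap, idx)]
  }
  out
}

#' Simulate founder lines for the two heterotic pools
#'
#' Base allele frequencies are drawn uniformly on (0.1, 0.9) per locus;
#' each pool receives its own frequencies from a Balding-Nichols
#' distribution around the base value with divergence parameter
#' `pool_divergence` (0 = identical pools, 1 = fixation within pools).
#' Within a pool, a small panel of ancestral haplotypes is drawn i.i.d.
#' from the pool frequencies, and each (inbred) founder is assembled as a
#' recombinant mosaic of these ancestors: segment origins follow a Markov
#' process along the map with switch rate `mosaic_switch_rate` per cM.
#' This emulates the shared breeding history of a heterotic pool and is
#' what generates within-pool linkage disequilibrium that decays with map
#' distance (calibrated so that r2 at 5 cM is around 0.3 at the default
#' configuration).
#'
#' @param config A [sim_config()] object.
#' @param map A marker or full locus map (columns `chrom`, `pos_cM`).
#' @return A list with haplotype matrices `flint` and `dent`
#'   (founders x loci) and the pool allele frequencies in
#'   `attr(, "pool_freq")`.
#' @export
simulate_founder_pools <- function(config, map) {
  validate_sim_config(config)
  m <- nrow(map)
  nf <- config$n_founders_per_pool
  k <- config$n_ancestral_haps
  rate <- config$mosaic_switch_rate
  Fst <- config$pool_divergence
  p_anc <- stats::runif(m, 0.1, 0.9)
  draw_pool_freq <- function() {
    if (Fst == 0) return(p_anc)
    if (Fst == 1) return(as.numeric(stats::rbinom(m, 1L, p_anc)))
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    stats::rbeta(m, a, b)
  }
  # per-locus switch probabilities of the mosaic origin process
  gap <- c(0, diff(map$pos_cM))
  gap[c(TRUE, diff(map$chrom) != 0)] <- Inf      # new chromosome: fresh draw
  p_switch <- 1 - exp(-rate * gap)
  make_pool <- function(prefix) {
    p <- draw_pool_freq()
    anc <- matrix(stats::rbinom(k * m, 1L, rep(p, each = k)),
                  nrow = k, ncol = m)
    haps <- matrix(0L, nf, m,
                   dimnames = list(sprintf("%s%02d", prefix, seq_len(nf)),
                                   map[[1L]]))
    for (f in seq_len(nf)) {
      switch_here <- stats::runif(m) < p_switch
      draws <- sample.int(k, sum(switch_here), replace = TRUE)
      origin <- integer(m)
      cur <- draws[1L]                           # first locus always switches
      d <- 1L
      for (j in seq_len(m)) {
        if (switch_here[j]) { cur <- draws[d]; d <- d + 1L }
        origin[j] <- cur
      }
      haps[f, ] <- anc[cbind(origin, seq_len(m))]
    }
    list(haps = haps, freq = p)
  }
  fl <- make_pool("FF")
  de <- make_pool("DF")
  out <- list(flint = fl$haps, dent = de$haps)
  attr(out, "pool_freq") <- list(flint = fl$freq, dent = de$freq,
                                 ancestral = p_anc)
  out
}

#' Simulate families of doubled-haploid lines
#'
#' Creates `n_families` biparental families per call by crossing random
#' founder pairs of one pool (pairs drawn with replacement from the founder
#' set, so families sharing one parent - half-sib families - arise whenever
#' families outnumber founders). Each DH line is produced by one meiosis of
#' the family's F1 via [make_gamete()] followed by chromosome doubling, so
#' its genotype equals its single haplotype and every line is fully
#' homozygous.
#'
#' @param founders Founder haplotype list from [simulate_founder_pools()].
#' @param config A [sim_config()] object.
#' @param map Locus map matching the founder matrices.
#' @param pool `"Flint"` or `"Dent"`.
#' @param n_families,lines_per_family Family structure; default from config.
#' @param cohort Label for the breeding cycle (e.g. the trial year) the
#'   lines belong to; part of the line identifiers.
#' @return A list with `geno` (lines x loci haplotype-dosage matrix, entries
#'   0/1) and `info` (data.frame: line, pool, family, cohort).
#' @export
simulate_dh_lines <- function(founders, config, map,
                              pool = c("Flint", "Dent"),
                              n_families = config$n_dh_families_per_pool,
                              lines_per_family = config$dh_lines_per_family,
                              cohort = 1L) {
  pool <- match.arg(pool)
  haps <- if (pool == "Flint") founders$flint else founders$dent
  if (is.null(haps) || nrow(haps) < 2L)
    stop_invalid("simulate_dh_lines: need at least 2 founders in the ", pool, " pool")
  nf <- nrow(haps)
  n_lines <- n_families * lines_per_family
  geno <- matrix(0, n_lines, ncol(haps),
                 dimnames = list(NULL, colnames(haps)))
  info <- data.frame(line = character(n_lines), pool = pool,
                     family = character(n_lines), cohort = cohort,
                     stringsAsFactors = FALSE)
  row <- 0L
  for (fam in seq_len(n_families)) {
    pair <- sample.int(nf, 2L, replace = FALSE)
    f1 <- haps[pair, , drop = FALSE]
    fam_id <- sprintf("%s_C%s_F%02d", substr(pool, 1L, 1L), cohort, fam)
    for (l in seq_len(lines_per_family)) {
      row <- row + 1L
      geno[row, ] <- make_gamete(f1, map)
      info$line[row] <- sprintf("%s_L%02d", fam_id, l)
      info$family[row] <- fam_id
    }
  }
  rownames(geno) <- info$line
  list(geno = geno, info = info)
}
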