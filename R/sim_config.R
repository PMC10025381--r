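#' Default trait parameter table for the breeding-program simulator
#'
#' Two traits are simulated, analogues of grain yield and grain moisture in a
#' maize testcross program. Variance components are on the plot scale and are
#' interpreted as population variances of the corresponding model terms:
#' `var_year` (year main effects), `var_location` (location-within-year
#' effects), `var_testcross` (additive testcross values of the hybrids,
#' transferable across years), `var_gxy` (genotype-by-year interaction,
#' realized as year-specific QTL-effect deviations), `var_gxe`
#' (genotype-by-environment interaction, realized as environment-specific
#' QTL-effect deviations) and `var_error` (plot residual). The moisture
#' analogue has the higher plot heritability.
#'
#' @return A data.frame with one row per trait.
#' @export
default_traits <- function() {
  data.frame(
    trait         = c("yield", "moisture"),
    mean          = c(100, 30),
    var_year      = c(1.5, 0.8),
    var_location  = c(0.8, 0.4),
    var_testcross = c(0.3, 0.4),
    var_gxy       = c(2.0, 2.4),
    var_gxe       = c(0.04, 0.04),
    var_error     = c(1.2, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic breeding-program simulator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_dataset()] and the lower-level `simulate_*` functions. Defaults
#' emulate the data structure of an unreplicated maize testcross program:
#' two diverged heterotic pools (Flint and Dent) of doubled-haploid (DH)
#' lines in full-sib/half-sib families, 461 SNP markers on 10 chromosomes at
#' ~5 cM average spacing, and tester x candidate trials at several locations
#' over three years with 89-110 candidates per environment.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_cM Range (length-2 numeric, cM) from which chromosome
#'   lengths are drawn uniformly. The default `c(200, 250)` reproduces a mean
#'   adjacent-marker spacing of ~5 cM with the default marker count.
#' @param n_markers Total number of SNP markers across the genome.
#' @param n_founders_per_pool Founder inbreds per heterotic pool.
#' @param n_dh_families_per_pool DH families created per pool and per year
#'   (each year is a new breeding cycle with new crosses of the founders).
#' @param dh_lines_per_family DH lines per family.
#' @param n_years,n_locations Trial dimensions; every location is used in
#'   every year and one (year, location) pair is one environment.
#' @param candidates_per_environment Range (length-2 integer) of candidate
#'   counts per environment.
#' @param n_qtl Number of QTL per trait. QTL are unobserved loci placed at
#'   random map positions; markers tag them only through linkage
#'   disequilibrium.
#' @param qtl_at_markers Place QTL exactly at (randomly chosen) marker
#'   positions instead (default FALSE). In this diagnostic mode markers tag
#'   the QTL perfectly, which is useful for noise-free recovery checks.
#' @param n_testers_per_pool Tester lines per pool, reused across
#'   environments and years.
#' @param testers_per_env Testers used within one environment (1 or 2;
#'   default 2, with the second tester crossed to a ~25% minority of the
#'   candidates, as in trial sets that carry a second tester on part of the
#'   material).
#' @param pool_divergence Fst-like divergence in `[0, 1]` between the pools'
#'   founder allele frequencies (Balding-Nichols model).
#' @param n_ancestral_haps Number of ancestral haplotypes per pool from
#'   which founders are built as recombinant mosaics; together with
#'   `mosaic_switch_rate` this sets the within-pool LD level (fewer
#'   ancestors, slower switching = more LD).
#' @param mosaic_switch_rate Switch rate (per cM) of the Markov segment
#'   process that assembles founders from ancestral haplotypes; the default
#'   calibrates within-pool r2 at 5 cM to ~0.3.
#' @param traits Trait parameter table, see [default_traits()].
#' @param missing_rate Fraction of genotype calls set to missing in the
#'   exported parental genotype matrix (default 0 = complete data).
#' @param mu,var_year,var_location,var_testcross,var_gxy,var_gxe,var_error
#'   Optional scalar overrides applied to every trait (convenience for
#'   experiments such as noise-free runs).
#' @param master_seed Integer seed controlling the whole dataset draw.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 10,
                       chrom_length_cM = c(200, 250),
                       n_markers = 461,
                       n_founders_per_pool = 64,
                       n_dh_families_per_pool = 150,
                       dh_lines_per_family = 3,
                       n_years = 3,
                       n_locations = 7,
                       candidates_per_environment = c(89, 110),
                       n_qtl = 150,
                       qtl_at_markers = FALSE,
                       n_testers_per_pool = 4,
                       testers_per_env = 2,
                       pool_divergence = 0.35,
                       n_ancestral_haps = 3,
                       mosaic_switch_rate = 0.06,
                       traits = default_traits(),
                       missing_rate = 0,
                       mu = NULL,
                       var_year = NULL, var_location = NULL,
                       var_testcross = NULL, var_gxy = NULL,
                       var_gxe = NULL, var_error = NULL,
                       master_seed = 1L) {
  if (!is.null(mu)) traits$mean <- mu
  for (vn in c("var_year", "var_location", "var_testcross",
               "var_gxy", "var_gxe", "var_error")) {
    ov <- get(vn)
    if (!is.null(ov)) traits[[vn]] <- ov
  }
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_cM = as.numeric(chrom_length_cM),
    n_markers = as.integer(n_markers),
    n_founders_per_pool = as.integer(n_founders_per_pool),
    n_dh_families_per_pool = as.integer(n_dh_families_per_pool),
    dh_lines_per_family = as.integer(dh_lines_per_family),
    n_years = as.integer(n_years),
    n_locations = as.integer(n_locations),
    candidates_per_environment = as.integer(candidates_per_environment),
    n_qtl = as.integer(n_qtl),
    qtl_at_markers = isTRUE(qtl_at_markers),
    n_testers_per_pool = as.integer(n_testers_per_pool),
    testers_per_env = as.integer(testers_per_env),
    pool_divergence = as.numeric(pool_divergence),
    n_ancestral_haps = as.integer(n_ancestral_haps),
    mosaic_switch_rate = as.numeric(mosaic_switch_rate),
    traits = traits,
    missing_rate = as.numeric(missing_rate),
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "n_markers", "n_founders_per_pool",
              "n_dh_families_per_pool", "dh_lines_per_family", "n_years",
              "n_locations", "n_qtl", "n_testers_per_pool",
              "testers_per_env", "n_ancestral_haps")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop_invalid("sim_config: `", f, "` must be a count >= 1")
  }
  if (cfg$n_markers < cfg$n_chromosomes)
    stop_invalid("sim_config: n_markers must be >= n_chromosomes")
  if (length(cfg$chrom_length_cM) != 2L ||
      cfg$chrom_length_cM[1] > cfg$chrom_length_cM[2] ||
      cfg$chrom_length_cM[1] <= 0)
    stop_invalid("sim_config: chrom_length_cM must be a positive range c(low, high)")
  if (length(cfg$candidates_per_environment) != 2L ||
      cfg$candidates_per_environment[1] > cfg$candidates_per_environment[2] ||
      cfg$candidates_per_environment[1] < 1L)
    stop_invalid("sim_config: candidates_per_environment must be a range c(low, high), low >= 1")
  if (cfg$pool_divergence < 0 || cfg$pool_divergence > 1)
    stop_invalid("sim_config: pool_divergence must lie in [0, 1]")
  if (cfg$mosaic_switch_rate < 0)
    stop_invalid("sim_config: mosaic_switch_rate must be >= 0")
  if (!cfg$testers_per_env %in% 1:2)
    stop_invalid("sim_config: testers_per_env must be 1 or 2")
  if (cfg$testers_per_env > cfg$n_testers_per_pool)
    stop_invalid("sim_config: testers_per_env cannot exceed n_testers_per_pool")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_invalid("sim_config: missing_rate must lie in [0, 1)")
  tr <- cfg$traits
  need <- c("trait", "mean", "var_year", "var_location", "var_testcross",
            "var_gxy", "var_gxe", "var_error")
  if (!is.data.frame(tr) || !all(need %in% names(tr)) || nrow(tr) < 1L)
    stop_invalid("sim_config: traits must be a data.frame with columns ",
                 paste(need, collapse = ", "))
  vv <- as.matrix(tr[, grep("^var_", need, value = TRUE)])
  if (any(!is.finite(vv)) || any(vv < 0))
    stop_invalid("sim_config: all trait variance components must be finite and >= 0")
  if (anyDuplicated(tr$trait))
    stop_invalid("sim_config: trait names must be unique")
  if (length(cfg$master_seed) != 1L || is.na(cfg$master_seed))
    stop_invalid("sim_config: master_seed is mandatory")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Breeding-program simulator configuration\n")
  cat(sprintf("  genome : %d chromosomes (%g-%g cM), %d markers, %d QTL/trait\n",
              x$n_chromosomes, x$chrom_length_cM[1], x$chrom_length_cM[2],
              x$n_markers, x$n_qtl))
  cat(sprintf("  pools  : %d founders, %d families x %d DH lines per pool-year, divergence %.2f\n",
              x$n_founders_per_pool, x$n_dh_families_per_pool,
              x$dh_lines_per_family, x$pool_divergence))
  cat(sprintf("  trials : %d years x %d locations, %d-%d candidates/env, %d testers/pool\n",
              x$n_years, x$n_locations, x$candidates_per_environment[1],
              x$candidates_per_environment[2], x$n_testers_per_pool))
  cat(sprintf("  traits : %s\n", paste(x$traits$trait, collapse = ", ")))
  cat(sprintf("  seed   : %d\n", x$master_seed))
  invisible(x)
}
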