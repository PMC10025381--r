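# Trial layout, true genetic effects and phenotype simulation.

#' Simulate a multi-environment testcross trial layout
#'
#' Every (year, location) pair is one environment. Each environment receives
#' one tester and a candidate count drawn uniformly from the configured
#' range; the tester pool alternates over locations, and the pattern shifts
#' by one location each year, so that both tester/candidate orientations
#' occur in every year (the two pools' testcross trials run in parallel)
#' while a given location flips its orientation from one year to the next,
#' as testcross networks that rotate their tester assignments do. One
#' consequence mirrored from such programs: training on the previous year
#' of the same location supplies candidates of the opposite pool, which is
#' why strict across-year/same-location prediction carries almost no
#' transferable marker signal. Within a year, the lines of
#' one DH family are dealt round-robin over that pool's environments, the
#' usual allocation that avoids confounding family with location; sib lines
#' therefore end up at different locations. Candidates are lines of the tester's opposite pool
#' from the breeding cycle (cohort) of the trial year; each candidate is used
#' in exactly one environment, so every hybrid is tested in a single plot
#' (unreplicated trial).
#'
#' @param line_info Line metadata (columns `line`, `pool`, `cohort`, `role`)
#'   as produced by [simulate_dataset()].
#' @param config A [sim_config()] object.
#' @return A data.frame (one row per plot-candidate) with columns `year`,
#'   `location`, `env`, `tester`, `candidate`, `candidate_pool`, `hybrid`.
#' @export
simulate_trial_layout <- function(line_info, config) {
  validate_sim_config(config)
  testers <- split(line_info$line[line_info$role == "tester"],
                   line_info$pool[line_info$role == "tester"])
  if (any(!c("Flint", "Dent") %in% names(testers)))
    stop_invalid("simulate_trial_layout: need testers in both pools")
  rows <- list()
  for (year in seq_len(config$n_years)) {
    idx <- line_info$role == "candidate" & line_info$cohort == year
    avail <- split(line_info$line[idx], line_info$pool[idx])
    fam_of <- stats::setNames(line_info$family[idx], line_info$line[idx])
    # Deal each family's lines round-robin over that year's environments of
    # its pool, as trial networks do to avoid confounding family with
    # location: sib lines end up at different locations.
    locs <- seq_len(config$n_locations)
    pools_of_loc <- ifelse((locs + year) %% 2L == 0L, "Flint", "Dent")
    env_queue <- list()
    for (cand_pool in c("Flint", "Dent")) {
      cand <- avail[[cand_pool]] %||% character(0)
      cand <- cand[order(fam_of[cand], sample(length(cand)),
                         method = "radix")]
      n_env <- sum(pools_of_loc == cand_pool)
      if (n_env > 0L && length(cand))
        env_queue[[cand_pool]] <- split(cand, rep_len(seq_len(n_env),
                                                      length(cand)))
    }
    slot <- list(Flint = 0L, Dent = 0L)
    for (loc in locs) {
      cand_pool <- pools_of_loc[loc]
      tester_pool <- setdiff(c("Flint", "Dent"), cand_pool)
      rng <- config$candidates_per_environment
      n_cand <- if (rng[1] == rng[2]) rng[1] else
        sample(seq.int(rng[1], rng[2]), 1L)
      slot[[cand_pool]] <- slot[[cand_pool]] + 1L
      pool_avail <- env_queue[[cand_pool]][[slot[[cand_pool]]]]
      if (is.null(pool_avail) || length(pool_avail) < n_cand)
        stop_invalid("simulate_trial_layout: not enough unused ", cand_pool,
                     " candidates in year ", year, " (need ", n_cand,
                     ", have ", length(pool_avail), ")")
      cand <- sample(pool_avail, n_cand)
      n_tst <- min(config$testers_per_env, length(testers[[tester_pool]]))
      tst <- if (length(testers[[tester_pool]]) == n_tst)
        testers[[tester_pool]] else sample(testers[[tester_pool]], n_tst)
      # second tester (if any) covers a ~25% minority of the candidates
      tester <- rep(tst[1L], n_cand)
      if (n_tst == 2L) {
        n_minor <- max(1L, round(0.25 * n_cand))
        tester[seq_len(n_minor)] <- tst[2L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        year = year, location = loc,
        env = sprintf("Y%d_LOC%d", year, loc),
        tester = tester, candidate = cand, candidate_pool = cand_pool,
        hybrid = paste(cand, tester, sep = "_x_"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hybrid table with explicit Flint-side and Dent-side parents.
hybrid_parent_table <- function(layout) {
  flint <- ifelse(layout$candidate_pool == "Flint",
                  layout$candidate, layout$tester)
  dent <- ifelse(layout$candidate_pool == "Dent",
                 layout$candidate, layout$tester)
  data.frame(hybrid = layout$hybrid, flint_parent = flint,
             dent_parent = dent, env = layout$env, year = layout$year,
             location = layout$location, stringsAsFactors = FALSE)
}

#' Draw the true genetic architecture and environmental effects
#'
#' For each trait, additive testcross effects are drawn per QTL and pool and
#' applied to the parental QTL dosages of every hybrid in the layout.
#' Genotype-by-year and genotype-by-environment interactions are generated
#' as year- and environment-specific QTL-effect deviations, i.e. they are
#' genetically structured: a hybrid's interaction deviation is a property of
#' its genotype within that year/environment, which is what lets training
#' data from the same year or environment capture it. All drawn components
#' are rescaled so that their realized population variances equal the
#' configured components exactly (testcross variance over all hybrids;
#' interaction variances within each year/environment; year and
#' location-within-year effect variances over their levels).
#'
#' @param layout Trial layout from [simulate_trial_layout()].
#' @param qtl_geno Lines x QTL-loci dosage matrix (haplotype scale 0/1).
#' @param loci Full locus map from the simulator (with `is_marker`, `trait`).
#' @param config A [sim_config()] object.
#' @return A list of class `true_effects`: one element per trait with QTL
#'   effect tables, year and environment effects, per-(hybrid, environment)
#'   genetic components and the residual SD.
#' @export
simulate_true_effects <- function(layout, qtl_geno, loci, config) {
  hyb <- hybrid_parent_table(layout)
  out <- list()
  qtl_of <- attr(loci, "qtl")
  for (i in seq_len(nrow(config$traits))) {
    tr <- config$traits[i, ]
    qtl <- qtl_of[[tr$trait]]
    Zf <- qtl_geno[hyb$flint_parent, qtl, drop = FALSE]
    Zd <- qtl_geno[hyb$dent_parent, qtl, drop = FALSE]
    nq <- length(qtl)

    af <- stats::rnorm(nq); ad <- stats::rnorm(nq)
    g_main_raw <- drop(Zf %*% af + Zd %*% ad)
    g_main <- scale_to_var(g_main_raw, tr$var_testcross)
    v_raw <- sum((g_main_raw - mean(g_main_raw))^2) / length(g_main_raw)
    s_eff <- if (v_raw > 0 && tr$var_testcross > 0)
      sqrt(tr$var_testcross / v_raw) else 0

    g_year <- numeric(nrow(hyb))
    for (y in unique(hyb$year)) {
      idx <- hyb$year == y
      raw <- drop(Zf[idx, , drop = FALSE] %*% stats::rnorm(nq) +
                    Zd[idx, , drop = FALSE] %*% stats::rnorm(nq))
      g_year[idx] <- scale_to_var(raw, tr$var_gxy)
    }

    g_env <- numeric(nrow(hyb))
    for (e in unique(hyb$env)) {
      idx <- hyb$env == e
      raw <- drop(Zf[idx, , drop = FALSE] %*% stats::rnorm(nq) +
                    Zd[idx, , drop = FALSE] %*% stats::rnorm(nq))
      g_env[idx] <- scale_to_var(raw, tr$var_gxe)
    }

    years <- sort(unique(layout$year))
    q <- scale_to_var(stats::rnorm(length(years)), tr$var_year)
    names(q) <- years

    envs <- unique(layout[, c("year", "env")])
    p <- numeric(nrow(envs))
    names(p) <- envs$env
    for (y in years) {
      idx <- envs$year == y
      p[idx] <- scale_to_var(stats::rnorm(sum(idx)), tr$var_location)
    }

    out[[tr$trait]] <- list(
      trait = tr$trait, mu = tr$mean,
      qtl = qtl,
      qtl_effects = data.frame(locus = qtl, flint = af * s_eff,
                               dent = ad * s_eff, stringsAsFactors = FALSE),
      year_effects = q, env_effects = p,
      genetic = data.frame(hybrid = hyb$hybrid, env = hyb$env,
                           year = hyb$year,
                           g_main = g_main, g_year = g_year, g_env = g_env,
                           g_total = g_main + g_year + g_env,
                           stringsAsFactors = FALSE),
      residual_sd = sqrt(tr$var_error))
  }
  class(out) <- "true_effects"
  out
}

#' Simulate unreplicated plot phenotypes
#'
#' One plot value per (hybrid, environment, trait):
#' `y = mu + year + location(year) + g_total(hybrid, env) + e`, with
#' `g_total` the hybrid's genetic value in that environment (testcross value
#' plus genotype-by-year and genotype-by-environment deviations) and `e` an
#' independent plot residual.
#'
#' @param layout Trial layout from [simulate_trial_layout()].
#' @param effects A `true_effects` object from [simulate_true_effects()].
#' @param config A [sim_config()] object.
#' @return A data.frame of plot records: `plot`, `year`, `location`, `env`,
#'   `hybrid`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(layout, effects, config) {
  plots <- list()
  for (tr in names(effects)) {
    ef <- effects[[tr]]
    stopifnot(all(layout$hybrid == ef$genetic$hybrid))
    e <- stats::rnorm(nrow(layout), 0, ef$residual_sd)
    plots[[tr]] <- data.frame(
      plot = sprintf("P%05d_%s", seq_len(nrow(layout)), tr),
      year = layout$year, location = layout$location, env = layout$env,
      hybrid = layout$hybrid, trait = tr,
      value = ef$mu + unname(ef$year_effects[as.character(layout$year)]) +
        unname(ef$env_effects[layout$env]) + ef$genetic$g_total + e,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, plots)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic testcross dataset
#'
#' End-to-end draw of the synthetic breeding program: linkage map and
#' unobserved QTL positions, diverged founder pools, tester lines, one
#' cohort of DH families per pool and year, the trial layout, the true
#' genetic architecture, and unreplicated plot phenotypes. The ambient RNG
#' is seeded from `config$master_seed`, so identical configurations yield
#' bit-identical datasets.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `tc_dataset` with elements `config`, `map`
#'   (marker map), `loci` (markers + QTL), `geno` (parental lines x markers
#'   dosage matrix on the 0/1 haplotype scale, with missing calls if
#'   `missing_rate > 0`), `qtl_geno`, `line_info`, `layout`, `hybrids`
#'   (hybrid to Flint-/Dent-parent table), `plots` (phenotypes) and `truth`
#'   (the `true_effects` object).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$master_seed)
  map <- simulate_genome_map(config)
  loci <- add_qtl_loci(map, config)
  founders <- simulate_founder_pools(config, loci)

  rename_testers <- function(tl, prefix) {
    ids <- sprintf("%s%d", prefix, seq_len(nrow(tl$geno)))
    rownames(tl$geno) <- ids
    tl$info$line <- ids
    tl$info$family <- paste0(prefix, "_FAM")
    tl$info$role <- "tester"
    tl$info$cohort <- 0L
    tl
  }
  t_fl <- rename_testers(
    simulate_dh_lines(founders, config, loci, pool = "Flint",
                      n_families = config$n_testers_per_pool,
                      lines_per_family = 1L, cohort = "T"), "FT")
  t_de <- rename_testers(
    simulate_dh_lines(founders, config, loci, pool = "Dent",
                      n_families = config$n_testers_per_pool,
                      lines_per_family = 1L, cohort = "T"), "DT")

  cohorts <- list(t_fl, t_de)
  for (year in seq_len(config$n_years)) {
    for (pool in c("Flint", "Dent")) {
      dh <- simulate_dh_lines(founders, config, loci, pool = pool,
                              cohort = year)
      dh$info$role <- "candidate"
      cohorts[[length(cohorts) + 1L]] <- dh
    }
  }
  geno_loci <- do.call(rbind, lapply(cohorts, `[[`, "geno"))
  line_info <- do.call(rbind, lapply(cohorts, `[[`, "info"))
  line_info$cohort <- as.integer(line_info$cohort)
  rownames(line_info) <- NULL

  layout <- simulate_trial_layout(line_info, config)
  qtl_cols <- unique(unlist(attr(loci, "qtl")))
  qtl_geno <- geno_loci[, qtl_cols, drop = FALSE]
  truth <- simulate_true_effects(layout, qtl_geno, loci, config)
  plots <- simulate_phenotypes(layout, truth, config)

  geno <- geno_loci[, loci$locus[loci$is_marker], drop = FALSE]
  if (config$missing_rate > 0) {
    drop_mask <- stats::runif(length(geno)) < config$missing_rate
    geno[drop_mask] <- NA_real_
  }

  structure(list(config = config, map = map, loci = loci, geno = geno,
                 qtl_geno = qtl_geno, line_info = line_info, layout = layout,
                 hybrids = hybrid_parent_table(layout), plots = plots,
                 truth = truth),
            class = "tc_dataset")
}

#' @export
print.tc_dataset <- function(x, ...) {
  cat("Synthetic testcross dataset\n")
  cat(sprintf("  %d parental lines (%d markers), %d hybrids in %d environments, %d plot records\n",
              nrow(x$geno), ncol(x$geno), nrow(x$hybrids),
              length(unique(x$layout$env)), nrow(x$plots)))
  cat(sprintf("  years: %s; traits: %s\n",
              paste(sort(unique(x$layout$year)), collapse = ", "),
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}
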