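# End-to-end orchestration: simulate -> qc -> adjust -> cross-validate,
# driven by one flat configuration, with deterministic plain-TSV outputs
# and a JSON run manifest so any stage can be re-entered independently.

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic dataset (or load genotype/phenotype
#' tables from files), (2) marker and line QC plus within-pool mean
#' imputation, (3) adjustment of plot values for year and
#' location-within-year effects, (4) replicated cross-validation over the
#' requested training-set designs, (5) summary reports and a run manifest.
#' Re-running with an identical configuration reproduces byte-identical
#' TSV outputs.
#'
#' @param config A named list or path to a YAML file with entries:
#'   `seed` (mandatory), `out_dir` (mandatory), `simulator` (arguments for
#'   [sim_config()]; omit to load data from `paths$genotypes`,
#'   `paths$map`, `paths$phenotypes`, `paths$layout`), `qc` (`min_het`,
#'   `min_call_rate`, `max_line_missing`), `prediction` (`method`,
#'   `n_iter`, `burn_in`), `cv` (`designs`, `n_replications`,
#'   `prev_years`, `complete_size`).
#' @return The run manifest (named list), invisibly; all outputs are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop_invalid("run_pipeline: config must set a seed")
  if (is.null(config$out_dir))
    stop_invalid("run_pipeline: config must set out_dir")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  qc_cfg <- config$qc %||% list()
  pr_cfg <- config$prediction %||% list()
  cv_cfg <- config$cv %||% list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("hybridcv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = label_hash(paste(deparse(config), collapse = "")),
    stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  # stage 1: data
  if (!is.null(config$simulator)) {
    sim_args <- config$simulator
    sim_args$master_seed <- sim_args$master_seed %||% config$seed
    if (!is.null(sim_args$traits)) sim_args$traits <- as.data.frame(sim_args$traits)
    cfg <- do.call(sim_config, sim_args)
    dataset <- t_stage("simulate", simulate_dataset(cfg))
    write_dataset(dataset, file.path(out, "data"))
    geno_raw <- dataset$geno
    map <- dataset$map
    plots <- dataset$plots
    hybrids <- dataset$hybrids
    pools <- stats::setNames(dataset$line_info$pool, dataset$line_info$line)
  } else {
    pth <- config$paths
    if (is.null(pth$genotypes) || is.null(pth$phenotypes) ||
        is.null(pth$layout))
      stop_invalid("run_pipeline: without a simulator section, paths$genotypes, paths$phenotypes and paths$layout are required")
    geno_raw <- if (grepl("\\.vcf$", pth$genotypes))
      read_genotypes_vcf(pth$genotypes) else read_dosage_tsv(pth$genotypes)
    map <- if (!is.null(pth$map)) read_tsv(pth$map) else NULL
    plots <- read_tsv(pth$phenotypes)
    layout <- read_tsv(pth$layout)
    hybrids <- hybrid_parent_table(layout)
    pools <- NULL
    lines_tbl <- if (!is.null(pth$lines)) read_tsv(pth$lines) else NULL
    if (!is.null(lines_tbl))
      pools <- stats::setNames(lines_tbl$pool, lines_tbl$line)
    dataset <- NULL
  }
  manifest$stages$data <- list(n_lines = nrow(geno_raw),
                               n_markers = ncol(geno_raw),
                               n_plots = nrow(plots))

  # stage 2: qc + imputation
  fm <- t_stage("qc", filter_markers(geno_raw,
                                     min_het = qc_cfg$min_het %||% 0.10,
                                     min_call_rate = qc_cfg$min_call_rate %||% 0.90))
  geno_f <- geno_raw[, fm$kept, drop = FALSE]
  kept_lines <- filter_lines(geno_f,
                             max_missing = qc_cfg$max_line_missing %||% 0.10)
  geno_f <- geno_f[kept_lines, , drop = FALSE]
  if (is.null(pools)) pools <- rep("all", nrow(geno_f))
  geno_i <- impute_missing(geno_f, pools)
  write_tsv(fm$stats, file.path(out, "marker_stats.tsv"))
  write_tsv(data.frame(line = kept_lines), file.path(out, "kept_lines.tsv"))
  write_dosage_tsv(geno_i, file.path(out, "genotypes_imputed.tsv"))
  if (isTRUE(qc_cfg$diagnostics %||% TRUE) && !is.null(map)) {
    pool_of <- if (is.null(names(pools)))
      stats::setNames(pools, rownames(geno_i)) else pools[rownames(geno_i)]
    map_k <- map[map$marker %in% colnames(geno_i), , drop = FALSE]
    ld <- do.call(rbind, lapply(unique(pool_of), function(p) {
      rows <- geno_i[pool_of == p, , drop = FALSE]
      if (nrow(rows) < 2L) return(NULL)
      cbind(pool = p, ld_decay(rows, map_k, bin_width_cM = 1))
    }))
    write_tsv(ld, file.path(out, "ld_decay.tsv"))
    write_tsv(pca_projection(geno_i, 5), file.path(out, "pca_scores.tsv"))
    if (nrow(hybrids) <= 2000) {
      H <- hybrid_dosage_matrix(hybrids, geno_i)
      S <- pairwise_distance_summary(H, stats::setNames(hybrids$env,
                                                        hybrids$hybrid))
      write_tsv(data.frame(env = rownames(S), S, check.names = FALSE),
                file.path(out, "rogers_distance_environments.tsv"))
    }
  }
  manifest$stages$qc <- list(markers_kept = length(fm$kept),
                             lines_kept = length(kept_lines))

  # stage 3: adjustment
  est <- t_stage("adjust", fit_environment_effects(plots))
  adjusted <- adjust_phenotypes(plots, est)
  eff_tbl <- do.call(rbind, lapply(est, function(e)
    rbind(data.frame(trait = e$trait, term = "mu", level = "",
                     estimate = e$mu, stringsAsFactors = FALSE),
          data.frame(trait = e$trait, term = "year", level = names(e$q),
                     estimate = unname(e$q), stringsAsFactors = FALSE),
          data.frame(trait = e$trait, term = "location(year)",
                     level = names(e$p), estimate = unname(e$p),
                     stringsAsFactors = FALSE))))
  write_tsv(eff_tbl, file.path(out, "environment_effects.tsv"))
  write_tsv(adjusted, file.path(out, "phenotypes_adjusted.tsv"))
  manifest$stages$adjust <- list(n_rows = nrow(adjusted))

  # stage 4: cross-validation
  ok_hyb <- hybrids$flint_parent %in% rownames(geno_i) &
    hybrids$dent_parent %in% rownames(geno_i)
  cv <- t_stage("cv", run_cross_validation(
    adjusted[adjusted$hybrid %in% hybrids$hybrid[ok_hyb], , drop = FALSE],
    hybrids[ok_hyb, , drop = FALSE], geno_i,
    designs = cv_cfg$designs %||% CV_DESIGNS,
    n_replications = cv_cfg$n_replications %||% 100L,
    seed = config$seed,
    method = pr_cfg$method %||% "RR-BLUP",
    prev_years = cv_cfg$prev_years %||% 1L,
    complete_size = cv_cfg$complete_size %||% 80L,
    n_iter = pr_cfg$n_iter %||% 10000L,
    burn_in = pr_cfg$burn_in %||% 1000L))
  write_tsv(cv, file.path(out, "cv_results.tsv"))
  summary <- summarize_results(cv)
  write_reports(summary, out)
  manifest$stages$cv <- list(n_rows = nrow(cv),
                             designs = unique(cv$design))

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write cross-validation summary reports
#'
#' Writes the per-(design, trait, environment) median-accuracy table and a
#' design-family comparison (median over environments per design and
#' trait). Regeneration is idempotent.
#'
#' @param summary Output of [summarize_results()] (may be empty).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_reports <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(summary) || nrow(summary) == 0L) {
    warning("write_reports: empty summary; writing empty reports")
    summary <- data.frame(design = character(), family = character(),
                          trait = character(), env = character(),
                          year = numeric(), location = numeric(),
                          median_r = numeric(), q25 = numeric(),
                          q75 = numeric(), n_reps = integer(),
                          n_missing = integer())
  }
  write_tsv(summary, file.path(dir, "cv_summary.tsv"))
  if (nrow(summary)) {
    key <- interaction(summary$design, summary$trait, drop = TRUE)
    cmp <- do.call(rbind, lapply(split(summary, key), function(d)
      data.frame(design = d$design[1L], family = d$family[1L],
                 trait = d$trait[1L],
                 median_r = stats::median(d$median_r, na.rm = TRUE),
                 n_envs = sum(!is.na(d$median_r)),
                 stringsAsFactors = FALSE)))
    cmp <- cmp[order(cmp$trait, cmp$design), ]
    rownames(cmp) <- NULL
  } else {
    cmp <- data.frame(design = character(), family = character(),
                      trait = character(), median_r = numeric(),
                      n_envs = integer())
  }
  write_tsv(cmp, file.path(dir, "design_comparison.tsv"))
  invisible(dir)
}
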