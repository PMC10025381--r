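# Replicated cross-validation over the eight training-set designs.
#
# Design families (Fig.-1-style):
#   across year        CV1 (same location, previous year(s) -> complete set)
#                      CV2 (all previous-year sets -> current-year sets)
#   within environment CV3 (own training set -> own prediction set)
#                      CV4 (CV3 + same-location previous-year complete sets)
#                      CV5 (CV3 + all previous-year complete sets)
#   within year        CV6 (all current-year training sets -> prediction sets)
#                      CV7 (CV6 + same-location previous-year complete sets)
#                      CV8 (CV6 + all previous-year complete sets)
#
# Within a replication the 80/60/20 sampling of every environment is drawn
# once and shared by all designs; accuracies are always Pearson correlations
# computed within one environment.

CV_DESIGNS <- paste0("CV", 1:8)

design_scope <- function(design) {
  switch(design,
         CV2 = , CV6 = , CV8 = "year",
         CV1 = , CV3 = , CV4 = , CV5 = , CV7 = "env")
}

design_needs_previous <- function(design) {
  design %in% c("CV1", "CV2", "CV4", "CV5", "CV7", "CV8")
}

design_family <- function(design) {
  switch(design,
         CV1 = , CV2 = "across-year",
         CV3 = , CV4 = , CV5 = "within-environment",
         CV6 = , CV7 = , CV8 = "within-year")
}

#' Draw the per-environment complete/training/prediction sets
#'
#' For every environment a complete set of `min(complete_size, n)` hybrids
#' is sampled without replacement and split at random 3:1 into a training
#' and a prediction subset (80/60/20 at the defaults). Each environment's
#' draw is seeded from `(rep_seed, environment label)`, so within a
#' replication the assignment is by construction identical for every design
#' that uses it.
#'
#' @param hybrid_env Data.frame with columns `env`, `year`, `location`,
#'   `hybrid` (one row per hybrid; e.g. `dataset$hybrids`).
#' @param rep_seed Integer seed of this replication.
#' @param complete_size Target complete-set size (default 80).
#' @param train_frac Training fraction of the complete set (default 0.75).
#' @return An object of class `env_splits`: per environment a list with
#'   `env`, `year`, `location`, `complete`, `train`, `pred`. Environments
#'   with fewer than 4 hybrids are skipped with a warning.
#' @export
sample_complete_sets <- function(hybrid_env, rep_seed, complete_size = 80L,
                                 train_frac = 0.75) {
  stopifnot(all(c("env", "year", "location", "hybrid") %in% names(hybrid_env)))
  out <- list()
  for (e in sort(unique(hybrid_env$env), method = "radix")) {
    rows <- hybrid_env[hybrid_env$env == e, , drop = FALSE]
    hyb <- sort(rows$hybrid, method = "radix")
    if (length(hyb) < 4L) {
      warning("sample_complete_sets: skipping environment ", e,
              " with fewer than 4 hybrids")
      next
    }
    set.seed(derive_seed(rep_seed, label_hash(e)))
    complete <- sample(hyb, min(complete_size, length(hyb)))
    n_train <- round(train_frac * length(complete))
    out[[e]] <- list(env = e, year = rows$year[1L],
                     location = rows$location[1L],
                     complete = complete,
                     train = complete[seq_len(n_train)],
                     pred = complete[-seq_len(n_train)])
  }
  structure(out, class = "env_splits", rep_seed = rep_seed)
}

splits_env_table <- function(splits) {
  data.frame(env = vapply(splits, `[[`, character(1), "env"),
             year = vapply(splits, function(s) s$year[1L], numeric(1)),
             location = vapply(splits, function(s) s$location[1L], numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

set_rows <- function(splits, envs, what) {
  do.call(rbind, lapply(envs, function(e)
    data.frame(env = e, hybrid = splits[[e]][[what]],
               stringsAsFactors = FALSE)))
}

design_unavailable <- function(msg) {
  stop(structure(class = c("design_unavailable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Assemble training and prediction rows for one design and target
#'
#' Applies one of the eight training-set design rules to the shared
#' per-environment splits. Targets are single environments for CV1, CV3,
#' CV4, CV5 and CV7, and whole years for CV2, CV6 and CV8 (one model per
#' year, scored per environment downstream). Any hybrid appearing in the
#' prediction rows is removed from the training rows as a leakage
#' safeguard.
#'
#' @param design `"CV1"` to `"CV8"`.
#' @param target Target environment label (env-scope designs) or target
#'   year (year-scope designs: CV2, CV6, CV8).
#' @param splits An `env_splits` object from [sample_complete_sets()].
#' @param prev_years Number of previous years to draw from (1 or 2).
#' @return A list with data.frames `train` and `pred` (columns `env`,
#'   `hybrid`). Signals a `design_unavailable` condition when required
#'   previous-year data do not exist.
#' @export
assemble_design <- function(design, target, splits, prev_years = 1L) {
  design <- match.arg(design, CV_DESIGNS)
  stopifnot(prev_years %in% c(1L, 2L))
  envs <- splits_env_table(splits)
  scope <- design_scope(design)
  if (scope == "env") {
    if (!target %in% envs$env)
      design_unavailable(paste0("environment ", target, " has no splits"))
    t_year <- envs$year[envs$env == target]
    t_loc <- envs$location[envs$env == target]
  } else {
    t_year <- as.numeric(target)
    if (!any(envs$year == t_year))
      design_unavailable(paste0("year ", target, " has no environments"))
    t_loc <- NA
  }
  year_envs <- envs$env[envs$year == t_year]

  prev_all <- character(0); prev_loc <- character(0)
  if (design_needs_previous(design)) {
    py <- t_year - seq_len(prev_years)
    prev_all <- envs$env[envs$year %in% py]
    if (length(unique(envs$year[envs$year %in% py])) < prev_years)
      design_unavailable(paste0(design, ": no data for ", prev_years,
                                " previous year(s) before year ", t_year))
    if (design %in% c("CV1", "CV4", "CV7")) {
      prev_loc <- envs$env[envs$year %in% py & envs$location == t_loc]
      if (length(prev_loc) < prev_years)
        design_unavailable(paste0(design, ": location ", t_loc,
                                  " was not tested in the previous year(s)"))
    }
  }

  train <- switch(design,
    CV1 = set_rows(splits, prev_loc, "complete"),
    CV2 = set_rows(splits, prev_all, "complete"),
    CV3 = set_rows(splits, target, "train"),
    CV4 = rbind(set_rows(splits, target, "train"),
                set_rows(splits, prev_loc, "complete")),
    CV5 = rbind(set_rows(splits, target, "train"),
                set_rows(splits, prev_all, "complete")),
    CV6 = set_rows(splits, year_envs, "train"),
    CV7 = rbind(set_rows(splits, year_envs, "train"),
                set_rows(splits, prev_loc, "complete")),
    CV8 = rbind(set_rows(splits, year_envs, "train"),
                set_rows(splits, prev_all, "complete")))

  pred <- switch(design,
    CV1 = set_rows(splits, target, "complete"),
    CV2 = set_rows(splits, year_envs, "complete"),
    CV3 = , CV4 = , CV5 = , CV7 = set_rows(splits, target, "pred"),
    CV6 = , CV8 = set_rows(splits, year_envs, "pred"))

  train <- train[!train$hybrid %in% pred$hybrid, , drop = FALSE]
  rownames(train) <- rownames(pred) <- NULL
  list(design = design, train = train, pred = pred)
}

#' Per-environment Pearson prediction accuracy
#'
#' Pearson correlation between predicted and observed (adjusted) values,
#' computed strictly within one environment at a time (never pooled), to
#' avoid stratification effects. Environments with fewer than `min_n`
#' scored hybrids or zero variance in either vector yield `NA`.
#'
#' @param predictions Data.frame `hybrid`, `predicted` (from
#'   [predict.marker_effects()]).
#' @param observations Data.frame `hybrid`, `env`, `observed`.
#' @param min_n Minimum hybrids per environment (default 3).
#' @return Data.frame `env`, `r`, `n`.
#' @export
accuracy_per_environment <- function(predictions, observations, min_n = 3L) {
  d <- merge(observations, predictions, by = "hybrid")
  envs <- sort(unique(d$env), method = "radix")
  r <- vapply(envs, function(e) {
    s <- d[d$env == e, , drop = FALSE]
    if (nrow(s) < min_n || stats::sd(s$observed) == 0 ||
        stats::sd(s$predicted) == 0) return(NA_real_)
    stats::cor(s$observed, s$predicted)
  }, numeric(1))
  n <- vapply(envs, function(e) sum(d$env == e), integer(1))
  data.frame(env = envs, r = unname(r), n = unname(n),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run replicated cross-validation over training-set designs
#'
#' For each replication the per-environment 80/60/20 splits are drawn once
#' (shared across designs), then every (design, trait, target) is
#' assembled, fitted, predicted and scored per environment.
#'
#' @param adjusted Adjusted plot records (columns `env`, `year`,
#'   `location`, `hybrid`, `trait`, `value_adj`), see [adjust_phenotypes()].
#' @param hybrids Hybrid-parent table (`hybrid`, `flint_parent`,
#'   `dent_parent`, `env`, `year`, `location`).
#' @param geno Imputed parental lines x markers dosage matrix.
#' @param designs Subset of `"CV1"`..`"CV8"`.
#' @param traits Traits to evaluate (default: all in `adjusted`).
#' @param n_replications Cross-validation replications (default 100).
#' @param seed Master seed; each replication derives an independent
#'   substream from it.
#' @param method `"RR-BLUP"` (default) or one of the Bayesian samplers.
#' @param prev_years Previous years used by designs that draw on earlier
#'   data (1 or 2).
#' @param complete_size Per-environment complete-set size (default 80).
#' @param n_iter,burn_in Gibbs settings when a Bayesian method is chosen.
#' @return A data.frame of class `cv_result`: `design`, `family`, `trait`,
#'   `target`, `env`, `year`, `location`, `replication`, `r`, `n_train`.
#'   Unavailable (design, target) combinations are recorded with `r = NA`.
#' @export
run_cross_validation <- function(adjusted, hybrids, geno,
                                 designs = CV_DESIGNS,
                                 traits = NULL,
                                 n_replications = 100L,
                                 seed = 1L,
                                 method = c("RR-BLUP", "BRR", "BayesA", "BayesB"),
                                 prev_years = 1L,
                                 complete_size = 80L,
                                 n_iter = 10000L, burn_in = 1000L) {
  method <- match.arg(method)
  designs <- match.arg(designs, CV_DESIGNS, several.ok = TRUE)
  if (is.null(traits)) traits <- unique(adjusted$trait)
  hybrid_env <- unique(hybrids[, c("env", "year", "location", "hybrid")])

  lookup <- lapply(split(adjusted, adjusted$trait), function(d)
    stats::setNames(d$value_adj, paste(d$hybrid, d$env, sep = "@")))

  results <- list()
  for (rep in seq_len(n_replications)) {
    rep_seed <- derive_seed(seed, rep * 7919L)
    splits <- sample_complete_sets(hybrid_env, rep_seed,
                                   complete_size = complete_size)
    envs <- splits_env_table(splits)
    for (design in designs) {
      scope <- design_scope(design)
      targets <- if (scope == "year") sort(unique(envs$year)) else
        envs$env[order(envs$year, envs$location)]
      for (target in targets) {
        asm <- tryCatch(
          assemble_design(design, target, splits, prev_years = prev_years),
          design_unavailable = function(cnd) NULL)
        for (tr in traits) {
          if (is.null(asm)) {
            t_year <- if (scope == "year") as.numeric(target) else
              envs$year[envs$env == target]
            results[[length(results) + 1L]] <- data.frame(
              design = design, family = design_family(design), trait = tr,
              target = as.character(target),
              env = if (scope == "year") NA_character_ else target,
              year = t_year,
              location = if (scope == "year") NA_real_ else
                envs$location[envs$env == target],
              replication = rep, r = NA_real_, n_train = NA_integer_,
              stringsAsFactors = FALSE)
            next
          }
          key <- lookup[[tr]]
          y_train <- unname(key[paste(asm$train$hybrid, asm$train$env,
                                      sep = "@")])
          train_tbl <- hybrids[match(asm$train$hybrid, hybrids$hybrid), ,
                               drop = FALSE]
          des <- build_design_matrices(train_tbl, geno, y = y_train)
          fit <- switch(method,
                        `RR-BLUP` = fit_rrblup(des),
                        fit_bayes(des, method = method, n_iter = n_iter,
                                  burn_in = burn_in,
                                  seed = derive_seed(rep_seed,
                                                     label_hash(paste(design, target, tr)))))
          pred_tbl <- hybrids[match(asm$pred$hybrid, hybrids$hybrid), ,
                              drop = FALSE]
          preds <- predict(fit, build_design_matrices(pred_tbl, geno))
          obs <- data.frame(hybrid = asm$pred$hybrid, env = asm$pred$env,
                            observed = unname(key[paste(asm$pred$hybrid,
                                                        asm$pred$env,
                                                        sep = "@")]),
                            stringsAsFactors = FALSE)
          acc <- accuracy_per_environment(preds, obs)
          results[[length(results) + 1L]] <- data.frame(
            design = design, family = design_family(design), trait = tr,
            target = as.character(target), env = acc$env,
            year = envs$year[match(acc$env, envs$env)],
            location = envs$location[match(acc$env, envs$env)],
            replication = rep, r = acc$r, n_train = nrow(asm$train),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Median accuracies per design, trait and environment
#'
#' Medians (and quartiles) of the per-environment Pearson accuracies over
#' replications; missing replications (unavailable designs or undefined
#' correlations) are excluded from the quantiles and counted in
#' `n_missing`.
#'
#' @param results A `cv_result` table from [run_cross_validation()].
#' @return A data.frame with one row per (design, trait, env).
#' @export
summarize_results <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    stop_invalid("summarize_results: empty result table")
  results <- results[!is.na(results$env), , drop = FALSE]
  key <- interaction(results$design, results$trait, results$env, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    ok <- !is.na(d$r)
    data.frame(design = d$design[1L], family = d$family[1L],
               trait = d$trait[1L], env = d$env[1L], year = d$year[1L],
               location = d$location[1L],
               median_r = if (any(ok)) stats::median(d$r[ok]) else NA_real_,
               q25 = if (any(ok)) unname(stats::quantile(d$r[ok], 0.25)) else NA_real_,
               q75 = if (any(ok)) unname(stats::quantile(d$r[ok], 0.75)) else NA_real_,
               n_reps = sum(ok), n_missing = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$design, out$trait, out$year, out$location), ]
  rownames(out) <- NULL
  out
}
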