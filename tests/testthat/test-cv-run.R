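# End-to-end cross-validation runs and result summaries.

cv_inputs <- function(master_seed = 7) {
  ds <- tiny_dataset()
  adj <- adjust_phenotypes(ds$plots, fit_environment_effects(ds$plots))
  list(ds = ds, adj = adj)
}

test_that("per-environment accuracy matches the Pearson formula", {
  obs <- data.frame(hybrid = paste0("h", 1:5), env = "E1",
                    observed = c(1.2, 0.8, 2.4, 1.7, 0.3))
  pred_id <- data.frame(hybrid = paste0("h", 1:5),
                        predicted = c(1.2, 0.8, 2.4, 1.7, 0.3))
  expect_equal(accuracy_per_environment(pred_id, obs)$r, 1)
  pred_neg <- transform(pred_id, predicted = -predicted)
  expect_equal(accuracy_per_environment(pred_neg, obs)$r, -1)
  pred5 <- data.frame(hybrid = paste0("h", 1:5),
                      predicted = c(2.1, 0.4, 1.9, 2.2, 0.9))
  r_hand <- {
    x <- pred5$predicted; y <- obs$observed
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(accuracy_per_environment(pred5, obs)$r, r_hand)
  # too few hybrids or zero variance -> NA
  expect_true(is.na(accuracy_per_environment(pred5[1:2, ], obs[1:2, ])$r))
  pred_const <- transform(pred5, predicted = 1)
  expect_true(is.na(accuracy_per_environment(pred_const, obs)$r))
})

test_that("a single replication yields one scored row per trait and target", {
  inp <- cv_inputs()
  cv <- run_cross_validation(inp$adj, inp$ds$hybrids, inp$ds$geno,
                             designs = "CV3", n_replications = 1,
                             seed = 4, complete_size = 20)
  n_env <- length(unique(inp$ds$layout$env))
  n_traits <- length(unique(inp$adj$trait))
  expect_equal(nrow(cv), n_env * n_traits)
  expect_true(all(cv$r >= -1 & cv$r <= 1, na.rm = TRUE))
  expect_true(all(cv$n_train == 15))   # 20-hybrid complete sets split 3:1
})

test_that("identical master seeds give bit-identical result tables", {
  inp <- cv_inputs()
  cv1 <- run_cross_validation(inp$adj, inp$ds$hybrids, inp$ds$geno,
                              designs = c("CV3", "CV6"), n_replications = 2,
                              seed = 8, complete_size = 20)
  cv2 <- run_cross_validation(inp$adj, inp$ds$hybrids, inp$ds$geno,
                              designs = c("CV3", "CV6"), n_replications = 2,
                              seed = 8, complete_size = 20)
  expect_identical(cv1, cv2)
})

test_that("unavailable designs are recorded as missing, not zero", {
  inp <- cv_inputs()
  cv <- run_cross_validation(inp$adj, inp$ds$hybrids, inp$ds$geno,
                             designs = "CV1", n_replications = 1,
                             seed = 4, complete_size = 20)
  y1 <- cv[cv$year == 1, ]
  expect_true(all(is.na(y1$r)))
  expect_true(all(is.na(y1$n_train)))
  expect_gt(sum(!is.na(cv$r[cv$year > 1])), 0)
})

test_that("noise-free within-environment prediction is near-perfect", {
  # marker-tagged QTL, no plot error, no location-genetic interaction:
  # CV3 should recover the within-environment genetic ranking almost exactly
  cfg <- sim_config(n_locations = 2, n_years = 1,
                    n_founders_per_pool = 6,
                    n_dh_families_per_pool = 20, dh_lines_per_family = 5,
                    n_markers = 100, n_qtl = 10, qtl_at_markers = TRUE,
                    testers_per_env = 1,
                    candidates_per_environment = c(100, 100),
                    var_error = 0, var_gxe = 0, master_seed = 12)
  ds <- simulate_dataset(cfg)
  adj <- adjust_phenotypes(ds$plots, fit_environment_effects(ds$plots))
  cv <- run_cross_validation(adj, ds$hybrids, ds$geno, designs = "CV3",
                             n_replications = 3, seed = 5)
  expect_gt(median(cv$r, na.rm = TRUE), 0.95)
})

test_that("summaries compute medians and track missing replications", {
  res <- data.frame(design = "CV3", family = "within-environment",
                    trait = "t", target = "E1", env = "E1", year = 1,
                    location = 1, replication = 1:4,
                    r = c(0.1, 0.2, 0.3, NA), n_train = 60,
                    stringsAsFactors = FALSE)
  s <- summarize_results(res)
  expect_equal(s$median_r, 0.2)
  expect_equal(s$n_reps, 3L)
  expect_equal(s$n_missing, 1L)
  # order invariance and constant case
  res2 <- res[c(3, 1, 4, 2), ]
  expect_equal(summarize_results(res2)$median_r, 0.2)
  res3 <- transform(res, r = 0.4)
  expect_equal(summarize_results(res3)$median_r, 0.4)
  expect_error(summarize_results(res[0, ]), "empty")
})
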