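# Complete/training/prediction sampling and the eight design rules.

# A regular 3-year x 2-location grid with 100 hybrids per environment,
# built directly (no genetics needed for bookkeeping tests).
grid_hybrid_env <- function(n_years = 3, n_locs = 2, n_hyb = 100) {
  do.call(rbind, lapply(seq_len(n_years), function(y)
    do.call(rbind, lapply(seq_len(n_locs), function(l)
      data.frame(env = sprintf("Y%d_LOC%d", y, l), year = y, location = l,
                 hybrid = sprintf("Y%dL%dH%03d", y, l, seq_len(n_hyb)),
                 stringsAsFactors = FALSE)))))
}

test_that("environment splits are 80/60/20 with proportional fallback", {
  he <- grid_hybrid_env()
  sp <- sample_complete_sets(he, rep_seed = 5)
  s <- sp[["Y1_LOC1"]]
  expect_equal(length(s$complete), 80L)
  expect_equal(length(s$train), 60L)
  expect_equal(length(s$pred), 20L)
  expect_length(intersect(s$train, s$pred), 0)
  expect_setequal(c(s$train, s$pred), s$complete)

  he40 <- grid_hybrid_env(n_hyb = 40)
  sp40 <- sample_complete_sets(he40, rep_seed = 5)
  expect_equal(length(sp40[["Y1_LOC1"]]$complete), 40L)
  expect_equal(length(sp40[["Y1_LOC1"]]$train), 30L)
  expect_equal(length(sp40[["Y1_LOC1"]]$pred), 10L)

  expect_identical(sample_complete_sets(he, 5)[["Y2_LOC2"]],
                   sp[["Y2_LOC2"]])
  tiny <- grid_hybrid_env(n_years = 1, n_locs = 1, n_hyb = 3)
  expect_warning(sp3 <- sample_complete_sets(tiny, 5), "fewer than 4")
  expect_length(sp3, 0)
})

test_that("design assembly reproduces the rule arithmetic", {
  he <- grid_hybrid_env(n_years = 2, n_locs = 4)
  sp <- sample_complete_sets(he, rep_seed = 9)

  # CV6: all training subsets of the year -> 4 x 60
  a6 <- assemble_design("CV6", 2, sp)
  expect_equal(nrow(a6$train), 4 * 60)
  expect_equal(nrow(a6$pred), 4 * 20)

  # CV3: own training subset only
  a3 <- assemble_design("CV3", "Y2_LOC1", sp)
  expect_equal(nrow(a3$train), 60)
  expect_equal(a3$pred$hybrid, sp[["Y2_LOC1"]]$pred)

  # CV1: previous-year complete set of the same location
  a1 <- assemble_design("CV1", "Y2_LOC3", sp)
  expect_equal(a1$train$env, rep("Y1_LOC3", 80))
  expect_equal(nrow(a1$pred), 80)
  expect_true(all(a1$train$env != a1$pred$env))

  # CV2: all previous-year complete sets
  a2 <- assemble_design("CV2", 2, sp)
  expect_equal(nrow(a2$train), 4 * 80)
  expect_true(all(grepl("^Y1", a2$train$env)))
  expect_true(all(grepl("^Y2", a2$pred$env)))

  # CV4 = CV3 + previous same-location complete set
  a4 <- assemble_design("CV4", "Y2_LOC2", sp)
  expect_equal(nrow(a4$train), 60 + 80)

  # CV7 = CV6 + previous same-location complete set, scoring one location
  a7 <- assemble_design("CV7", "Y2_LOC2", sp)
  expect_equal(nrow(a7$train), 4 * 60 + 80)
  expect_equal(nrow(a7$pred), 20)

  # CV8 = CV6 + all previous complete sets
  a8 <- assemble_design("CV8", 2, sp)
  expect_equal(nrow(a8$train), 4 * 60 + 4 * 80)
})

test_that("CV5 training combines the own subset with 60 + 7 x 80 rows", {
  he <- grid_hybrid_env(n_years = 2, n_locs = 7)
  sp <- sample_complete_sets(he, rep_seed = 10)
  a5 <- assemble_design("CV5", "Y2_LOC4", sp)
  expect_equal(nrow(a5$train), 60 + 7 * 80)
  expect_equal(nrow(a5$pred), 20)
})

test_that("designs needing unavailable previous data signal the condition", {
  he <- grid_hybrid_env(n_years = 2, n_locs = 2)
  sp <- sample_complete_sets(he, rep_seed = 11)
  expect_error(assemble_design("CV1", "Y1_LOC1", sp),
               class = "design_unavailable")
  expect_error(assemble_design("CV2", 1, sp),
               class = "design_unavailable")
  expect_error(assemble_design("CV5", "Y2_LOC1", sp, prev_years = 2),
               class = "design_unavailable")
  # missing location in the previous year
  he_miss <- he[!(he$env == "Y1_LOC2"), ]
  sp_miss <- sample_complete_sets(he_miss, rep_seed = 11)
  expect_error(assemble_design("CV4", "Y2_LOC2", sp_miss),
               class = "design_unavailable")
})

test_that("prediction hybrids never remain in the training assembly", {
  # construct an overlap: the same hybrid name tested in two years
  he <- grid_hybrid_env(n_years = 2, n_locs = 2)
  he$hybrid[he$env == "Y1_LOC1"] <- sub("^Y1L1", "Y2L1", he$hybrid[he$env == "Y1_LOC1"])
  sp <- sample_complete_sets(he, rep_seed = 12)
  a1 <- assemble_design("CV1", "Y2_LOC1", sp)
  expect_length(intersect(a1$train$hybrid, a1$pred$hybrid), 0)
  for (d in c("CV3", "CV4", "CV5", "CV6", "CV7", "CV8")) {
    target <- if (d %in% c("CV6", "CV8")) 2 else "Y2_LOC1"
    a <- assemble_design(d, target, sp)
    expect_length(intersect(a$train$hybrid, a$pred$hybrid), 0)
  }
})

test_that("splits are shared byte-identically across designs", {
  he <- grid_hybrid_env()
  sp <- sample_complete_sets(he, rep_seed = 20)
  a3 <- assemble_design("CV3", "Y2_LOC1", sp)
  a6 <- assemble_design("CV6", 2, sp)
  # CV3's training subset is exactly CV6's rows for that environment
  expect_identical(a3$train$hybrid,
                   a6$train$hybrid[a6$train$env == "Y2_LOC1"])
  expect_identical(a3$pred$hybrid,
                   a6$pred$hybrid[a6$pred$env == "Y2_LOC1"])
})
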