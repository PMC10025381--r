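# Genome map, meiosis, founder pools and DH families.

test_that("genome map places the configured markers on ordered positions", {
  set.seed(1)
  cfg <- sim_config(master_seed = 1)
  map <- simulate_genome_map(cfg)
  expect_equal(nrow(map), 461L)
  expect_equal(length(unique(map$chrom)), 10L)
  expect_false(anyDuplicated(map$marker) > 0)
  for (c in unique(map$chrom))
    expect_false(is.unsorted(map$pos_cM[map$chrom == c]))
  len <- attr(map, "chrom_length")
  expect_true(all(len >= cfg$chrom_length_cM[1] & len <= cfg$chrom_length_cM[2]))

  set.seed(2)
  cfg1 <- sim_config(n_chromosomes = 1, n_markers = 2, master_seed = 1)
  map1 <- simulate_genome_map(cfg1)
  expect_equal(map1$chrom, c(1L, 1L))
  expect_lte(map1$pos_cM[1], map1$pos_cM[2])

  expect_error(sim_config(n_chromosomes = 10, n_markers = 5),
               "n_markers")
})

test_that("mean adjacent-marker spacing is 4-7 cM across many map draws", {
  set.seed(42)
  gaps <- replicate(60, {
    map <- simulate_genome_map(sim_config(master_seed = 1))
    mean(unlist(tapply(map$pos_cM, map$chrom, diff)))
  })
  expect_gte(mean(gaps), 4)
  expect_lte(mean(gaps), 7)
  expect_true(all(gaps > 4 & gaps < 7))
})

test_that("gametes from a homozygous parent are identical to it", {
  ds <- tiny_dataset()
  map <- ds$map
  hap <- rbinom(nrow(map), 1, 0.5)
  parent <- rbind(hap, hap)
  set.seed(5)
  expect_equal(make_gamete(parent, map), hap)
})

test_that("crossover counts follow the Haldane model (Poisson, mean L/100)", {
  # one 200 cM chromosome densely marked; count phase switches per meiosis
  L <- 200
  map <- data.frame(marker = sprintf("M%03d", 1:201), chrom = 1L,
                    pos_cM = seq(0, L, length.out = 201))
  attr(map, "chrom_length") <- L
  parent <- rbind(rep(0, 201), rep(1, 201))
  set.seed(99)
  n_mei <- 4000
  switches <- replicate(n_mei, sum(diff(make_gamete(parent, map)) != 0))
  # observed switches undercount crossovers only via double-crossovers
  # within 1 cM bins (negligible); Poisson mean 2, SE = sqrt(2/n)
  expect_lt(abs(mean(switches) - 2), 3 * sqrt(2 / n_mei) + 0.02)
})

test_that("recombinant fraction at 5 cM matches Haldane's map function", {
  map <- data.frame(marker = c("A", "B"), chrom = 1L, pos_cM = c(100, 105))
  attr(map, "chrom_length") <- 210
  parent <- rbind(c(0, 0), c(1, 1))
  set.seed(123)
  n_mei <- 20000
  rec <- replicate(n_mei, {
    g <- make_gamete(parent, map)
    g[1] != g[2]
  })
  c_expect <- 0.5 * (1 - exp(-2 * 0.05))   # 0.04758
  se <- sqrt(c_expect * (1 - c_expect) / n_mei)
  expect_lt(abs(mean(rec) - c_expect), 4 * se)
})

test_that("pool divergence controls founder allele-frequency separation", {
  map <- data.frame(marker = sprintf("M%03d", 1:200), chrom = 1L,
                    pos_cM = sort(runif(200, 0, 200)))
  attr(map, "chrom_length") <- 200

  set.seed(3)
  f0 <- simulate_founder_pools(tiny_config(pool_divergence = 0), map)
  d0 <- colMeans(f0$flint) - colMeans(f0$dent)
  expect_lt(abs(mean(d0)), 0.05)     # centred at zero

  set.seed(4)
  f1 <- simulate_founder_pools(tiny_config(pool_divergence = 1), map)
  # full divergence: each pool fixed at every locus
  expect_true(all(colMeans(f1$flint) %in% c(0, 1)))
  expect_true(all(colMeans(f1$dent) %in% c(0, 1)))
  expect_gt(mean(colMeans(f1$flint) != colMeans(f1$dent)), 0.2)
})

test_that("DH lines are homozygous haplotypes with family bookkeeping", {
  cfg <- tiny_config()
  set.seed(8)
  map <- simulate_genome_map(cfg)
  founders <- simulate_founder_pools(cfg, map)
  dh <- simulate_dh_lines(founders, cfg, map, pool = "Flint",
                          n_families = 1, lines_per_family = 5)
  expect_equal(nrow(dh$geno), 5L)
  expect_true(all(dh$geno %in% c(0, 1)))
  expect_equal(length(unique(dh$info$family)), 1L)
  expect_equal(dh$info$pool, rep("Flint", 5))

  few <- list(flint = founders$flint[1, , drop = FALSE],
              dent = founders$dent)
  expect_error(simulate_dh_lines(few, cfg, map, pool = "Flint"),
               "at least 2 founders")
})

test_that("full-sib DH lines share half their genome at segregating loci", {
  # two DH gametes from one F1 agree with probability 1/2 at any locus
  # where the F1 is heterozygous
  cfg <- tiny_config()
  set.seed(23)
  map <- simulate_genome_map(cfg)
  founders <- simulate_founder_pools(cfg, map)
  vals <- replicate(200, {
    pair <- sample(nrow(founders$dent), 2)
    f1 <- founders$dent[pair, ]
    g1 <- make_gamete(f1, map); g2 <- make_gamete(f1, map)
    het <- f1[1, ] != f1[2, ]
    mean(g1[het] == g2[het])
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("identical config and master seed give bit-identical datasets", {
  d1 <- simulate_dataset(tiny_config(master_seed = 31))
  d2 <- simulate_dataset(tiny_config(master_seed = 31))
  expect_identical(d1$geno, d2$geno)
  expect_identical(d1$plots, d2$plots)
  expect_identical(d1$layout, d2$layout)
})
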