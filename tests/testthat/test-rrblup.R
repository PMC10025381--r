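# RR-BLUP: design construction, REML, mixed-model solve, prediction.

test_that("design matrices pick the correct parental rows", {
  ds <- tiny_dataset()
  hy <- ds$hybrids[1:4, ]
  des <- build_design_matrices(hy, ds$geno)
  expect_equal(unname(des$Zf[1, ]), unname(ds$geno[hy$flint_parent[1], ]))
  expect_equal(unname(des$Zd[1, ]), unname(ds$geno[hy$dent_parent[1], ]))
  expect_equal(ncol(des$Zf), ncol(ds$geno))
  expect_equal(ncol(des$Zd), ncol(ds$geno))
  # hybrids sharing a tester share the tester-side row
  same_tester <- ds$layout$hybrid[ds$layout$tester == ds$layout$tester[1]][1:2]
  hy2 <- ds$hybrids[match(same_tester, ds$hybrids$hybrid), ]
  des2 <- build_design_matrices(hy2, ds$geno)
  side <- if (hy2$flint_parent[1] == hy2$flint_parent[2]) "Zf" else "Zd"
  expect_equal(des2[[side]][1, ], des2[[side]][2, ], ignore_attr = TRUE)
  # ungenotyped parent -> dropped with warning
  hy3 <- hy; hy3$flint_parent[2] <- "NOT_A_LINE"
  expect_warning(des3 <- build_design_matrices(hy3, ds$geno, y = 1:4),
                 "ungenotyped")
  expect_equal(length(des3$hybrid), 3L)
  expect_equal(des3$y, c(1L, 3L, 4L))
})

test_that("ridge solution at fixed lambda matches a dense oracle", {
  for (seed in 1:5) {
    des <- random_design(n = 20, m_per_pool = 15, seed = seed)
    lam <- 1.5
    fit <- fit_rrblup(des, lambda = lam)
    orc <- ridge_oracle(des$y, cbind(des$Zf, des$Zd), lam)
    expect_lt(max(abs(c(fit$u_f, fit$u_d) - orc$u)), 1e-8)
    pred <- predict(fit, des)$predicted
    pred_orc <- orc$b0 + drop(cbind(des$Zf, des$Zd) %*% orc$u)
    expect_lt(max(abs(pred - pred_orc)), 1e-8)
  }
})

test_that("lambda -> 0 with n > m reproduces ordinary least squares", {
  des <- random_design(n = 12, m_per_pool = 2, seed = 3)   # 4 columns
  Z <- cbind(des$Zf, des$Zd)
  fit <- fit_rrblup(des, lambda = 1e-8)
  ols <- lm(des$y ~ Z)
  expect_lt(max(abs(c(fit$u_f, fit$u_d) - coef(ols)[-1])), 1e-4)
})

test_that("infinite shrinkage collapses predictions to the training mean", {
  des <- random_design(n = 15, m_per_pool = 10, seed = 4)
  fit <- fit_rrblup(des, lambda = Inf)
  expect_true(all(c(fit$u_f, fit$u_d) == 0))
  expect_equal(predict(fit, des)$predicted, rep(mean(des$y), 15))
})

test_that("REML variance ratio matches a grid-search oracle", {
  for (seed in c(1, 9)) {
    des <- random_design(n = 40, m_per_pool = 15, seed = seed, h2 = 0.7)
    fit <- fit_rrblup(des)
    Z <- cbind(des$Zf, des$Zd)
    Zc <- sweep(Z, 2, colMeans(Z))
    grid <- seq(log(fit$lambda) - 0.5, log(fit$lambda) + 0.5,
                length.out = 2001)
    ll <- vapply(grid, function(g) reml_loglik_oracle(des$y, Zc, exp(g)),
                 numeric(1))
    lam_grid <- exp(grid[which.max(ll)])
    expect_lt(abs(log(fit$lambda) - log(lam_grid)), 1e-3)
    expect_lt(abs(fit$lambda - lam_grid) / lam_grid, 1e-3)
    # and the returned objective is no worse than anywhere on the grid
    expect_gte(reml_loglik_oracle(des$y, Zc, fit$lambda) + 1e-6, max(ll))
  }
})

test_that("marker-model predictions equal kernel (GBLUP) predictions", {
  for (seed in 1:4) {
    des <- random_design(n = 25, m_per_pool = 30, seed = seed)
    fit <- fit_rrblup(des)
    new <- random_design(n = 10, m_per_pool = 30, seed = seed + 100)
    new$y <- NULL
    pred <- predict(fit, new)$predicted
    # kernel oracle with G = Zc Zc' / c at the matched variance ratio
    Z <- cbind(des$Zf, des$Zd)
    ctr <- colMeans(Z)
    Zc <- sweep(Z, 2, ctr)
    Znc <- sweep(cbind(new$Zf, new$Zd), 2, ctr)
    cc <- 2 * ncol(des$Zf)
    G_tt <- tcrossprod(Zc) / cc
    G_nt <- Znc %*% t(Zc) / cc
    lam_g <- fit$lambda / cc
    ybar <- mean(des$y)
    g_hat <- drop(G_nt %*% solve(G_tt + lam_g * diag(nrow(Zc)),
                                 des$y - ybar))
    expect_lt(max(abs(pred - (ybar + g_hat))), 1e-6)
  }
})

test_that("predictions shift by exactly the constant added to the response", {
  des <- random_design(n = 20, m_per_pool = 12, seed = 6)
  f1 <- fit_rrblup(des)
  des2 <- des; des2$y <- des$y + 7
  f2 <- fit_rrblup(des2)
  expect_equal(c(f1$u_f, f1$u_d), c(f2$u_f, f2$u_d), tolerance = 1e-6)
  expect_equal(predict(f2, des)$predicted,
               predict(f1, des)$predicted + 7, tolerance = 1e-6)
})

test_that("noise-free effects are recovered when n greatly exceeds m", {
  set.seed(77)
  n <- 90; m <- 14                     # n > 3 * 2m
  Zf <- matrix(rbinom(n * m, 1, 0.5), n, m)
  Zd <- matrix(rbinom(n * m, 1, 0.5), n, m)
  u_true <- rnorm(2 * m)
  mk <- sprintf("M%02d", 1:m)
  des <- structure(list(Zf = `dimnames<-`(Zf, list(NULL, mk)),
                        Zd = `dimnames<-`(Zd, list(NULL, mk)),
                        hybrid = sprintf("H%02d", 1:n), markers = mk,
                        y = drop(cbind(Zf, Zd) %*% u_true) + 3),
                   class = "tc_design")
  fit <- fit_rrblup(des)
  expect_gt(cor(c(fit$u_f, fit$u_d), u_true), 0.99)
})

test_that("degenerate inputs raise errors", {
  des <- random_design(n = 10, m_per_pool = 5, seed = 8)
  des$y <- rep(1, 10)
  expect_error(fit_rrblup(des), "zero variance")
  des$y <- NULL
  expect_error(fit_rrblup(des), "no response")
  d2 <- random_design(n = 10, m_per_pool = 5, seed = 9)
  f <- fit_rrblup(d2)
  d3 <- random_design(n = 4, m_per_pool = 4, seed = 10)
  expect_error(predict(f, d3), "marker sets")
})
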