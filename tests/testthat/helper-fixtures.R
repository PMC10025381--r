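# Shared fixtures: small, fast configurations and cached datasets.

tiny_config <- function(master_seed = 7, ...) {
  args <- list(n_locations = 3,
               n_founders_per_pool = 16,
               n_dh_families_per_pool = 20,
               dh_lines_per_family = 4,
               n_qtl = 30,
               candidates_per_environment = c(20, 25),
               master_seed = master_seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

# Cached tiny dataset (built once per test run).
tiny_dataset <- function() {
  if (is.null(.fixture_cache$tiny)) .fixture_cache$tiny <-
      simulate_dataset(tiny_config())
  .fixture_cache$tiny
}

# A small two-pool parental matrix with known dosages, for QC tests.
toy_geno <- function() {
  set.seed(11)
  g <- matrix(rbinom(10 * 12, 1, 0.5), nrow = 10, ncol = 12,
              dimnames = list(sprintf("L%02d", 1:10),
                              sprintf("M%02d", 1:12)))
  storage.mode(g) <- "double"
  g
}

# Random tc_design instances for the linear-algebra oracles.
random_design <- function(n, m_per_pool, seed, h2 = 0.5) {
  set.seed(seed)
  Zf <- matrix(rbinom(n * m_per_pool, 1, runif(m_per_pool, 0.2, 0.8)),
               n, m_per_pool)
  Zd <- matrix(rbinom(n * m_per_pool, 1, runif(m_per_pool, 0.2, 0.8)),
               n, m_per_pool)
  u <- rnorm(2 * m_per_pool, 0, sqrt(1 / (2 * m_per_pool)))
  g <- drop(cbind(Zf, Zd) %*% u)
  y <- g + rnorm(n, 0, sd = sqrt(max(var(g), 1e-4) * (1 - h2) / h2))
  mk <- sprintf("M%03d", seq_len(m_per_pool))
  structure(list(Zf = `dimnames<-`(Zf, list(NULL, mk)),
                 Zd = `dimnames<-`(Zd, list(NULL, mk)),
                 hybrid = sprintf("H%03d", seq_len(n)), markers = mk,
                 y = y),
            class = "tc_design")
}

# Dense REML/ridge oracle: profiled restricted log-likelihood for the
# variance ratio of y = 1 b0 + Z u + e, u ~ N(0, s2_u I), evaluated from
# first principles (generalised least squares on H = ZZ' + lambda I).
reml_loglik_oracle <- function(y, Z, lambda) {
  n <- length(y)
  X <- matrix(1, n, 1)
  H <- tcrossprod(Z) + lambda * diag(n)
  Hi <- solve(H)
  XtHiX <- crossprod(X, Hi %*% X)
  beta <- solve(XtHiX, crossprod(X, Hi %*% y))
  r <- y - X %*% beta
  s2 <- drop(crossprod(r, Hi %*% r)) / (n - 1)
  -0.5 * ((n - 1) * log(s2) + determinant(H)$modulus +
            determinant(XtHiX)$modulus + (n - 1))
}

# Dense solve of the ridge / mixed-model equations at fixed lambda, with
# the intercept profiled out by GLS.
ridge_oracle <- function(y, Z, lambda) {
  n <- length(y)
  H <- tcrossprod(Z) + lambda * diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  b0 <- drop(crossprod(one, Hi %*% y) / crossprod(one, Hi %*% one))
  u <- drop(crossprod(Z, Hi %*% (y - b0)))
  list(b0 = b0, u = u)
}
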