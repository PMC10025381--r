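# Bayesian whole-genome regression for the two-pool testcross model,
# fitted by single-site Gibbs sampling.
#
#   BRR    : one common Gaussian shrinkage variance (scaled-inv-chi2 prior)
#   BayesA : marker-specific variances (scaled-inv-chi2 per marker)
#   BayesB : BayesA plus a point mass at zero; each marker carries an
#            inclusion indicator with probability `prob_in` (sampled under a
#            Beta prior unless fixed)
#
# Hyperpriors follow the usual weakly-informative defaults: degrees of
# freedom 5 for effect and residual variances, scales set from the response
# variance with an R2 heuristic of 0.5.

#' Fit the testcross model by Bayesian whole-genome regression
#'
#' Gibbs sampler over the intercept, the concatenated Flint/Dent marker
#' effects and all variances; posterior means over post-burn-in samples are
#' reported as effect estimates. With `method = "BayesB"` and `prob_in`
#' fixed at 1 the point mass vanishes and the sampler follows the BayesA
#' update path exactly, so the chains match BayesA draw for draw under a
#' shared seed.
#'
#' @param design A `tc_design` with response `y`.
#' @param method `"BRR"`, `"BayesA"` or `"BayesB"`.
#' @param n_iter Total Gibbs iterations (default 10000).
#' @param burn_in Burn-in iterations discarded from the posterior means
#'   (default 1000).
#' @param seed Chain seed (mandatory for reproducibility).
#' @param prob_in Prior/initial inclusion probability of a marker effect for
#'   BayesB (default 0.5).
#' @param sample_prob_in Sample `prob_in` under a Beta(1, 1) prior
#'   (default TRUE for BayesB; forced off when `prob_in = 1`).
#' @param df_prior Prior degrees of freedom for effect and residual
#'   variances (default 5).
#' @param R2 Heuristic proportion of variance attributed to markers when
#'   setting prior scales (default 0.5).
#' @param keep_effect_samples Keep the post-burn-in effect draws (needed for
#'   Monte-Carlo standard errors; off by default to save memory).
#' @return A `marker_effects` object; Bayesian extras: `n_iter`, `burn_in`,
#'   `seed`, posterior-mean `prob_in`, `lambda` (posterior mean of
#'   `sigma2_e/sigma2_tc`), and optionally `effect_samples`.
#' @export
fit_bayes <- function(design, method = c("BRR", "BayesA", "BayesB"),
                      n_iter = 10000L, burn_in = 1000L, seed,
                      prob_in = 0.5, sample_prob_in = NULL,
                      df_prior = 5, R2 = 0.5,
                      keep_effect_samples = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(design, "tc_design"))
  if (missing(seed)) stop_invalid("fit_bayes: a chain seed is required")
  if (n_iter <= burn_in)
    stop_invalid("fit_bayes: n_iter must exceed burn_in")
  y <- design$y
  if (is.null(y)) stop_invalid("fit_bayes: design has no response")
  n <- length(y)
  if (n < 2L || stats::var(y) == 0)
    stop_invalid("fit_bayes: need >= 2 hybrids and a non-constant response")

  Z <- cbind(design$Zf, design$Zd)
  p <- ncol(Z)
  ctr <- colMeans(Z)
  Zc <- sweep(Z, 2L, ctr)
  xtx <- colSums(Zc^2)
  active <- xtx > 0                      # monomorphic columns stay at 0
  vy <- stats::var(y)
  msx <- sum(xtx) / n                    # sum of column variances of Z

  if (is.null(sample_prob_in)) sample_prob_in <- method == "BayesB"
  if (method == "BayesB" && prob_in >= 1) sample_prob_in <- FALSE
  # BayesB with no point mass is BayesA; running the BayesA path keeps the
  # RNG trajectory identical between the two methods under a shared seed.
  effective <- if (method == "BayesB" && prob_in >= 1 && !sample_prob_in)
    "BayesA" else method

  df_e <- df_prior
  S_e <- vy * (1 - R2) * (df_e + 2)
  df_u <- df_prior
  S_u <- switch(effective,
                BRR = vy * R2 / msx * (df_u + 2),
                BayesA = vy * R2 / msx * (df_u + 2),
                BayesB = vy * R2 / (prob_in * msx) * (df_u + 2))

  set.seed(as.integer(seed))
  b0 <- mean(y)
  u <- numeric(p)
  delta <- rep(TRUE, p)
  sigma2_e <- vy * (1 - R2)
  sigma2_u <- rep(vy * R2 / msx, p)       # per-marker (BRR keeps them equal)
  e <- y - b0

  n_keep <- n_iter - burn_in
  sum_u <- numeric(p); sum_b0 <- 0
  sum_s2u <- 0; sum_s2e <- 0; sum_lambda <- 0; sum_pi <- 0
  samples <- if (keep_effect_samples) matrix(NA_real_, n_keep, p) else NULL

  for (it in seq_len(n_iter)) {
    # intercept
    b0_new <- stats::rnorm(1L, mean(e) + b0, sqrt(sigma2_e / n))
    e <- e - (b0_new - b0)
    b0 <- b0_new

    if (effective == "BayesB") {
      log_odds_prior <- log(prob_in) - log1p(-prob_in)
      for (j in which(active)) {
        r <- sum(Zc[, j] * e) + xtx[j] * u[j]          # x_j' (e excluding j)
        v1 <- sigma2_e + xtx[j] * sigma2_u[j]
        log_bf <- 0.5 * (log(sigma2_e) - log(v1)) +
          0.5 * r^2 * sigma2_u[j] / (sigma2_e * v1)
        pin <- 1 / (1 + exp(-(log_odds_prior + log_bf)))
        incl <- stats::runif(1L) < pin
        u_new <- if (incl) {
          C <- xtx[j] / sigma2_e + 1 / sigma2_u[j]
          stats::rnorm(1L, (r / sigma2_e) / C, sqrt(1 / C))
        } else 0
        if (u_new != u[j]) e <- e - Zc[, j] * (u_new - u[j])
        u[j] <- u_new
        delta[j] <- incl
      }
      sigma2_u <- ifelse(delta,
                         (S_u + u^2) / stats::rchisq(p, df_u + 1),
                         S_u / stats::rchisq(p, df_u))
      if (sample_prob_in) {
        k <- sum(delta[active])
        prob_in <- stats::rbeta(1L, 1 + k, 1 + sum(active) - k)
        log_odds_prior <- log(prob_in) - log1p(-prob_in)
      }
    } else {
      for (j in which(active)) {
        r <- sum(Zc[, j] * e) + xtx[j] * u[j]
        C <- xtx[j] / sigma2_e + 1 / sigma2_u[j]
        u_new <- stats::rnorm(1L, (r / sigma2_e) / C, sqrt(1 / C))
        e <- e - Zc[, j] * (u_new - u[j])
        u[j] <- u_new
      }
      if (effective == "BRR") {
        s2 <- (S_u + sum(u^2)) / stats::rchisq(1L, df_u + sum(active))
        sigma2_u <- rep(s2, p)
      } else {                                        # BayesA
        sigma2_u <- (S_u + u^2) / stats::rchisq(p, df_u + 1)
      }
    }
    sigma2_e <- (S_e + sum(e^2)) / stats::rchisq(1L, df_e + n)

    if (it > burn_in) {
      k <- it - burn_in
      sum_u <- sum_u + u
      sum_b0 <- sum_b0 + b0
      s2u_bar <- mean(sigma2_u[active])
      sum_s2u <- sum_s2u + s2u_bar
      sum_s2e <- sum_s2e + sigma2_e
      sum_lambda <- sum_lambda + sigma2_e / s2u_bar
      sum_pi <- sum_pi + prob_in
      if (keep_effect_samples) samples[k, ] <- u
    }
  }

  u_hat <- sum_u / n_keep
  extra <- list(n_iter = n_iter, burn_in = burn_in, seed = as.integer(seed),
                prob_in = if (method == "BayesB") sum_pi / n_keep else NA_real_)
  if (keep_effect_samples) extra$effect_samples <- samples
  new_marker_effects(design, u_hat, sum_b0 / n_keep, ctr,
                     sigma2_tc = sum_s2u / n_keep,
                     sigma2_e = sum_s2e / n_keep,
                     lambda = sum_lambda / n_keep,
                     reml = NA_real_, method = method, extra = extra)
}
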