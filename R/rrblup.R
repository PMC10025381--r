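# Two-pool testcross marker-effect model:
#   y_adj = 1 b0 + Z_f u_f + Z_d u_d + e,   u = (u_f, u_d) ~ N(0, s2_tc I)
# Z_f holds the Flint-side parent's dosages of each hybrid and Z_d the
# Dent-side parent's, regardless of which side is the tester, so both
# tester/candidate orientations enter one model.

#' Build the two-pool testcross design matrices
#'
#' @param hybrids Data.frame with columns `hybrid`, `flint_parent`,
#'   `dent_parent` (e.g. rows of `dataset$hybrids`); an optional `y` column
#'   or the `y` argument supplies the training response.
#' @param geno Imputed parental lines x markers dosage matrix.
#' @param markers Marker set to use (default: all columns of `geno`).
#' @param y Optional numeric response vector aligned with `hybrids` rows.
#' @return An object of class `tc_design` with `Zf`, `Zd` (hybrids x
#'   markers), `hybrid` identifiers and optionally `y`. Hybrids with an
#'   ungenotyped parent are dropped with a warning.
#' @export
build_design_matrices <- function(hybrids, geno, markers = colnames(geno),
                                  y = NULL) {
  stopifnot(all(c("hybrid", "flint_parent", "dent_parent") %in% names(hybrids)))
  if (!all(markers %in% colnames(geno)))
    stop_invalid("build_design_matrices: markers absent from genotype matrix")
  if (is.null(y) && !is.null(hybrids$y)) y <- hybrids$y
  ok <- hybrids$flint_parent %in% rownames(geno) &
    hybrids$dent_parent %in% rownames(geno)
  if (!all(ok)) {
    warning("build_design_matrices: dropping ", sum(!ok),
            " hybrids with ungenotyped parents")
    hybrids <- hybrids[ok, , drop = FALSE]
    if (!is.null(y)) y <- y[ok]
  }
  Zf <- geno[hybrids$flint_parent, markers, drop = FALSE]
  Zd <- geno[hybrids$dent_parent, markers, drop = FALSE]
  rownames(Zf) <- rownames(Zd) <- hybrids$hybrid
  structure(list(Zf = Zf, Zd = Zd, hybrid = hybrids$hybrid,
                 markers = markers, y = y),
            class = "tc_design")
}

#' Fit the testcross model by RR-BLUP (REML)
#'
#' Treats the concatenated matrix `Z = [Z_f Z_d]` with one common effect
#' variance. The variance ratio `lambda = s2_e / s2_tc` is estimated by
#' REML through a spectral decomposition of the (column-centred) `Z Z'`
#' kernel restricted to the orthogonal complement of the intercept, with a
#' one-dimensional optimisation on the log scale (tolerance 1e-10); the
#' mixed-model equations are then solved exactly in the eigenbasis.
#' Column centring is internal and undone in the reported intercept, so
#' predictions are on the raw dosage scale.
#'
#' @param design A `tc_design` with response `y`.
#' @param lambda Optional fixed variance ratio overriding the REML estimate
#'   (`Inf` gives total shrinkage: all effects 0, predictions = mean(y)).
#' @return An object of class `marker_effects`: `intercept`, effect vectors
#'   `u_f` and `u_d`, variance components `sigma2_tc` and `sigma2_e`,
#'   `lambda`, REML log-likelihood value and the method label.
#' @export
fit_rrblup <- function(design, lambda = NULL) {
  stopifnot(inherits(design, "tc_design"))
  y <- design$y
  if (is.null(y)) stop_invalid("fit_rrblup: design has no response")
  n <- length(y)
  if (n < 2L) stop_invalid("fit_rrblup: need >= 2 training hybrids")
  if (stats::var(y) == 0) stop_invalid("fit_rrblup: response has zero variance")
  Z <- cbind(design$Zf, design$Zd)
  m2 <- ncol(Z)
  ctr <- colMeans(Z)
  Zc <- sweep(Z, 2L, ctr)
  ybar <- mean(y)

  if (!is.null(lambda) && is.infinite(lambda)) {
    u <- numeric(m2)
    return(new_marker_effects(design, u, ybar, ctr,
                              sigma2_tc = 0, sigma2_e = stats::var(y),
                              lambda = Inf, reml = NA_real_,
                              method = "RR-BLUP"))
  }

  Phi <- tcrossprod(Zc)                      # n x n kernel, Phi %*% 1 = 0
  # Shift by the centring projector S = I - J/n: eigenvalues on the
  # complement of the intercept become theta + 1 (> 0) while the intercept
  # direction stays at 0, so the n-1 retained eigenvectors are orthogonal
  # to 1 even when Phi is rank-deficient.
  A <- Phi + diag(n) - matrix(1 / n, n, n)
  eg <- eigen(A, symmetric = TRUE)
  theta <- pmax(eg$values[seq_len(n - 1L)] - 1, 0)
  U <- eg$vectors[, seq_len(n - 1L), drop = FALSE]
  omega <- drop(crossprod(U, y))

  reml_obj <- function(log_lambda) {
    lam <- exp(log_lambda)
    (n - 1L) * log(sum(omega^2 / (theta + lam))) + sum(log(theta + lam))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(reml_obj, interval = c(-25, 25), tol = 1e-10)
    if (!is.finite(opt$objective))
      stop_invalid("fit_rrblup: REML optimisation failed (non-finite objective)")
    lambda <- exp(opt$minimum)
    reml <- -0.5 * (opt$objective +
                      (n - 1L) * (1 + log(2 * pi / (n - 1L))))
  } else {
    reml <- -0.5 * (reml_obj(log(lambda)) +
                      (n - 1L) * (1 + log(2 * pi / (n - 1L))))
  }
  sigma2_tc <- sum(omega^2 / (theta + lambda)) / (n - 1L)
  sigma2_e <- lambda * sigma2_tc
  u <- drop(crossprod(Zc, U %*% (omega / (theta + lambda))))
  new_marker_effects(design, u, ybar, ctr, sigma2_tc, sigma2_e, lambda,
                     reml, "RR-BLUP")
}

new_marker_effects <- function(design, u, ybar, ctr, sigma2_tc, sigma2_e,
                               lambda, reml, method, extra = list()) {
  m <- length(design$markers)
  u_f <- stats::setNames(u[seq_len(m)], design$markers)
  u_d <- stats::setNames(u[m + seq_len(m)], design$markers)
  structure(c(list(intercept = ybar - sum(ctr * u),
                   u_f = u_f, u_d = u_d, markers = design$markers,
                   sigma2_tc = sigma2_tc, sigma2_e = sigma2_e,
                   lambda = lambda, reml_loglik = reml, method = method),
              extra),
            class = "marker_effects")
}

#' @export
print.marker_effects <- function(x, ...) {
  cat(sprintf("%s marker-effect fit: %d markers per pool\n",
              x$method, length(x$u_f)))
  cat(sprintf("  intercept %.4f, sigma2_tc %.5g, sigma2_e %.5g, lambda %.5g\n",
              x$intercept, x$sigma2_tc, x$sigma2_e, x$lambda))
  invisible(x)
}

#' Predict testcross performance of hybrids
#'
#' `prediction = intercept + Z_f u_f + Z_d u_d` for the rows of `newdata`.
#'
#' @param object A `marker_effects` fit.
#' @param newdata A `tc_design` built on the same marker set.
#' @param ... Unused.
#' @return A data.frame with `hybrid` and `predicted`.
#' @export
predict.marker_effects <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "tc_design"))
  if (!identical(newdata$markers, object$markers))
    stop_invalid("predict: marker sets of fit and newdata differ")
  pred <- object$intercept +
    drop(newdata$Zf %*% object$u_f + newdata$Zd %*% object$u_d)
  data.frame(hybrid = newdata$hybrid, predicted = unname(pred),
             stringsAsFactors = FALSE)
}
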