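# Adjustment of unreplicated plot values for environmental effects.
#
# Model: y = mu + year + location(year) + e, fitted per trait by least
# squares. Because location is nested in year and saturates the environment
# cells, the fitted value for every environment equals its observed mean;
# constraints only identify the decomposition into mu, year and
# location-within-year effects, and the closed form below *is* the
# least-squares solution (tests check it against a constrained lm fit).

#' Estimate year and location-within-year effects
#'
#' Fits, separately per trait, the fixed-effects model
#' `y = mu + year + location(year) + e` to unreplicated plot records.
#' Under the default unweighted sum-to-zero constraints (year effects sum
#' to zero over years; location effects sum to zero within each year) the
#' estimates are: environment cell means, year means as unweighted means of
#' their environments' cell means, and `mu` as the unweighted mean of the
#' year means. A reference-level scheme (first year and first environment
#' within each year as baseline) is provided to demonstrate that the choice
#' only shifts adjusted values by per-environment constants.
#'
#' @param plots Plot records: data.frame with columns `year`, `env`,
#'   `hybrid`, `trait`, `value` (e.g. `dataset$plots`).
#' @param constraint `"sum_to_zero"` (default) or `"reference"`.
#' @return An object of class `env_effects`: per trait the general mean
#'   `mu`, year effects `q`, environment (location-within-year) effects
#'   `p`, and per-plot residuals.
#' @export
fit_environment_effects <- function(plots,
                                    constraint = c("sum_to_zero", "reference")) {
  constraint <- match.arg(constraint)
  need <- c("year", "env", "trait", "value")
  if (!all(need %in% names(plots)))
    stop_invalid("fit_environment_effects: plots must have columns ",
                 paste(need, collapse = ", "))
  keep <- !is.na(plots$value)
  if (!all(keep)) {
    warning("fit_environment_effects: dropping ", sum(!keep),
            " plots with missing values")
    plots <- plots[keep, , drop = FALSE]
  }
  if (nrow(plots) == 0L) stop_invalid("fit_environment_effects: no plots")

  out <- list()
  for (tr in unique(plots$trait)) {
    sub <- plots[plots$trait == tr, , drop = FALSE]
    cell <- c(tapply(sub$value, sub$env, mean))              # env means
    env_year <- c(tapply(sub$year, sub$env, function(x) x[1L]))
    years <- sort(unique(env_year))
    if (constraint == "sum_to_zero") {
      ybar <- vapply(years, function(y)
        mean(cell[names(env_year)[env_year == y]]), numeric(1))
      names(ybar) <- years
      mu <- mean(ybar)
      q <- ybar - mu
      p <- cell - mu - q[as.character(env_year[names(cell)])]
    } else {
      # reference levels: first year, first environment within each year
      ref_env <- vapply(years, function(y)
        sort(names(env_year)[env_year == y], method = "radix")[1L], character(1))
      names(ref_env) <- years
      mu <- unname(cell[ref_env[1L]])
      q <- cell[ref_env[as.character(years)]] - mu
      names(q) <- years
      q[1L] <- 0
      mu <- unname(cell[ref_env[1L]])
      p <- cell - mu - q[as.character(env_year[names(cell)])]
    }
    fitted_env <- c(mu + q[as.character(env_year[names(cell)])] + p)
    names(fitted_env) <- names(cell)
    resid <- sub$value - fitted_env[sub$env]
    out[[tr]] <- list(trait = tr, mu = unname(mu), q = c(q), p = c(p),
                      residuals = stats::setNames(unname(resid), sub$plot),
                      constraint = constraint)
  }
  structure(out, class = "env_effects")
}

#' Adjust plot values for year and environment effects
#'
#' Subtracts the estimated year and location-within-year effects from each
#' plot value: `y_adj = y - q - p(q)`. After adjustment the mean of
#' `y_adj` in every environment equals the fitted general mean `mu` of its
#' trait.
#'
#' @param plots Plot records (as in [fit_environment_effects()]).
#' @param estimates An `env_effects` object fitted on these plots (or a
#'   superset covering all their environments).
#' @return The plot table with an additional column `value_adj`.
#' @export
adjust_phenotypes <- function(plots, estimates) {
  stopifnot(inherits(estimates, "env_effects"))
  out <- plots
  out$value_adj <- NA_real_
  for (tr in unique(plots$trait)) {
    est <- estimates[[tr]]
    if (is.null(est))
      stop_invalid("adjust_phenotypes: no estimates for trait ", tr)
    idx <- which(plots$trait == tr)
    miss <- setdiff(unique(plots$env[idx]), names(est$p))
    if (length(miss))
      stop_invalid("adjust_phenotypes: environments without estimates: ",
                   paste(miss, collapse = ", "))
    out$value_adj[idx] <- plots$value[idx] -
      est$q[as.character(plots$year[idx])] -
      est$p[plots$env[idx]]
  }
  out
}
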