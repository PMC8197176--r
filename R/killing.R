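#' Poisson maximum-likelihood models for tumour-cell apoptosis counts
#'
#' The number of tumour-cell apoptosis events at an imaged position is
#' treated as Poisson with an intensity proportional either to the number of
#' CTLs present ("linear" model) or to the product of CTL and tumour-cell
#' numbers ("mass-action" model), times the imaging duration. The MLE is
#' available in closed form as total events over total exposure:
#' `lambda = sum(kills) / sum(n_ctl * tau)` for the linear model and
#' `lambda = sum(kills) / sum(n_ctl * n_tc * tau)` for mass action, with
#' `tau` the imaging duration in days. With `grouping = "per-treatment"`
#' one rate is fitted per treatment group (column `group`), increasing the
#' parameter count accordingly.
#'
#' Positions with zero exposure (no CTLs, for the linear model) are
#' uninformative about the rate and are dropped; dropping a zero-exposure
#' position that nevertheless recorded kills would silently discard
#' model-impossible data, so that raises an error.
#'
#' @param positions Position table as in [intravital_rates()]; a `group`
#'   column is required for per-treatment fits.
#' @param grouping `"pooled"` (one rate) or `"per-treatment"` (one rate per
#'   group).
#' @return A `kill_fit` object: list with elements `model`, `grouping`,
#'   `rates` (day^-1 per CTL, or day^-1 per CTL per TC for mass action),
#'   `log_lik`, `n_params`, `n_obs`, `aic`, `bic`.
#' @examples
#' pos <- data.frame(day = 6, duration = c(2, 1), n_ctl = c(5, 10),
#'                   n_tc = 100, tc_apoptosis = c(1, 1), tc_mitosis = 0,
#'                   ctl_apoptosis = 0, ctl_mitosis = 0)
#' fit_poisson_linear(pos)$rates  # 2 kills / 20 CTL-hours = 2.4 per CTL-day
#' @export
fit_poisson_linear <- function(positions, grouping = c("pooled", "per-treatment")) {
  poisson_kill_fit(positions, match.arg(grouping), model = "linear")
}

#' @rdname fit_poisson_linear
#' @export
fit_poisson_massaction <- function(positions,
                                   grouping = c("pooled", "per-treatment")) {
  poisson_kill_fit(positions, match.arg(grouping), model = "mass-action")
}

poisson_kill_fit <- function(positions, grouping, model) {
  positions <- as.data.frame(positions)
  validate_positions(positions)
  tau <- positions$duration / HOURS_PER_DAY
  exposure <- switch(model,
    "linear" = positions$n_ctl * tau,
    "mass-action" = positions$n_ctl * positions$n_tc * tau
  )
  kills <- positions$tc_apoptosis
  if (any(exposure == 0 & kills > 0)) {
    stop("position with kill events but zero exposure under the ", model,
         " model", call. = FALSE)
  }
  keep <- exposure > 0
  if (!any(keep)) stop("all exposures are zero; cannot fit a rate", call. = FALSE)
  exposure <- exposure[keep]; kills <- kills[keep]

  if (grouping == "per-treatment") {
    if (!"group" %in% names(positions)) {
      stop("per-treatment fit needs a `group` column", call. = FALSE)
    }
    grp <- as.character(positions$group)[keep]
  } else {
    grp <- rep("all", length(kills))
  }
  levels <- unique(grp)
  rates <- vapply(levels, function(g) {
    sum(kills[grp == g]) / sum(exposure[grp == g])
  }, numeric(1L))
  lambda_i <- rates[match(grp, levels)] * exposure
  log_lik <- sum(dpois(kills, lambda_i, log = TRUE))
  n_obs <- length(kills)
  n_params <- length(levels)
  structure(
    list(model = model, grouping = grouping, rates = rates,
         log_lik = log_lik, n_params = n_params, n_obs = n_obs,
         aic = 2 * n_params - 2 * log_lik,
         bic = n_params * log(n_obs) - 2 * log_lik,
         data_id = c(n_obs, sum(kills))),
    class = "kill_fit"
  )
}

#' @export
print.kill_fit <- function(x, ...) {
  cat(sprintf("<kill_fit> %s intensity, %s (%d obs)\n", x$model, x$grouping,
              x$n_obs))
  unit <- if (x$model == "linear") "CTL^-1 day^-1" else "CTL^-1 TC^-1 day^-1"
  for (g in names(x$rates)) {
    cat(sprintf("  rate[%s] = %.4g %s\n", g, x$rates[[g]], unit))
  }
  cat(sprintf("  logLik %.3f | AIC %.2f | BIC %.2f (k = %d)\n",
              x$log_lik, x$aic, x$bic, x$n_params))
  invisible(x)
}

#' Rank Poisson killing models by information criteria
#'
#' @param fits List of `kill_fit` objects fitted to the same observations.
#' @return A tibble with one row per fit (model, grouping, n_params,
#'   log_lik, aic, bic, delta_aic, delta_bic), sorted by AIC.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1L), "kill_fit")))
  ids <- vapply(fits, function(f) paste(f$data_id, collapse = "/"), character(1L))
  if (length(unique(ids)) != 1L) {
    stop("fits were not computed on the same observations", call. = FALSE)
  }
  tab <- tibble::tibble(
    model = vapply(fits, `[[`, character(1L), "model"),
    grouping = vapply(fits, `[[`, character(1L), "grouping"),
    n_params = vapply(fits, `[[`, numeric(1L), "n_params"),
    log_lik = vapply(fits, `[[`, numeric(1L), "log_lik"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    bic = vapply(fits, `[[`, numeric(1L), "bic")
  )
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$delta_bic <- tab$bic - min(tab$bic)
  tab
}

#' Expected kill counts and exact Poisson band
#'
#' For a constant per-CTL killing rate, gives the expected number of kills
#' during an imaging window as a function of the CTL count, together with
#' exact Poisson quantiles (inverse CDF: smallest count with CDF >= q;
#' counts are small, so a normal approximation would be inappropriate).
#'
#' @param n_ctl Vector of CTL counts.
#' @param rate Per-CTL killing rate (day^-1).
#' @param duration Imaging duration in hours (default 1, i.e. kills per hour).
#' @param quantiles Two probabilities for the band (default 5-95%).
#' @return Tibble with columns `n_ctl`, `mean`, `lower`, `upper`.
#' @examples
#' poisson_band(0:20, rate = 0.44)
#' @export
poisson_band <- function(n_ctl, rate, duration = 1,
                         quantiles = c(0.05, 0.95)) {
  stopifnot(rate >= 0, duration > 0, length(quantiles) == 2L,
            all(quantiles >= 0 & quantiles <= 1))
  mu <- rate * n_ctl * duration / HOURS_PER_DAY
  tibble::tibble(
    n_ctl = n_ctl, mean = mu,
    lower = qpois(min(quantiles), mu),
    upper = qpois(max(quantiles), mu)
  )
}
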