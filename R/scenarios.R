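#' Scale a single rate and re-simulate
#'
#' Effect-attribution experiment: multiplies one of the two CTL effect
#' rates — killing `k_e` or quiescence induction `k_q` — by each factor in
#' turn (default 0, 1, 3, 4; factor 0 abrogates the effect, factor 1 is the
#' baseline) and simulates the model with all other parameters untouched.
#'
#' @param params Baseline parameter set (e.g. [act_only_params()]).
#' @param target `"k_e"` or `"k_q"`.
#' @param factors Non-negative multipliers.
#' @param horizon Final day of the simulation.
#' @param step Output grid step (days).
#' @param init Initial state.
#' @return Named list of `ctl_trajectory` objects (`"x0"`, `"x1"`, ...),
#'   with attributes `target`, `factors` and `params`.
#' @export
scale_sweep <- function(params, target = c("k_e", "k_q"),
                        factors = c(0, 1, 3, 4), horizon = 15, step = 0.25,
                        init = default_init()) {
  target <- match.arg(target)
  validate_params(params)
  if (any(factors < 0)) stop("factors must be >= 0", call. = FALSE)
  t_grid <- seq(0, horizon, by = step)
  out <- lapply(factors, function(f) {
    p <- do.call(update_params,
                 c(list(params), setNames(list(params[[target]] * f), target)))
    simulate_model(p, init = init, t_grid = t_grid)
  })
  names(out) <- paste0("x", factors)
  structure(out, target = target, factors = factors, params = params,
            class = c("ctl_sweep", "list"))
}

#' Summarise tumour burden across a sweep
#'
#' Two scalar summaries per trajectory: the final total tumour cell count
#' at the horizon, and the area under log(T) over the whole simulation
#' (trapezoidal rule) as an integrated-burden measure less dominated by the
#' endpoint.
#'
#' @param sweep Result of [scale_sweep()] (or any named list of
#'   trajectories).
#' @return Tibble with columns `factor` (or `label`), `final_T`,
#'   `auc_log_T`.
#' @export
burden_summary <- function(sweep) {
  facs <- attr(sweep, "factors")
  tibble::tibble(
    factor = if (!is.null(facs)) facs else names(sweep),
    final_T = vapply(sweep, function(tr) tr$T[nrow(tr)], numeric(1L)),
    auc_log_T = vapply(sweep, function(tr) {
      lt <- log(pmax(tr$T, 1))
      sum(diff(tr$time) * (lt[-1L] + lt[-length(lt)]) / 2)
    }, numeric(1L))
  )
}

#' Tabulated model readout for one condition
#'
#' Packages [model_predictions()] into a wide per-day table of the fitted
#' process rates (killing, tumour-cell mitosis, CTL mitosis, CTL
#' apoptosis), the E:T ratio and the net volumetric growth rate — the
#' model-side analogue of the per-condition summary figures.
#'
#' @param params Parameter set for the condition.
#' @param transfer_day Day of adoptive transfer.
#' @param days Days to report; must not exceed `horizon`.
#' @param horizon Simulated span (day 0 to `horizon`).
#' @param init Initial state.
#' @return Tibble with one row per day: `day`, `killing`, `tc_mitosis`,
#'   `ctl_mitosis`, `ctl_apoptosis`, `et_ratio`, `net_growth`, plus the
#'   state columns `T`, `E`.
#' @export
condition_report <- function(params, transfer_day = params$transfer_day,
                             days = 0:15, horizon = 15,
                             init = default_init()) {
  if (any(days < 0) || any(days > horizon)) {
    stop("report days must lie within [0, horizon]", call. = FALSE)
  }
  p <- update_params(params, transfer_day = transfer_day)
  t_grid <- sort(unique(c(0, days, horizon)))
  traj <- simulate_model(p, init = init, t_grid = t_grid)
  pred <- model_predictions(traj, days)
  wide <- tibble::tibble(day = days)
  for (k in c("killing", "tc_mitosis", "ctl_mitosis", "ctl_apoptosis",
              "et_ratio")) {
    sub <- pred[pred$kind == k, ]
    wide[[k]] <- sub$value[match(days, sub$day)]
  }
  g <- pred[pred$kind == "growth", ]
  wide$net_growth <- g$value[match(days, g$day)]
  st <- interp_state(traj, days)
  wide$T <- st[, "T_p"] + st[, "T_q"]
  wide$E <- st[, "E"]
  wide
}

#' Plot a condition report
#'
#' Line panels of the process rates, E:T ratio and net growth over time.
#' Requires ggplot2.
#'
#' @param report Output of [condition_report()].
#' @return A ggplot object.
#' @export
plot_condition_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  long <- do.call(rbind, lapply(
    c("killing", "tc_mitosis", "ctl_mitosis", "ctl_apoptosis", "et_ratio",
      "net_growth"),
    function(k) data.frame(day = report$day, quantity = k, value = report[[k]])
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = day, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL)
}
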