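#' Configuration for the differential-evolution fit
#'
#' Defaults reproduce the study's search setup: bounds 0-50 day^-1 for the
#' rate constants and 0-5 for the infiltration constant `s`, population 200,
#' 500 generations, 5 independently seeded repeats, local-to-best strategy.
#' The mutation factor `F` and crossover rate `CR` are standard values for
#' that strategy.
#'
#' @param free Names of the parameters being fitted.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults filled per the rule above.
#' @param population Population size.
#' @param generations Number of generations.
#' @param repeats Independent optimisation repeats (different seeded
#'   starting populations); the best repeat is reported.
#' @param F Differential weight (mutation factor).
#' @param CR Crossover probability.
#' @param seed Master seed; all randomness in the fit flows from it.
#' @return A `fit_config` object.
#' @export
fit_config <- function(free = free_param_names(), bounds = NULL,
                       population = 200, generations = 500, repeats = 5,
                       F = 0.8, CR = 0.9, seed = 1) {
  default_bound <- function(nm) if (nm == "s") c(0, 5) else c(0, 50)
  full <- setNames(lapply(free, default_bound), free)
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), free)
    if (length(bad)) stop("bounds given for non-free parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    full[names(bounds)] <- bounds
  }
  for (nm in free) {
    b <- full[[nm]]
    if (length(b) != 2L || b[1L] < 0 || b[2L] <= b[1L]) {
      stop("invalid bounds for ", nm, call. = FALSE)
    }
  }
  structure(list(free = free, bounds = full, population = as.integer(population),
                 generations = as.integer(generations),
                 repeats = as.integer(repeats), F = F, CR = CR,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' RMSE between calibration points and model predictions
#'
#' Simulates the model once per treatment schedule present in `points`
#' (transfer day 3 and/or 7, with shared parameters) and returns the root
#' mean square error over all points. Growth-rate points are compared
#' like-for-like: the model's total cell count is log-differenced over the
#' same measurement interval that produced the data point. Intravital-rate
#' and E:T points are compared against [model_predictions()] at the
#' observation day. Points from untreated conditions (`transfer_day` NA)
#' are excluded: the baseline growth rate `g` is fixed from those data
#' before fitting. A failed integration yields a large finite penalty
#' (1e6) so a stochastic optimiser can keep exploring.
#'
#' @param params A [ctl_params()] object (its `transfer_day` is overridden
#'   per condition).
#' @param points Calibration points as from [calibration_points()].
#' @param init Initial state for the simulations.
#' @return Non-negative scalar RMSE (day^-1-denominated residuals pooled
#'   with the dimensionless E:T residuals).
#' @export
rmse_objective <- function(params, points, init = default_init()) {
  validate_params(params)
  pts <- points[!is.na(points$transfer_day), , drop = FALSE]
  if (!nrow(pts)) stop("no calibration points from treated conditions", call. = FALSE)
  res <- numeric(0)
  for (td in sort(unique(pts$transfer_day))) {
    sub <- pts[pts$transfer_day == td, , drop = FALSE]
    needed <- sort(unique(c(
      0, td, sub$day[is.na(sub$day_lo)],
      sub$day_lo[!is.na(sub$day_lo)], sub$day_hi[!is.na(sub$day_hi)]
    )))
    p <- update_params(params, transfer_day = td)
    # extreme corners of the search box make the system unintegrable; keep
    # the optimiser running on a finite penalty and mute solver chatter
    traj <- tryCatch({
      msgs <- utils::capture.output(
        tr <- suppressWarnings(simulate_model(p, init = init, t_grid = needed)),
        file = nullfile()
      )
      tr
    }, error = function(e) NULL)
    if (is.null(traj)) return(1e6)
    res <- c(res, residuals_for(traj, sub))
  }
  sqrt(mean(res^2))
}

residuals_for <- function(traj, points) {
  out <- numeric(nrow(points))
  is_growth <- points$kind == "growth" & !is.na(points$day_lo)
  if (any(is_growth)) {
    g <- points[is_growth, ]
    T_lo <- interp_state(traj, g$day_lo)
    T_hi <- interp_state(traj, g$day_hi)
    tot_lo <- T_lo[, "T_p"] + T_lo[, "T_q"]
    tot_hi <- T_hi[, "T_p"] + T_hi[, "T_q"]
    if (any(tot_lo <= 0) || any(tot_hi <= 0)) return(rep(1e3, nrow(points)))
    model_g <- log(tot_hi / tot_lo) / (g$day_hi - g$day_lo)
    out[is_growth] <- g$value - model_g
  }
  rest <- points[!is_growth, , drop = FALSE]
  if (nrow(rest)) {
    p <- trajectory_params(traj)
    st <- interp_state(traj, rest$day)
    Tt <- st[, "T_p"] + st[, "T_q"]
    inv_T <- ifelse(Tt < 1, 0, 1 / Tt)
    pred <- rep(NA_real_, nrow(rest))
    k <- rest$kind
    pred[k == "killing"] <- p$k_e
    pred[k == "tc_mitosis"] <- (p$g * st[, "T_p"] * inv_T)[k == "tc_mitosis"]
    pred[k == "ctl_mitosis"] <- st[k == "ctl_mitosis", "I"]
    pred[k == "ctl_apoptosis"] <- st[k == "ctl_apoptosis", "R"]
    pred[k == "et_ratio"] <- (st[, "E"] * inv_T)[k == "et_ratio"]
    pred[k == "growth"] <- ((p$g * st[, "T_p"] - p$k_e * st[, "E"]) * inv_T)[k == "growth"]
    if (anyNA(pred)) stop("unknown point kind in calibration set", call. = FALSE)
    out[!is_growth] <- rest$value - pred
  }
  out
}

#' Differential evolution with the local-to-best strategy
#'
#' Minimises `fn` over a box. Each candidate is mutated towards the current
#' best member (`x_i + F (best - x_i) + F (x_r1 - x_r2)`), recombined with
#' binomial crossover, clipped to the bounds, and replaces its parent only
#' if it does not increase the objective (greedy selection, so the best
#' objective value is non-increasing across generations).
#'
#' @param fn Objective, a function of a numeric vector.
#' @param lower,upper Bounds (equal length).
#' @param population,generations,F,CR,seed As in [fit_config()].
#' @return List with `par`, `value`, `trace` (best value per generation,
#'   including the initial population), and `n_eval`.
#' @export
de_optimize <- function(fn, lower, upper, population = 40, generations = 120,
                        F = 0.8, CR = 0.9, seed = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower), population >= 4)
  with_private_rng(seed, function() {
    pop <- matrix(0, nrow = population, ncol = d)
    for (i in seq_len(population)) pop[i, ] <- lower + runif(d) * (upper - lower)
    vals <- apply(pop, 1L, fn)
    best <- which.min(vals)
    trace <- numeric(generations + 1L)
    trace[1L] <- vals[best]
    n_eval <- population
    for (gen in seq_len(generations)) {
      for (i in seq_len(population)) {
        r <- sample(seq_len(population)[-i], 2L)
        v <- pop[i, ] + F * (pop[best, ] - pop[i, ]) +
          F * (pop[r[1L], ] - pop[r[2L], ])
        cross <- runif(d) < CR
        cross[sample.int(d, 1L)] <- TRUE
        u <- ifelse(cross, v, pop[i, ])
        u <- pmin(pmax(u, lower), upper)
        fu <- fn(u)
        n_eval <- n_eval + 1L
        if (fu <= vals[i]) {
          pop[i, ] <- u
          vals[i] <- fu
          if (fu < vals[best]) best <- i
        }
      }
      trace[gen + 1L] <- vals[best]
    }
    list(par = pop[best, ], value = vals[best], trace = trace, n_eval = n_eval)
  })
}

#' Fit the model to a cohort's calibration points
#'
#' Minimises [rmse_objective()] over the free parameters with repeated,
#' independently seeded runs of [de_optimize()]. Both transfer-day
#' conditions present in the points are fitted jointly with one shared
#' parameter set; `g` and `d_r` stay at their values in `base` (fixed
#' before fitting).
#'
#' @param points Calibration points (treated conditions).
#' @param config A [fit_config()].
#' @param base A [ctl_params()] supplying the fixed parameters (defaults to
#'   `g = 0.5`, `d_r = 0`).
#' @param init Initial state for the simulations.
#' @return A `ctl_fit`: list with `best_params` (`ctl_params`), `rmse`,
#'   `per_repeat` (tibble of each repeat's parameters, RMSE and seed),
#'   `n_points`, `config`.
#' @export
fit_group <- function(points, config = fit_config(), base = ctl_params(g = 0.5),
                      init = default_init()) {
  stopifnot(inherits(config, "fit_config"))
  pts <- points[!is.na(points$transfer_day), , drop = FALSE]
  if (!nrow(pts)) stop("no calibration points to fit", call. = FALSE)
  free <- config$free
  lower <- vapply(config$bounds, `[[`, numeric(1L), 1L)
  upper <- vapply(config$bounds, `[[`, numeric(1L), 2L)
  obj <- function(x) {
    p <- base
    p[free] <- as.list(x)
    rmse_objective(p, pts, init = init)
  }
  repeat_seeds <- with_private_rng(config$seed, function() {
    sample.int(.Machine$integer.max - 1L, config$repeats)
  })
  runs <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    runs[[r]] <- de_optimize(obj, lower, upper,
                             population = config$population,
                             generations = config$generations,
                             F = config$F, CR = config$CR,
                             seed = repeat_seeds[r])
  }
  values <- vapply(runs, `[[`, numeric(1L), "value")
  best_r <- which.min(values)
  best <- base
  best[free] <- as.list(runs[[best_r]]$par)
  par_mat <- do.call(rbind, lapply(runs, `[[`, "par"))
  colnames(par_mat) <- free
  per_repeat <- tibble::as_tibble(par_mat)
  per_repeat$rmse <- values
  per_repeat$seed <- repeat_seeds
  structure(
    list(best_params = best, rmse = values[best_r], per_repeat = per_repeat,
         n_points = nrow(pts), config = config, traces = lapply(runs, `[[`, "trace")),
    class = "ctl_fit"
  )
}

#' @export
print.ctl_fit <- function(x, ...) {
  cat(sprintf("<ctl_fit> %d points, %d repeat(s); best RMSE %.4g\n",
              x$n_points, nrow(x$per_repeat), x$rmse))
  print(x$best_params)
  invisible(x)
}

#' Local sensitivity of the fit objective
#'
#' Perturbs each parameter by +/- `delta` (multiplicatively) around the
#' supplied values and reports the change in RMSE. Parameters held fixed
#' during fitting are still perturbed but flagged, since their sensitivity
#' is informative even though the optimiser never moved them.
#'
#' @param params Parameter set around which to perturb (e.g. a best fit).
#' @param points Calibration points defining the objective.
#' @param delta Fractional perturbation (default 0.2, i.e. +/- 20%).
#' @param fixed Names of parameters fixed during fitting (flagged in the
#'   output).
#' @param init Initial state for the simulations.
#' @return Tibble with columns `parameter`, `direction`, `value`, `rmse`,
#'   `delta_rmse`, `fixed`.
#' @export
local_sensitivity <- function(params, points, delta = 0.2,
                              fixed = c("g", "d_r"), init = default_init()) {
  validate_params(params)
  base_rmse <- rmse_objective(params, points, init = init)
  rows <- list()
  for (nm in param_names()) {
    for (dir in c(-1, 1)) {
      val <- params[[nm]] * (1 + dir * delta)
      p <- do.call(update_params, c(list(params), setNames(list(val), nm)))
      r <- rmse_objective(p, points, init = init)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = nm, direction = if (dir < 0) "down" else "up",
        value = val, rmse = r, delta_rmse = r - base_rmse,
        fixed = nm %in% fixed
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "base_rmse") <- base_rmse
  out
}
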