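#' @keywords internal
state_names <- function() c("T_p", "T_q", "E", "I", "R")

#' Default initial state
#'
#' The model starts on the day of tumour inoculation with `T` tumour cells,
#' all proliferating, and no intratumoural CTLs, induction or resistance.
#'
#' @param T0 Initial tumour-cell count.
#' @return Named numeric state vector `(T_p, T_q, E, I, R)`.
#' @export
default_init <- function(T0 = 1200) {
  c(T_p = T0, T_q = 0, E = 0, I = 0, R = 0)
}

# Right-hand side shared by the validated public wrapper and the integrator.
# `s_eff` is the infiltration constant already gated on the transfer day.
# The well-mixed rate laws only hold while tumour cells are plentiful, so
# below one cell the 1/T terms are ramped continuously to zero (fractions
# T_x/max(T,1), E:T ratio E*T/max(T,1)^2) instead of being cut off: for
# T >= 1 this is exactly T_x/T and E/T, while a hard cutoff would hand the
# integrator a discontinuity at extinction.
.deriv <- function(y, p, s_eff) {
  T_p <- max(y[[1L]], 0)
  T_q <- max(y[[2L]], 0)
  E   <- max(y[[3L]], 0)
  I   <- max(y[[4L]], 0)
  R   <- max(y[[5L]], 0)
  Tt <- T_p + T_q
  Tc <- max(Tt, 1)
  f_p <- T_p / Tc
  f_q <- T_q / Tc
  et  <- E * Tt / (Tc * Tc)
  c(p$g * T_p - (p$k_e + p$k_q) * f_p * E + p$d_q * T_q,
    p$k_q * f_p * E - p$k_e * f_q * E - p$d_q * T_q,
    s_eff * Tt^(2 / 3) + E * (I - R),
    p$k_i * et - p$d_i * I,
    p$k_r * et - p$d_r * R)
}

.s_active <- function(t, params) {
  td <- params$transfer_day
  if (is.na(td) || t < td) 0 else params$s
}

#' Time derivatives of the model state
#'
#' Evaluates the right-hand side of the five-variable system: proliferating
#' tumour cells `T_p` grow at rate `g` and are killed or arrested by CTLs;
#' quiescent cells `T_q` accumulate at rate `k_q` per CTL (shared with `T_p`
#' in proportion to compartment frequency, as is killing) and recover at
#' `d_q`; CTLs `E` infiltrate across the tumour boundary at `s * T^(2/3)` and
#' turn over at the induced mitosis rate `I` minus the apoptosis rate `R`;
#' the induction and resistance levels are driven by the E:T ratio.
#' Infiltration is inactive before the transfer day.
#'
#' @param state Non-negative named state vector `(T_p, T_q, E, I, R)`.
#' @param params A [ctl_params()] object.
#' @param t Time (day), used only to gate infiltration on `transfer_day`.
#' @return Named numeric vector of derivatives, same shape as `state`.
#' @examples
#' model_derivatives(default_init(), untreated_params(), t = 0)
#' @export
model_derivatives <- function(state, params, t = 0) {
  validate_params(params)
  if (length(state) != 5L || !is.numeric(state)) {
    stop("`state` must be a numeric vector (T_p, T_q, E, I, R)", call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("state components must be finite and non-negative", call. = FALSE)
  }
  d <- .deriv(state, params, .s_active(t, params))
  names(d) <- state_names()
  d
}

#' Simulate the tumour/CTL model over a time grid
#'
#' Integrates the system with an adaptive stiff-capable solver
#' (`deSolve::ode`, `lsoda`). The integration is split at `transfer_day` and
#' the solver restarted there, so the step activation of the infiltration
#' term is handled exactly rather than as a discontinuity inside one solver
#' call. Tight tolerances are used by default because the CTL-turnover loop
#' is mildly stiff when induction rates are large.
#'
#' @param params A [ctl_params()] object.
#' @param init Initial state (non-negative); defaults to [default_init()].
#' @param t_grid Strictly increasing time grid in days; the first entry is
#'   the initial time (day 0, the day of inoculation, by convention).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `ctl_trajectory`: a tibble with columns `time`, `T_p`, `T_q`,
#'   `E`, `I`, `R` and the total `T = T_p + T_q`, carrying the parameters
#'   used as an attribute.
#' @examples
#' tr <- simulate_model(untreated_params(), t_grid = 0:15)
#' head(tr)
#' @export
simulate_model <- function(params, init = default_init(),
                           t_grid = seq(0, 15, by = 0.25),
                           rtol = 1e-8, atol = 1e-8) {
  validate_params(params)
  if (length(init) != 5L || any(!is.finite(init)) || any(init < 0)) {
    stop("`init` must be 5 finite non-negative values (T_p, T_q, E, I, R)",
         call. = FALSE)
  }
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0)) {
    stop("`t_grid` must be non-empty and strictly increasing", call. = FALSE)
  }
  y0 <- as.numeric(init)

  if (length(t_grid) == 1L) {
    states <- matrix(y0, nrow = 1L)
    return(new_trajectory(t_grid, states, params))
  }

  td <- params$transfer_day
  split <- is.finite(td) && td > t_grid[1L] && td < t_grid[length(t_grid)]
  if (split) {
    seg <- list(
      list(times = unique(c(t_grid[t_grid <= td], td)), s = 0),
      list(times = unique(c(td, t_grid[t_grid > td])), s = params$s)
    )
  } else {
    t_mid <- (t_grid[1L] + t_grid[length(t_grid)]) / 2
    seg <- list(list(times = t_grid, s = .s_active(t_mid, params)))
  }

  rows <- vector("list", length(seg))
  y <- y0
  for (i in seq_along(seg)) {
    sg <- seg[[i]]
    if (length(sg$times) == 1L) {
      rows[[i]] <- matrix(c(sg$times, y), nrow = 1L)
      next
    }
    parms <- c(params$g, sg$s, params$k_e, params$k_i, params$d_i,
               params$k_r, params$d_r, params$k_q, params$d_q)
    out <- deSolve::ode(y = y, times = sg$times, func = "actdyn_deriv",
                        parms = parms, dllname = "actdyn",
                        initfunc = "actdyn_init",
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    if (nrow(out) < length(sg$times) || any(!is.finite(out))) {
      stop(sprintf("integration failed on [%g, %g]",
                   sg$times[1L], sg$times[length(sg$times)]), call. = FALSE)
    }
    rows[[i]] <- unname(out)
    y <- as.numeric(out[nrow(out), -1L])
  }
  out <- do.call(rbind, rows)
  keep <- match(t_grid, out[, 1L])
  if (anyNA(keep)) stop("internal error: requested times missing from solution")
  states <- pmax(out[keep, -1L, drop = FALSE], 0)  # floor solver jitter at 0
  new_trajectory(t_grid, states, params)
}

new_trajectory <- function(times, states, params) {
  colnames(states) <- state_names()
  col <- function(nm) unname(states[, nm])
  tr <- tibble::tibble(
    time = times,
    T_p = col("T_p"), T_q = col("T_q"),
    E = col("E"), I = col("I"), R = col("R"),
    T = col("T_p") + col("T_q")
  )
  attr(tr, "params") <- params
  class(tr) <- c("ctl_trajectory", class(tr))
  tr
}

#' Parameters attached to a trajectory
#'
#' @param traj A `ctl_trajectory`.
#' @return The `ctl_params` used to produce it.
#' @export
trajectory_params <- function(traj) {
  p <- attr(traj, "params")
  if (is.null(p)) stop("trajectory carries no parameters", call. = FALSE)
  p
}
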