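#' Design of a synthetic imaging cohort
#'
#' Encodes the study design being emulated: tumour volumes measured on days
#' 1, 3, 6, 9, 13 and 15 in every mouse; about four intravital positions per
#' mouse imaged for 1-3 h on days 6 and 9 (only on days on or after the
#' transfer day); event counts Poisson-distributed given the model's
#' per-capita rates.
#'
#' @param n_mice Mice per condition.
#' @param volume_days Days of volume measurement.
#' @param imaging_days Days on which positions are imaged.
#' @param positions_per_day Imaged positions per mouse per imaging day.
#' @param duration_range Imaging duration range in hours.
#' @param field_cell_scale Expected tumour cells in one field when the
#'   tumour holds `t_ref` cells. The default 1600 is the field volume
#'   (0.35 x 0.35 x 0.1 mm) times the assumed cell density.
#' @param t_ref Reference tumour size for `field_cell_scale` (default
#'   2.4e4, the model's untreated size on day 6).
#' @param field_sigma Lognormal sigma for between-field variation in cell
#'   numbers (imaging windows land on very different neighbourhoods).
#' @param volume_cv Coefficient of variation of multiplicative lognormal
#'   volume noise.
#' @param cells_per_mm3 Cell density converting model cell counts to
#'   volumes. The default 1.3e5 places the untreated day-3 volume near the
#'   observed median of 0.04 mm^3 given 1200 inoculated cells; it is a
#'   bookkeeping constant, not a biological density estimate.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of design + parameters + seed.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_mice = 4, volume_days = c(1, 3, 6, 9, 13, 15),
                          imaging_days = c(6, 9), positions_per_day = 4,
                          duration_range = c(1, 3), field_cell_scale = 1600,
                          t_ref = 2.4e4, field_sigma = 0.5, volume_cv = 0.2,
                          cells_per_mm3 = 1.3e5, seed = 1) {
  stopifnot(n_mice >= 1, positions_per_day >= 1, volume_cv >= 0,
            field_sigma >= 0, length(duration_range) == 2L,
            duration_range[1L] > 0, diff(duration_range) >= 0,
            field_cell_scale > 0, t_ref > 0, cells_per_mm3 > 0)
  structure(list(n_mice = as.integer(n_mice), volume_days = volume_days,
                 imaging_days = imaging_days,
                 positions_per_day = as.integer(positions_per_day),
                 duration_range = duration_range,
                 field_cell_scale = field_cell_scale, t_ref = t_ref,
                 field_sigma = field_sigma, volume_cv = volume_cv,
                 cells_per_mm3 = cells_per_mm3, seed = as.integer(seed)),
            class = "cohort_design")
}

#' The study's treatment conditions
#'
#' Convenience constructor for the condition list consumed by
#' [generate_cohort()]: an untreated control plus ACT-only and ACT+mAb
#' conditions transferred on day 3 and day 7, at the packaged best-fit
#' parameter values.
#'
#' @param include_control Include the untreated control condition.
#' @param transfer_days Transfer days to include for treated conditions.
#' @return Named list of conditions, each a list with `group`, `params`,
#'   `transfer_day`.
#' @export
default_conditions <- function(include_control = TRUE, transfer_days = c(3, 7)) {
  conds <- list()
  if (include_control) {
    conds[["control"]] <- list(group = "no-ACT control",
                               params = untreated_params(),
                               transfer_day = NA_real_)
  }
  for (td in transfer_days) {
    conds[[paste0("act_only_d", td)]] <- list(
      group = "ACT-only", params = act_only_params(td), transfer_day = td)
    conds[[paste0("act_mab_d", td)]] <- list(
      group = "ACT+mAb", params = act_mab_params(td), transfer_day = td)
  }
  conds
}

#' Expected per-position counts at a given day
#'
#' Closed-form expectations used by the generator, exposed for testing:
#' field tumour-cell count scales with total tumour size, the CTL count
#' follows the model's E:T ratio, and each event count is (per-capita rate)
#' x (cell count) x (duration in days): TC apoptosis at `k_e` per CTL, TC
#' mitosis at `g T_p / T` per tumour cell, CTL mitosis at `I` and CTL
#' apoptosis at `R` per CTL.
#'
#' @param params A [ctl_params()].
#' @param design A [cohort_design()].
#' @param day Day of imaging.
#' @param duration Imaging duration in hours (default: midpoint of the
#'   design's range).
#' @param n_ctl,n_tc Optionally condition on observed cell counts instead
#'   of their expectations.
#' @return One-row tibble: `day, duration, n_ctl, n_tc, tc_apoptosis,
#'   tc_mitosis, ctl_apoptosis, ctl_mitosis` (expectations, not integers).
#' @export
expected_counts <- function(params, design, day,
                            duration = mean(design$duration_range),
                            n_ctl = NULL, n_tc = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  traj <- simulate_model(params, t_grid = sort(unique(c(0, day))))
  st <- interp_state(traj, day)
  expected_counts_state(params, design, day, st, duration, n_ctl, n_tc)
}

expected_counts_state <- function(params, design, day, st, duration,
                                  n_ctl = NULL, n_tc = NULL) {
  Tt <- st[, "T_p"] + st[, "T_q"]
  if (is.null(n_tc)) n_tc <- design$field_cell_scale * Tt / design$t_ref
  if (is.null(n_ctl)) n_ctl <- if (Tt < 1) 0 else n_tc * st[, "E"] / Tt
  tau <- duration / HOURS_PER_DAY
  f_p <- if (Tt < 1) 0 else st[, "T_p"] / Tt
  tibble::tibble(
    day = day, duration = duration, n_ctl = unname(as.numeric(n_ctl)),
    n_tc = unname(as.numeric(n_tc)),
    tc_apoptosis = unname(params$k_e * n_ctl * tau),
    tc_mitosis = unname(params$g * f_p * n_tc * tau),
    ctl_apoptosis = unname(st[, "R"] * n_ctl * tau),
    ctl_mitosis = unname(st[, "I"] * n_ctl * tau)
  )
}

#' Generate a synthetic cohort
#'
#' Simulates the model per condition and draws a cohort with the study's
#' statistical structure: per-mouse volumes `T(day) / cells_per_mm3` with
#' multiplicative lognormal noise; per-position imaging durations uniform
#' in the design range; field cell counts Poisson around a
#' lognormal-dispersed expectation scaling with tumour size; CTL counts
#' Poisson with mean `n_tc * E / T`; event counts Poisson with the
#' [expected_counts()] means. With `noise = FALSE` every draw is replaced
#' by its expectation (durations fixed at the range midpoint, counts left
#' non-integer), so that downstream rate estimators recover the model rates
#' exactly — the deterministic round trip used in self-consistency checks.
#'
#' @param conditions List of conditions (`group`, `params`, `transfer_day`),
#'   e.g. from [default_conditions()].
#' @param design A [cohort_design()].
#' @param noise Draw stochastic realisations (default) or expectations.
#' @return A `ctl_cohort` with a manifest attribute recording design and
#'   seed.
#' @examples
#' des <- cohort_design(n_mice = 2, seed = 7)
#' coh <- generate_cohort(default_conditions(transfer_days = 3), des)
#' coh
#' @export
generate_cohort <- function(conditions, design = cohort_design(), noise = TRUE) {
  stopifnot(inherits(design, "cohort_design"), length(conditions) >= 1L)
  with_private_rng(design$seed, function() {
    vol_rows <- list(); pos_rows <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      p <- update_params(cond$params,
                         transfer_day = if (is.na(cond$transfer_day)) Inf
                                        else cond$transfer_day)
      td <- cond$transfer_day
      img_days <- design$imaging_days[
        is.finite(td) & design$imaging_days >= ifelse(is.na(td), Inf, td)]
      t_grid <- sort(unique(c(0, design$volume_days, img_days,
                              if (is.finite(td)) td)))
      traj <- simulate_model(p, t_grid = t_grid)
      for (m in seq_len(design$n_mice)) {
        id <- sprintf("%s_m%02d", names(conditions)[ci] %||% paste0("c", ci), m)
        st_v <- interp_state(traj, design$volume_days)
        v_true <- (st_v[, "T_p"] + st_v[, "T_q"]) / design$cells_per_mm3
        v_obs <- if (noise && design$volume_cv > 0) {
          sdl <- sqrt(log(1 + design$volume_cv^2))
          v_true * rlnorm(length(v_true), meanlog = -sdl^2 / 2, sdlog = sdl)
        } else v_true
        vol_rows[[length(vol_rows) + 1L]] <- tibble::tibble(
          mouse_id = id, group = cond$group, transfer_day = td,
          day = design$volume_days, volume = v_obs
        )
        for (dy in img_days) {
          st <- interp_state(traj, dy)
          for (k in seq_len(design$positions_per_day)) {
            dur <- if (noise) runif(1L, design$duration_range[1L],
                                    design$duration_range[2L])
                   else mean(design$duration_range)
            disp <- if (noise && design$field_sigma > 0) {
              rlnorm(1L, meanlog = -design$field_sigma^2 / 2,
                     sdlog = design$field_sigma)
            } else 1
            Tt <- st[, "T_p"] + st[, "T_q"]
            mu_tc <- design$field_cell_scale * Tt / design$t_ref * disp
            n_tc <- if (noise) rpois(1L, mu_tc) else mu_tc
            mu_ctl <- if (Tt < 1) 0 else n_tc * st[, "E"] / Tt
            n_ctl <- if (noise) rpois(1L, mu_ctl) else mu_ctl
            ev <- expected_counts_state(p, design, dy, st, dur,
                                        n_ctl = n_ctl, n_tc = n_tc)
            if (noise) {
              ev$tc_apoptosis <- rpois(1L, ev$tc_apoptosis)
              ev$tc_mitosis <- rpois(1L, ev$tc_mitosis)
              ev$ctl_apoptosis <- rpois(1L, ev$ctl_apoptosis)
              ev$ctl_mitosis <- rpois(1L, ev$ctl_mitosis)
            }
            pos_rows[[length(pos_rows) + 1L]] <- tibble::tibble(
              mouse_id = id, group = cond$group, transfer_day = td,
              day = dy, duration = dur, n_ctl = ev$n_ctl, n_tc = ev$n_tc,
              tc_apoptosis = ev$tc_apoptosis, tc_mitosis = ev$tc_mitosis,
              ctl_apoptosis = ev$ctl_apoptosis, ctl_mitosis = ev$ctl_mitosis
            )
          }
        }
      }
    }
    volumes <- dplyr::bind_rows(vol_rows)
    positions <- if (length(pos_rows)) dplyr::bind_rows(pos_rows) else
      tibble::tibble(mouse_id = character(), group = character(),
                     transfer_day = numeric(), day = numeric(),
                     duration = numeric(), n_ctl = numeric(), n_tc = numeric(),
                     tc_apoptosis = numeric(), tc_mitosis = numeric(),
                     ctl_apoptosis = numeric(), ctl_mitosis = numeric())
    manifest <- list(
      generator = "actdyn::generate_cohort", noise = noise,
      seed = design$seed,
      design = unclass(design),
      conditions = lapply(conditions, function(cn) {
        list(group = cn$group, transfer_day = cn$transfer_day,
             params = lapply(unclass(cn$params), function(v)
               if (is.infinite(v)) "Inf" else v))
      })
    )
    new_cohort(volumes, positions, manifest)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
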