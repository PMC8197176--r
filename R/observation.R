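#' @keywords internal
point_kinds <- function() {
  c("growth", "killing", "tc_mitosis", "ctl_mitosis", "ctl_apoptosis",
    "et_ratio")
}

new_points <- function(kind, day, value, day_lo = NA_real_, day_hi = NA_real_,
                       mouse_id = NA_character_, group = NA_character_,
                       transfer_day = NA_real_) {
  tibble::tibble(
    kind = kind, day = as.numeric(day), value = as.numeric(value),
    day_lo = as.numeric(day_lo), day_hi = as.numeric(day_hi),
    mouse_id = as.character(mouse_id), group = as.character(group),
    transfer_day = as.numeric(transfer_day)
  )
}

#' Per-interval volumetric growth rates
#'
#' Converts a tumour-volume time series into growth-rate estimates: for each
#' pair of successive measurements the rate is `ln(V2/V1) / (t2 - t1)`
#' (day^-1), placed at the midpoint of the interval. The interval bounds are
#' retained (`day_lo`, `day_hi`) so a model trajectory can later be
#' differenced over exactly the same intervals.
#'
#' @param volumes Data frame with columns `day` (strictly increasing) and
#'   `volume` (mm^3, strictly positive), one row per measurement.
#' @param ... Condition tags (`mouse_id`, `group`, `transfer_day`) attached
#'   to the emitted points.
#' @return A tibble of calibration points of kind `"growth"`.
#' @examples
#' growth_rate_series(data.frame(day = c(1, 3), volume = c(0.1, 0.1 * exp(1))))
#' @export
growth_rate_series <- function(volumes, ...) {
  stopifnot(is.data.frame(volumes), all(c("day", "volume") %in% names(volumes)))
  d <- as.numeric(volumes$day)
  v <- as.numeric(volumes$volume)
  if (length(d) < 2L) stop("need at least two volume measurements", call. = FALSE)
  if (any(diff(d) <= 0)) stop("volume days must be strictly increasing", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("volumes must be finite and strictly positive", call. = FALSE)
  }
  n <- length(d)
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  new_points(
    kind = "growth",
    day = (d[i1] + d[i2]) / 2,
    value = log(v[i2] / v[i1]) / (d[i2] - d[i1]),
    day_lo = d[i1], day_hi = d[i2],
    ...
  )
}

validate_positions <- function(positions) {
  req <- c("day", "duration", "n_ctl", "n_tc",
           "tc_apoptosis", "tc_mitosis", "ctl_apoptosis", "ctl_mitosis")
  miss <- setdiff(req, names(positions))
  if (length(miss)) stop("position table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(positions$duration <= 0)) stop("imaging durations must be > 0", call. = FALSE)
  cnt <- positions[c("n_ctl", "n_tc", "tc_apoptosis", "tc_mitosis",
                     "ctl_apoptosis", "ctl_mitosis")]
  if (any(unlist(cnt) < 0) || any(!is.finite(unlist(cnt)))) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  invisible(positions)
}

#' Process rates from intravital imaging positions
#'
#' Converts per-position event counts into per-day process rates:
#' killing = TC apoptosis / (time x CTLs); TC mitosis = TC mitosis events /
#' (time x tumour cells); CTL mitosis and apoptosis are events / (time x
#' CTLs); plus the dimensionless E:T ratio `n_ctl / n_tc`. Imaging durations
#' are in hours and all rates are returned in day^-1. Rates whose
#' denominator count is zero are not emitted: a 0/0 per-capita rate carries
#' no information and must not enter a fit as a spurious zero.
#'
#' @param positions Data frame with one row per imaged position; columns
#'   `day`, `duration` (hours), `n_ctl`, `n_tc`, `tc_apoptosis`,
#'   `tc_mitosis`, `ctl_apoptosis`, `ctl_mitosis`, and optionally
#'   `mouse_id`, `group`, `transfer_day`.
#' @return A tibble of calibration points (kinds `killing`, `tc_mitosis`,
#'   `ctl_mitosis`, `ctl_apoptosis`, `et_ratio`).
#' @examples
#' pos <- data.frame(day = 6, duration = 2, n_ctl = 4, n_tc = 50,
#'                   tc_apoptosis = 2, tc_mitosis = 1,
#'                   ctl_apoptosis = 0, ctl_mitosis = 0)
#' intravital_rates(pos)
#' @export
intravital_rates <- function(positions) {
  positions <- as.data.frame(positions)
  validate_positions(positions)
  tag <- function(col, default) {
    if (col %in% names(positions)) positions[[col]] else default
  }
  mouse <- tag("mouse_id", NA_character_)
  group <- tag("group", NA_character_)
  td <- tag("transfer_day", NA_real_)
  tau_days <- positions$duration / HOURS_PER_DAY

  per <- function(kind, events, denom) {
    ok <- denom > 0
    if (!any(ok)) return(NULL)
    new_points(kind = kind, day = positions$day[ok],
               value = events[ok] / (tau_days[ok] * denom[ok]),
               mouse_id = mouse[ok], group = group[ok], transfer_day = td[ok])
  }
  et <- {
    ok <- positions$n_tc > 0
    if (any(ok)) new_points(kind = "et_ratio", day = positions$day[ok],
                            value = positions$n_ctl[ok] / positions$n_tc[ok],
                            mouse_id = mouse[ok], group = group[ok],
                            transfer_day = td[ok]) else NULL
  }
  dplyr::bind_rows(
    per("killing", positions$tc_apoptosis, positions$n_ctl),
    per("tc_mitosis", positions$tc_mitosis, positions$n_tc),
    per("ctl_mitosis", positions$ctl_mitosis, positions$n_ctl),
    per("ctl_apoptosis", positions$ctl_apoptosis, positions$n_ctl),
    et
  )
}

interp_state <- function(traj, days) {
  tt <- traj$time
  if (any(days < tt[1L] - 1e-9) || any(days > tt[length(tt)] + 1e-9)) {
    stop("requested day outside the trajectory span", call. = FALSE)
  }
  cols <- c("T_p", "T_q", "E", "I", "R")
  out <- vapply(cols, function(cl) {
    if (length(tt) == 1L) rep(traj[[cl]], length(days))
    else approx(tt, traj[[cl]], xout = days)$y
  }, numeric(length(days)))
  if (length(days) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, cols))
  out
}

#' Model-side counterparts of the observed statistics
#'
#' Evaluates, at the requested days, the model quantities corresponding to
#' each observed statistic: killing rate `k_e` (constant per CTL), tumour
#' mitosis rate `g * T_p / T`, CTL mitosis rate `I`, CTL apoptosis rate `R`,
#' E:T ratio `E / T`, and the instantaneous volumetric growth rate
#' `(1/T) dT/dt = (g * T_p - k_e * E) / T` (the quiescence exchange cancels
#' from the total, so killing is the only loss term).
#'
#' @param traj A `ctl_trajectory` from [simulate_model()].
#' @param days Days at which to evaluate; must lie inside the trajectory
#'   span (states are linearly interpolated between grid points).
#' @return A tibble of calibration points, one row per kind and day.
#' @export
model_predictions <- function(traj, days) {
  p <- trajectory_params(traj)
  st <- interp_state(traj, days)
  Tt <- st[, "T_p"] + st[, "T_q"]
  inv_T <- ifelse(Tt < 1, 0, 1 / Tt)
  dplyr::bind_rows(
    new_points("killing", days, rep(p$k_e, length(days))),
    new_points("tc_mitosis", days, p$g * st[, "T_p"] * inv_T),
    new_points("ctl_mitosis", days, st[, "I"]),
    new_points("ctl_apoptosis", days, st[, "R"]),
    new_points("et_ratio", days, st[, "E"] * inv_T),
    new_points("growth", days, (p$g * st[, "T_p"] - p$k_e * st[, "E"]) * inv_T)
  )
}

#' Assemble all calibration points from a cohort
#'
#' Runs [growth_rate_series()] on every mouse's volume series and
#' [intravital_rates()] on every imaged position, tagging each point with
#' its mouse, treatment group and transfer day.
#'
#' @param cohort A `ctl_cohort` (see [generate_cohort()] / [read_cohort()]).
#' @param aggregate_positions If `TRUE`, intravital points are averaged per
#'   mouse, day and kind before being returned (one point per mouse-day
#'   instead of one per position). Default `FALSE`: the fit treats each
#'   position as one observation.
#' @return A tibble of calibration points.
#' @export
calibration_points <- function(cohort, aggregate_positions = FALSE) {
  stopifnot(inherits(cohort, "ctl_cohort"))
  vol <- cohort$volumes
  growth <- dplyr::bind_rows(lapply(split(vol, vol$mouse_id), function(vm) {
    vm <- vm[order(vm$day), ]
    growth_rate_series(vm[c("day", "volume")],
                       mouse_id = vm$mouse_id[1L], group = vm$group[1L],
                       transfer_day = vm$transfer_day[1L])
  }))
  intra <- if (nrow(cohort$positions)) intravital_rates(cohort$positions) else NULL
  if (!is.null(intra) && aggregate_positions) {
    agg <- stats::aggregate(
      value ~ kind + day + mouse_id + group + transfer_day,
      data = intra, FUN = mean, na.action = stats::na.pass
    )
    intra <- new_points(kind = agg$kind, day = agg$day, value = agg$value,
                        mouse_id = agg$mouse_id, group = agg$group,
                        transfer_day = agg$transfer_day)
  }
  dplyr::bind_rows(growth, intra)
}

#' Read / write a cohort as delimited text
#'
#' A cohort is stored as two CSV tables: `volumes.csv` (one row per volume
#' measurement: `mouse_id, group, transfer_day, day, volume`) and
#' `positions.csv` (one row per imaged position: `mouse_id, group,
#' transfer_day, day, duration, n_ctl, n_tc, tc_apoptosis, tc_mitosis,
#' ctl_apoptosis, ctl_mitosis`), plus a YAML `manifest.yaml` recording the
#' generating design and seed when the cohort is synthetic.
#'
#' @param cohort A `ctl_cohort`.
#' @param dir Directory to write to / read from.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `ctl_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctl_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  write.csv(cohort$positions, file.path(dir, "positions.csv"), row.names = FALSE)
  manifest <- attr(cohort, "manifest")
  if (!is.null(manifest)) yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  vols <- tibble::as_tibble(read.csv(file.path(dir, "volumes.csv")))
  pos <- tibble::as_tibble(read.csv(file.path(dir, "positions.csv")))
  manifest_path <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else NULL
  new_cohort(vols, pos, manifest)
}

new_cohort <- function(volumes, positions, manifest = NULL) {
  stopifnot(all(c("mouse_id", "group", "transfer_day", "day", "volume")
                %in% names(volumes)))
  obj <- structure(list(volumes = tibble::as_tibble(volumes),
                        positions = tibble::as_tibble(positions)),
                   class = "ctl_cohort")
  attr(obj, "manifest") <- manifest
  obj
}

#' @export
print.ctl_cohort <- function(x, ...) {
  cat("<ctl_cohort>", length(unique(x$volumes$mouse_id)), "mice,",
      nrow(x$volumes), "volume measurements,",
      nrow(x$positions), "imaged positions\n")
  grp <- unique(x$volumes[c("group", "transfer_day")])
  for (i in seq_len(nrow(grp))) {
    cat(sprintf("  %s (transfer day %s)\n", grp$group[i],
                format(grp$transfer_day[i])))
  }
  invisible(x)
}
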