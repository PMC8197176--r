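#' Model parameter set
#'
#' Container for the nine rate constants of the tumour/CTL model plus the
#' treatment schedule. All rates are per day; `s` is per TC^(2/3) per day
#' (a constant infiltration flux per unit tumour boundary area).
#'
#' @param g Tumour-cell mitosis rate (day^-1). Fixed at 0.5 for all fits,
#'   estimated from untreated growth.
#' @param s CTL infiltration rate constant (TC^-2/3 day^-1). Inactive
#'   (treated as 0) before `transfer_day`.
#' @param k_e Per-CTL killing rate of tumour cells (CTL^-1 day^-1).
#' @param k_i Rate of CTL-induced increase in CTL mitosis (day^-1).
#' @param d_i Decay rate of the mitosis-inducing stimulus (day^-1).
#' @param k_r Rate of CTL-induced resistance, i.e. tumour-driven increase in
#'   CTL apoptosis (day^-1).
#' @param d_r Decay rate of resistance (day^-1). Fixed at 0 by default: over
#'   the two-week experiment the resistance does not measurably decay.
#' @param k_q Rate at which CTLs push tumour cells into quiescence
#'   (CTL^-1 day^-1) — the antiproliferative effect.
#' @param d_q Recovery rate from quiescence (day^-1).
#' @param transfer_day Day of adoptive cell transfer (non-negative). Use
#'   `Inf` (or `NA`) for an untreated condition in which `s` never activates.
#'
#' @return An object of class `ctl_params` (a validated named list).
#' @seealso [act_only_params()], [act_mab_params()], [untreated_params()],
#'   [read_params()], [write_params()]
#' @examples
#' p <- ctl_params(g = 0.5, s = 0.7, k_e = 0.75, transfer_day = 3)
#' p
#' @export
ctl_params <- function(g = 0.5, s = 0, k_e = 0, k_i = 0, d_i = 0,
                       k_r = 0, d_r = 0, k_q = 0, d_q = 0,
                       transfer_day = 3) {
  p <- structure(
    list(g = g, s = s, k_e = k_e, k_i = k_i, d_i = d_i,
         k_r = k_r, d_r = d_r, k_q = k_q, d_q = d_q,
         transfer_day = transfer_day),
    class = "ctl_params"
  )
  validate_params(p)
  p
}

#' Names of the model's rate parameters
#'
#' @return Character vector of the nine rate-constant names (excludes
#'   `transfer_day`).
#' @export
param_names <- function() {
  c("g", "s", "k_e", "k_i", "d_i", "k_r", "d_r", "k_q", "d_q")
}

#' Parameters varied during calibration
#'
#' The seven rate constants that are free in the fitting procedure; `g` is
#' pre-fixed from untreated growth and `d_r` is pinned to 0.
#'
#' @return Character vector of seven parameter names.
#' @export
free_param_names <- function() {
  c("s", "k_e", "k_i", "d_i", "k_r", "k_q", "d_q")
}

validate_params <- function(p) {
  if (!inherits(p, "ctl_params")) stop("not a `ctl_params` object", call. = FALSE)
  for (nm in param_names()) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter `%s` must be a single finite number", nm),
           call. = FALSE)
    }
    if (v < 0) stop(sprintf("parameter `%s` must be >= 0 (got %g)", nm, v),
                    call. = FALSE)
  }
  td <- p$transfer_day
  if (!is.numeric(td) || length(td) != 1L) {
    stop("`transfer_day` must be a single number (Inf/NA for never)",
         call. = FALSE)
  }
  if (is.finite(td) && td < 0) stop("`transfer_day` must be >= 0", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' @param params A `ctl_params` object.
#' @param ... Named parameter values to replace.
#' @return A new validated `ctl_params` object.
#' @export
update_params <- function(params, ...) {
  validate_params(params)
  repl <- list(...)
  bad <- setdiff(names(repl), c(param_names(), "transfer_day"))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  params[names(repl)] <- repl
  validate_params(params)
  params
}

#' @export
print.ctl_params <- function(x, ...) {
  cat("<ctl_params>\n")
  vals <- unlist(x[param_names()])
  cat(paste0("  ", format(names(vals), width = 4), " = ",
             format(vals, digits = 4), collapse = "\n"), "\n")
  cat("  transfer_day =", x$transfer_day, "\n")
  invisible(x)
}

#' @export
as.list.ctl_params <- function(x, ...) unclass(x)

#' Read / write a parameter set as a flat YAML file
#'
#' The file holds one `key: value` pair per parameter, using the field's
#' symbol names (`g`, `s`, `k_e`, ...), plus `transfer_day`.
#'
#' @param path File path.
#' @param params A `ctl_params` object (for `write_params`).
#' @return `read_params` returns a `ctl_params`; `write_params` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c(param_names(), "transfer_day")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown key(s) in ", path, ": ",
                        paste(bad, collapse = ", "), call. = FALSE)
  raw <- lapply(raw, function(v) if (identical(v, "Inf")) Inf else v)
  do.call(ctl_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- unclass(params)
  if (is.infinite(out$transfer_day)) out$transfer_day <- "Inf"
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Best-fitting parameter sets for the two treated conditions
#'
#' Packaged calibrated parameter sets for CTL transfer alone (`act_only`) and
#' CTL transfer plus intratumoural anti-CD137 costimulation (`act_mab`),
#' loaded from the YAML fixtures shipped in `inst/extdata/`. These are the
#' reference operating points used throughout the examples, the scenario
#' sweeps, and as ground truth for synthetic-cohort recovery experiments.
#'
#' @param transfer_day Day of adoptive transfer for the returned set
#'   (the study used day 3 or day 7).
#' @return A `ctl_params` object.
#' @export
act_only_params <- function(transfer_day = 3) {
  p <- read_params(system.file("extdata", "params_act_only.yaml",
                               package = "actdyn", mustWork = TRUE))
  update_params(p, transfer_day = transfer_day)
}

#' @rdname act_only_params
#' @export
act_mab_params <- function(transfer_day = 3) {
  p <- read_params(system.file("extdata", "params_act_mab.yaml",
                               package = "actdyn", mustWork = TRUE))
  update_params(p, transfer_day = transfer_day)
}

#' Parameters for a tumour growing without CTL pressure
#'
#' @param g Tumour mitosis rate (day^-1).
#' @return A `ctl_params` with `s = 0` and no transfer day, i.e. pure
#'   exponential growth at rate `g`.
#' @export
untreated_params <- function(g = 0.5) {
  ctl_params(g = g, transfer_day = Inf)
}
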