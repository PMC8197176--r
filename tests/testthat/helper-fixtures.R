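# Shared fixtures built in code: a minimal position table and the noise-free
# two-schedule cohort used by the calibration tests.

make_positions <- function(day = 6, duration = 2, n_ctl = 4, n_tc = 50,
                           tc_apoptosis = 0, tc_mitosis = 0,
                           ctl_apoptosis = 0, ctl_mitosis = 0, ...) {
  data.frame(day = day, duration = duration, n_ctl = n_ctl, n_tc = n_tc,
             tc_apoptosis = tc_apoptosis, tc_mitosis = tc_mitosis,
             ctl_apoptosis = ctl_apoptosis, ctl_mitosis = ctl_mitosis, ...)
}

# Noise-free ACT+mAb cohort, day-3 and day-7 schedules, 1 mouse each.
noise_free_mab_points <- function() {
  conds <- list(
    d3 = list(group = "ACT+mAb", params = act_mab_params(3), transfer_day = 3),
    d7 = list(group = "ACT+mAb", params = act_mab_params(7), transfer_day = 7)
  )
  coh <- generate_cohort(conds, cohort_design(n_mice = 1, seed = 1),
                         noise = FALSE)
  calibration_points(coh)
}

rel_err <- function(x, ref, floor = 1e-8) {
  abs(x - ref) / pmax(abs(ref), floor)
}

# Independent numerical Poisson-rate MLE: bracket the minimum of the negative
# log-likelihood, then locate the zero of its central-difference gradient.
# Assumes at least one event (otherwise the MLE sits on the boundary at 0).
numeric_poisson_mle <- function(kills, expo) {
  nll <- function(l) -sum(dpois(kills, l * expo, log = TRUE))
  grad <- function(l) {
    h <- min(1e-6 * max(l, 1e-3), l / 2)
    (nll(l + h) - nll(l - h)) / (2 * h)
  }
  hi <- 1
  while (grad(hi) < 0) hi <- hi * 4
  uniroot(grad, c(1e-10, hi), tol = 1e-13)$root
}
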