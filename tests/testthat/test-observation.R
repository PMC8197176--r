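test_that("growth-rate series places log rates at interval midpoints", {
  g0 <- growth_rate_series(data.frame(day = c(1, 3), volume = c(0.1, 0.1)))
  expect_equal(g0$value, 0)
  expect_equal(g0$day, 2)
  expect_equal(c(g0$day_lo, g0$day_hi), c(1, 3))

  g1 <- growth_rate_series(data.frame(day = c(1, 3),
                                      volume = c(0.1, 0.1 * exp(1))))
  expect_equal(g1$value, 0.5)

  v <- data.frame(day = c(1, 3, 6), volume = c(1, 2, 8))
  g <- growth_rate_series(v)
  expect_equal(g$day, c(2, 4.5))
  expect_equal(g$value, c(log(2) / 2, log(4) / 3))

  expect_error(growth_rate_series(data.frame(day = 1, volume = 1)), "two")
  expect_error(growth_rate_series(data.frame(day = c(1, 3), volume = c(1, 0))),
               "positive")
  expect_error(growth_rate_series(data.frame(day = c(3, 1), volume = c(1, 1))),
               "increasing")
})

test_that("intravital rates follow the per-capita definitions in day^-1", {
  pos <- make_positions(duration = 2, n_ctl = 4, n_tc = 50,
                        tc_apoptosis = 2, tc_mitosis = 1)
  pts <- intravital_rates(pos)
  get <- function(k) pts$value[pts$kind == k]
  expect_equal(get("killing"), 2 / (2 * 4) * 24)      # 6.0 day^-1
  expect_equal(get("tc_mitosis"), 1 / (2 * 50) * 24)  # 0.24 day^-1
  expect_equal(get("et_ratio"), 4 / 50)               # 0.08
  expect_equal(get("ctl_mitosis"), 0)
  expect_equal(get("ctl_apoptosis"), 0)

  # no CTLs: per-CTL rates are absent (not zero), E:T is still defined
  pts0 <- intravital_rates(make_positions(n_ctl = 0))
  expect_setequal(unique(pts0$kind), c("tc_mitosis", "et_ratio"))
  expect_equal(pts0$value[pts0$kind == "et_ratio"], 0)

  expect_error(intravital_rates(make_positions(duration = 0)), "duration")
  expect_error(intravital_rates(make_positions(tc_apoptosis = -1)), "counts")
})

test_that("rates are inversely proportional to imaging duration", {
  p1 <- intravital_rates(make_positions(duration = 1.5, tc_apoptosis = 3,
                                        tc_mitosis = 2, ctl_mitosis = 1))
  p2 <- intravital_rates(make_positions(duration = 3, tc_apoptosis = 3,
                                        tc_mitosis = 2, ctl_mitosis = 1))
  rate_kinds <- setdiff(p1$kind, "et_ratio")
  for (k in rate_kinds) {
    expect_equal(p2$value[p2$kind == k], p1$value[p1$kind == k] / 2)
  }
  expect_equal(p2$value[p2$kind == "et_ratio"],
               p1$value[p1$kind == "et_ratio"])
})

test_that("model predictions match analytic values and the growth identity", {
  tr_u <- simulate_model(untreated_params(g = 0.5), t_grid = 0:15)
  pr <- model_predictions(tr_u, days = c(2, 9.5, 14))
  expect_equal(pr$value[pr$kind == "tc_mitosis"], rep(0.5, 3))
  expect_equal(pr$value[pr$kind == "et_ratio"], rep(0, 3))
  expect_equal(pr$value[pr$kind == "growth"], rep(0.5, 3))
  expect_error(model_predictions(tr_u, days = 16), "span")

  # treated condition: the killing prediction is the constant k_e, and the
  # emitted growth rate matches a finite difference of log T from a dense
  # simulation
  p <- act_only_params(3)
  tr <- simulate_model(p, t_grid = seq(0, 15, by = 0.01))
  pr <- model_predictions(tr, days = c(6, 9))
  expect_equal(pr$value[pr$kind == "killing"], c(0.75, 0.75))
  for (d in c(6, 9)) {
    i <- match(d, tr$time)
    fd <- (log(tr$T[i + 1]) - log(tr$T[i - 1])) / 0.02
    expect_lt(abs(pr$value[pr$kind == "growth" & pr$day == d] - fd), 1e-3)
  }
})

test_that("per-capita rate estimators are unbiased over many positions", {
  conds <- list(d3 = list(group = "ACT+mAb", params = act_mab_params(3),
                          transfer_day = 3))
  des <- cohort_design(n_mice = 1, imaging_days = 6, positions_per_day = 500,
                       seed = 31)
  coh <- generate_cohort(conds, des)
  pts <- intravital_rates(coh$positions)
  p <- act_mab_params(3)
  kill <- pts$value[pts$kind == "killing"]
  se <- sd(kill) / sqrt(length(kill))
  expect_lt(abs(mean(kill) - p$k_e), 3 * se)

  st <- simulate_model(p, t_grid = c(0, 3, 6))
  R6 <- st$R[st$time == 6]
  apo <- pts$value[pts$kind == "ctl_apoptosis"]
  se_a <- sd(apo) / sqrt(length(apo))
  expect_lt(abs(mean(apo) - R6), 3 * se_a)
})

test_that("cohorts round-trip through the delimited-text format", {
  coh <- generate_cohort(default_conditions(transfer_days = 3),
                         cohort_design(n_mice = 2, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$volumes), as.data.frame(coh$volumes))
  expect_equal(as.data.frame(back$positions), as.data.frame(coh$positions))
})
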