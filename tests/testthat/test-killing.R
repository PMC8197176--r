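test_that("closed-form Poisson MLEs match hand calculations", {
  # 2 kills over 5*2 + 10*1 = 20 CTL-hours -> 0.1 h^-1 = 2.4 per CTL-day
  pos <- make_positions(duration = c(2, 1), n_ctl = c(5, 10), n_tc = 100,
                        tc_apoptosis = c(1, 1))
  fit <- fit_poisson_linear(pos)
  expect_equal(unname(fit$rates), 2.4)
  expect_equal(fit$n_params, 1L)
  expect_equal(fit$aic, 2 - 2 * fit$log_lik)
  expect_equal(fit$bic, log(2) - 2 * fit$log_lik)

  # mass action: 4 kills / (2 * 100 * 1 h) = 0.02 per CTL-TC-hour
  pos2 <- make_positions(duration = 1, n_ctl = 2, n_tc = 100, tc_apoptosis = 4)
  fit2 <- fit_poisson_massaction(pos2)
  expect_equal(unname(fit2$rates), 0.02 * 24)

  # zero kills everywhere -> zero rate
  expect_equal(unname(fit_poisson_linear(make_positions())$rates), 0)

  # shared n_tc = c: mass-action rate is the linear rate / c
  pos3 <- make_positions(duration = c(1, 2, 3), n_ctl = c(2, 5, 9), n_tc = 80,
                         tc_apoptosis = c(1, 0, 2))
  expect_equal(unname(fit_poisson_massaction(pos3)$rates),
               unname(fit_poisson_linear(pos3)$rates) / 80)

  expect_error(fit_poisson_linear(make_positions(n_ctl = 0)), "zero")
})

test_that("closed forms agree with numerical likelihood maximisation", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pos <- make_positions(
      day = 6, duration = runif(n, 1, 3), n_ctl = sample(1:20, n, TRUE),
      n_tc = sample(20:200, n, TRUE), tc_apoptosis = rpois(n, 1.5)
    )
    for (fitter in list(fit_poisson_linear, fit_poisson_massaction)) {
      fit <- fitter(pos)
      lam <- unname(fit$rates)
      expo <- if (fit$model == "linear") {
        pos$n_ctl * pos$duration / 24
      } else {
        pos$n_ctl * pos$n_tc * pos$duration / 24
      }
      if (sum(pos$tc_apoptosis) == 0) {
        expect_equal(lam, 0)
      } else {
        num <- numeric_poisson_mle(pos$tc_apoptosis, expo)
        expect_lt(abs(lam - num) / max(1, lam), 1e-8)
      }
    }
  }
})

test_that("model comparison ranks by information criteria and checks data", {
  set.seed(43)
  n <- 40
  pos <- make_positions(
    day = 6, duration = runif(n, 1, 3), n_ctl = sample(1:20, n, TRUE),
    n_tc = sample(20:200, n, TRUE), tc_apoptosis = rpois(n, 1),
    group = rep(c("ACT-only", "ACT+mAb"), each = n / 2)
  )
  fits <- list(fit_poisson_linear(pos), fit_poisson_linear(pos, "per-treatment"),
               fit_poisson_massaction(pos))
  tab <- compare_models(fits)
  expect_equal(nrow(tab), 3L)
  expect_true(!is.unsorted(tab$aic))
  expect_equal(min(tab$delta_aic), 0)
  expect_equal(fits[[2]]$n_params, 2L)
  # nested models: the 2-rate fit can only improve the likelihood
  expect_gte(fits[[2]]$log_lik, fits[[1]]$log_lik - 1e-10)

  # equal log-likelihoods: fewer parameters must rank first
  f1 <- fits[[1]]; f2 <- fits[[1]]
  f2$n_params <- 2L
  f2$aic <- 2 * 2 - 2 * f2$log_lik
  f2$bic <- 2 * log(f2$n_obs) - 2 * f2$log_lik
  tab2 <- compare_models(list(f2, f1))
  expect_equal(tab2$n_params[1], 1L)

  other <- make_positions(tc_apoptosis = 5)
  expect_error(compare_models(list(fits[[1]], fit_poisson_linear(other))),
               "same observations")
})

test_that("pooled fit is preferred by BIC when one rate generated the data", {
  set.seed(47)
  wins <- 0
  for (r in 1:20) {
    n <- 60
    pos <- make_positions(
      day = 6, duration = runif(n, 1, 3), n_ctl = sample(1:20, n, TRUE),
      n_tc = 100, group = rep(c("ACT-only", "ACT+mAb"), each = n / 2)
    )
    pos$tc_apoptosis <- rpois(n, 0.44 * pos$n_ctl * pos$duration / 24)
    pooled <- fit_poisson_linear(pos)
    split <- fit_poisson_linear(pos, "per-treatment")
    if (pooled$bic < split$bic) wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("Poisson band uses exact inverse-CDF quantiles", {
  b0 <- poisson_band(0:10, rate = 0)
  expect_true(all(b0$lower == 0 & b0$upper == 0 & b0$mean == 0))

  # mean 3: rate 3 day^-1 * 24 CTLs * 1 h / 24 = 3
  b <- poisson_band(24, rate = 3, duration = 1)
  expect_equal(b$mean, 3)
  # independent oracle: smallest k with sum of pmf >= q
  cdf <- cumsum(dpois(0:50, 3))
  expect_equal(b$lower, which(cdf >= 0.05)[1] - 1)  # 1
  expect_equal(b$upper, which(cdf >= 0.95)[1] - 1)  # 6
  expect_equal(c(b$lower, b$upper), c(1, 6))

  # central line is linear in the CTL count
  b2 <- poisson_band(c(5, 10), rate = 0.44, duration = 2)
  expect_equal(b2$mean[2], 2 * b2$mean[1])
})
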