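test_that("derivatives reproduce closed-form rates", {
  # no CTLs: pure exponential growth of the proliferating compartment
  d <- model_derivatives(c(T_p = 1200, T_q = 0, E = 0, I = 0, R = 0),
                         ctl_params(g = 0.5, k_e = 2, k_q = 7), t = 0)
  expect_equal(unname(d), c(600, 0, 0, 0, 0))

  # infiltration flux across the boundary: s * T^(2/3)
  p <- ctl_params(g = 0.5, s = 0.7, transfer_day = 3)
  d <- model_derivatives(c(T_p = 1000, T_q = 0, E = 0, I = 0, R = 0), p, t = 5)
  expect_equal(unname(d[["E"]]), 0.7 * 1000^(2 / 3))  # = 70
  # before the transfer day the same term is switched off
  d0 <- model_derivatives(c(T_p = 1000, T_q = 0, E = 0, I = 0, R = 0), p, t = 2)
  expect_equal(unname(d0[["E"]]), 0)

  # quiescence exchange cancels from the total: d(T)/dt = g T_p - k_e E
  p2 <- ctl_params(g = 0.5, k_e = 0.5, k_q = 12.3, d_q = 0.7)
  d2 <- model_derivatives(c(T_p = 600, T_q = 400, E = 10, I = 0, R = 0), p2)
  expect_equal(unname(d2[["T_p"]] + d2[["T_q"]]), 0.5 * 600 - 0.5 * 10)  # 295
})

test_that("derivatives reject invalid states", {
  p <- ctl_params()
  expect_error(model_derivatives(c(-1, 0, 0, 0, 0), p), "non-negative")
  expect_error(model_derivatives(c(1, 2, 3), p), "state")
})

test_that("quiescence exchange conserves tumour cells across the search box", {
  set.seed(11)
  for (i in 1:200) {
    p <- ctl_params(g = runif(1, 0, 2), s = runif(1, 0, 5),
                    k_e = runif(1, 0, 50), k_i = runif(1, 0, 50),
                    d_i = runif(1, 0, 50), k_r = runif(1, 0, 50),
                    k_q = runif(1, 0, 50), d_q = runif(1, 0, 50))
    st <- c(T_p = runif(1, 1, 1e5), T_q = runif(1, 0, 1e5),
            E = runif(1, 0, 1e4), I = runif(1, 0, 20), R = runif(1, 0, 20))
    d <- model_derivatives(st, p, t = 10)
    lhs <- d[["T_p"]] + d[["T_q"]]
    rhs <- p$g * st[["T_p"]] - p$k_e * st[["E"]]
    scale <- max(1, abs(d[["T_p"]]), abs(d[["T_q"]]))
    expect_lt(abs(lhs - rhs) / scale, 1e-10)
  }
})

test_that("without CTLs the model is exactly exponential (doubling 1.4 d)", {
  tr <- simulate_model(untreated_params(g = 0.5), t_grid = 0:15,
                       rtol = 1e-12, atol = 1e-12)
  slope <- (log(tr$T[16]) - log(tr$T[1])) / 15
  expect_lt(abs(slope - 0.5), 1e-9)
  # log T affine in t throughout
  expect_lt(max(abs(log(tr$T) - (log(1200) + 0.5 * tr$time))), 1e-8)
  expect_equal(round(log(2) / slope, 1), 1.4)
})

test_that("constant-CTL killing limit matches its closed form", {
  # k_q = s = k_i = k_r = 0: E stays at E0 and
  # T(t) = (T0 - k_e E0 / g) e^(g t) + k_e E0 / g
  g <- 0.5; k_e <- 0.5; E0 <- 100; T0 <- 1200
  p <- ctl_params(g = g, k_e = k_e, transfer_day = Inf)
  init <- c(T_p = T0, T_q = 0, E = E0, I = 0, R = 0)
  tr <- simulate_model(p, init = init, t_grid = seq(0, 10, by = 0.5))
  expect_lt(max(abs(tr$E - E0)), 1e-6 * E0)
  closed <- (T0 - k_e * E0 / g) * exp(g * tr$time) + k_e * E0 / g
  expect_lt(max(rel_err(tr$T, closed)), 1e-6)
})

test_that("solutions self-converge under refined tolerances and grid", {
  p <- act_mab_params(3)
  coarse <- simulate_model(p, t_grid = seq(0, 15, by = 0.5))
  fine <- simulate_model(p, t_grid = seq(0, 15, by = 0.05),
                         rtol = 5e-9, atol = 5e-9)
  idx <- match(coarse$time, fine$time)
  for (col in c("T_p", "T_q", "E", "I", "R")) {
    ref <- fine[[col]][idx]
    expect_lt(max(abs(coarse[[col]] - ref) / pmax(abs(ref), 1e-3)), 1e-4)
  }
})

test_that("infiltration activates exactly at the transfer day", {
  p <- act_only_params(transfer_day = 3)
  tr <- simulate_model(p, t_grid = c(0, 1, 2, 3, 3.5, 6))
  expect_true(all(tr$E[tr$time <= 3] == 0))
  expect_true(all(tr$E[tr$time > 3] > 0))
  # a single-point grid returns the initial state only
  tr0 <- simulate_model(p, t_grid = 0)
  expect_equal(nrow(tr0), 1L)
  expect_equal(tr0$T_p, 1200)
})

test_that("trajectories stay non-negative across sampled parameter space", {
  set.seed(23)
  n_ok <- 0
  for (i in 1:30) {
    p <- ctl_params(g = 0.5, s = runif(1, 0, 5), k_e = runif(1, 0, 50),
                    k_i = runif(1, 0, 50), d_i = runif(1, 0, 50),
                    k_r = runif(1, 0, 50), k_q = runif(1, 0, 50),
                    d_q = runif(1, 0, 50), transfer_day = 3)
    tr <- tryCatch(
      suppressWarnings(simulate_model(p, t_grid = seq(0, 15, by = 0.5))),
      error = function(e) NULL
    )
    if (is.null(tr)) next  # unintegrable corner of the box
    n_ok <- n_ok + 1
    expect_true(all(tr$T_p >= 0 & tr$T_q >= 0 & tr$E >= 0 &
                      tr$I >= 0 & tr$R >= 0))
  }
  expect_gte(n_ok, 15)
})
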