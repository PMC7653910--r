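test_that("recovered-vs-susceptible closed form matches its special values and the ODE", {
  p <- fig_sir()
  expect_equal(sir_recovered(p$s0, p), 0)
  expect_equal(sir_recovered(p$s0 / exp(1), p), 0.5)
  expect_error(sir_recovered(-0.1, p), class = "seirshape_error_domain")
  expect_error(sir_recovered(p$s0 + 0.01, p), class = "seirshape_error_domain")

  traj <- integrate_sir(p, integrator_control(stop_after_decline = FALSE, t_max = 30))
  k <- nrow(traj)
  expect_equal(sir_recovered(traj$s[k], p), traj$r[k], tolerance = 1e-8)
})

test_that("infectious-vs-susceptible closed form peaks at s = 1/r0 and matches the ODE peak", {
  p <- fig_sir()
  expect_equal(sir_infectious(p$s0, p), p$i0)
  # the maximiser over s is 1/r0
  s_pk <- 1 / p$r0
  eps <- 1e-6
  expect_gt(sir_infectious(s_pk, p), sir_infectious(s_pk + eps, p))
  expect_gt(sir_infectious(s_pk, p), sir_infectious(s_pk - eps, p))

  traj <- integrate_sir(p)
  expect_lt(abs(sir_infectious(s_pk, p) - find_peak(traj)$peak_value), 1e-6)
  # conservation of the closed forms: i = 1 - s - r identically
  sg <- seq(0.3, p$s0, length.out = 25)
  expect_equal(sir_infectious(sg, p) + sir_recovered(sg, p) + sg,
               rep(1, 25), tolerance = 1e-12)
})

test_that("semi-analytic time integral matches ODE event times and is monotone", {
  p <- fig_sir()
  expect_equal(sir_time(p$s0, p)$time, 0)
  tt <- sir_time(c(0.5, 0.4), p)
  expect_gt(tt$time[2], tt$time[1])

  # independent event detection on the ODE system: time at which s crosses 0.5
  sol <- deSolve::lsodar(
    c(s = p$s0, i = p$i0, r = 0), seq(0, 100, 0.5),
    function(t, y, q) list(c(-q$beta * y[2] * y[1],
                             q$beta * y[2] * y[1] - q$gamma * y[2],
                             q$gamma * y[2])),
    p, rtol = 1e-12, atol = 1e-14,
    rootfunc = function(t, y, q) y[1] - 0.5)
  t_cross <- attr(sol, "troot")
  expect_equal(tt$time[1], t_cross, tolerance = 1e-5)
})

test_that("peak summary matches the ODE argmax, and a larger seed peaks earlier", {
  p <- fig_sir()
  pk <- sir_peak(p)
  ode_pk <- find_peak(integrate_sir(p))
  expect_equal(pk$delta_t, ode_pk$delta_t, tolerance = 1e-4)
  expect_equal(pk$scaled_delta_t, p$gamma * pk$delta_t)
  expect_gte(pk$peak_value, p$i0)

  pk_big_seed <- sir_peak(fig_sir(i0 = 1e-2))
  expect_lt(pk_big_seed$delta_t, pk$delta_t)

  # gamma * delta_t depends only on r0 and i0: gamma factors out
  p2 <- epi_params(r0 = 2, gamma = 0.25, i0 = 1e-4)
  expect_equal(sir_peak(p2)$scaled_delta_t, pk$scaled_delta_t, tolerance = 1e-9)

  # subcritical: no interior peak convention
  sub <- epi_params(r0 = 0.8, gamma = 0.5, i0 = 1e-4)
  pk_sub <- sir_peak(sub)
  expect_equal(pk_sub$delta_t, 0)
  expect_equal(pk_sub$peak_value, sub$i0)
})

test_that("idealised i0-free peak integrand is exposed as an approximation flag", {
  p <- fig_sir()
  pk <- sir_peak(p)
  pk0 <- sir_peak(p, drop_i0 = TRUE)
  # same order of magnitude, but not the quantitative peak time
  expect_gt(pk0$delta_t, 0)
  expect_equal(pk0$scaled_delta_t, pk$scaled_delta_t, tolerance = 0.2)
})

test_that("early-time closed form tracks the ODE while the outbreak is small", {
  p <- fig_sir()
  early <- sir_early(0, p)
  expect_equal(early$s, p$s0, tolerance = 10 * p$i0)

  # by construction the closed form is a pure exponential mode: once the
  # outbreak term dominates, s decays at exactly the growth rate lambda
  ts <- seq(40, 60, 2)
  slopes <- diff(log(sir_early(ts, p)$s)) / diff(ts)
  expect_equal(slopes, rep(-sir_growth_rate(p), length(slopes)),
               tolerance = 1e-4)

  traj <- integrate_sir(p)
  k <- which(traj$i >= 1e-2)[1]
  idx <- seq_len(k - 1)
  pred <- sir_early(traj$time[idx], p)
  expect_lt(max(abs(pred$i - traj$i[idx])), tol$early_i)
})

test_that("growth-rate relation and its inverse are consistent", {
  expect_equal(sir_growth_rate(fig_sir()), 0.5)
  expect_equal(sir_growth_rate(epi_params(1, 0.5, i0 = 1e-4)), 0)
  expect_equal(sir_growth_rate(epi_params(3, 0.25, i0 = 1e-4)), 0.5)
  expect_equal(r0_from_growth(0.5, 2), 2)
  expect_equal(r0_from_growth(0, 3), 1)
  p <- epi_params(3.7, 0.41, i0 = 1e-4)
  expect_equal(r0_from_growth(sir_growth_rate(p), p$d_inf), p$r0,
               tolerance = 1e-14)
})

test_that("SIR reconstruction is exact up to numerics and conserves mass", {
  p <- fig_sir()
  err <- semianalytic_error(p, n = 300)
  expect_lt(max(err$sup_abs_err), 1e-6)

  traj <- semianalytic_trajectory(p, n = 150)
  expect_lt(max(abs(traj$s + traj$e + traj$i + traj$r - 1)), 1e-9)
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(diff(traj$s) < 0))
})

test_that("reconstruction on an explicit time grid inverts t(s) accurately", {
  p <- fig_sir()
  target <- sir_time(c(0.9, 0.6, 0.5), p)
  traj <- semianalytic_trajectory(p, times = c(0, target$time))
  expect_equal(traj$s, c(p$s0, 0.9, 0.6, 0.5), tolerance = 1e-9)
})

test_that("final size solves the outbreak-size relation and matches the long-time ODE", {
  p <- fig_sir()
  s_inf <- final_size(p)
  # the relation itself
  expect_equal(1 - s_inf, log(p$s0 / s_inf) / p$r0, tolerance = 1e-12)
  traj <- integrate_sir(p, integrator_control(stop_after_decline = FALSE))
  expect_equal(traj$s[nrow(traj)], s_inf, tolerance = 1e-6)
})
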