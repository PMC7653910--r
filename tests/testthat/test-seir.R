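test_that("exposed/infectious closed forms hit their boundary values and conserve mass", {
  p <- fig_seir()
  expect_equal(seir_exposed(p$s0, p), p$e0)
  expect_equal(seir_infectious(p$s0, p), p$i0)
  pe <- fig_seir(e0 = 0.01)
  expect_equal(seir_exposed(pe$s0, pe), 0.01)

  sg <- seq(0.25, p$s0, length.out = 40)
  expect_equal(sg + seir_exposed(sg, p) + seir_infectious(sg, p) +
                 seir_recovered(sg, p), rep(1, 40), tolerance = 1e-12)

  # stationarity of the infectious profile at s = 1/r0
  eps <- 1e-6
  expect_gt(seir_infectious(1 / p$r0, p), seir_infectious(1 / p$r0 + eps, p))
  expect_gt(seir_infectious(1 / p$r0, p), seir_infectious(1 / p$r0 - eps, p))
})

test_that("with the SIR sentinel every profile reduces exactly to the SIR formulas", {
  p <- fig_sir()
  sg <- seq(0.25, p$s0, length.out = 20)
  expect_identical(seir_recovered(sg, p), sir_recovered(sg, p))
  expect_equal(seir_infectious(sg, p), sir_infectious(sg, p), tolerance = 1e-15)
  expect_equal(seir_exposed(sg, p), rep(0, 20), tolerance = 1e-15)
  expect_equal(seir_time(0.6, p)$time, sir_time(0.6, p)$time, tolerance = 1e-10)
})

test_that("profiles against s track the ODE within the frozen approximation bound", {
  for (prm in list(fig_seir(0.5, 0.5), fig_seir(0.5, 0.2, r0 = 7))) {
    traj <- integrate_seir(prm)
    expect_lt(max(abs(seir_exposed(traj$s, prm) - traj$e)), tol$profile_s)
    expect_lt(max(abs(seir_infectious(traj$s, prm) - traj$i)), tol$profile_s)
  }
})

test_that("time integral tracks ODE event times within the frozen approximation bound", {
  p <- fig_seir()
  traj <- integrate_seir(p)
  # monotone interpolant of t as a function of s on the pre-final-size branch
  t_of_s <- stats::splinefun(rev(traj$s), rev(traj$time))
  sg <- seq(1 / p$r0, 0.99 * p$s0, length.out = 25)
  t_semi <- seir_time(sg, p)$time
  expect_lt(max(abs(t_semi - t_of_s(sg)) / t_of_s(sg)), tol$time_rel)
})

test_that("scaled peak time is unit-free and within the frozen bound of the ODE peak", {
  p <- fig_seir()
  pk <- seir_peak(p)
  expect_equal(pk$scaled_delta_t, p$alpha * p$gamma * pk$delta_t)

  # pure change of time units leaves alpha*gamma*dt unchanged
  pk_slow <- seir_peak(fig_seir(0.2, 0.2))
  expect_equal(pk_slow$scaled_delta_t, pk$scaled_delta_t, tolerance = 1e-9)

  # sentinel equals the SIR peak exactly
  expect_equal(seir_peak(fig_sir()), sir_peak(fig_sir()), tolerance = 1e-12)

  p34 <- fig_seir(sigma = 1 / 3, gamma = 1 / 4)
  ode_pk <- find_peak(integrate_seir(p34))
  expect_lt(abs(seir_peak(p34)$delta_t - ode_pk$delta_t) / ode_pk$delta_t,
            tol$peak_rel)
})

test_that("early-time closed form reduces to SIR and respects its seed asymptotics", {
  p <- fig_sir()
  ts <- seq(0, 8, 0.5)
  expect_equal(seir_early(ts, p), sir_early(ts, p), tolerance = 1e-14)

  # self-consistency at t0: i(0) stays within O(i0) of the seed (here the
  # leading-order terms cancel, so the gap is far below i0 itself), and s(0)
  # within O(i0) of s0, for a shrinking seed
  for (i0 in c(1e-3, 1e-4, 1e-5)) {
    q <- fig_seir(i0 = i0)
    e0t <- seir_early(0, q)
    expect_lt(abs(e0t$i - i0), i0)
    expect_lt(abs(e0t$s - q$s0), 10 * i0)
  }
})

test_that("fitted early growth of the ODE favours the exact relation over the approximate one", {
  p <- fig_seir(i0 = 1e-6)
  traj <- integrate_seir(p)
  k_pk <- which.max(traj$i)
  w <- which(traj$i > 10 * p$i0 & traj$i < 1e3 * p$i0)
  w <- w[w < k_pk]
  fit <- unname(coef(lm(log(i) ~ time, data = traj[w, ]))[2])
  lam_exact <- seir_growth_rate_exact(p)
  lam_approx <- seir_growth_rate(p)
  expect_equal(fit, lam_exact, tolerance = 0.02)
  expect_lt(abs(fit - lam_exact), abs(fit - lam_approx))
})

test_that("growth-rate relations obey their arithmetic, reductions and round trips", {
  # alpha = 0.5, r0 = 2, s0 ~ 1: lambda ~ 0.25/d
  expect_equal(seir_growth_rate(fig_seir()), with(fig_seir(), gamma * r0 * (i0 + alpha * s0) - alpha * gamma))
  expect_equal(seir_growth_rate(fig_sir()), sir_growth_rate(fig_sir()))
  # seir growth is ~1/alpha slower than sir at the same gamma
  expect_equal(seir_growth_rate(fig_seir()) / sir_growth_rate(fig_sir()),
               0.5, tolerance = 1e-3)

  expect_equal(r0_from_growth_approx(0.25, 2, 2, s0 = 1, i0 = 0), 2)
  expect_equal(r0_from_growth_approx(0.5, 2, 0, s0 = 1, i0 = 0),
               r0_from_growth(0.5, 2))
  expect_equal(r0_from_growth_exact(0.25, 2, 2), 2.25)
  expect_equal(r0_from_growth_exact(0.4, 2, 0), r0_from_growth(0.4, 2))

  withr::with_seed(5, {
    r0s <- runif(20, 1.2, 8); dinc <- runif(20, 1, 6); dinf <- runif(20, 1, 6)
  })
  for (k in 1:20) {
    pk <- epi_params(r0s[k], 1 / dinf[k], 1 / dinc[k], i0 = 1e-4)
    lam <- seir_growth_rate(pk)
    expect_equal(r0_from_growth_approx(lam, pk$d_inf, pk$d_inc,
                                       s0 = pk$s0, i0 = pk$i0),
                 pk$r0, tolerance = 1e-12)
    # the approximate relation lacks exactly the lambda^2 d' d term
    lam0 <- runif(1, 0.05, 0.6)
    expect_equal(r0_from_growth_exact(lam0, dinf[k], dinc[k]) -
                   r0_from_growth_approx(lam0, dinf[k], dinc[k]),
                 lam0^2 * dinf[k] * dinc[k], tolerance = 1e-12)
    # exact growth rate inverts the exact relation
    expect_equal(r0_from_growth_exact(seir_growth_rate_exact(pk),
                                      pk$d_inf, pk$d_inc),
                 pk$r0, tolerance = 1e-10)
  }
})

test_that("the approximation degrades as the exposed stage lengthens", {
  sup_err <- vapply(c(0.5, 0.9), function(a) {
    gam <- 0.5
    p <- fig_seir(sigma = a * gam / (1 - a), gamma = gam)
    err <- semianalytic_error(p, n = 150)
    err$sup_abs_err[err$compartment == "i"]
  }, numeric(1))
  expect_gt(sup_err[1], sup_err[2])
})
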