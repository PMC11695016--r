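p_test <- list(f_max_iso = 1500, l_opt = 0.1, l_ts = 0.16,
               alpha_opt = deg2rad(8), v_max = 10)

test_that("Hill equilibrium holds in the slack and isometric limits", {
  l0 <- p_test$l_opt * cos(p_test$alpha_opt) + p_test$l_ts
  # passive-free slack state: zero activation, zero force, nominal length
  expect_lt(abs(hill_equilibrium_residual(0, 0, 0, l0, 0, p_test)), 1e-6)
  # isometric maximum: fiber at optimal length, equilibrium force is
  # f_max_iso * cos(alpha_opt)
  ft_iso <- cos(p_test$alpha_opt)
  hc <- predgait:::hill_constants()
  l_iso <- p_test$l_ts * (1 + log(ft_iso / hc$cT + 1) / hc$kT) +
    p_test$l_opt * cos(p_test$alpha_opt)
  expect_lt(abs(hill_equilibrium_residual(1, ft_iso, 0, l_iso, 0, p_test)),
            1e-6)
})

test_that("static equilibrium force matches the bisection oracle and is unique", {
  for (a in c(0.1, 0.5, 0.9)) {
    for (stretch in c(0.99, 1.0, 1.02)) {
      l_mt <- (p_test$l_opt * cos(p_test$alpha_opt) + p_test$l_ts) * stretch
      ft_o <- oracle_hill_bisect(a, l_mt, p_test)
      expect_lt(abs(hill_equilibrium_residual(a, ft_o, 0, l_mt, 0, p_test)),
                1e-10)
      ft_p <- muscle_equilibrium_ftilde(a, l_mt, 0, p_test)
      expect_equal(ft_p, ft_o, tolerance = 1e-8)
      # residual brackets a single sign change: positive below, negative above
      expect_gt(hill_equilibrium_residual(a, max(ft_o - 0.05, 0), 0,
                                          l_mt, 0, p_test), 0)
      expect_lt(hill_equilibrium_residual(a, ft_o + 0.05, 0, l_mt, 0, p_test),
                0)
    }
  }
})

test_that("activation dynamics reproduce the first-order closed form", {
  # equilibrium: excitation equals activation
  expect_equal(activation_rate(0.4, 0.4), 0)
  expect_equal(activation_dynamics_residual(0.4, 0.4, 0), 0)
  # step-response limit at a = 0 with e = 1
  expect_equal(activation_rate(1, 0, tau_act = 0.015), 1 / 0.015,
               tolerance = 0.02)
  # with equal time constants the rate blend is exactly constant, so the
  # integrated response is the closed-form exponential
  tau <- 0.05
  g <- collocation_grid(40, 3, 0, 0.2)
  r <- radau_integrate(function(x, t) activation_rate(1, x, tau, tau), 0, g)
  expect_equal(r$x_f, 1 - exp(-0.2 / tau), tolerance = 1e-6)
})

test_that("MPK activation follows its first-order lag", {
  expect_equal(mpk_activation_residual(0.5, 0.5, 0), 0)
  g <- collocation_grid(30, 3, 0, 0.1)
  r <- radau_integrate(function(x, t) (1 - x) / 0.030, 0, g)
  expect_equal(r$x_f, 1 - exp(-0.1 / 0.030), tolerance = 1e-8)
  # infinite time constant freezes the activation
  expect_equal(mpk_activation_residual(1, 0.2, 0, tau_mpk = Inf), 0)
})

test_that("metabolic rate is nonnegative and strictly increasing in activation", {
  mp <- metabolic_model_params()
  e0 <- metabolic_rate(0, 1, 0, 0, p_test, mp)
  expect_gte(e0, 0)
  expect_lt(e0, 5)  # near-zero floor at rest
  lfN <- 1.05; lfd <- -0.02
  a <- seq(0.1, 1, by = 0.1)
  ft <- muscle_equilibrium_ftilde(a, p_test$l_opt * cos(p_test$alpha_opt) +
                                    p_test$l_ts, 0, p_test)
  ed <- metabolic_rate(a, lfN, lfd, ft * p_test$f_max_iso, p_test, mp)
  expect_true(all(diff(ed) > 0))
})
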