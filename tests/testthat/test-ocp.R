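# Estimation OCP and prediction bookkeeping.  The full gait predictions are
# exercised in test-acceptance.R; here the cheaper problems and the
# reporting invariants are covered.

am_est <- build_amputee_model(68.5, 1.78)

test_that("estimation reproduces an exactly achievable dataset", {
  ds <- generate_estimation_dataset(am_est, seed = 7)
  es <- estimation_problem_spec(ds, n_mesh = 12,
                                solver = list(max_outer = 12, max_inner = 20,
                                              time_limit = 60))
  est <- estimate_parameters(am_est, es)
  # moments generated by the generic model itself: reserves stay small and
  # the moment is reproduced
  expect_lt(est$reserve_rms, 1)
  expect_lt(est$moment_rms, 0.5)
  # all personalized multipliers within the 50%-200% bounds
  pars <- as.matrix(est$parameters[, c("f_max_ratio", "l_opt_ratio",
                                       "l_ts_ratio")])
  expect_true(all(pars >= 0.5 - 1e-9 & pars <= 2 + 1e-9))
  expect_true(all(est$activations >= 1e-4 - 1e-9 & est$activations <= 1))
})

test_that("personalization beats the generic fit on perturbed-truth data", {
  ds <- generate_estimation_dataset(am_est, list(iliopsoas_il = 1.5),
                                    seed = 3)
  es <- estimation_problem_spec(ds, n_mesh = 12,
                                solver = list(max_outer = 12, max_inner = 20,
                                              time_limit = 60))
  est_free <- estimate_parameters(am_est, es)
  est_gen <- estimate_parameters(am_est, es, fix_params = TRUE)
  # the estimation objective (fit error) improves over the generic model
  expect_lt(est_free$objective, est_gen$objective)
  # the perturbed muscle moves toward its known stronger truth
  r_il <- est_free$parameters$f_max_ratio[
    est_free$parameters$muscle == "iliopsoas_il"]
  expect_gt(r_il, 1.2)
  expect_lte(r_il, 2 + 1e-9)
})

test_that("objective breakdown terms add up and scale with their weights", {
  # small synthetic prediction result assembled directly from a guess
  ps <- prediction_problem_spec(n_mesh = 3, solver = list())
  nlp <- predgait:::build_prediction_nlp(am_est, ps)
  up <- nlp$unpack(nlp$z0)
  terms <- predgait:::prediction_objective_terms(nlp, up, ps$weights)
  expect_equal(unname(terms["total"]),
               unname(sum(terms[setdiff(names(terms), "total")])),
               tolerance = 1e-12)
  res <- structure(list(objective_terms = terms, weights = ps$weights),
                   class = "prediction_result")
  bd <- objective_breakdown(res)
  expect_equal(bd$value[bd$term == "total"],
               sum(bd$value[bd$term != "total"]), tolerance = 1e-12)
  # doubling one weight on the fixed trajectory doubles exactly that term
  w2 <- ps$weights; w2$w_p1 <- 2 * w2$w_p1
  bd2 <- objective_breakdown(res, weights = w2)
  expect_equal(bd2$value[bd2$term == "activation"],
               2 * bd$value[bd$term == "activation"], tolerance = 1e-12)
  expect_equal(bd2$value[bd2$term == "acceleration"],
               bd$value[bd$term == "acceleration"], tolerance = 1e-12)
  # only one nonzero weight: the total equals that term
  w3 <- objective_weights(w_p1 = 0, w_p2 = 0, w_p3 = ps$weights$w_p3,
                          w_p4 = 0, w_p5 = 0)
  terms3 <- predgait:::prediction_objective_terms(nlp, up, w3)
  expect_equal(unname(terms3["total"]), unname(terms3["acceleration"]),
               tolerance = 1e-12)
})

test_that("initial guesses respect joint bounds and reuse prior solutions", {
  ps <- prediction_problem_spec(n_mesh = 4)
  g <- make_initial_guess(am_est, ps)
  expect_true(all(g$Q[, "knee_il"] > deg2rad(-12)))
  expect_true(all(g$Q[, "knee_il"] < deg2rad(150)))
  expect_true(all(g$A >= 1e-4 & g$A <= 1))
  expect_true(all(is.finite(g$FT)))
  # a stiff-knee model saturates the guess below the limit
  skg <- apply_skg_condition(am_est, 14.9)
  gs <- make_initial_guess(skg, ps)
  expect_lt(max(gs$Q[, "knee_il"]), deg2rad(14.9))
  # prior-solution reuse requires the matching grid
  fake <- structure(list(z_scaled = rep(0, 10), n_mesh = 4, degree = 3,
                         state_dims_signature = c(99, 1), T = 1),
                    class = "prediction_result")
  expect_error(make_initial_guess(am_est,
    prediction_problem_spec(n_mesh = 4, initial_guess = fake)),
    "same model/grid")
})
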