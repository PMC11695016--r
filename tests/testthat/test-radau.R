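test_that("Radau collocation integrates classic test equations", {
  # dx/dt = -x over [0, 1]: endpoint within 1e-6 of exp(-1) on 10 intervals
  g <- collocation_grid(10, 3, 0, 1)
  r <- radau_integrate(function(x, t) -x, 1, g)
  expect_lt(abs(r$x_f - exp(-1)), 1e-6)
  # polynomial exactness: dx/dt = 3 t^2 over one interval gives x(1) = 1
  r2 <- radau_integrate(function(x, t) 3 * t^2, 0, collocation_grid(1, 3))
  expect_lt(abs(r2$x_f - 1), 1e-12)
  # dx/dt = 0 keeps the state constant at every mesh point
  r3 <- radau_integrate(function(x, t) 0 * x, c(2, -1), collocation_grid(5, 3))
  expect_true(all(abs(sweep(r3$x_mesh, 2, c(2, -1))) < 1e-14))
})

test_that("transcription order: halving the mesh gains at least 2^4", {
  err <- function(n) abs(radau_integrate(function(x, t) -x, 1,
                                         collocation_grid(n, 3))$x_f - exp(-1))
  expect_gte(err(4) / err(8), 2^4)
})

test_that("the NLP transcription agrees with the closed-form solution", {
  tr <- transcribe_radau(function(x, t) -x, collocation_grid(10, 3, 0, 1), 1)
  sol <- solve_nlp_sqp(tr$prob, tr$guess,
                       list(feas_tol = 1e-10, opt_tol = 1, max_iter = 50))
  X <- tr$extract(sol$z)
  expect_equal(sol$status, "converged")
  expect_lt(abs(X[nrow(X), 1] - exp(-1)), 1e-6)
})

test_that("the SQP and AL solvers reach a known constrained optimum", {
  # min (x-2)^2 + (y-1)^2  s.t.  x + y = 1, solution (1, 0)
  prob <- list(
    n = 2,
    fval = function(z) (z[1] - 2)^2 + (z[2] - 1)^2,
    grad_jac = function(z) list(
      grad = c(2 * (z[1] - 2), 2 * (z[2] - 1)),
      J = Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(1, 1),
                               dims = c(1, 2))),
    cons = function(z) sum(z) - 1,
    hess_diag = function(z) c(2, 2),
    lb = c(-10, -10), ub = c(10, 10))
  s1 <- solve_nlp_sqp(prob, c(0, 0), list(feas_tol = 1e-10, opt_tol = 1e-8))
  expect_equal(s1$z, c(1, 0), tolerance = 1e-6)
  s2 <- solve_nlp_al(prob, c(0, 0), list(feas_tol = 1e-9, opt_tol = 1e-8,
                                         max_outer = 40))
  expect_equal(s2$z, c(1, 0), tolerance = 1e-5)
  # with an active bound y >= 0.4 the optimum moves to (0.6, 0.4)
  prob$lb <- c(-10, 0.4)
  s3 <- solve_nlp_sqp(prob, c(0, 0.5), list(feas_tol = 1e-10, opt_tol = 1e-8))
  expect_equal(s3$z, c(0.6, 0.4), tolerance = 1e-6)
})
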