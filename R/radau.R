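# Third-order Radau IIA collocation primitives.
#
# On a mesh interval scaled to [0, 1] the state is represented by the
# degree-d Lagrange polynomial through the interval start (tau = 0) and the
# d Radau collocation nodes (which include the right endpoint tau = 1, so
# state continuity across intervals is automatic when the endpoint variable
# is shared).  The collocation equations enforce
#   sum_j D[k, j] * x_j = h * f(x_k, u_k)      k = 1..d
# where D is the derivative of the interpolating polynomial at node k.

#' Radau collocation scheme
#'
#' Returns the collocation nodes, differentiation matrix and quadrature
#' weights of the Radau IIA scheme of the requested degree.
#'
#' @param degree Number of collocation nodes per mesh interval (default 3,
#'   the third-order Radau scheme; the right endpoint is always a node).
#' @return A list with `tau` (nodes in (0, 1]), `D` (degree x (degree+1)
#'   differentiation matrix acting on the values at c(0, tau)), and `w`
#'   (quadrature weights for integrating over the interval using the values
#'   at the collocation nodes).
#' @export
radau_scheme <- function(degree = 3) {
  if (degree == 3) {
    tau <- c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1)
  } else if (degree == 2) {
    tau <- c(1 / 3, 1)
  } else if (degree == 1) {
    tau <- 1
  } else {
    stop("radau_scheme: degree must be 1, 2 or 3")
  }
  pts <- c(0, tau)
  d <- length(tau)
  # Lagrange basis through pts; D[k, j] = l_j'(tau_k)
  D <- matrix(0, d, d + 1)
  for (j in seq_len(d + 1)) {
    cf <- lagrange_coefs(pts, j)
    dcf <- polynomial_derivative(cf)
    D[, j] <- polynomial_eval(dcf, tau)
  }
  # quadrature weights over the d collocation nodes (Radau quadrature,
  # exact for polynomials of degree 2d - 2)
  w <- numeric(d)
  for (j in seq_len(d)) {
    cf <- lagrange_coefs(tau, j)
    icf <- polynomial_integral(cf)
    w[j] <- polynomial_eval(icf, 1) - polynomial_eval(icf, 0)
  }
  list(tau = tau, D = D, w = w, degree = d)
}

# polynomial helpers: coefficients in increasing powers
lagrange_coefs <- function(pts, j) {
  cf <- 1
  for (m in seq_along(pts)) {
    if (m == j) next
    # multiply by (x - pts[m]) / (pts[j] - pts[m])
    cf <- c(0, cf) - c(cf * pts[m], 0)
    cf <- cf / (pts[j] - pts[m])
  }
  cf
}

polynomial_eval <- function(cf, x) {
  out <- 0
  for (k in rev(seq_along(cf))) out <- out * x + cf[k]
  out
}

polynomial_derivative <- function(cf) {
  n <- length(cf)
  if (n == 1) return(0)
  cf[-1] * seq_len(n - 1)
}

polynomial_integral <- function(cf) {
  c(0, cf / seq_along(cf))
}

#' Build a collocation grid
#'
#' @param n_mesh Number of mesh intervals (>= 1).
#' @param degree Radau degree (default 3).
#' @param t_i,t_f Initial and final time in seconds. In gait prediction the
#'   final time is free; `t_f` then only sets the initial guess of the cycle
#'   time.
#' @return An object of class `collocation_grid`.
#' @export
collocation_grid <- function(n_mesh, degree = 3, t_i = 0, t_f = 1) {
  stopifnot_scalar(n_mesh, "n_mesh", positive = TRUE)
  if (n_mesh != round(n_mesh) || n_mesh < 1) stop("n_mesh must be a positive integer")
  if (t_f <= t_i) stop("t_f must be greater than t_i")
  structure(list(n_mesh = as.integer(n_mesh), degree = degree,
                 t_i = t_i, t_f = t_f, scheme = radau_scheme(degree)),
            class = "collocation_grid")
}

#' Integrate an ODE with Radau collocation
#'
#' Solves dx/dt = f(x, t) on a fixed grid by Newton iteration on the
#' collocation equations, interval by interval.  This is the same
#' transcription used inside the optimal-control problems; exposed directly
#' so its order of accuracy can be verified against closed-form solutions.
#'
#' @param f Right-hand side, `f(x, t)` with `x` a numeric vector.
#' @param x0 Initial state.
#' @param grid A `collocation_grid`.
#' @param tol Newton tolerance on the collocation residual.
#' @return A list with `t_mesh`, `x_mesh` (states at mesh points, one row per
#'   mesh point) and the final state `x_f`.
#' @export
radau_integrate <- function(f, x0, grid, tol = 1e-12) {
  sch <- grid$scheme
  d <- sch$degree
  n <- grid$n_mesh
  h <- (grid$t_f - grid$t_i) / n
  nx <- length(x0)
  x_mesh <- matrix(0, n + 1, nx)
  x_mesh[1, ] <- x0
  t_mesh <- grid$t_i + h * (0:n)
  for (i in seq_len(n)) {
    xk <- x_mesh[i, ]
    # unknowns: states at the d collocation nodes
    X <- matrix(rep(xk, d), d, nx, byrow = TRUE)
    tn <- t_mesh[i] + h * sch$tau
    eval_F <- function(Xm) {
      Fm <- matrix(0, d, nx)
      for (k in seq_len(d)) Fm[k, ] <- f(Xm[k, ], tn[k])
      Fm
    }
    for (iter in 1:50) {
      Fm <- eval_F(X)
      R <- sch$D[, 1] %o% xk + sch$D[, -1, drop = FALSE] %*% X - h * Fm
      if (max(abs(R)) < tol) break
      # Newton with finite-difference Jacobian on the (d * nx) unknowns
      J <- matrix(0, d * nx, d * nx)
      eps <- 1e-7
      for (k in seq_len(d)) for (s in seq_len(nx)) {
        Xp <- X; Xp[k, s] <- Xp[k, s] + eps
        Fp <- eval_F(Xp)
        Rp <- sch$D[, 1] %o% xk + sch$D[, -1, drop = FALSE] %*% Xp - h * Fp
        J[, (k - 1) * nx + s] <- as.vector(t(Rp - R)) / eps
      }
      dz <- solve(J, -as.vector(t(R)))
      X <- X + matrix(dz, d, nx, byrow = TRUE)
    }
    x_mesh[i + 1, ] <- X[d, ]
  }
  list(t_mesh = t_mesh, x_mesh = x_mesh, x_f = x_mesh[n + 1, ])
}
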