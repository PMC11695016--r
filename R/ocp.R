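# Optimal-control problems: muscle-tendon parameter estimation and
# predictive gait, transcribed with third-order Radau collocation into
# sparse NLPs and solved with the augmented-Lagrangian solver.
#
# Implicit formulation: the states are skeletal positions/velocities,
# muscle activations, normalized tendon forces and (amputee) the MPK
# activation; the controls are the time derivatives of the states (joint
# accelerations, tendon force rates) plus muscle and MPK excitations.  The
# skeletal equations of motion and the Hill equilibrium enter as algebraic
# path constraints at every collocation node.  The constraint Jacobian
# combines exact triplets for the collocation algebra with grouped
# finite-difference sweeps for the dynamics blocks (each sweep perturbs one
# variable class at all nodes at once; the path constraints at a node
# depend on at most one perturbed column, so the sweep identifies a full
# Jacobian block).

#' Objective weight factors
#'
#' Weights of the prediction objective (`w_p1` activations squared, `w_p2`
#' metabolic rate squared, `w_p3` joint accelerations squared, `w_p4` state
#' derivative regularization, `w_p5` MPK excitation squared; the integrand
#' is divided by the pelvis forward distance) and of the estimation
#' objective (`w_e1` activations squared, `w_e2` optimal fiber length,
#' `w_e3` reserve actuator squared, `w_e4` derivative regularization).
#' Defaults are chosen so the prediction terms have comparable magnitude on
#' a nominal walking guess; all are configuration-exposed.
#'
#' @param w_p1,w_p2,w_p3,w_p4,w_p5 Prediction weights.
#' @param w_e1,w_e2,w_e3,w_e4 Estimation weights.
#' @export
objective_weights <- function(w_p1 = 2000, w_p2 = 0.01, w_p3 = 1, w_p4 = 1,
                              w_p5 = 100, w_e1 = 10, w_e2 = 1, w_e3 = 1,
                              w_e4 = 0.1) {
  w <- list(w_p1 = w_p1, w_p2 = w_p2, w_p3 = w_p3, w_p4 = w_p4, w_p5 = w_p5,
            w_e1 = w_e1, w_e2 = w_e2, w_e3 = w_e3, w_e4 = w_e4)
  if (any(unlist(w) < 0)) stop("objective weights must be >= 0")
  structure(w, class = "objective_weights")
}

#' Prediction problem specification
#'
#' @param target_speed Imposed average gait speed (m/s); the cycle time is
#'   free and the pelvis forward travel must equal speed x cycle time.
#' @param condition Label (REF, DACT, SKG15, ...), recorded in the result.
#' @param n_mesh Mesh intervals (default 50).
#' @param degree Radau degree (default 3).
#' @param weights An [objective_weights].
#' @param initial_guess `"synthetic_nominal"`, a prior `prediction_result`,
#'   or a list of guess trajectories.
#' @param cycle_time_guess Initial guess of the cycle time (s).
#' @param solver Options for the continuation/SQP solve (see
#'   [predict_gait()] and [solve_nlp_sqp()]): `feas_tol`, `opt_tol`,
#'   `time_limit`, `res_schedule`, `stage_iter`, `verbose`.
#' @export
prediction_problem_spec <- function(target_speed = 1.48, condition = "REF",
                                    n_mesh = 50, degree = 3,
                                    weights = objective_weights(),
                                    initial_guess = "synthetic_nominal",
                                    cycle_time_guess = 1.0,
                                    solver = list()) {
  stopifnot_scalar(target_speed, "target_speed", positive = TRUE)
  structure(list(target_speed = target_speed, condition = condition,
                 n_mesh = n_mesh, degree = degree, weights = weights,
                 initial_guess = initial_guess,
                 cycle_time_guess = cycle_time_guess, solver = solver),
            class = "prediction_problem_spec")
}

#' Estimation problem specification
#'
#' @param dataset A dataset as produced by [generate_estimation_dataset()]
#'   (fields `time`, `q`, `qdot`, `moment`).
#' @param n_mesh Mesh intervals (default 50).
#' @param degree Radau degree.
#' @param weights An [objective_weights].
#' @param param_bounds Multiplier interval on the generic parameter values
#'   (default `c(0.5, 2)`, i.e. 50% to 200%).
#' @param reserve_bound Bound on the reserve actuator (N m).
#' @param solver Options passed to [solve_nlp_al()].
#' @export
estimation_problem_spec <- function(dataset, n_mesh = 50, degree = 3,
                                    weights = objective_weights(),
                                    param_bounds = c(0.5, 2),
                                    reserve_bound = 300, solver = list()) {
  if (param_bounds[1] > param_bounds[2] || param_bounds[1] <= 0)
    stop("invalid param_bounds")
  structure(list(dataset = dataset, n_mesh = n_mesh, degree = degree,
                 weights = weights, param_bounds = param_bounds,
                 reserve_bound = reserve_bound, solver = solver),
            class = "estimation_problem_spec")
}

# --- variable layout ------------------------------------------------------

# states live at NX = n*d + 1 nodes (node 1 = t_i), controls at the n*d
# collocation nodes; returns index matrices (rows = nodes)
ocp_layout <- function(state_dims, ctrl_dims, n_mesh, degree, extra = 0L) {
  n_mesh <- as.integer(n_mesh); degree <- as.integer(degree)
  nc <- n_mesh * degree
  NX <- nc + 1L
  off <- 0L
  Mstate <- list()
  for (g in names(state_dims)) {
    k <- state_dims[[g]]
    Mstate[[g]] <- matrix(off + seq_len(NX * k), NX, k)
    off <- off + NX * k
  }
  Mctrl <- list()
  for (g in names(ctrl_dims)) {
    k <- ctrl_dims[[g]]
    Mctrl[[g]] <- matrix(off + seq_len(nc * k), nc, k)
    off <- off + nc * k
  }
  iextra <- if (extra > 0) off + seq_len(extra) else integer(0)
  off <- off + extra
  # interval -> node-row map (n x (d+1)): row i gives the nodes of interval i
  Rmap <- t(vapply(seq_len(n_mesh), function(i) (i - 1L) * degree + seq_len(degree + 1L),
                   integer(degree + 1L)))
  if (n_mesh == 1L) Rmap <- matrix(Rmap, 1L)
  list(Mstate = Mstate, Mctrl = Mctrl, iextra = iextra, n = off,
       nc = nc, NX = NX, n_mesh = n_mesh, degree = degree, Rmap = Rmap)
}

# quadrature factors per collocation node (in interval-fraction units)
quad_weights <- function(scheme, n_mesh) rep(scheme$w, n_mesh)

# reshape a per-collocation-node vector (cnode order) to (n x d)
cn_to_interval <- function(v, n_mesh, degree) t(matrix(v, degree, n_mesh))

# --- generic Radau transcription (exported surface) -----------------------

#' Transcribe an ODE/DAE residual into an NLP by Radau collocation
#'
#' Builds the finite-dimensional nonlinear program of the collocation
#' transcription for a generic explicit ODE `dx/dt = f(x, t)` with fixed
#' initial state: the unknowns are the states at the collocation nodes, and
#' the constraints are the collocation equations.  Used directly for
#' verification against closed-form solutions; the gait problems use the
#' same scheme with their implicit dynamics.
#'
#' @param f Right-hand side `f(x, t)`.
#' @param grid A [collocation_grid].
#' @param x0 Initial state (boundary constraint at `t_i`).
#' @return A problem list compatible with [solve_nlp_al()] (zero objective)
#'   plus `meta` (layout, node times) and `extract(z)` returning the state
#'   trajectory matrix.
#' @export
transcribe_radau <- function(f, grid, x0) {
  nx <- length(x0)
  n <- grid$n_mesh; d <- grid$degree
  sch <- grid$scheme
  lay <- ocp_layout(list(x = nx), list(), n, d)
  h <- (grid$t_f - grid$t_i) / n
  t_nodes <- grid$t_i + h * (rep(seq_len(n) - 1, each = d) + rep(sch$tau, n))
  cons <- function(z) {
    X <- matrix(z[lay$Mstate$x], lay$NX, nx)
    Fv <- matrix(0, lay$nc, nx)
    for (c in seq_len(lay$nc)) Fv[c, ] <- f(X[c + 1, ], t_nodes[c])
    out <- numeric(nx * lay$nc + nx)
    for (j in seq_len(nx)) {
      Xm <- matrix(X[as.vector(lay$Rmap), j], n, d + 1)
      R <- Xm %*% t(sch$D) - h * cn_to_interval(Fv[, j], n, d)
      out[(j - 1) * lay$nc + seq_len(lay$nc)] <- as.vector(t(R))
    }
    out[nx * lay$nc + seq_len(nx)] <- X[1, ] - x0
    out
  }
  grad_jac <- function(z) {
    # dense-ish finite-difference Jacobian; fine at the sizes this surface
    # is used for
    c0 <- cons(z)
    m <- length(c0)
    J <- matrix(0, m, lay$n)
    for (j in seq_len(lay$n)) {
      zp <- z; zp[j] <- zp[j] + 1e-7
      J[, j] <- (cons(zp) - c0) / 1e-7
    }
    list(grad = numeric(lay$n), J = methods::as(Matrix::Matrix(J, sparse = TRUE), "CsparseMatrix"))
  }
  prob <- list(n = lay$n, fval = function(z) 0, cons = cons,
               grad_jac = grad_jac, hess_diag = function(z) rep(1e-8, lay$n),
               lb = rep(-Inf, lay$n), ub = rep(Inf, lay$n))
  list(prob = prob,
       meta = list(layout = lay, t_nodes = t_nodes, grid = grid),
       extract = function(z) matrix(z[lay$Mstate$x], lay$NX, nx),
       guess = rep(x0, each = lay$NX))
}
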