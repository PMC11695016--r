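# Continuous-time physics of the planar model: passive joint moments,
# Hunt-Crossley foot-ground contact, the MPK damper, muscle path geometry,
# and the multibody equations of motion in implicit (inverse-dynamics
# residual) form.
#
# The planar chain is handled without symbolic algebra: every body COM is a
# sum of lever terms A_k * w(phi_k + delta_k) with w(phi) = (cos, sin) and
# phi_k a fixed linear combination of the generalized coordinates, so point
# Jacobians and velocity-product accelerations have closed forms.

# --- passive joint moment -------------------------------------------------

#' Exponential passive joint-limit moment
#'
#' `M = k1 exp(-k2 (q - q_lower)) - k1 exp(k2 (q - q_upper)) - b qdot - k_lin q`.
#' The double exponential resists exceeding either limit, `b` is linear
#' damping and `k_lin` an optional linear spring (MTP joint, ESR ankle).
#'
#' @param q Joint angle (rad), vectorized.
#' @param qdot Joint angular velocity (rad/s).
#' @param p A `passive_moment_params`.
#' @return Moment in N m.
#' @export
passive_joint_moment <- function(q, qdot, p) {
  p$k1 * exp(-p$k2 * (q - p$q_lower)) - p$k1 * exp(p$k2 * (q - p$q_upper)) -
    p$b * qdot - p$k_lin * q
}

# --- MPK ------------------------------------------------------------------

#' Moment of the variable-damping prosthetic knee
#'
#' `T_MPK = a_MPK * D_MPK * qdot`: the flexion resistance of the
#' microprocessor knee, modulated by its activation.  In the equations of
#' motion the moment is applied with opposing sign, so that
#' `T_MPK * qdot >= 0` (the damper only dissipates).
#'
#' @param a_mpk MPK activation in [0, 1].
#' @param d_mpk Damper coefficient (N m s / rad).
#' @param qdot Prosthetic knee angular velocity (rad/s).
#' @export
mpk_damper_moment <- function(a_mpk, d_mpk, qdot) {
  a_mpk * d_mpk * qdot
}

#' MPK activation dynamics residual (first-order lag)
#'
#' @param e_mpk MPK excitation in [0, 1].
#' @param a_mpk MPK activation in [0, 1].
#' @param a_mpk_dot Candidate activation rate (1/s).
#' @param tau_mpk Time constant (s).
#' @export
mpk_activation_residual <- function(e_mpk, a_mpk, a_mpk_dot, tau_mpk = 0.030) {
  a_mpk_dot - (e_mpk - a_mpk) / tau_mpk
}

# --- Hunt-Crossley contact ------------------------------------------------

#' Hunt-Crossley sphere-ground contact force
#'
#' Ground is the plane y = 0.  Penetration is the smoothed positive part of
#' `radius - y_center`; the normal force is
#' `stiffness * delta^(3/2) * (1 + 3/2 dissipation * ddelta)` smoothly
#' clamped at zero (no adhesion); the tangential force is smoothed Coulomb
#' friction plus a viscous term scaled by the transition velocity `v_t`.
#'
#' @param pos Sphere center position, `c(x, y)` or an n x 2 matrix.
#' @param vel Sphere center velocity, same shape.
#' @param c A contact sphere spec (list with `radius`, `stiffness`,
#'   `dissipation`, `mu`, `v_t`).
#' @return An n x 2 matrix of forces `(fx, fy)` in N.
#' @export
hunt_crossley_force <- function(pos, vel, c) {
  pos <- matrix(pos, ncol = 2); vel <- matrix(vel, ncol = 2)
  y <- pos[, 2]; vx <- vel[, 1]; vy <- vel[, 2]
  delta <- softplus(c$radius - y, 1e-3)
  ddelta <- -vy * sigmoid((c$radius - y) / 1e-3)  # chain rule of the softplus
  fac <- softplus(1 + 1.5 * c$dissipation * ddelta, 0.1)
  fn <- c$stiffness * delta^1.5 * fac
  ft <- -fn * (c$mu * tanh(vx / c$v_t) + 0.1 * vx)
  cbind(ft, fn)
}

# --- muscle path geometry -------------------------------------------------

#' Musculotendon length, velocity and moment arms
#'
#' Evaluates the muscle's geometry polynomials (length as a polynomial in
#' each spanned joint angle; moment arms as the exact negative analytic
#' derivative) at the given skeletal state.
#'
#' @param model A `model_spec`.
#' @param muscle Muscle name or the muscle entry itself.
#' @param q,qdot Named numeric vectors (or matrices with columns in
#'   [model_dof_names()] order) of joint angles and velocities.
#' @return List with `l_mt` (m), `v_mt` (m/s) and `moment_arms` (m, one
#'   column per spanned joint).
#' @export
muscle_geometry <- function(model, muscle, q, qdot) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  if (is.null(muscle)) stop("unknown muscle")
  dofs <- model_dof_names(model)
  Q <- if (is.matrix(q)) q else matrix(q, nrow = 1)
  Qd <- if (is.matrix(qdot)) qdot else matrix(qdot, nrow = 1)
  n <- nrow(Q)
  l_mt <- rep(muscle$l_mt0, n)
  v_mt <- rep(0, n)
  arms <- matrix(0, n, length(muscle$spanned_joints),
                 dimnames = list(NULL, muscle$spanned_joints))
  for (jn in muscle$spanned_joints) {
    if (model$joints[[jn]]$locked)
      stop("muscle ", muscle$name, " references locked joint ", jn)
    idx <- match(jn, dofs)
    cf <- muscle$geometry[[jn]]
    qj <- Q[, idx]
    l_mt <- l_mt + polynomial_eval(cf, qj)
    dl <- polynomial_eval(polynomial_derivative(cf), qj)
    arms[, jn] <- -dl
    v_mt <- v_mt + dl * Qd[, idx]
  }
  list(l_mt = l_mt, v_mt = v_mt, moment_arms = arms)
}

# --- multibody plan -------------------------------------------------------

# Precompute, for each body, the lever-term decomposition of its COM and the
# linear combination defining its absolute angle.  Coordinate order:
# (pelvis_tx, pelvis_ty, pelvis_tilt, hip_il, knee_il, ankle_il,
#  hip_cl, knee_cl, ankle_cl).
dyn_plan <- function(model) {
  dofs <- model_dof_names(model)
  nq <- length(dofs)
  cvec <- function(...) {
    v <- numeric(nq)
    args <- list(...)
    for (i in seq(1, length(args), by = 2)) v[match(args[[i]], dofs)] <- args[[i + 1]]
    v
  }
  segs <- model$segments
  bodies <- list()
  for (side in c("il", "cl")) {
    hipn <- paste0("hip_", side); kneen <- paste0("knee_", side)
    anklen <- paste0("ankle_", side)
    th <- segs[[paste0("thigh_", side)]]
    sh <- segs[[paste0("shank_", side)]]
    ft <- segs[[paste0("foot_", side)]]
    c_th <- cvec("pelvis_tilt", 1, hipn, 1)
    c_sh <- cvec("pelvis_tilt", 1, hipn, 1, kneen, -1)
    c_ft <- cvec("pelvis_tilt", 1, hipn, 1, kneen, -1, anklen, 1)
    # foot COM in the foot frame (origin ankle, x forward, y up)
    com_ft <- c(0.5 * ft$length - 0.25 * ft$length, -0.03)
    r_ft <- sqrt(sum(com_ft^2)); psi_ft <- atan2(com_ft[2], com_ft[1])
    bodies[[paste0("thigh_", side)]] <- list(
      mass = th$mass, I = th$inertia_zz, c_ang = c_th,
      terms = list(list(A = th$com_offset, c = c_th, delta = -pi / 2)))
    bodies[[paste0("shank_", side)]] <- list(
      mass = sh$mass, I = sh$inertia_zz, c_ang = c_sh,
      terms = list(list(A = th$length, c = c_th, delta = -pi / 2),
                   list(A = sh$com_offset, c = c_sh, delta = -pi / 2)))
    bodies[[paste0("foot_", side)]] <- list(
      mass = ft$mass, I = ft$inertia_zz, c_ang = c_ft,
      terms = list(list(A = th$length, c = c_th, delta = -pi / 2),
                   list(A = sh$length, c = c_sh, delta = -pi / 2),
                   list(A = r_ft, c = c_ft, delta = psi_ft)))
  }
  hat <- segs$hat
  bodies$hat <- list(
    mass = hat$mass, I = hat$inertia_zz, c_ang = cvec("pelvis_tilt", 1),
    terms = list(list(A = hat$com_offset, c = cvec("pelvis_tilt", 1),
                      delta = pi / 2)))
  # contact sphere point plans (terms from the pelvis to the sphere center)
  spheres <- list()
  for (cs in model$contacts) {
    side <- sub("^.*_", "", cs$segment)
    b <- bodies[[cs$segment]]
    th <- segs[[paste0("thigh_", side)]]
    sh <- segs[[paste0("shank_", side)]]
    r_s <- sqrt(sum(cs$location^2))
    psi_s <- if (r_s > 0) atan2(cs$location[2], cs$location[1]) else 0
    terms <- list(list(A = th$length, c = b$terms[[1]]$c, delta = -pi / 2),
                  list(A = sh$length, c = b$terms[[2]]$c, delta = -pi / 2))
    if (r_s > 0) terms <- c(terms, list(list(A = r_s, c = b$c_ang, delta = psi_s)))
    spheres[[cs$name]] <- list(spec = cs, terms = terms, body = cs$segment)
  }
  list(nq = nq, dofs = dofs, bodies = bodies, spheres = spheres,
       g = model$gravity,
       joint_idx = match(c("hip_il", "knee_il", "ankle_il",
                           "hip_cl", "knee_cl", "ankle_cl"), dofs))
}

# world position/velocity/acceleration (and optionally the Jacobian) of a
# point defined by lever terms; Q, Qd, Qdd are P x nq matrices
point_kinematics <- function(terms, Q, Qd = NULL, Qdd = NULL, jac = FALSE) {
  P <- nrow(Q)
  px <- Q[, 1]; py <- Q[, 2]
  vx <- if (!is.null(Qd)) Qd[, 1] else NULL
  vy <- if (!is.null(Qd)) Qd[, 2] else NULL
  ax <- if (!is.null(Qdd)) Qdd[, 1] else NULL
  ay <- if (!is.null(Qdd)) Qdd[, 2] else NULL
  nq <- ncol(Q)
  Jx <- Jy <- NULL
  if (jac) {
    Jx <- matrix(0, P, nq); Jy <- matrix(0, P, nq)
    Jx[, 1] <- 1; Jy[, 2] <- 1
  }
  for (tm in terms) {
    phi <- as.vector(Q %*% tm$c) + tm$delta
    cphi <- cos(phi); sphi <- sin(phi)
    px <- px + tm$A * cphi
    py <- py + tm$A * sphi
    if (!is.null(Qd)) {
      phid <- as.vector(Qd %*% tm$c)
      vx <- vx - tm$A * sphi * phid
      vy <- vy + tm$A * cphi * phid
      if (!is.null(Qdd)) {
        phidd <- as.vector(Qdd %*% tm$c)
        ax <- ax + tm$A * (-sphi * phidd - cphi * phid^2)
        ay <- ay + tm$A * (cphi * phidd - sphi * phid^2)
      }
    }
    if (jac) {
      nz <- which(tm$c != 0)
      for (j in nz) {
        Jx[, j] <- Jx[, j] - tm$A * sphi * tm$c[j]
        Jy[, j] <- Jy[, j] + tm$A * cphi * tm$c[j]
      }
    }
  }
  list(px = px, py = py, vx = vx, vy = vy, ax = ax, ay = ay, Jx = Jx, Jy = Jy)
}

# inverse dynamics: generalized forces required to realize (Q, Qd, Qdd),
# gravity included.  Returns a P x nq matrix.
inverse_dynamics_plan <- function(plan, Q, Qd, Qdd) {
  P <- nrow(Q); nq <- plan$nq
  tau <- matrix(0, P, nq)
  g <- plan$g
  for (b in plan$bodies) {
    pk <- point_kinematics(b$terms, Q, Qd, Qdd, jac = TRUE)
    fx <- b$mass * pk$ax
    fy <- b$mass * (pk$ay + g)
    tau <- tau + pk$Jx * fx + pk$Jy * fy
    # rotational part: angular Jacobian is the constant combination c_ang
    phidd <- as.vector(Qdd %*% b$c_ang)
    nz <- which(b$c_ang != 0)
    for (j in nz) tau[, j] <- tau[, j] + b$I * phidd * b$c_ang[j]
  }
  tau
}

# generalized forces of the contact spheres; returns list(tau = P x nq,
# forces = list per sphere with fx, fy, px, py)
contact_generalized_forces <- function(plan, Q, Qd) {
  P <- nrow(Q); nq <- plan$nq
  tau <- matrix(0, P, nq)
  forces <- list()
  for (nm in names(plan$spheres)) {
    sp <- plan$spheres[[nm]]
    pk <- point_kinematics(sp$terms, Q, Qd, jac = TRUE)
    f <- hunt_crossley_force(cbind(pk$px, pk$py), cbind(pk$vx, pk$vy), sp$spec)
    tau <- tau + pk$Jx * f[, 1] + pk$Jy * f[, 2]
    forces[[nm]] <- list(fx = f[, 1], fy = f[, 2], px = pk$px, py = pk$py)
  }
  list(tau = tau, forces = forces)
}

#' Skeletal dynamics residual (implicit equations of motion)
#'
#' `residual = ID(q, qdot, qddot) - tau_applied - tau_contact`, where `ID`
#' is the inverse dynamics of the planar chain (gravity included).  Zero iff
#' the equations of motion `M(q) qddot + C(q, qdot) + G(q) = tau` are
#' satisfied.
#'
#' @param model A `model_spec`.
#' @param q,qdot,qddot Generalized positions/velocities/accelerations in
#'   [model_dof_names()] order (vectors or P x 9 matrices).
#' @param joint_moments Applied generalized forces per DoF (same shape as
#'   `q`; defaults to zero).  Pelvis coordinates are unactuated, so their
#'   entries are normally 0.
#' @param include_contact If TRUE, Hunt-Crossley contact forces are
#'   evaluated from the state and included.
#' @return Residual per DoF (same shape as `q`), in N or N m.
#' @export
skeletal_dynamics_residual <- function(model, q, qdot, qddot,
                                       joint_moments = NULL,
                                       include_contact = FALSE) {
  plan <- dyn_plan(model)
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  Q <- as_m(q); Qd <- as_m(qdot); Qdd <- as_m(qddot)
  if (ncol(Q) != plan$nq) stop("state dimension mismatch: expected ", plan$nq)
  tau_app <- if (is.null(joint_moments)) matrix(0, nrow(Q), plan$nq) else as_m(joint_moments)
  if (!all(dim(tau_app) == dim(Q))) stop("joint_moments dimension mismatch")
  res <- inverse_dynamics_plan(plan, Q, Qd, Qdd) - tau_app
  if (include_contact) {
    cf <- contact_generalized_forces(plan, Q, Qd)
    res <- res - cf$tau
  }
  if (!is.matrix(q)) res <- drop(res)
  res
}

#' Forward dynamics of the planar model
#'
#' Solves `M(q) qddot = tau - C - G` for the accelerations by evaluating the
#' inverse dynamics residual at unit accelerations (the mass matrix is
#' extracted column by column).
#'
#' @inheritParams skeletal_dynamics_residual
#' @param tau Applied generalized forces (length 9).
#' @return Acceleration vector (length 9).
#' @export
forward_dynamics <- function(model, q, qdot, tau = NULL,
                             include_contact = FALSE) {
  plan <- dyn_plan(model)
  nq <- plan$nq
  if (is.null(tau)) tau <- numeric(nq)
  Q <- matrix(q, 1); Qd <- matrix(qdot, 1)
  bias <- drop(inverse_dynamics_plan(plan, Q, Qd, matrix(0, 1, nq)))
  M <- matrix(0, nq, nq)
  for (j in seq_len(nq)) {
    e <- matrix(0, 1, nq); e[1, j] <- 1
    M[, j] <- drop(inverse_dynamics_plan(plan, Q, Qd, e)) - bias
  }
  rhs <- tau - bias
  if (include_contact) {
    cf <- contact_generalized_forces(plan, Q, Qd)
    rhs <- rhs + drop(cf$tau)
  }
  drop(solve(M, rhs))
}
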