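# Predictive gait OCP: builder, initial guess, solve, reporting.

# per-muscle cached quantities for fast path evaluation
muscle_cache <- function(model) {
  dofs <- model_dof_names(model)
  lapply(unname(model$muscles), function(m) {
    list(name = m$name, p = m$params, l0 = m$l_mt0,
         jidx = match(m$spanned_joints, dofs),
         coefs = m$geometry[m$spanned_joints])
  })
}

# joint passive-moment cache (pin joints only)
passive_cache <- function(model) {
  dofs <- model_dof_names(model)
  out <- list()
  for (j in model$joints) {
    if (isTRUE(j$locked)) next
    out[[j$name]] <- list(idx = match(j$name, dofs), p = j$passive)
  }
  out
}

#' Initial guess trajectories for the gait prediction
#'
#' Builds a full state/control guess on the collocation grid.  Sources:
#' `"synthetic_nominal"` evaluates the smooth periodic gait templates (IL
#' and CL half a cycle apart), seeds muscle activations at 0.05 with tendon
#' forces at static Hill equilibrium; a prior `prediction_result` is reused
#' directly; a time-series file (`.sto`/CSV with columns named after the
#' model DoF, angles in degrees) is resampled to the grid.
#'
#' @param model A `model_spec`.
#' @param pspec A [prediction_problem_spec].
#' @return List of guess matrices (`Q`, `Qd`, `Qdd` at state nodes /
#'   collocation nodes, muscle states, `T0`).
#' @export
make_initial_guess <- function(model, pspec) {
  src <- pspec$initial_guess
  n <- pspec$n_mesh; d <- pspec$degree
  sch <- radau_scheme(d)
  nc <- n * d
  # cycle fractions of state nodes (incl node 0) and collocation nodes
  s_cn <- (rep(seq_len(n) - 1, each = d) + rep(sch$tau, n)) / n
  s_st <- c(0, s_cn)
  T0 <- pspec$cycle_time_guess
  v <- pspec$target_speed
  dofs <- model_dof_names(model)
  y0 <- model$segments$thigh_il$length + model$segments$shank_il$length +
    model$ankle_height

  if (inherits(src, "prediction_result")) {
    if (!is.null(src$z_scaled) && src$n_mesh == n && src$degree == d &&
        identical(src$state_dims_signature, guess_signature(model)))
      return(list(prior_z = src$z_scaled, T0 = src$T))
    stop("prior_solution guess requires a result from the same model/grid")
  }

  dense_s <- seq(0, 1, length.out = 401)
  if (identical(src, "synthetic_nominal")) {
    tm <- gait_templates(dense_s)
    knee_il <- tm$knee_angle
    if (!is.null(model$prosthesis)) {
      # passive prosthetic knees give little stance support: seed the IL
      # knee near extension during stance, keeping the swing flexion peak
      knee_il <- knee_il - 0.85 * (3 + 15 * cyc_gauss(dense_s, 0.15, 0.07)) *
        cyc_gauss(dense_s, 0.2, 0.22)
    }
    chan <- list(
      hip_il = deg2rad(tm$hip_angle), knee_il = deg2rad(knee_il),
      ankle_il = deg2rad(tm$ankle_angle),
      pelvis_tilt = deg2rad(tm$pelvis_tilt))
  } else if (is.character(src)) {
    tab <- read_storage(src)
    need <- c("hip_il", "knee_il", "ankle_il")
    miss <- setdiff(need, tab$labels)
    if (length(miss) > 0)
      stop("initial-guess file lacks channels: ", paste(miss, collapse = ", "))
    tfrac <- (tab$time - tab$time[1]) / diff(range(tab$time))
    chan <- lapply(stats::setNames(need, need), function(nm) {
      stats::splinefun(tfrac, tab$data[, nm], method = "periodic")(dense_s) |>
        deg2rad()
    })
    chan$pelvis_tilt <- if ("pelvis_tilt" %in% tab$labels)
      deg2rad(stats::splinefun(tfrac, tab$data[, "pelvis_tilt"],
                               method = "periodic")(dense_s))
    else rep(0.03, length(dense_s))
  } else stop("unknown initial guess source")

  per <- function(x) { x[length(x)] <- x[1]; x }
  half <- function(x) {  # contralateral: half a cycle out of phase
    stats::splinefun(dense_s, per(x), method = "periodic")((dense_s + 0.5) %% 1)
  }
  curves <- list(
    pelvis_tx = NULL, pelvis_ty = NULL, pelvis_tilt = per(chan$pelvis_tilt),
    hip_il = per(chan$hip_il), knee_il = per(chan$knee_il),
    ankle_il = per(chan$ankle_il),
    hip_cl = half(chan$hip_il), knee_cl = half(chan$knee_il),
    ankle_cl = half(chan$ankle_il))
  # under a stiff-knee condition the passive limit would be violated
  # violently by the nominal swing flexion; saturate the IL knee guess
  # smoothly below the limit
  klim <- model$joints$knee_il$passive$q_upper
  if (max(curves$knee_il) > klim) {
    margin <- deg2rad(3)
    x <- curves$knee_il
    curves$knee_il <- per(x - softplus(x - (klim - margin), deg2rad(1)))
  }
  # pelvis height consistent with foot-ground contact: place the pelvis so
  # that the lowest contact-sphere bottom (smooth minimum over the spheres
  # of both feet) penetrates the ground by ~5 mm (about one body weight of
  # Hunt-Crossley load at the default stiffness)
  plan0 <- dyn_plan(model)
  dofs0 <- model_dof_names(model)
  Qg <- matrix(0, length(dense_s), length(dofs0),
               dimnames = list(NULL, dofs0))
  for (nm in setdiff(dofs0, c("pelvis_tx", "pelvis_ty")))
    Qg[, nm] <- curves[[nm]]
  bottoms <- vapply(plan0$spheres, function(sp) {
    pk <- point_kinematics(sp$terms, Qg)
    pk$py - sp$spec$radius
  }, numeric(length(dense_s)))
  sm <- 0.01
  soft_min <- -sm * log(rowSums(exp(-bottoms / sm)))
  # ~17 mm penetration carries one body weight at the default stiffness
  curves$pelvis_ty <- per(-soft_min - 0.015)

  nq <- length(dofs)
  Q <- matrix(0, nc + 1, nq, dimnames = list(NULL, dofs))
  Qd <- matrix(0, nc + 1, nq, dimnames = list(NULL, dofs))
  Qdd <- matrix(0, nc, nq, dimnames = list(NULL, dofs))
  for (j in seq_along(dofs)) {
    nm <- dofs[j]
    if (nm == "pelvis_tx") {
      Q[, j] <- v * T0 * s_st; Qd[, j] <- v; next
    }
    spf <- stats::splinefun(dense_s, curves[[nm]], method = "periodic")
    Q[, j] <- spf(s_st)
    Qd[, j] <- spf(s_st, deriv = 1) / T0
    Qdd[, j] <- spf(s_cn, deriv = 2) / T0^2
  }
  mus <- muscle_cache(model)
  nmus <- length(mus)
  A <- matrix(0.05, nc + 1, nmus)
  FT <- matrix(0, nc + 1, nmus)
  for (m in seq_len(nmus)) {
    mc <- mus[[m]]
    l_mt <- rep(mc$l0, nc + 1)
    for (k in seq_along(mc$jidx))
      l_mt <- l_mt + polynomial_eval(mc$coefs[[k]], Q[, mc$jidx[k]])
    FT[, m] <- muscle_equilibrium_ftilde(A[, m], l_mt, 0, mc$p)
  }
  list(Q = Q, Qd = Qd, Qdd = Qdd, A = A, FT = FT,
       FTd = matrix(0, nc, nmus), E = A[-1, , drop = FALSE],
       ampk = rep(0.3, nc + 1), empk = rep(0.3, nc), T0 = T0)
}

guess_signature <- function(model) {
  c(length(model$muscles), as.integer(!is.null(model$prosthesis)))
}

# forward-dynamics-consistent accelerations along a guess trajectory
consistent_qdd <- function(model, plan, mus, pas, has_mpk, g) {
  Qc <- g$Q[-1, , drop = FALSE]
  Qdc <- g$Qd[-1, , drop = FALSE]
  nc <- nrow(Qc); nq <- ncol(Qc)
  tau <- matrix(0, nc, nq)
  for (m in seq_along(mus)) {
    mc <- mus[[m]]
    Fm <- g$FT[-1, m] * mc$p$f_max_iso
    for (k in seq_along(mc$jidx)) {
      dl <- polynomial_eval(polynomial_derivative(mc$coefs[[k]]),
                            Qc[, mc$jidx[k]])
      tau[, mc$jidx[k]] <- tau[, mc$jidx[k]] - dl * Fm
    }
  }
  for (pj in pas)
    tau[, pj$idx] <- tau[, pj$idx] +
      passive_joint_moment(Qc[, pj$idx], Qdc[, pj$idx], pj$p)
  if (has_mpk) {
    kidx <- match("knee_il", model_dof_names(model))
    tau[, kidx] <- tau[, kidx] -
      mpk_damper_moment(g$ampk[-1], model$prosthesis$d_mpk, Qdc[, kidx])
  }
  cg <- contact_generalized_forces(plan, Qc, Qdc)
  tau <- tau + cg$tau
  Qdd <- matrix(0, nc, nq)
  for (i in seq_len(nc)) {
    Qi <- Qc[i, , drop = FALSE]; Qdi <- Qdc[i, , drop = FALSE]
    bias <- drop(inverse_dynamics_plan(plan, Qi, Qdi, matrix(0, 1, nq)))
    M <- matrix(0, nq, nq)
    for (j in seq_len(nq)) {
      e <- matrix(0, 1, nq); e[1, j] <- 1
      M[, j] <- drop(inverse_dynamics_plan(plan, Qi, Qdi, e)) - bias
    }
    Qdd[i, ] <- solve(M, tau[i, ] - bias)
  }
  Qdd
}

# --- prediction NLP builder ----------------------------------------------

build_prediction_nlp <- function(model, pspec) {
  n <- pspec$n_mesh; d <- pspec$degree
  sch <- radau_scheme(d)
  nc <- n * d
  dofs <- model_dof_names(model)
  nq <- length(dofs)
  mus <- muscle_cache(model)
  nmus <- length(mus)
  has_mpk <- !is.null(model$prosthesis)
  pas <- passive_cache(model)
  plan <- dyn_plan(model)
  W <- pspec$weights
  v_tgt <- pspec$target_speed
  mp <- metabolic_model_params()
  kidx <- match("knee_il", dofs)

  state_dims <- list(q = nq, qd = nq, a = nmus, ft = nmus)
  # `res` are bounded residual joint actuators used only for continuation:
  # outer stages solve with generous bounds and the bounds are driven to
  # zero, so the final NLP contains the exact dynamics (see predict_gait)
  ctrl_dims <- list(qdd = nq, ftd = nmus, e = nmus, res = nq)
  if (has_mpk) { state_dims$ampk <- 1L; ctrl_dims$empk <- 1L }
  w_res <- 1e-3
  lay <- ocp_layout(state_dims, ctrl_dims, n, d, extra = 1L)  # extra = T
  iT <- lay$iextra[1]

  # scales -----------------------------------------------------------------
  sc_state <- list(q = rep(1, nq), qd = rep(5, nq), a = rep(0.5, nmus),
                   ft = rep(0.5, nmus), ampk = 0.5)
  sc_ctrl <- list(qdd = rep(100, nq), ftd = rep(10, nmus),
                  e = rep(0.5, nmus), res = rep(50, nq), empk = 0.5)
  svec <- numeric(lay$n)
  for (g in names(state_dims))
    svec[lay$Mstate[[g]]] <- rep(sc_state[[g]][seq_len(state_dims[[g]])],
                                 each = lay$NX)
  for (g in names(ctrl_dims))
    svec[lay$Mctrl[[g]]] <- rep(sc_ctrl[[g]][seq_len(ctrl_dims[[g]])],
                                each = nc)
  svec[iT] <- 0.3

  rs_coll <- list(q = 0.05, qd = 1, a = 0.3, ft = 0.2, ampk = 0.3)
  rs_skel <- c(700, 700, 200, 150, 80, 60, 150, 80, 60)
  rs_hill <- 0.5
  rs_per <- list(q = 1, qd = 5, a = 0.5, ft = 0.5, ampk = 0.5)
  rs_speed <- 0.05
  rs_pin <- 0.1

  # constraint row offsets
  off <- 0L
  coll_off <- list()
  for (g in names(state_dims)) {
    coll_off[[g]] <- off
    off <- off + state_dims[[g]] * nc
  }
  skel_off <- off; off <- off + nq * nc
  hill_off <- off; off <- off + nmus * nc
  per_rows <- list()
  per_off <- off
  nper <- 0L
  for (g in names(state_dims)) for (j in seq_len(state_dims[[g]])) {
    if (g == "q" && dofs[j] == "pelvis_tx") next
    nper <- nper + 1L
    per_rows[[nper]] <- list(g = g, j = j, row = per_off + nper)
  }
  off <- off + nper
  speed_row <- off + 1L
  pin_row <- off + 2L
  m_con <- off + 2L

  wq <- quad_weights(sch, n)       # per collocation node
  cost_fac <- wq / (n * v_tgt)     # includes the 1/Dist = 1/(v T) x h = T/n

  # --- unpack -------------------------------------------------------------
  unpack <- function(z) {
    zp <- z * svec
    up <- list()
    for (g in names(state_dims))
      up[[g]] <- matrix(zp[lay$Mstate[[g]]], lay$NX, state_dims[[g]])
    for (g in names(ctrl_dims))
      up[[paste0("u_", g)]] <- matrix(zp[lay$Mctrl[[g]]], nc, ctrl_dims[[g]])
    up$T <- zp[iT]
    up
  }

  # --- path evaluation (skel + hill + cost) -------------------------------
  path_eval <- function(up) {
    Qc <- up$q[-1, , drop = FALSE]
    Qdc <- up$qd[-1, , drop = FALSE]
    Ac <- up$a[-1, , drop = FALSE]
    FTc <- up$ft[-1, , drop = FALSE]
    Qddc <- up$u_qdd
    FTdc <- up$u_ftd
    Ec <- up$u_e
    tau_app <- matrix(0, nc, nq)
    hill <- matrix(0, nc, nmus)
    edot2 <- numeric(nc)
    for (m in seq_len(nmus)) {
      mc <- mus[[m]]
      l_mt <- rep(mc$l0, nc); v_mt <- numeric(nc)
      arms <- vector("list", length(mc$jidx))
      for (k in seq_along(mc$jidx)) {
        cf <- mc$coefs[[k]]
        qj <- Qc[, mc$jidx[k]]
        l_mt <- l_mt + polynomial_eval(cf, qj)
        dl <- polynomial_eval(polynomial_derivative(cf), qj)
        arms[[k]] <- -dl
        v_mt <- v_mt + dl * Qdc[, mc$jidx[k]]
      }
      hill[, m] <- hill_equilibrium_residual(Ac[, m], FTc[, m], FTdc[, m],
                                             l_mt, v_mt, mc$p)
      Fm <- FTc[, m] * mc$p$f_max_iso
      for (k in seq_along(mc$jidx))
        tau_app[, mc$jidx[k]] <- tau_app[, mc$jidx[k]] + arms[[k]] * Fm
      if (W$w_p2 > 0) {
        fs <- fiber_state(l_mt, v_mt, FTc[, m], FTdc[, m], mc$p)
        f_fiber <- Fm / fs$cos_a
        ed <- metabolic_rate(Ac[, m], fs$lfN, fs$lf_dot, f_fiber, mc$p, mp)
        edot2 <- edot2 + ed^2
      }
    }
    for (pj in pas)
      tau_app[, pj$idx] <- tau_app[, pj$idx] +
        passive_joint_moment(Qc[, pj$idx], Qdc[, pj$idx], pj$p)
    if (has_mpk) {
      tau_app[, kidx] <- tau_app[, kidx] -
        mpk_damper_moment(up$ampk[-1, 1], model$prosthesis$d_mpk, Qdc[, kidx])
    }
    cg <- contact_generalized_forces(plan, Qc, Qdc)
    skel <- inverse_dynamics_plan(plan, Qc, Qdc, Qddc) - tau_app - cg$tau
    Adot <- activation_rate(Ec, Ac)
    cost <- W$w_p1 * rowSums(Ac^2) + W$w_p2 * edot2 +
      W$w_p3 * rowSums(Qddc^2) +
      W$w_p4 * (rowSums(Adot^2) + rowSums(FTdc^2))
    if (has_mpk) cost <- cost + W$w_p5 * up$u_empk[, 1]^2
    list(skel = sweep(skel, 2, rs_skel, "/"), hill = hill / rs_hill,
         cost = cost)
  }

  # collocation right-hand sides per state group, at collocation nodes
  coll_rhs <- function(up) {
    out <- list(q = up$qd[-1, , drop = FALSE], qd = up$u_qdd,
                a = activation_rate(up$u_e, up$a[-1, , drop = FALSE]),
                ft = up$u_ftd)
    if (has_mpk)
      out$ampk <- matrix((up$u_empk[, 1] - up$ampk[-1, 1]) /
                           model$prosthesis$tau_mpk, nc, 1)
    out
  }

  # assemble the full constraint vector
  cons_impl <- function(up, path) {
    rhs <- coll_rhs(up)
    cc <- numeric(m_con)
    Tn <- up$T / n
    for (g in names(state_dims)) {
      for (j in seq_len(state_dims[[g]])) {
        Xm <- matrix(up[[g]][as.vector(lay$Rmap), j], n, d + 1)
        R <- Xm %*% t(sch$D) - Tn * cn_to_interval(rhs[[g]][, j], n, d)
        cc[coll_off[[g]] + (j - 1) * nc + seq_len(nc)] <-
          as.vector(t(R)) / rs_coll[[g]]
      }
    }
    cc[skel_off + seq_len(nq * nc)] <-
      as.vector(path$skel - sweep(up$u_res, 2, rs_skel, "/"))
    cc[hill_off + seq_len(nmus * nc)] <- as.vector(path$hill)
    for (pr in per_rows) {
      x <- up[[pr$g]]
      cc[pr$row] <- (x[lay$NX, pr$j] - x[1, pr$j]) / rs_per[[pr$g]]
    }
    cc[speed_row] <- (up$q[lay$NX, 1] - up$q[1, 1] - v_tgt * up$T) / rs_speed
    cc[pin_row] <- up$q[1, 1] / rs_pin
    cc
  }

  cache <- new.env(parent = emptyenv())
  eval_point <- function(z) {
    if (!is.null(cache$z) && identical(cache$z, z)) return(cache$val)
    up <- unpack(z)
    path <- path_eval(up)
    val <- list(up = up, path = path, cons = cons_impl(up, path),
                fval = sum(cost_fac * (path$cost + w_res *
                                         rowSums(up$u_res^2))))
    cache$z <- z; cache$val <- val
    val
  }

  # --- analytic triplets --------------------------------------------------
  # constant D-entries of the collocation equations
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  for (g in names(state_dims)) {
    Mg <- lay$Mstate[[g]]
    for (j in seq_len(state_dims[[g]])) {
      base_rows <- coll_off[[g]] + (j - 1) * nc
      for (k in seq_len(d)) for (jn in seq_len(d + 1)) {
        rows <- base_rows + (seq_len(n) - 1) * d + k
        cols <- Mg[lay$Rmap[, jn], j]
        push(rows, cols, rep(sch$D[k, jn], n) * svec[cols] / rs_coll[[g]])
      }
    }
  }
  # periodicity, speed, pin (constant)
  for (pr in per_rows) {
    Mg <- lay$Mstate[[pr$g]]
    cN <- Mg[lay$NX, pr$j]; c0 <- Mg[1, pr$j]
    push(pr$row, cN, svec[cN] / rs_per[[pr$g]])
    push(pr$row, c0, -svec[c0] / rs_per[[pr$g]])
  }
  cxN <- lay$Mstate$q[lay$NX, 1]; cx0 <- lay$Mstate$q[1, 1]
  push(rep(speed_row, 3L), c(cxN, cx0, iT),
       c(svec[cxN], -svec[cx0], -v_tgt * svec[iT]) / rs_speed)
  push(pin_row, cx0, svec[cx0] / rs_pin)
  # residual actuators enter the skeletal rows linearly
  for (j in seq_len(nq)) {
    rows <- skel_off + (j - 1) * nc + seq_len(nc)
    cols <- lay$Mctrl$res[, j]
    push(rows, cols, rep(-svec[cols[1]] / rs_skel[j], nc))
  }
  const_trip <- list(i = unlist(ii), j = unlist(jj), x = unlist(xx))

  # index arrays for the T/(n) coupling of the collocation equations
  # (columns of the rhs variables), plus the T column
  coup <- list()
  for (g in names(state_dims)) {
    cols <- switch(g,
      q = lay$Mstate$qd[-1, , drop = FALSE],
      qd = lay$Mctrl$qdd, ft = lay$Mctrl$ftd,
      a = NULL,       # handled separately (rate depends on e and a)
      ampk = NULL)
    if (is.null(cols)) next
    rows <- matrix(0, nc, state_dims[[g]])
    for (j in seq_len(state_dims[[g]]))
      rows[, j] <- coll_off[[g]] + (j - 1) * nc + seq_len(nc)
    coup[[g]] <- list(rows = as.vector(rows), cols = as.vector(cols))
  }
  # rows of every collocation equation (for the T column)
  coll_rows_all <- list()
  for (g in names(state_dims)) {
    rows <- matrix(0, nc, state_dims[[g]])
    for (j in seq_len(state_dims[[g]]))
      rows[, j] <- coll_off[[g]] + (j - 1) * nc + seq_len(nc)
    coll_rows_all[[g]] <- as.vector(rows)
  }

  # --- FD sweep classes for the path blocks and the cost gradient ---------
  classes <- list()
  add_class <- function(kind, g, j, skel = FALSE, hill_m = integer(0),
                        cost = FALSE) {
    cols <- if (kind == "state") lay$Mstate[[g]][-1, j] else lay$Mctrl[[g]][, j]
    classes[[length(classes) + 1]] <<-
      list(kind = kind, g = g, j = j, cols = cols, skel = skel,
           hill_m = hill_m, cost = cost)
  }
  spans <- lapply(seq_len(nq), function(j)
    which(vapply(mus, function(mc) j %in% mc$jidx, TRUE)))
  for (j in seq_len(nq)) add_class("state", "q", j, skel = TRUE,
                                   hill_m = spans[[j]], cost = TRUE)
  for (j in seq_len(nq)) add_class("state", "qd", j, skel = TRUE,
                                   hill_m = spans[[j]], cost = TRUE)
  for (j in seq_len(nq)) add_class("ctrl", "qdd", j, skel = TRUE, cost = TRUE)
  for (m in seq_len(nmus)) {
    add_class("state", "a", m, hill_m = m, cost = TRUE)
    add_class("state", "ft", m, skel = TRUE, hill_m = m, cost = TRUE)
    add_class("ctrl", "ftd", m, hill_m = m, cost = TRUE)
    add_class("ctrl", "e", m, cost = TRUE)
  }
  if (has_mpk) {
    add_class("state", "ampk", 1, skel = TRUE)
    add_class("ctrl", "empk", 1, cost = TRUE)
  }

  h_fd <- 1e-6
  grad_jac <- function(z) {
    base <- eval_point(z)
    up <- base$up
    grad <- numeric(lay$n)
    ti <- vector("list", 64); tj <- vector("list", 64); tx <- vector("list", 64)
    nt <- 0L
    addt <- function(i, j, x) {
      nt <<- nt + 1L
      ti[[nt]] <<- i; tj[[nt]] <<- j; tx[[nt]] <<- x
    }
    # constants
    addt(const_trip$i, const_trip$j, const_trip$x)
    # T/n couplings
    Tn <- up$T / n
    rhs <- coll_rhs(up)
    for (g in names(coup)) {
      cg <- coup[[g]]
      addt(cg$rows, cg$cols, rep(-Tn / rs_coll[[g]], length(cg$rows)) *
             svec[cg$cols])
    }
    # activation collocation: rate(e, a) partials (analytic)
    Ac <- up$a[-1, , drop = FALSE]
    ar <- activation_rate(up$u_e, Ac, grad = TRUE)
    for (j in seq_len(nmus)) {
      rows <- coll_off$a + (j - 1) * nc + seq_len(nc)
      ce <- lay$Mctrl$e[, j]
      ca <- lay$Mstate$a[-1, j]
      addt(rows, ce, -Tn * ar$de[, j] * svec[ce] / rs_coll$a)
      addt(rows, ca, -Tn * ar$da[, j] * svec[ca] / rs_coll$a)
    }
    if (has_mpk) {
      rows <- coll_off$ampk + seq_len(nc)
      ce <- lay$Mctrl$empk[, 1]; ca <- lay$Mstate$ampk[-1, 1]
      tau <- model$prosthesis$tau_mpk
      addt(rows, ce, rep(-Tn / tau / rs_coll$ampk, nc) * svec[ce])
      addt(rows, ca, rep(Tn / tau / rs_coll$ampk, nc) * svec[ca])
    }
    # T column: -f/n for every collocation equation
    for (g in names(state_dims)) {
      fvals <- as.vector(rhs[[g]])
      addt(coll_rows_all[[g]], rep(iT, length(fvals)),
           -fvals / n * svec[iT] / rs_coll[[g]])
    }
    # residual-actuator penalty gradient (analytic)
    for (j in seq_len(nq)) {
      cols <- lay$Mctrl$res[, j]
      grad[cols] <- grad[cols] +
        cost_fac * 2 * w_res * up$u_res[, j] * svec[cols[1]]
    }
    # FD sweeps for skel/hill blocks and the cost gradient
    for (cl in classes) {
      zp <- z
      zp[cl$cols] <- zp[cl$cols] + h_fd
      pp <- path_eval(unpack(zp))
      if (cl$skel) {
        dr <- (pp$skel - base$path$skel) / h_fd
        for (dd in seq_len(nq)) {
          rows <- skel_off + (dd - 1) * nc + seq_len(nc)
          addt(rows, cl$cols, dr[, dd])
        }
      }
      for (mm in cl$hill_m) {
        dr <- (pp$hill[, mm] - base$path$hill[, mm]) / h_fd
        rows <- hill_off + (mm - 1) * nc + seq_len(nc)
        addt(rows, cl$cols, dr)
      }
      if (cl$cost) {
        dcost <- (pp$cost - base$path$cost) / h_fd
        grad[cl$cols] <- grad[cl$cols] + cost_fac * dcost
      }
    }
    J <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]),
                              j = unlist(tj[seq_len(nt)]),
                              x = unlist(tx[seq_len(nt)]),
                              dims = c(m_con, lay$n))
    list(grad = grad, J = J)
  }

  # diagonal objective curvature model (constant, scaled units)
  Df <- rep(1e-8, lay$n)
  wbar <- mean(cost_fac)
  Df[lay$Mstate$a[-1, ]] <- 2 * W$w_p1 * wbar * 0.5^2
  Df[lay$Mctrl$qdd] <- 2 * W$w_p3 * wbar * 100^2
  Df[lay$Mctrl$ftd] <- 2 * W$w_p4 * wbar * 10^2
  Df[lay$Mctrl$res] <- 2 * w_res * wbar * 50^2
  Df[lay$Mctrl$e] <- 2 * W$w_p4 * wbar * (1 / 0.015)^2 * 0.5^2 * 0.01
  if (has_mpk) Df[lay$Mctrl$empk] <- 2 * W$w_p5 * wbar * 0.5^2

  # --- bounds -------------------------------------------------------------
  lb <- rep(-Inf, lay$n); ub <- rep(Inf, lay$n)
  y0 <- model$segments$thigh_il$length + model$segments$shank_il$length +
    model$ankle_height
  q_lb <- c(-1, 0.6 * y0, -0.5, deg2rad(-40), deg2rad(-12), deg2rad(-60),
            deg2rad(-40), deg2rad(-12), deg2rad(-60))
  q_ub <- c(6, 1.15 * y0, 0.5, deg2rad(130), deg2rad(150), deg2rad(40),
            deg2rad(130), deg2rad(150), deg2rad(40))
  for (j in seq_len(nq)) {
    lb[lay$Mstate$q[, j]] <- q_lb[j] / sc_state$q[j]
    ub[lay$Mstate$q[, j]] <- q_ub[j] / sc_state$q[j]
  }
  lb[lay$Mstate$qd] <- -25 / 5; ub[lay$Mstate$qd] <- 25 / 5
  lb[lay$Mstate$a] <- 1e-4 / 0.5; ub[lay$Mstate$a] <- 1 / 0.5
  lb[lay$Mstate$ft] <- 0; ub[lay$Mstate$ft] <- 3 / 0.5
  lb[lay$Mctrl$qdd] <- -1500 / 100; ub[lay$Mctrl$qdd] <- 1500 / 100
  lb[lay$Mctrl$ftd] <- -100 / 10; ub[lay$Mctrl$ftd] <- 100 / 10
  lb[lay$Mctrl$e] <- 1e-4 / 0.5; ub[lay$Mctrl$e] <- 1 / 0.5
  lb[lay$Mctrl$res] <- 0; ub[lay$Mctrl$res] <- 0  # opened by continuation
  if (has_mpk) {
    lb[lay$Mstate$ampk] <- 0; ub[lay$Mstate$ampk] <- 1 / 0.5
    lb[lay$Mctrl$empk] <- 0; ub[lay$Mctrl$empk] <- 1 / 0.5
  }
  lb[iT] <- 0.6 / 0.3; ub[iT] <- 1.8 / 0.3

  # --- guess --------------------------------------------------------------
  g <- make_initial_guess(model, pspec)
  if (is.null(g$prior_z)) {
    # replace the template accelerations by forward-dynamics-consistent
    # ones, so the skeletal residual rows start at zero and the initial
    # mismatch sits in the (nearly linear) collocation rows instead
    g$Qdd <- consistent_qdd(model, plan, mus, pas, has_mpk, g)
    g$Qdd <- pmin(pmax(g$Qdd, -500), 500)
  }
  z0 <- numeric(lay$n)
  if (!is.null(g$prior_z)) z0 <- g$prior_z
  else {
    z0[lay$Mstate$q] <- g$Q
    z0[lay$Mstate$qd] <- g$Qd
    z0[lay$Mstate$a] <- g$A
    z0[lay$Mstate$ft] <- g$FT
    z0[lay$Mctrl$qdd] <- g$Qdd
    z0[lay$Mctrl$ftd] <- g$FTd
    z0[lay$Mctrl$e] <- g$E
    if (has_mpk) {
      z0[lay$Mstate$ampk] <- g$ampk
      z0[lay$Mctrl$empk] <- g$empk
    }
    z0[iT] <- g$T0
    z0 <- z0 / svec
  }

  prob <- list(
    n = lay$n,
    fval = function(z) eval_point(z)$fval,
    cons = function(z) eval_point(z)$cons,
    grad_jac = grad_jac,
    hess_diag = function(z) Df,
    dense_cols = iT,
    lb = lb, ub = ub)

  list(prob = prob, z0 = z0, lay = lay, svec = svec, unpack = unpack,
       path_eval = path_eval, cost_fac = cost_fac, iT = iT,
       state_dims = state_dims, ctrl_dims = ctrl_dims, mus = mus,
       has_mpk = has_mpk, sch = sch)
}

#' Predict a periodic gait cycle by optimal control
#'
#' Solves the predictive gait OCP: minimize the weighted sum of squared
#' activations, metabolic rate, joint accelerations, state-derivative
#' regularization and (amputee) MPK excitation, divided by the pelvis
#' forward distance, subject to the collocated skeletal, muscle and MPK
#' dynamics, Hill equilibrium, foot-ground contact, periodicity of all
#' states except the pelvis forward position, and the imposed average gait
#' speed.  The cycle time is a free variable.
#'
#' @param model A `model_spec`.
#' @param pspec A [prediction_problem_spec].
#' @return A `prediction_result` with trajectories at the collocation
#'   nodes, cycle time `T`, forward distance `dist`, per-term objective
#'   breakdown, solver statistics and an independent post-hoc verification
#'   of the dynamics residuals.
#' @export
predict_gait <- function(model, pspec = prediction_problem_spec()) {
  nlp <- build_prediction_nlp(model, pspec)
  ctrl <- modifyList(list(feas_tol = 1e-3, opt_tol = 50, max_iter = 200,
                          time_limit = 600, stage_iter = 60,
                          res_schedule = c(100, 30, 10, 3, 1, 0.3, 0.1, 0),
                          verbose = FALSE),
                     pspec$solver)
  # continuation: solve with bounded residual joint actuators and shrink
  # the bound to zero; the final stage is the exact problem (the residual
  # actuator variables are fixed at zero by their bounds)
  sched <- ctrl$res_schedule
  res_cols <- as.vector(nlp$lay$Mctrl$res)
  res_scale <- nlp$svec[res_cols[1]]
  t_start <- proc.time()[3]
  z <- nlp$z0
  total_iter <- 0L
  lam <- NULL
  for (si in seq_along(sched)) {
    B <- sched[si]
    nlp$prob$lb[res_cols] <- -B / res_scale
    nlp$prob$ub[res_cols] <- B / res_scale
    last <- si == length(sched)
    stage_ctrl <- list(
      feas_tol = if (last) ctrl$feas_tol else max(2e-4, ctrl$feas_tol),
      opt_tol = ctrl$opt_tol,
      max_iter = if (last) ctrl$max_iter else ctrl$stage_iter,
      stop_on_feas = !last,
      verbose = ctrl$verbose,
      time_limit = max(15, ctrl$time_limit - (proc.time()[3] - t_start)))
    sol <- solve_nlp_sqp(nlp$prob, z, stage_ctrl, lambda0 = lam)
    z <- sol$z
    lam <- sol$lambda
    total_iter <- total_iter + sol$iterations
    if (ctrl$verbose)
      message(sprintf("stage %d (res bound %g N m): feas %.2e, f %.5g, %s",
                      si, B, sol$feas, sol$f, sol$status))
    if (proc.time()[3] - t_start > ctrl$time_limit) break
  }
  sol$iterations <- total_iter
  if (sol$feas >= ctrl$feas_tol &&
      proc.time()[3] - t_start < ctrl$time_limit) {
    # feasibility polish: damped minimum-norm Gauss-Newton steps on the
    # constraints alone (zero objective), staying close to the optimum
    prob0 <- nlp$prob
    prob0$fval <- function(z) 0
    prob0$grad_jac <- function(z) {
      gj <- nlp$prob$grad_jac(z)
      gj$grad <- numeric(nlp$prob$n)
      gj
    }
    prob0$hess_diag <- function(z) rep(0.1, nlp$prob$n)
    pol <- solve_nlp_sqp(prob0, z, list(
      feas_tol = ctrl$feas_tol, stop_on_feas = TRUE, opt_tol = 1e-8,
      freeze_at_bounds = TRUE, max_iter = 50, verbose = ctrl$verbose,
      time_limit = max(15, ctrl$time_limit - (proc.time()[3] - t_start))),
      lambda0 = NULL)
    if (pol$feas < sol$feas) {
      z <- pol$z
      sol$z <- z
      sol$feas <- pol$feas
      sol$f <- nlp$prob$fval(z)
      sol$status <- pol$status
      total_iter <- total_iter + pol$iterations
      sol$iterations <- total_iter
    }
  }
  # a merit-stalled point that satisfies the feasibility tolerance is a
  # local solution for practical purposes (no further merit descent exists)
  if (sol$feas < ctrl$feas_tol && sol$status %in% c("stalled", "converged"))
    sol$status <- "converged"
  up <- nlp$unpack(sol$z)
  Tcyc <- up$T
  dist <- up$q[nlp$lay$NX, 1] - up$q[1, 1]
  # independent post-hoc verification: re-evaluate the physical residuals
  path <- nlp$path_eval(up)
  verify <- list(
    max_skel_residual = max(abs(path$skel)),
    max_hill_residual = max(abs(path$hill)),
    max_constraint_violation = max(abs(nlp$prob$cons(sol$z))),
    speed_error = abs(dist / Tcyc - pspec$target_speed))
  dofs <- model_dof_names(model)
  s_nodes <- c(0, (rep(seq_len(pspec$n_mesh) - 1, each = pspec$degree) +
                     rep(nlp$sch$tau, pspec$n_mesh)) / pspec$n_mesh)
  traj <- list(
    time = s_nodes * Tcyc, cycle_frac = s_nodes,
    q = structure(up$q, dimnames = list(NULL, dofs)),
    qd = structure(up$qd, dimnames = list(NULL, dofs)),
    qdd = up$u_qdd,
    a = structure(up$a, dimnames = list(NULL,
      vapply(nlp$mus, `[[`, "", "name"))),
    ft = up$ft, ftd = up$u_ftd, e = up$u_e)
  if (nlp$has_mpk) { traj$ampk <- up$ampk; traj$empk <- up$u_empk }
  terms <- prediction_objective_terms(nlp, up, pspec$weights)
  structure(list(
    trajectories = traj, T = Tcyc, dist = dist,
    objective = sol$f, objective_terms = terms,
    converged = identical(sol$status, "converged"),
    solver = list(status = sol$status, iterations = sol$iterations,
                  feasibility = sol$feas, history = sol$history),
    verification = verify, condition = pspec$condition,
    target_speed = pspec$target_speed,
    n_mesh = pspec$n_mesh, degree = pspec$degree,
    z_scaled = sol$z, state_dims_signature = guess_signature(model),
    weights = pspec$weights), class = "prediction_result")
}

# per-term weighted integrals of the prediction objective
prediction_objective_terms <- function(nlp, up, W) {
  # recompute the cost pieces term by term
  saved <- W
  terms <- c(activation = NA, metabolic = NA, acceleration = NA,
             derivatives = NA, mpk_excitation = NA)
  zero <- objective_weights(w_p1 = 0, w_p2 = 0, w_p3 = 0, w_p4 = 0, w_p5 = 0)
  for (nm in names(terms)) {
    Wk <- zero
    sel <- switch(nm, activation = "w_p1", metabolic = "w_p2",
                  acceleration = "w_p3", derivatives = "w_p4",
                  mpk_excitation = "w_p5")
    Wk[[sel]] <- saved[[sel]]
    terms[nm] <- sum(nlp$cost_fac *
                       path_cost_only(nlp, up, Wk))
  }
  c(terms, total = sum(terms))
}

path_cost_only <- function(nlp, up, W) {
  # re-run the path cost with substituted weights
  old <- environment(nlp$path_eval)$W
  environment(nlp$path_eval)$W <- W
  on.exit(environment(nlp$path_eval)$W <- old)
  nlp$path_eval(up)$cost
}

#' Per-term objective breakdown of a prediction
#'
#' Returns the weighted integral of each objective term and the total.  The
#' total matches the solver objective to bookkeeping precision; terms are
#' linear in their weights, so scaling one weight on a fixed trajectory
#' scales that term exactly.
#'
#' @param result A `prediction_result`.
#' @param weights Optional [objective_weights] to re-evaluate the stored
#'   trajectory under different weights (the trajectory is not
#'   re-optimized).
#' @return A data.frame with columns `term` and `value`.
#' @export
objective_breakdown <- function(result, weights = NULL) {
  terms <- result$objective_terms
  if (!is.null(weights)) {
    # scale stored terms by the weight ratios (terms are weight-linear)
    W0 <- result$weights
    ratio <- c(activation = weights$w_p1 / max(W0$w_p1, .Machine$double.xmin),
               metabolic = weights$w_p2 / max(W0$w_p2, .Machine$double.xmin),
               acceleration = weights$w_p3 / max(W0$w_p3, .Machine$double.xmin),
               derivatives = weights$w_p4 / max(W0$w_p4, .Machine$double.xmin),
               mpk_excitation = weights$w_p5 / max(W0$w_p5, .Machine$double.xmin))
    nm <- setdiff(names(terms), "total")
    terms[nm] <- terms[nm] * ratio[nm]
    terms["total"] <- sum(terms[nm])
  }
  data.frame(term = names(terms), value = unname(terms),
             stringsAsFactors = FALSE)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s: %s\n", x$condition,
              if (x$converged) "converged" else x$solver$status))
  cat(sprintf("  cycle time T = %.4f s, dist = %.4f m, speed = %.6f m/s\n",
              x$T, x$dist, x$dist / x$T))
  cat(sprintf("  objective = %.6g, max constraint violation = %.2e\n",
              x$objective, x$solver$feasibility))
  invisible(x)
}
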