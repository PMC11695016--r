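# Muscle-tendon parameter estimation OCP: reproduce measured joint moments
# with the IL hip-spanning muscles while personalizing maximal isometric
# force, optimal fiber length and tendon slack length (bounded multipliers
# on the generic values), solving the muscle redundancy problem.  A reserve
# actuator keeps moment matching feasible and is penalized.

build_estimation_nlp <- function(model, espec, fix_params = FALSE) {
  ds <- espec$dataset
  n <- espec$n_mesh; deg <- espec$degree
  sch <- radau_scheme(deg)
  nc <- n * deg
  W <- espec$weights
  mus_all <- muscle_cache(model)
  keep <- vapply(mus_all, function(mc) {
    kj <- match("hip_il", model_dof_names(model))
    kj %in% mc$jidx
  }, TRUE)
  mus <- mus_all[keep]
  nmus <- length(mus)
  if (nmus == 0) stop("no IL hip-spanning muscles in the model")
  Tcyc <- max(ds$time) - min(ds$time)
  # collocation node times and prescribed kinematics
  t_cn <- min(ds$time) + Tcyc *
    (rep(seq_len(n) - 1, each = deg) + rep(sch$tau, n)) / n
  dofs <- model_dof_names(model)
  hipj <- match("hip_il", dofs)
  qs <- stats::splinefun(ds$time, ds$q[, hipj], method = "periodic")
  q_cn <- qs(t_cn); qd_cn <- qs(t_cn, deriv = 1)
  mom_t <- stats::splinefun(ds$time, ds$moment, method = "periodic")(t_cn)
  # constant musculotendon geometry along the prescribed motion
  geo <- lapply(mus, function(mc) {
    k <- which(mc$jidx == hipj)
    cf <- mc$coefs[[k]]
    l_mt <- mc$l0 + polynomial_eval(cf, q_cn)
    for (kk in seq_along(mc$jidx)) {
      if (kk == k) next
      l_mt <- l_mt + polynomial_eval(mc$coefs[[kk]], 0)
    }
    dl <- polynomial_eval(polynomial_derivative(cf), q_cn)
    list(l_mt = l_mt, v_mt = dl * qd_cn, arm = -dl)
  })

  lay <- ocp_layout(list(a = nmus, ft = nmus),
                    list(e = nmus, ftd = nmus, re = 1L),
                    n, deg, extra = 3L * nmus)
  ipf <- lay$iextra[seq_len(nmus)]
  ipl <- lay$iextra[nmus + seq_len(nmus)]
  ipt <- lay$iextra[2 * nmus + seq_len(nmus)]

  sc_a <- 0.5; sc_ft <- 0.5; sc_e <- 0.5; sc_ftd <- 10; sc_re <- 50
  sc_p <- 1
  svec <- numeric(lay$n)
  svec[lay$Mstate$a] <- sc_a; svec[lay$Mstate$ft] <- sc_ft
  svec[lay$Mctrl$e] <- sc_e; svec[lay$Mctrl$ftd] <- sc_ftd
  svec[lay$Mctrl$re] <- sc_re
  svec[lay$iextra] <- sc_p
  rs_coll <- list(a = 0.3, ft = 0.2)
  rs_hill <- 0.5
  rs_mom <- 50
  rs_per <- list(a = 0.5, ft = 0.5)

  off <- 0L
  coll_off <- list(a = 0L, ft = nmus * nc)
  off <- 2L * nmus * nc
  hill_off <- off; off <- off + nmus * nc
  mom_off <- off; off <- off + nc
  per_off <- off
  nper <- 2L * nmus
  m_con <- off + nper

  wq <- quad_weights(sch, n)
  tfac <- wq * Tcyc / n

  unpack <- function(z) {
    zp <- z * svec
    list(a = matrix(zp[lay$Mstate$a], lay$NX, nmus),
         ft = matrix(zp[lay$Mstate$ft], lay$NX, nmus),
         e = matrix(zp[lay$Mctrl$e], nc, nmus),
         ftd = matrix(zp[lay$Mctrl$ftd], nc, nmus),
         re = zp[lay$Mctrl$re],
         pf = zp[ipf], pl = zp[ipl], pt = zp[ipt])
  }

  path_eval <- function(up) {
    hill <- matrix(0, nc, nmus)
    mom <- -mom_t + up$re
    for (m in seq_len(nmus)) {
      mc <- mus[[m]]
      p <- mc$p
      p$f_max_iso <- p$f_max_iso * up$pf[m]
      p$l_opt <- p$l_opt * up$pl[m]
      p$l_ts <- p$l_ts * up$pt[m]
      hill[, m] <- hill_equilibrium_residual(
        up$a[-1, m], up$ft[-1, m], up$ftd[, m],
        geo[[m]]$l_mt, geo[[m]]$v_mt, p)
      mom <- mom + geo[[m]]$arm * up$ft[-1, m] * p$f_max_iso
    }
    Adot <- activation_rate(up$e, up$a[-1, , drop = FALSE])
    cost <- W$w_e1 * rowSums(up$a[-1, , drop = FALSE]^2) +
      W$w_e3 * up$re^2 +
      W$w_e4 * (rowSums(Adot^2) + rowSums(up$ftd^2))
    # the fiber-length term is time-invariant; fold it into the node cost
    cost <- cost + W$w_e2 * sum(vapply(seq_len(nmus), function(m)
      mus[[m]]$p$l_opt * up$pl[m], 0))
    list(hill = hill / rs_hill, mom = mom / rs_mom, cost = cost)
  }

  cons_impl <- function(up, path) {
    cc <- numeric(m_con)
    Tn <- Tcyc / n
    rhs <- list(a = activation_rate(up$e, up$a[-1, , drop = FALSE]),
                ft = up$ftd)
    for (g in c("a", "ft")) {
      for (j in seq_len(nmus)) {
        Xm <- matrix(up[[g]][as.vector(lay$Rmap), j], n, deg + 1)
        R <- Xm %*% t(sch$D) - Tn * cn_to_interval(rhs[[g]][, j], n, deg)
        cc[coll_off[[g]] + (j - 1) * nc + seq_len(nc)] <-
          as.vector(t(R)) / rs_coll[[g]]
      }
    }
    cc[hill_off + seq_len(nmus * nc)] <- as.vector(path$hill)
    cc[mom_off + seq_len(nc)] <- path$mom
    k <- 0L
    for (g in c("a", "ft")) for (j in seq_len(nmus)) {
      k <- k + 1L
      cc[per_off + k] <- (up[[g]][lay$NX, j] - up[[g]][1, j]) / rs_per[[g]]
    }
    cc
  }

  cache <- new.env(parent = emptyenv())
  eval_point <- function(z) {
    if (!is.null(cache$z) && identical(cache$z, z)) return(cache$val)
    up <- unpack(z)
    path <- path_eval(up)
    val <- list(up = up, path = path, cons = cons_impl(up, path),
                fval = sum(tfac * path$cost))
    cache$z <- z; cache$val <- val
    val
  }

  # constant triplets: D entries and periodicity
  ii <- list(); jj <- list(); xx <- list()
  push <- function(i, j, x) {
    k <- length(ii) + 1
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  for (g in c("a", "ft")) {
    Mg <- lay$Mstate[[g]]
    for (j in seq_len(nmus)) {
      base_rows <- coll_off[[g]] + (j - 1) * nc
      for (k in seq_len(deg)) for (jn in seq_len(deg + 1)) {
        rows <- base_rows + (seq_len(n) - 1) * deg + k
        cols <- Mg[lay$Rmap[, jn], j]
        push(rows, cols, rep(sch$D[k, jn], n) * svec[cols] / rs_coll[[g]])
      }
    }
  }
  Tn <- Tcyc / n
  # ft collocation coupling to ftd (constant since T is fixed)
  for (j in seq_len(nmus)) {
    rows <- coll_off$ft + (j - 1) * nc + seq_len(nc)
    cols <- lay$Mctrl$ftd[, j]
    push(rows, cols, rep(-Tn / rs_coll$ft, nc) * svec[cols])
  }
  k <- 0L
  for (g in c("a", "ft")) for (j in seq_len(nmus)) {
    k <- k + 1L
    cN <- lay$Mstate[[g]][lay$NX, j]; c0 <- lay$Mstate[[g]][1, j]
    push(rep(per_off + k, 2L), c(cN, c0), c(svec[cN], -svec[c0]) / rs_per[[g]])
  }
  const_trip <- list(i = unlist(ii), j = unlist(jj), x = unlist(xx))

  classes <- list()
  add_class <- function(cols, hill_m = integer(0), mom = FALSE,
                        cost = FALSE) {
    classes[[length(classes) + 1]] <<-
      list(cols = cols, hill_m = hill_m, mom = mom, cost = cost)
  }
  for (m in seq_len(nmus)) {
    add_class(lay$Mstate$a[-1, m], hill_m = m, cost = TRUE)
    add_class(lay$Mstate$ft[-1, m], hill_m = m, mom = TRUE)
    add_class(lay$Mctrl$ftd[, m], hill_m = m, cost = TRUE)
    add_class(lay$Mctrl$e[, m], cost = TRUE)
    if (!fix_params) {
      add_class(ipf[m], mom = TRUE)
      add_class(ipl[m], hill_m = m, cost = TRUE)
      add_class(ipt[m], hill_m = m)
    }
  }
  add_class(lay$Mctrl$re[, 1], mom = TRUE, cost = TRUE)

  h_fd <- 1e-6
  grad_jac <- function(z) {
    base <- eval_point(z)
    up <- base$up
    grad <- numeric(lay$n)
    ti <- list(); tj <- list(); tx <- list()
    nt <- 0L
    addt <- function(i, j, x) {
      nt <<- nt + 1L
      ti[[nt]] <<- i; tj[[nt]] <<- j; tx[[nt]] <<- x
    }
    addt(const_trip$i, const_trip$j, const_trip$x)
    ar <- activation_rate(up$e, up$a[-1, , drop = FALSE], grad = TRUE)
    for (j in seq_len(nmus)) {
      rows <- coll_off$a + (j - 1) * nc + seq_len(nc)
      ce <- lay$Mctrl$e[, j]; ca <- lay$Mstate$a[-1, j]
      addt(rows, ce, -Tn * ar$de[, j] * svec[ce] / rs_coll$a)
      addt(rows, ca, -Tn * ar$da[, j] * svec[ca] / rs_coll$a)
    }
    for (cl in classes) {
      zp <- z
      zp[cl$cols] <- zp[cl$cols] + h_fd
      pp <- path_eval(unpack(zp))
      for (mm in cl$hill_m) {
        dr <- (pp$hill[, mm] - base$path$hill[, mm]) / h_fd
        rows <- hill_off + (mm - 1) * nc + seq_len(nc)
        if (length(cl$cols) == 1L) addt(rows, rep(cl$cols, nc), dr)
        else addt(rows, cl$cols, dr)
      }
      if (cl$mom) {
        dr <- (pp$mom - base$path$mom) / h_fd
        rows <- mom_off + seq_len(nc)
        if (length(cl$cols) == 1L) addt(rows, rep(cl$cols, nc), dr)
        else addt(rows, cl$cols, dr)
      }
      if (cl$cost) {
        dcost <- (pp$cost - base$path$cost) / h_fd
        if (length(cl$cols) == 1L)
          grad[cl$cols] <- grad[cl$cols] + sum(tfac * dcost)
        else grad[cl$cols] <- grad[cl$cols] + tfac * dcost
      }
    }
    J <- Matrix::sparseMatrix(i = unlist(ti[seq_len(nt)]),
                              j = unlist(tj[seq_len(nt)]),
                              x = unlist(tx[seq_len(nt)]),
                              dims = c(m_con, lay$n))
    list(grad = grad, J = J)
  }

  Df <- rep(1e-8, lay$n)
  wbar <- mean(tfac)
  Df[lay$Mstate$a[-1, ]] <- 2 * W$w_e1 * wbar * sc_a^2
  Df[lay$Mctrl$re] <- 2 * W$w_e3 * wbar * sc_re^2
  Df[lay$Mctrl$ftd] <- 2 * W$w_e4 * wbar * sc_ftd^2

  lb <- rep(-Inf, lay$n); ub <- rep(Inf, lay$n)
  lb[lay$Mstate$a] <- 1e-4 / sc_a; ub[lay$Mstate$a] <- 1 / sc_a
  lb[lay$Mstate$ft] <- 0; ub[lay$Mstate$ft] <- 3 / sc_ft
  lb[lay$Mctrl$e] <- 1e-4 / sc_e; ub[lay$Mctrl$e] <- 1 / sc_e
  lb[lay$Mctrl$ftd] <- -100 / sc_ftd; ub[lay$Mctrl$ftd] <- 100 / sc_ftd
  lb[lay$Mctrl$re] <- -espec$reserve_bound / sc_re
  ub[lay$Mctrl$re] <- espec$reserve_bound / sc_re
  pb <- if (fix_params) c(1, 1) else espec$param_bounds
  lb[lay$iextra] <- pb[1] / sc_p; ub[lay$iextra] <- pb[2] / sc_p

  # guess: generic parameters, low activation, equilibrium forces
  z0 <- numeric(lay$n)
  a0 <- 0.1
  A0 <- matrix(a0, lay$NX, nmus)
  FT0 <- matrix(0, lay$NX, nmus)
  for (m in seq_len(nmus)) {
    lq <- stats::splinefun(t_cn, geo[[m]]$l_mt)(
      c(min(ds$time), t_cn))
    FT0[, m] <- muscle_equilibrium_ftilde(a0, lq, 0, mus[[m]]$p)
  }
  z0[lay$Mstate$a] <- A0; z0[lay$Mstate$ft] <- FT0
  z0[lay$Mctrl$e] <- a0
  z0[lay$iextra] <- 1
  z0 <- z0 / svec

  prob <- list(n = lay$n,
               fval = function(z) eval_point(z)$fval,
               cons = function(z) eval_point(z)$cons,
               grad_jac = grad_jac,
               hess_diag = function(z) Df,
               lb = lb, ub = ub)
  list(prob = prob, z0 = z0, lay = lay, svec = svec, unpack = unpack,
       path_eval = path_eval, mus = mus, t_cn = t_cn, mom_t = mom_t,
       tfac = tfac, rs_mom = rs_mom)
}

#' Estimate personalized muscle-tendon parameters
#'
#' Solves the parameter-estimation OCP: reproduce the given joint-moment
#' trajectory with the IL hip-spanning muscles (Hill equilibrium and
#' activation dynamics collocated along the prescribed kinematics) while
#' minimizing activations squared, optimal fiber length, the squared
#' reserve actuator and derivative regularization.  Maximal isometric
#' force, optimal fiber length and tendon slack length are personalized as
#' bounded multipliers of the generic values (default 50% to 200%), with
#' the generic values as the initial guess.
#'
#' @param model A `model_spec` whose IL hip muscles will be personalized.
#' @param espec An [estimation_problem_spec].
#' @param fix_params If TRUE the multipliers are frozen at 1 (generic
#'   model); used to quantify the improvement of personalization.
#' @return An `estimation_result`: `parameters` (data.frame of multipliers
#'   per muscle), `activations`, `f_tilde`, `reserve` trajectories,
#'   `reserve_rms` (N m), `moment_rms` residual (N m), `objective`,
#'   `converged` and solver statistics.
#' @export
estimate_parameters <- function(model, espec, fix_params = FALSE) {
  nlp <- build_estimation_nlp(model, espec, fix_params)
  ctrl <- modifyList(list(feas_tol = 1e-6, opt_tol = 1e-2, max_outer = 30,
                          max_inner = 25, rho0 = 100, time_limit = 100),
                     espec$solver)
  sol <- solve_nlp_al(nlp$prob, nlp$z0, ctrl)
  up <- nlp$unpack(sol$z)
  path <- nlp$path_eval(up)
  pars <- data.frame(
    muscle = vapply(nlp$mus, `[[`, "", "name"),
    f_max_ratio = up$pf, l_opt_ratio = up$pl, l_ts_ratio = up$pt,
    stringsAsFactors = FALSE)
  structure(list(
    parameters = pars,
    activations = up$a, f_tilde = up$ft, reserve = up$re,
    reserve_rms = sqrt(mean(up$re^2)),
    moment_rms = sqrt(mean((path$mom * nlp$rs_mom)^2)),
    objective = sol$f,
    converged = identical(sol$status, "converged"),
    solver = list(status = sol$status, iterations = sol$iterations,
                  feasibility = sol$feas),
    time = nlp$t_cn), class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s, objective %.5g, reserve RMS %.3g N m\n",
              if (x$converged) "converged" else x$solver$status,
              x$objective, x$reserve_rms))
  print(x$parameters, row.names = FALSE)
  invisible(x)
}
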