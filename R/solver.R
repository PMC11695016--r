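# Augmented-Lagrangian solver for the sparse equality-constrained NLPs
# produced by the collocation transcriptions.
#
#   minimize f(z)   s.t.  c(z) = 0,  lb <= z <= ub
#
# Inner iterations minimize the augmented Lagrangian
#   L(z) = f(z) + lambda' c(z) + rho/2 ||c(z)||^2
# by a damped Gauss-Newton step: H = Df + rho J'J + mu I with Df a positive
# diagonal model of the objective curvature and J the (sparse) constraint
# Jacobian supplied by the problem.  Bounds are handled by freezing
# variables whose step would leave an active bound and projecting trial
# points.  Outer iterations update the multipliers (first order) and
# increase rho when feasibility stalls.  The method is deterministic: the
# same problem, guess and options give the same iterates.

#' Solve an equality-constrained NLP by sequential quadratic programming
#'
#' Newton-type steps on the KKT system
#' `[H J'; J -delta I] [d; nu] = [-g; -c]` with `H` a positive diagonal
#' objective-curvature model plus Levenberg damping, and bounds handled by
#' freezing variables at active bounds.  Steps are globalized with an
#' l1-penalty merit function and backtracking.  Converges much faster than
#' the augmented-Lagrangian path on problems whose constraints are nearly
#' linear in most variables (the collocation transcriptions); used as the
#' default for the gait OCPs.
#'
#' @inheritParams solve_nlp_al
#' @return Same structure as [solve_nlp_al()].
#' @export
solve_nlp_sqp <- function(prob, z0, control = list(), lambda0 = NULL) {
  ct <- modifyList(list(feas_tol = 1e-7, opt_tol = 1e-3, max_iter = 150,
                        mu0 = 1e-4, nu = 10, verbose = FALSE,
                        time_limit = Inf, kkt_delta = 1e-7),
                   control)
  n <- prob$n
  lb <- prob$lb; ub <- prob$ub
  z <- pmin(pmax(z0, lb), ub)
  cc <- prob$cons(z)
  m <- length(cc)
  lambda <- if (is.null(lambda0)) numeric(m) else lambda0
  mu <- ct$mu0
  nu <- ct$nu
  t0 <- proc.time()[3]
  fv <- prob$fval(z)
  status <- "max_iterations"
  hist <- list()
  merit <- function(f, c) f + nu * sum(abs(c))
  it <- 0L
  while (it < ct$max_iter) {
    it <- it + 1L
    gj <- prob$grad_jac(z)
    J <- gj$J; g <- gj$grad
    gl <- g + as.vector(Matrix::crossprod(J, lambda))
    at_bound <- z <= lb + 1e-12 | z >= ub - 1e-12
    if (isTRUE(ct$freeze_at_bounds)) {
      free <- !at_bound
    } else {
      at_lo <- z <= lb + 1e-12 & gl > 0
      at_hi <- z >= ub - 1e-12 & gl < 0
      free <- !(at_lo | at_hi)
    }
    feas <- max(abs(cc))
    pg <- if (any(free)) max(abs(gl[free])) else 0
    hist[[it]] <- c(f = fv, feas = feas, pg = pg)
    if (ct$verbose && (it %% 10 == 0 || it <= 3))
      message(sprintf("sqp %3d: f=%.6e feas=%.3e pg=%.2e mu=%.1e",
                      it, fv, feas, pg, mu))
    if (feas < ct$feas_tol &&
        (pg < ct$opt_tol || isTRUE(ct$stop_on_feas))) {
      status <- "converged"
      break
    }
    if (proc.time()[3] - t0 > ct$time_limit) { status <- "time_limit"; break }
    Df <- if (is.null(prob$hess_diag)) rep(1e-6, n) else prob$hess_diag(z)
    idx <- which(free)
    nf <- length(idx)
    # columns declared dense (e.g. the free cycle time, which appears in
    # every collocation row) are split off and handled by a low-rank
    # Woodbury update, keeping the Schur complement sparse
    dsel <- idx %in% (prob$dense_cols %||% integer(0))
    isp <- idx[!dsel]; idn <- idx[dsel]
    Js <- J[, isp, drop = FALSE]
    U <- as.matrix(J[, idn, drop = FALSE])
    k <- length(idn)
    accepted <- FALSE
    for (reg in 1:12) {
      # H is diagonal, so the KKT system reduces to the SPD Schur
      # complement (J H^-1 J' + delta I) lam = c - J H^-1 g
      hs <- Df[isp] + mu
      hd <- Df[idn] + mu
      JH <- Js %*% Matrix::Diagonal(length(isp), 1 / hs)
      S0 <- Matrix::tcrossprod(JH, Js) +
        Matrix::Diagonal(m, ct$kkt_delta * (1 + 1 / mu))
      ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(S0),
                                      LDL = FALSE, super = TRUE, perm = TRUE),
                     error = function(e) NULL)
      if (is.null(ch)) { mu <- max(mu * 100, 1e-2); next }
      rhs <- cc - as.vector(JH %*% g[isp])
      if (k > 0) rhs <- rhs - U %*% (g[idn] / hd)
      y <- as.vector(Matrix::solve(ch, rhs))
      if (k > 0) {
        W <- as.matrix(Matrix::solve(ch, U))
        Cap <- diag(hd, k) + crossprod(U, W)
        lam_new <- y - as.vector(W %*% solve(Cap, crossprod(U, y)))
      } else lam_new <- y
      if (any(!is.finite(lam_new))) { mu <- max(mu * 100, 1e-2); next }
      d <- numeric(n)
      d[isp] <- -(g[isp] + as.vector(Matrix::crossprod(Js, lam_new))) / hs
      if (k > 0)
        d[idn] <- -(g[idn] + as.vector(crossprod(U, lam_new))) / hd
      nu <- max(nu, 1.5 * max(abs(lam_new)), 1)
      phi0 <- merit(fv, cc)
      # directional derivative of the merit along d
      dphi <- sum(g * d) - nu * sum(abs(cc))
      # Schur solve reusing the current factorization (Woodbury for the
      # dense columns); used for the second-order correction below
      schur_solve <- function(r) {
        y <- as.vector(Matrix::solve(ch, r))
        if (k > 0) y - as.vector(W %*% solve(Cap, crossprod(U, y))) else y
      }
      alpha <- 1
      soc_done <- FALSE
      for (ls in 1:8) {
        zt <- pmin(pmax(z + alpha * d, lb), ub)
        cct <- prob$cons(zt)
        fvt <- prob$fval(zt)
        pht <- merit(fvt, cct)
        if (is.finite(pht) && pht <= phi0 + 1e-4 * alpha * min(dphi, 0)) {
          accepted <- TRUE
          break
        }
        if (alpha == 1 && !soc_done && all(is.finite(cct))) {
          # second-order correction: cancel the constraint curvature picked
          # up along the full step, without recomputing the Jacobian
          soc_done <- TRUE
          wsoc <- schur_solve(cct)
          dsoc <- numeric(n)
          dsoc[isp] <- -as.vector(Matrix::crossprod(Js, wsoc)) / hs
          if (k > 0) dsoc[idn] <- -as.vector(crossprod(U, wsoc)) / hd
          zt2 <- pmin(pmax(z + d + dsoc, lb), ub)
          cct2 <- prob$cons(zt2)
          fvt2 <- prob$fval(zt2)
          pht2 <- merit(fvt2, cct2)
          if (is.finite(pht2) && pht2 <= phi0 + 1e-4 * min(dphi, 0)) {
            zt <- zt2; cct <- cct2; fvt <- fvt2
            accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (accepted) {
        z <- zt; cc <- cct; fv <- fvt
        lambda <- (1 - alpha) * lambda + alpha * lam_new
        mu <- if (alpha == 1) max(mu * 0.3, 1e-8) else mu * 2
        break
      }
      mu <- mu * 10
    }
    if (!accepted) { status <- "stalled"; break }
  }
  list(z = z, lambda = lambda, f = fv, feas = max(abs(cc)),
       status = status, iterations = it, rho = NA,
       history = do.call(rbind, hist))
}

#' Solve an equality-constrained NLP with an augmented-Lagrangian method
#'
#' @param prob A list describing the problem: `n` (number of variables);
#'   `fval(z)` returning the objective; `grad_jac(z)` returning
#'   `list(grad = objective gradient, J = sparse constraint Jacobian)`;
#'   `cons(z)` returning the constraint vector; `hess_diag(z)` (optional)
#'   returning a positive diagonal curvature model of the objective; `lb`,
#'   `ub` bound vectors.
#' @param z0 Starting point (projected into the bounds).
#' @param lambda0 Optional warm-start multipliers (length = number of
#'   constraints).
#' @param control List of options: `feas_tol` (max-norm of the scaled
#'   constraints, default 1e-7), `opt_tol` (projected-gradient tolerance,
#'   default 1e-3), `max_outer`, `max_inner`, `rho0`, `rho_max`,
#'   `time_limit` (seconds), `verbose`.
#' @return List with `z`, `lambda`, `f`, `feas` (final max constraint
#'   violation), `status` (`"converged"`, `"max_iterations"`,
#'   `"time_limit"` or `"stalled"`), `iterations` and `history`.
#' @export
solve_nlp_al <- function(prob, z0, control = list(), lambda0 = NULL) {
  ct <- modifyList(list(feas_tol = 1e-7, opt_tol = 1e-3, max_outer = 30,
                        max_inner = 25, rho0 = 10, rho_max = 1e9,
                        mu0 = 1e-3, verbose = FALSE, time_limit = Inf),
                   control)
  n <- prob$n
  lb <- prob$lb; ub <- prob$ub
  z <- pmin(pmax(z0, lb), ub)
  cc <- prob$cons(z)
  m <- length(cc)
  lambda <- if (is.null(lambda0)) numeric(m) else lambda0
  rho <- ct$rho0
  mu <- ct$mu0
  t0 <- proc.time()[3]
  feas_prev <- max(abs(cc))
  hist <- list()
  status <- "max_iterations"
  total_inner <- 0
  fv <- prob$fval(z)
  timed_out <- FALSE

  al_val <- function(fval, cc) fval + sum(lambda * cc) + 0.5 * rho * sum(cc^2)

  for (outer in seq_len(ct$max_outer)) {
    inner_converged <- FALSE
    for (inner in seq_len(ct$max_inner)) {
      total_inner <- total_inner + 1
      gj <- prob$grad_jac(z)
      J <- gj$J
      gal <- gj$grad + as.vector(Matrix::crossprod(J, lambda + rho * cc))
      at_lo <- z <= lb + 1e-12 & gal > 0
      at_hi <- z >= ub - 1e-12 & gal < 0
      free <- !(at_lo | at_hi)
      pg <- if (any(free)) max(abs(gal[free])) else 0
      feas <- max(abs(cc))
      if (pg < ct$opt_tol * max(1, sqrt(rho) * feas_prev) || pg < ct$opt_tol) {
        inner_converged <- TRUE
        break
      }
      Df <- if (is.null(prob$hess_diag)) rep(1e-6, n) else prob$hess_diag(z)
      Hbase <- rho * Matrix::crossprod(J)
      dH <- Matrix::diag(Hbase) + Df
      idx <- which(free)
      Hf <- Hbase[idx, idx]
      gf <- gal[idx]
      accepted <- FALSE
      L0 <- al_val(fv, cc)
      # Levenberg-Marquardt: damp until the quadratic model is trusted
      for (reg in 1:10) {
        Hd <- Hf + Matrix::Diagonal(length(idx),
                                    (Df + mu * (1 + dH))[idx])
        df <- tryCatch(as.vector(Matrix::solve(Hd, -gf)),
                       error = function(e) NULL)
        if (is.null(df) || any(!is.finite(df))) { mu <- max(mu * 100, 1); next }
        d <- numeric(n); d[idx] <- df
        zt <- pmin(pmax(z + d, lb), ub)
        dd <- zt - z
        cct <- prob$cons(zt)
        fvt <- prob$fval(zt)
        Lt <- al_val(fvt, cct)
        ddf <- dd[idx]
        pred <- -(sum(gf * ddf) +
                    0.5 * sum(ddf * as.vector(Hd %*% ddf)))
        ared <- L0 - Lt
        if (is.finite(Lt) && ared > 0 && pred > 0) {
          accepted <- TRUE
          ratio <- ared / pred
          mu <- if (ratio > 0.75) max(mu * 0.33, 1e-10) else
            if (ratio < 0.25) mu * 3 else mu
          break
        }
        mu <- mu * 8
      }
      if (!accepted) break  # inner cannot progress; let the outer react
      z <- zt; cc <- cct; fv <- fvt
      if (proc.time()[3] - t0 > ct$time_limit) { timed_out <- TRUE; break }
    }
    feas <- max(abs(cc))
    if (ct$verbose)
      message(sprintf("outer %2d: f=%.6e feas=%.3e rho=%.1e inner=%d mu=%.1e",
                      outer, fv, feas, rho, inner, mu))
    hist[[outer]] <- c(f = fv, feas = feas, rho = rho)
    if (feas < ct$feas_tol && inner_converged) { status <- "converged"; break }
    if (timed_out || proc.time()[3] - t0 > ct$time_limit) {
      status <- "time_limit"
      break
    }
    if (feas <= max(ct$feas_tol, 0.25 * feas_prev)) {
      # good progress: first-order multiplier update
      lambda <- lambda + rho * cc
      feas_prev <- feas
    } else {
      # feasibility stalled: raise the penalty, keep the multipliers
      rho <- min(rho * 5, ct$rho_max)
    }
  }
  list(z = z, lambda = lambda, f = fv, feas = max(abs(cc)),
       status = status, iterations = total_inner, rho = rho,
       history = do.call(rbind, hist))
}
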