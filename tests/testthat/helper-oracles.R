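# Independent oracles used by the tests.  These deliberately re-derive
# quantities with different algorithms/algebra than the package code paths.

# Bisection on the Hill equilibrium residual at zero force rate: the
# reference solver for the static tendon force (the package uses its own
# vectorized bisection; this one is a plain scalar loop kept independent).
oracle_hill_bisect <- function(a, l_mt, p, lo = 0, hi = 5, iters = 200) {
  f <- function(ft) hill_equilibrium_residual(a, ft, 0, l_mt, 0, p)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Closed-form static gravity compensation of a hanging 2-link chain
# (thigh + shank, foot massless), derived by hand from the potential
# energy; independent of the package's lever-term machinery.
oracle_two_link_gravity <- function(model, theta, q_hip, q_knee) {
  g <- model$gravity
  th <- model$segments$thigh_il
  sh <- model$segments$shank_il
  phi_th <- theta + q_hip
  phi_sh <- theta + q_hip - q_knee
  tau_hip <- g * sin(phi_th) * (th$mass * th$com_offset + sh$mass * th$length) +
    g * sin(phi_sh) * sh$mass * sh$com_offset
  tau_knee <- -g * sin(phi_sh) * sh$mass * sh$com_offset
  list(hip = tau_hip, knee = tau_knee)
}

# Exhaustive sign-flip enumeration for the paired SPM maximum statistic,
# written directly from the definition (per-permutation loop, explicit
# t computation) rather than the package's vectorized path.
oracle_spm_exhaustive <- function(A, B, alpha = 0.05) {
  D <- A - B
  n <- nrow(D)
  t_curve <- function(Dm) {
    apply(Dm, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) 0 else mean(col) / (s / sqrt(length(col)))
    })
  }
  maxstats <- numeric(2^n)
  for (k in seq_len(2^n)) {
    bits <- as.integer(intToBits(k - 1))[seq_len(n)]
    signs <- ifelse(bits == 1, -1, 1)
    maxstats[k] <- max(abs(t_curve(signs * D)))
  }
  t_crit <- as.numeric(stats::quantile(maxstats, 1 - alpha, type = 1))
  list(maxstats = sort(maxstats), t_crit = t_crit,
       t_obs = t_curve(D))
}

# Unbanded DTW (full dynamic program, no Sakoe-Chiba restriction)
oracle_dtw_unbanded <- function(x, y) {
  N <- length(x); M <- length(y)
  D <- matrix(Inf, N, M)
  D[1, 1] <- abs(x[1] - y[1])
  for (i in seq_len(N)) for (j in seq_len(M)) {
    if (i == 1 && j == 1) next
    best <- Inf
    if (i > 1) best <- min(best, D[i - 1, j])
    if (j > 1) best <- min(best, D[i, j - 1])
    if (i > 1 && j > 1) best <- min(best, D[i - 1, j - 1])
    D[i, j] <- abs(x[i] - y[j]) + best
  }
  D[N, M]
}

# total mechanical energy of the model in a given state (independent
# kinematics: explicit per-segment positions, not the package lever terms)
oracle_mech_energy <- function(model, q, qd) {
  g <- model$gravity
  dofs <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
            "hip_il", "knee_il", "ankle_il", "hip_cl", "knee_cl", "ankle_cl")
  qn <- stats::setNames(q, dofs); qdn <- stats::setNames(qd, dofs)
  E <- 0
  h <- 1e-6
  # kinetic energy by central differencing the positions along time
  pos_all <- function(qv) {
    out <- list()
    segs <- model$segments
    th_l <- segs$thigh_il$length; sh_l <- segs$shank_il$length
    for (side in c("il", "cl")) {
      phi_th <- qv["pelvis_tilt"] + qv[paste0("hip_", side)]
      phi_sh <- phi_th - qv[paste0("knee_", side)]
      phi_ft <- phi_sh + qv[paste0("ankle_", side)]
      hipxy <- c(qv["pelvis_tx"], qv["pelvis_ty"])
      knee <- hipxy + th_l * c(sin(phi_th), -cos(phi_th))
      ankle <- knee + sh_l * c(sin(phi_sh), -cos(phi_sh))
      th <- segs[[paste0("thigh_", side)]]
      sh <- segs[[paste0("shank_", side)]]
      ftg <- segs[[paste0("foot_", side)]]
      com_ft_local <- c(0.25 * ftg$length, -0.03)
      Rf <- matrix(c(cos(phi_ft), sin(phi_ft), -sin(phi_ft), cos(phi_ft)), 2)
      out[[paste0("thigh_", side)]] <-
        list(p = hipxy + th$com_offset * c(sin(phi_th), -cos(phi_th)),
             phi = phi_th, m = th$mass, I = th$inertia_zz)
      out[[paste0("shank_", side)]] <-
        list(p = knee + sh$com_offset * c(sin(phi_sh), -cos(phi_sh)),
             phi = phi_sh, m = sh$mass, I = sh$inertia_zz)
      out[[paste0("foot_", side)]] <-
        list(p = ankle + as.vector(Rf %*% com_ft_local),
             phi = phi_ft, m = ftg$mass, I = ftg$inertia_zz)
    }
    hat <- segs$hat
    out$hat <- list(
      p = c(qv["pelvis_tx"], qv["pelvis_ty"]) +
        hat$com_offset * c(-sin(qv["pelvis_tilt"]), cos(qv["pelvis_tilt"])),
      phi = qv["pelvis_tilt"], m = hat$mass, I = hat$inertia_zz)
    out
  }
  p0 <- pos_all(qn - h * qdn)
  p1 <- pos_all(qn + h * qdn)
  pc <- pos_all(qn)
  for (nm in names(pc)) {
    v <- (p1[[nm]]$p - p0[[nm]]$p) / (2 * h)
    w <- (p1[[nm]]$phi - p0[[nm]]$phi) / (2 * h)
    E <- E + 0.5 * pc[[nm]]$m * sum(v^2) + 0.5 * pc[[nm]]$I * w^2 +
      pc[[nm]]$m * g * pc[[nm]]$p[2]
  }
  unname(E)
}
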