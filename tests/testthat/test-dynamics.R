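test_that("passive joint moment resists beyond the limits and damps", {
  p <- passive_moment_params(k1 = 1, k2 = 15, q_lower = -0.5, q_upper = 2,
                             b = 0.2)
  # midway between the limits the moment is negligible
  expect_lt(abs(passive_joint_moment(0.75, 0, p)), 0.01)
  # beyond the flexion limit the moment opposes and grows with the excess
  m10 <- passive_joint_moment(p$q_upper + deg2rad(10), 0, p)
  m5 <- passive_joint_moment(p$q_upper + deg2rad(5), 0, p)
  expect_lt(m10, 0)
  expect_gt(abs(m10), abs(m5))
  # pure damping at mid-range
  expect_equal(passive_joint_moment(0.75, 1, p), -p$b, tolerance = 1e-4)
  # linear spring term
  pl <- passive_moment_params(k_lin = 300, q_lower = -2, q_upper = 2.5)
  expect_equal(passive_joint_moment(0.1, 0, pl),
               passive_joint_moment(0.1, 0, passive_moment_params(
                 q_lower = -2, q_upper = 2.5)) - 30, tolerance = 1e-9)
})

test_that("MPK damper follows the bilinear law and only dissipates", {
  expect_equal(mpk_damper_moment(1, 1.0, 1), 1.0)
  expect_equal(mpk_damper_moment(0.5, 0.75, -2), -0.75)
  expect_equal(mpk_damper_moment(0, 0.9, 100), 0)
  # dissipativity: T_mpk * qdot >= 0 for any state
  set.seed(1)
  qd <- runif(50, -10, 10); a <- runif(50); d <- runif(50, 0, 2)
  expect_true(all(mpk_damper_moment(a, d, qd) * qd >= 0))
})

test_that("Hunt-Crossley contact matches the compliance law", {
  cs <- list(radius = 0.03, stiffness = 3e5, dissipation = 1, mu = 0.9,
             v_t = 0.2)
  # fully above ground: forces below the smoothing floor
  f <- hunt_crossley_force(c(0, 0.1), c(0, 0), cs)
  expect_lt(abs(f[1, 2]), 1e-6)
  # static penetration: k * delta^(3/2)
  delta <- 0.01
  f <- hunt_crossley_force(c(0, cs$radius - delta), c(0, 0), cs)
  expect_equal(unname(f[1, 2]), cs$stiffness * delta^1.5, tolerance = 1e-3)
  # rapid separation never produces adhesion
  f <- hunt_crossley_force(c(0, cs$radius - delta), c(0, 5), cs)
  expect_gte(f[1, 2], 0)
  # normal force nondecreasing in penetration at zero velocity
  ds <- seq(0, 0.02, length.out = 30)
  fn <- hunt_crossley_force(cbind(0, cs$radius - ds), cbind(0, 0), cs)[, 2]
  expect_true(all(diff(fn) >= 0))
})

test_that("skeletal residual matches the hanging two-link closed form", {
  m <- build_reference_model(77.8, 1.81)
  # make the foot massless so the chain is exactly two links
  m$segments$foot_il$mass <- 0; m$segments$foot_il$inertia_zz <- 0
  m$segments$foot_cl$mass <- 0; m$segments$foot_cl$inertia_zz <- 0
  m$segments$hat$mass <- 0; m$segments$hat$inertia_zz <- 0
  for (pose in list(c(0.1, 0.3, 0.2), c(0, 0.7, 0.5), c(-0.2, -0.1, 0.4))) {
    q <- numeric(9)
    q[3] <- pose[1]; q[4] <- pose[2]; q[5] <- pose[3]
    orc <- oracle_two_link_gravity(m, pose[1], pose[2], pose[3])
    tau <- numeric(9)
    tau[4] <- orc$hip; tau[5] <- orc$knee
    # contralateral leg hangs straight down: gravity needs no torque there
    res <- skeletal_dynamics_residual(m, q, numeric(9), numeric(9),
                                      joint_moments = tau)
    expect_lt(max(abs(res[4:5])), 1e-9)
  }
  # no gravity, no motion, no forces: identically zero residual
  m0 <- build_reference_model(77.8, 1.81)
  m0$gravity <- 0
  res <- skeletal_dynamics_residual(m0, runif(9, -0.3, 0.3), numeric(9),
                                    numeric(9))
  expect_lt(max(abs(res)), 1e-9)
})

test_that("forward dynamics conserves energy in passive ballistic motion", {
  skip_if_not_installed("deSolve")
  m <- build_reference_model(77.8, 1.81)
  q0 <- c(0, 1, 0.05, 0.3, 0.4, -0.1, -0.2, 0.1, 0.05)
  qd0 <- c(0.1, 0, 0.2, -0.5, 0.3, 0.1, 0.4, -0.2, 0)
  rhs <- function(t, y, parms) {
    q <- y[1:9]; qd <- y[10:18]
    list(c(qd, forward_dynamics(m, q, qd)))
  }
  out <- deSolve::ode(c(q0, qd0), c(0, 0.5), rhs, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-11)
  E0 <- oracle_mech_energy(m, q0, qd0)
  E1 <- oracle_mech_energy(m, out[2, 2:10], out[2, 11:19])
  expect_lt(abs(E1 - E0), 1e-6 * max(1, abs(E0)))
})

test_that("muscle geometry is consistent between length rate and moment arms", {
  m <- build_reference_model(77.8, 1.81)
  set.seed(7)
  q <- runif(9, -0.4, 0.4); qd <- runif(9, -2, 2)
  for (nm in c("gastroc_il", "rectfem_cl", "soleus_il")) {
    geo <- muscle_geometry(m, nm, q, qd)
    jidx <- match(m$muscles[[nm]]$spanned_joints, model_dof_names(m))
    v_expect <- -sum(geo$moment_arms[1, ] * qd[jidx])
    expect_equal(geo$v_mt, v_expect, tolerance = 1e-12)
  }
  # zero velocity gives zero lengthening rate
  expect_equal(muscle_geometry(m, "vasti_il", q, q * 0)$v_mt, 0)
})
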