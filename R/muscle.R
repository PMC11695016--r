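# Hill-type muscle-tendon model with compliant tendon in implicit form.
#
# States per muscle: activation a in [0, 1] and normalized tendon force
# f_tilde = F_tendon / F_max_iso >= 0.  The tendon force-length curve is an
# exponential, which is inverted in closed form so that the fiber length is
# an explicit function of (l_mt, f_tilde); the tendon lengthening rate then
# enters through the time derivative of f_tilde, making d(f_tilde)/dt a
# control of the optimal-control problem.  All curves are smooth closed
# forms: Gaussian active force-length, exponential passive force-length,
# logistic force-velocity with an eccentric plateau of 1.4, and exponential
# tendon with 4.9% strain at maximal isometric force.

hill_constants <- function() {
  list(
    kT = 35,                      # tendon exponential shape
    cT = 1 / (exp(35 * 0.049) - 1),  # 4.9% strain at f_tilde = 1
    gamma_fl = 0.2,               # active force-length width
    kpe = 4, e0 = 0.6,            # passive force-length
    fv_max = 1.4, fv_k = 6,       # force-velocity plateau and slope
    fv_b = log(1 / 0.4)           # so that fv(0) = 1
  )
}

tendon_force_length <- function(ltN, hc = hill_constants()) {
  hc$cT * (exp(hc$kT * (ltN - 1)) - 1)
}

# closed-form inverse of the tendon curve: normalized tendon length at a
# given normalized tendon force (>= 0 maps to ltN >= 1)
tendon_length_from_force <- function(f_tilde, hc = hill_constants()) {
  1 + log(f_tilde / hc$cT + 1) / hc$kT
}

active_force_length <- function(lfN, hc = hill_constants()) {
  exp(-(lfN - 1)^2 / hc$gamma_fl)
}

passive_force_length <- function(lfN, hc = hill_constants()) {
  (exp(hc$kpe * (lfN - 1) / hc$e0) - 1) / (exp(hc$kpe) - 1)
}

force_velocity <- function(vN, hc = hill_constants()) {
  hc$fv_max * sigmoid(hc$fv_k * vN + hc$fv_b)
}

#' Fiber state implied by the tendon force
#'
#' Given musculotendon length and normalized tendon force, returns the
#' normalized fiber length, the cosine of the pennation angle, and (given
#' the tendon force rate and musculotendon velocity) the normalized fiber
#' velocity.  Vectorized over all inputs.
#' @noRd
fiber_state <- function(l_mt, v_mt, f_tilde, f_tilde_dot, p,
                        hc = hill_constants()) {
  ltN <- tendon_length_from_force(f_tilde, hc)
  lt <- p$l_ts * ltN
  w <- p$l_opt * sin(p$alpha_opt)
  proj <- l_mt - lt
  # keep the along-tendon fiber projection positive and smooth
  proj_s <- 0.5 * (proj + sqrt(proj^2 + (0.001 * p$l_opt)^2))
  lf <- sqrt(proj_s^2 + w^2)
  cos_a <- proj_s / lf
  lfN <- lf / p$l_opt
  # tendon lengthening rate from d(f_tilde)/dt through the inverse curve
  lt_dot <- p$l_ts * f_tilde_dot / (hc$kT * (f_tilde + hc$cT))
  lf_dot <- (v_mt - lt_dot) * cos_a
  vN <- lf_dot / (p$v_max * p$l_opt)
  list(lfN = lfN, cos_a = cos_a, vN = vN, lf_dot = lf_dot)
}

#' Hill equilibrium residual (implicit compliant-tendon formulation)
#'
#' Zero iff the projected fiber force (active force-length x force-velocity
#' x activation + passive force-length) equals the tendon force implied by
#' the tendon force-length curve at the current force state.  The tendon
#' force rate enters through the tendon lengthening rate, so the residual is
#' an algebraic path constraint of the optimal-control problem.
#'
#' @param a Activation in [0, 1].
#' @param f_tilde Normalized tendon force (>= 0).
#' @param f_tilde_dot Time derivative of `f_tilde` (1/s).
#' @param l_mt Musculotendon length (m).
#' @param v_mt Musculotendon lengthening velocity (m/s).
#' @param p Muscle-tendon parameters: list with `f_max_iso`, `l_opt`,
#'   `l_ts`, `alpha_opt`, `v_max` (the latter in optimal fiber lengths per
#'   second).
#' @return Dimensionless residual (same scale as normalized force).
#'   Vectorized over all numeric arguments.
#' @export
hill_equilibrium_residual <- function(a, f_tilde, f_tilde_dot, l_mt, v_mt, p) {
  hc <- hill_constants()
  fs <- fiber_state(l_mt, v_mt, f_tilde, f_tilde_dot, p, hc)
  fl <- active_force_length(fs$lfN, hc)
  fv <- force_velocity(fs$vN, hc)
  fp <- passive_force_length(fs$lfN, hc)
  (a * fl * fv + fp) * fs$cos_a - f_tilde
}

#' Solve the static Hill equilibrium for the tendon force
#'
#' Finds the unique `f_tilde >= 0` that zeroes
#' [hill_equilibrium_residual()] at `f_tilde_dot = 0`, by bisection.
#' Used to seed muscle force states in initial guesses.
#'
#' @inheritParams hill_equilibrium_residual
#' @param tol Bisection half-width tolerance.
#' @export
muscle_equilibrium_ftilde <- function(a, l_mt, v_mt = 0, p, tol = 1e-12) {
  n <- max(length(a), length(l_mt), length(v_mt))
  a <- rep_len(a, n); l_mt <- rep_len(l_mt, n); v_mt <- rep_len(v_mt, n)
  lo <- rep(0, n); hi <- rep(4, n)
  for (it in 1:60) {
    mid <- 0.5 * (lo + hi)
    r <- hill_equilibrium_residual(a, mid, 0, l_mt, v_mt, p)
    # residual is decreasing in f_tilde
    up <- r > 0
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
    if (max(hi - lo) < tol) break
  }
  0.5 * (lo + hi)
}

# --- Raasch-type activation dynamics -------------------------------------

#' Activation rate with smoothly blended time constants
#'
#' First-order excitation-to-activation dynamics with distinct activation
#' and deactivation time constants, blended smoothly around e = a.
#'
#' @param e Excitation in [0, 1].
#' @param a Activation in [0, 1].
#' @param tau_act,tau_deact Activation / deactivation time constants (s).
#' @param grad If TRUE also return partial derivatives w.r.t. `e` and `a`.
#' @return The rate da/dt (or a list with `val`, `de`, `da`).
#' @export
activation_rate <- function(e, a, tau_act = 0.015, tau_deact = 0.060,
                            grad = FALSE) {
  kb <- 20
  s <- sigmoid(kb * (e - a))
  rate <- s / tau_act + (1 - s) / tau_deact
  val <- (e - a) * rate
  if (!grad) return(val)
  ds <- kb * s * (1 - s)
  drate <- ds * (1 / tau_act - 1 / tau_deact)
  list(val = val,
       de = rate + (e - a) * drate,
       da = -rate - (e - a) * drate)
}

#' Activation dynamics residual
#'
#' `residual = adot - activation_rate(e, a)`; zero defines the feasible
#' activation rate for a given excitation.
#'
#' @param e Excitation in [0, 1].
#' @param a Activation in [0, 1].
#' @param adot Candidate activation time derivative (1/s).
#' @inheritParams activation_rate
#' @export
activation_dynamics_residual <- function(e, a, adot, tau_act = 0.015,
                                         tau_deact = 0.060) {
  adot - activation_rate(e, a, tau_act, tau_deact)
}

# --- metabolic energy rate ------------------------------------------------

#' Metabolic model parameters
#'
#' @param basal_rate Whole-body basal rate (W/kg of body mass).
#' @param sigma Muscle specific tension (Pa), used to derive muscle mass
#'   from maximal isometric force and optimal fiber length.
#' @param rho Muscle density (kg/m^3).
#' @param smoothing Softplus scale (W) for the positive-part terms.
#' @export
metabolic_model_params <- function(basal_rate = 1.2, sigma = 2.5e5,
                                   rho = 1059.7, smoothing = 1) {
  structure(list(basal_rate = basal_rate, sigma = sigma, rho = rho,
                 smoothing = smoothing), class = "metabolic_model_params")
}

muscle_mass <- function(p, mp) p$f_max_iso / mp$sigma * mp$rho * p$l_opt

#' Smooth per-muscle metabolic energy rate
#'
#' Bhargava-style heat terms with softplus smoothing: activation and
#' maintenance heat scale with muscle mass and activation, shortening heat
#' and positive mechanical fiber work use smoothed positive parts.  Always
#' nonnegative and strictly increasing in activation.
#'
#' @param a Activation.
#' @param lfN Normalized fiber length.
#' @param lf_dot Fiber lengthening velocity (m/s, negative when shortening).
#' @param f_fiber Fiber force along the fiber (N).
#' @param p Muscle-tendon parameters.
#' @param mp A `metabolic_model_params`.
#' @return Energy rate in W (per muscle; the whole-body basal rate is added
#'   at the model level).  Vectorized.
#' @export
metabolic_rate <- function(a, lfN, lf_dot, f_fiber, p,
                           mp = metabolic_model_params()) {
  m <- muscle_mass(p, mp)
  hc <- hill_constants()
  h_act <- 40 * a
  h_maint <- 74 * a * active_force_length(lfN, hc)
  shortening <- 0.25 * f_fiber * softplus(-lf_dot, 1e-3 * mp$smoothing)
  work <- softplus(-f_fiber * lf_dot, mp$smoothing)
  m * (h_act + h_maint) + shortening + work
}
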