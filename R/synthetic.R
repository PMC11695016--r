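# Synthetic gait data with known ground truth.
#
# Baseline curves are smooth periodic templates (sums of circularly wrapped
# Gaussian bumps) qualitatively matching normative gait: double-peaked knee
# flexion with a swing peak near 65 degrees, double-bump vertical GRF,
# burst-like EMG envelopes.  Trial-to-trial variability is multiplicative
# amplitude scaling plus a smooth monotone time warp (how real gait trials
# vary); additive white noise is used only for EMG envelopes.  Every
# dataset carries its generating truth so tests can compare against stored
# quantities only.

#' Circularly wrapped Gaussian bump on the unit gait cycle
#' @param s Cycle fraction(s) in [0, 1].
#' @param center,width Bump centre and width in cycle fraction.
#' @export
cyc_gauss <- function(s, center, width) {
  d <- (s - center) %% 1
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

#' Template gait curves
#'
#' Evaluates the smooth periodic templates at cycle fractions `s` (0 =
#' ipsilateral heel strike).  Angles in degrees, GRF in units of body
#' weight, moments in N m per kg body mass, EMG normalized.
#'
#' @param s Vector of cycle fractions in [0, 1].
#' @param knee_peak_deg Swing knee-flexion peak of the template
#'   (default 65).
#' @return A named list of numeric vectors.
#' @export
gait_templates <- function(s, knee_peak_deg = 65) {
  swing_amp <- knee_peak_deg - 3
  list(
    knee_angle = 3 + 15 * cyc_gauss(s, 0.15, 0.07) +
      swing_amp * cyc_gauss(s, 0.72, 0.09),
    hip_angle = 8 + 22 * cos(2 * pi * (s + 0.03)),
    ankle_angle = 10 * cyc_gauss(s, 0.45, 0.12) -
      18 * cyc_gauss(s, 0.62, 0.05) - 5 * cyc_gauss(s, 0.05, 0.03),
    pelvis_tilt = 2 + 1.5 * sin(4 * pi * s),
    grf_v = 1.10 * cyc_gauss(s, 0.17, 0.06) +
      1.05 * cyc_gauss(s, 0.47, 0.06) + 0.80 * cyc_gauss(s, 0.32, 0.09),
    hip_moment = 0.6 * cyc_gauss(s, 0.08, 0.06) -
      0.7 * cyc_gauss(s, 0.45, 0.08) + 0.2 * cyc_gauss(s, 0.85, 0.1),
    knee_moment = 0.45 * cyc_gauss(s, 0.15, 0.06) -
      0.25 * cyc_gauss(s, 0.42, 0.08),
    ankle_moment = -1.5 * cyc_gauss(s, 0.45, 0.10) +
      0.15 * cyc_gauss(s, 0.05, 0.04),
    emg_quadriceps = 0.6 * cyc_gauss(s, 0.12, 0.05) +
      0.25 * cyc_gauss(s, 0.95, 0.05),
    emg_hamstrings = 0.5 * cyc_gauss(s, 0.95, 0.06) +
      0.3 * cyc_gauss(s, 0.15, 0.08),
    emg_gastroc = 0.8 * cyc_gauss(s, 0.40, 0.08),
    emg_tibant = 0.5 * cyc_gauss(s, 0.70, 0.10) +
      0.4 * cyc_gauss(s, 0.02, 0.04)
  )
}

#' Synthetic gait trial configuration
#'
#' @param n_trials Number of repeated trials (the study recorded 5 trials
#'   for the amputee and 7 for the healthy subject).
#' @param seed Integer seed; same seed, same data.
#' @param cycle_time Gait cycle duration (s).
#' @param speed Walking speed (m/s).
#' @param amplitude_sd SD of the multiplicative per-trial amplitude factor
#'   (fraction, default 0.05).
#' @param timing_jitter_sd SD of the smooth time shift in % of the cycle
#'   (default 1).
#' @param effect Optional injected condition effect:
#'   `list(variable=, window=c(start%, end%), offset=)`.
#' @param knee_limit_deg Optional stiff-knee restriction applied to the
#'   knee-angle curves (degrees).
#' @param emg_noise_sd Additive noise SD for EMG envelopes (default 0.02).
#' @export
synthetic_gait_config <- function(n_trials = 7, seed = 1L, cycle_time = 1.1,
                                  speed = 1.48, amplitude_sd = 0.05,
                                  timing_jitter_sd = 1, effect = NULL,
                                  knee_limit_deg = NULL,
                                  emg_noise_sd = 0.02) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (amplitude_sd < 0 || timing_jitter_sd < 0) stop("SDs must be >= 0")
  if (!is.null(effect)) {
    if (any(effect$window < 0) || any(effect$window > 100))
      stop("effect window must lie within [0, 100]")
  }
  structure(list(n_trials = n_trials, seed = as.integer(seed),
                 cycle_time = cycle_time, speed = speed,
                 amplitude_sd = amplitude_sd,
                 timing_jitter_sd = timing_jitter_sd, effect = effect,
                 knee_limit_deg = knee_limit_deg,
                 emg_noise_sd = emg_noise_sd),
            class = "synthetic_gait_config")
}

#' Generate repeated synthetic gait trials
#'
#' @param config A [synthetic_gait_config].
#' @return List with `curves` (named list of [gait_curve_set], one per
#'   template variable; 101 samples per trial, periodic) and `truth`
#'   (per-trial amplitude factors and time-warp parameters, the template
#'   peaks, and any injected effect).
#' @export
generate_trials <- function(config) {
  set.seed(config$seed)
  s <- seq(0, 1, length.out = 101)
  n <- config$n_trials
  amps <- matrix(stats::rnorm(n * 12, 1, config$amplitude_sd), n, 12)
  deltas <- stats::rnorm(n, 0, config$timing_jitter_sd / 100)
  phases <- stats::runif(n, 0, 2 * pi)
  tmpl_names <- names(gait_templates(0))
  curves <- stats::setNames(vector("list", length(tmpl_names)), tmpl_names)
  for (v in seq_along(tmpl_names)) {
    nm <- tmpl_names[v]
    tr <- matrix(0, n, 101)
    for (k in seq_len(n)) {
      warp <- s + deltas[k] * sin(2 * pi * s + phases[k])
      tm <- gait_templates(warp %% 1)
      base <- tm[[nm]]
      if (!is.null(config$effect) && config$effect$variable == nm) {
        wl <- config$effect$window / 100
        mid <- mean(wl); hw <- diff(wl) / 2
        bump <- ifelse(abs(s - mid) < hw,
                       0.5 * (1 + cos(pi * (s - mid) / hw)), 0)
        base <- base + config$effect$offset * bump
      }
      row <- amps[k, v] * base
      if (startsWith(nm, "emg")) {
        noise <- stats::rnorm(101, 0, config$emg_noise_sd)
        noise[101] <- noise[1]  # keep the wrap point periodic
        row <- row + noise
      }
      row[101] <- row[1]
      tr[k, ] <- row
    }
    units <- if (grepl("angle|tilt", nm)) "deg"
    else if (grepl("moment", nm)) "N m/kg"
    else if (nm == "grf_v") "BW" else "normalized"
    curves[[nm]] <- gait_curve_set(tr, label = nm, units = units)
  }
  if (!is.null(config$knee_limit_deg))
    curves$knee_angle <- inject_skg_effect(curves$knee_angle,
                                           config$knee_limit_deg)
  truth <- list(amplitudes = amps, timing_deltas = deltas,
                timing_phases = phases,
                template_peaks = lapply(gait_templates(s), max),
                effect = config$effect,
                knee_limit_deg = config$knee_limit_deg)
  list(curves = curves, truth = truth)
}

#' Impose a stiff-knee restriction on knee-flexion curves
#'
#' Saturates the knee-flexion curve smoothly below `limit_deg` (soft
#' minimum with a 1-degree smoothing scale).  Curves whose maximum already
#' lies at or below the limit are returned unchanged, which also makes the
#' operation idempotent.
#'
#' @param curves A [gait_curve_set] (or matrix/vector) of knee flexion in
#'   degrees, or a named list of curve sets in which case `knee_angle` is
#'   saturated and, if present, an early-stance flexion-moment bump is
#'   added to `knee_moment_cl` (the contralateral compensation seen when
#'   ipsilateral knee flexion is restricted).
#' @param limit_deg Flexion limit in degrees (> 0).
#' @param smooth Softplus smoothing scale in degrees (default 1).
#' @export
inject_skg_effect <- function(curves, limit_deg, smooth = 1) {
  if (limit_deg <= 0) stop("limit_deg must be > 0")
  saturate <- function(x) {
    if (max(x) <= limit_deg) return(x)
    x - softplus(x - limit_deg, smooth)
  }
  if (is.list(curves) && !inherits(curves, "gait_curve_set")) {
    if (!is.null(curves$knee_angle)) {
      cs <- curves$knee_angle
      cs$trials <- t(apply(cs$trials, 1, saturate))
      curves$knee_angle <- cs
    }
    if (!is.null(curves$knee_moment_cl)) {
      s <- seq(0, 1, length.out = 101)
      bump <- 0.15 * cyc_gauss(s, 0.15, 0.06)
      cs <- curves$knee_moment_cl
      cs$trials <- sweep(cs$trials, 2, bump, "+")
      curves$knee_moment_cl <- cs
    }
    return(curves)
  }
  if (inherits(curves, "gait_curve_set")) {
    curves$trials <- t(apply(curves$trials, 1, saturate))
    return(curves)
  }
  if (is.matrix(curves)) return(t(apply(curves, 1, saturate)))
  saturate(curves)
}

#' Synthetic joint-moment dataset with known muscle-tendon truth
#'
#' Builds a hip-moment trajectory that is exactly achievable (zero
#' reserves) by the model with perturbed muscle-tendon parameters: smooth
#' periodic normalized tendon-force curves are chosen per muscle, the
#' corresponding activations are recovered in closed form from the Hill
#' equilibrium, and the moment is the sum of moment arm x tendon force.
#'
#' @param model A `model_spec` (the IL hip-spanning muscles are used).
#' @param truth_multipliers Named list/vector of per-muscle f_max_iso
#'   multipliers (names = muscle names; missing muscles default to 1).
#' @param seed Integer seed for the force-curve shapes.
#' @param cycle_time Duration of the moment trajectory (s).
#' @param n_samples Number of samples (default 101).
#' @return List with `time`, `q` (kinematics matrix), `moment` (hip moment
#'   trajectory, N m) and `truth` (multipliers, force and activation
#'   curves).
#' @export
generate_estimation_dataset <- function(model, truth_multipliers = list(),
                                        seed = 1L, cycle_time = 1.1,
                                        n_samples = 101) {
  set.seed(seed)
  mus <- Filter(function(m) m$side == "il" && "hip_il" %in% m$spanned_joints,
                model$muscles)
  if (length(mus) == 0) stop("model has no IL hip-spanning muscles")
  bounds_warn <- FALSE
  s <- seq(0, 1, length.out = n_samples)
  tt <- s * cycle_time
  dofs <- model_dof_names(model)
  Q <- matrix(0, n_samples, length(dofs), dimnames = list(NULL, dofs))
  tm <- gait_templates(s)
  Q[, "hip_il"] <- deg2rad(tm$hip_angle)
  Qd <- matrix(0, n_samples, length(dofs), dimnames = list(NULL, dofs))
  # analytic-ish derivative of the periodic hip template via FFT would be
  # overkill; central differences on the periodic curve are exact enough
  Qd[, "hip_il"] <- periodic_derivative(Q[, "hip_il"], cycle_time)
  moment <- numeric(n_samples)
  truth_ft <- list(); truth_a <- list()
  mults <- list()
  hc <- hill_constants()
  for (m in mus) {
    mult <- truth_multipliers[[m$name]] %||% 1
    if (mult <= 0) stop("multipliers must be positive")
    if (mult < 0.5 || mult > 2) {
      warning("truth multiplier for ", m$name, " outside the estimation ",
              "bounds [0.5, 2]: recovery cannot reach the truth")
      bounds_warn <- TRUE
    }
    mults[[m$name]] <- mult
    p <- m$params; p$f_max_iso <- p$f_max_iso * mult
    geo <- muscle_geometry(model, m$name, Q, Qd)
    # start from the quasi-static force at a small base activation (this
    # keeps the curve above the passive floor along the whole motion) and
    # superimpose a smooth periodic burst; the burst amplitude is halved
    # until the implied activation stays inside (0, 1)
    ft_base <- muscle_equilibrium_ftilde(0.05, geo$l_mt, geo$v_mt, p)
    ft_base <- stats::filter(c(ft_base, ft_base, ft_base), rep(1 / 5, 5),
                             circular = TRUE)[n_samples + seq_len(n_samples)]
    ft_base <- as.numeric(ft_base)
    ft_base[n_samples] <- ft_base[1]
    c1 <- stats::runif(1, 0.05, 0.95); w1 <- stats::runif(1, 0.08, 0.15)
    bump <- cyc_gauss(s, c1, w1)
    amp <- 0.3
    repeat {
      ft <- ft_base + amp * bump
      ft[n_samples] <- ft[1]
      ftdot <- periodic_derivative(ft, cycle_time)
      fs <- fiber_state(geo$l_mt, geo$v_mt, ft, ftdot, p, hc)
      fl <- active_force_length(fs$lfN, hc)
      fv <- force_velocity(fs$vN, hc)
      fp <- passive_force_length(fs$lfN, hc)
      a <- (ft / fs$cos_a - fp) / (fl * fv)
      if (all(a > 0 & a < 1)) break
      amp <- amp / 2
      if (amp < 1e-3)
        stop("could not construct a feasible activation curve for ", m$name)
    }
    moment <- moment + geo$moment_arms[, "hip_il"] * ft * p$f_max_iso
    truth_ft[[m$name]] <- ft
    truth_a[[m$name]] <- a
  }
  list(time = tt, q = Q, qdot = Qd, moment = moment,
       truth = list(multipliers = mults, f_tilde = truth_ft,
                    activation = truth_a, cycle_time = cycle_time,
                    outside_bounds = bounds_warn))
}

# derivative of a periodic curve sampled on [0, T] (first = last sample)
periodic_derivative <- function(x, period) {
  n <- length(x)
  h <- period / (n - 1)
  xm <- c(x[n - 1], x, x[2])
  (xm[3:(n + 2)] - xm[1:n]) / (2 * h)
}
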