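# Reduced sagittal-plane musculoskeletal model and its clinical variants.
#
# The default model is a bilateral planar chain: a floating pelvis+HAT
# segment (x/y translation + tilt) with hip, knee and ankle pin joints per
# leg and nine Hill-type muscles per leg covering the functional groups
# (uniarticular hip flexor/extensor, biarticular hamstrings / rectus
# femoris / gastrocnemius, vasti, short biceps femoris, soleus, tibialis
# anterior).  Variants model a knee-disarticulation amputee fitted with a
# variable-damping microprocessor knee (MPK) and an energy-storage-and-
# return (ESR) foot, the mirrored "hypothetical healthy" model, and
# stiff-knee-gait (SKG) conditions imposed through the passive joint-limit
# moment.  Angle convention: hip flexion, knee flexion and ankle
# dorsiflexion positive; radians internally, degrees at all file/report
# boundaries.

#' Reference anthropometry table
#'
#' Winter-style segment proportions of the reference adult: mass and length
#' fractions of body mass and height, centre of mass measured from the
#' proximal joint, radius of gyration about the COM (sagittal axis).
#' @export
reference_anthropometry <- function() {
  data.frame(
    segment  = c("hat", "thigh", "shank", "foot"),
    mass_frac = c(0.678, 0.100, 0.0465, 0.0145),
    len_frac  = c(0.288, 0.245, 0.246, 0.152),
    com_frac  = c(0.626, 0.433, 0.433, 0.500),
    rog_frac  = c(0.496, 0.323, 0.302, 0.475),
    stringsAsFactors = FALSE
  )
}

#' Default muscle table of the planar model
#'
#' Constant moment arms (geometry polynomials of degree 1); signs follow
#' the sign convention (moment arm r = -dL/dq, so a positive r produces a
#' positive, i.e. flexion/dorsiflexion, moment).  Values are representative
#' of planar gait models.
#' @export
default_muscle_table <- function() {
  df <- data.frame(
    name  = c("iliopsoas", "glutmax", "hamstrings", "rectfem",
              "vasti", "bifemsh", "gastroc", "soleus", "tibant"),
    f_max_iso = c(1500, 1950, 2600, 1200, 5000, 800, 2500, 3550, 1800),
    l_opt     = c(0.100, 0.140, 0.080, 0.075, 0.080, 0.110, 0.060, 0.050, 0.098),
    l_ts      = c(0.160, 0.125, 0.350, 0.350, 0.230, 0.100, 0.390, 0.250, 0.223),
    alpha_opt = deg2rad(c(8, 5, 0, 5, 3, 23, 17, 25, 5)),
    v_max     = rep(10, 9),
    r_hip   = c( 0.050, -0.062, -0.060,  0.040, 0, 0, 0, 0, 0),
    r_knee  = c( 0, 0,  0.035, -0.040, -0.042,  0.035,  0.020, 0, 0),
    r_ankle = c( 0, 0, 0, 0, 0, 0, -0.050, -0.048,  0.037),
    stringsAsFactors = FALSE
  )
  df
}

#' Passive joint-limit moment parameters
#'
#' Double-exponential joint-limit moment with linear damping and an optional
#' linear spring (the linear spring is used for the MTP joint and the ESR
#' prosthetic ankle).
#'
#' @param k1 Exponential magnitude coefficient (N m).
#' @param k2 Exponential shape coefficient (1/rad).
#' @param q_lower,q_upper Limit angles in radians (`q_lower < q_upper`).
#' @param b Linear damping (N m s / rad).
#' @param k_lin Linear spring stiffness (N m / rad), 0 unless modelling the
#'   MTP joint or the ESR ankle.
#' @export
passive_moment_params <- function(k1 = 1, k2 = 15, q_lower = -0.5, q_upper = 2,
                                  b = 0.2, k_lin = 0) {
  for (nm in c("k1", "k2", "b", "k_lin"))
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  if (q_lower >= q_upper) stop("q_lower must be < q_upper")
  structure(list(k1 = k1, k2 = k2, q_lower = q_lower, q_upper = q_upper,
                 b = b, k_lin = k_lin), class = "passive_moment_params")
}

#' Prosthesis specification (MPK + ESR foot)
#'
#' @param d_mpk MPK damper coefficient (N m s / rad); 1.0 in the optimally
#'   configured (REF) setting, 0.75 when the device is deactivated (DACT).
#' @param tau_mpk MPK activation time constant in seconds (first-order lag).
#' @param mpk_passive Passive moment of the prosthetic knee (hyperextension
#'   stop plus flexion limit, default limit 137.5 degrees).
#' @param esr_passive Passive moment of the prosthetic (ESR) ankle; the
#'   linear spring term reproduces elastic energy storage and return.
#' @param shank_mass_frac,foot_mass_frac Prosthetic segment masses as a
#'   fraction of the intact segment mass (default 0.6; prosthetic components
#'   are lighter than the limb they replace and exact masses are treated as
#'   configurable assumptions).
#' @export
prosthesis_spec <- function(d_mpk = 1.0, tau_mpk = 0.030,
                            mpk_passive = passive_moment_params(
                              k1 = 5, k2 = 20,
                              q_lower = deg2rad(-2), q_upper = deg2rad(137.5),
                              b = 0.3),
                            esr_passive = passive_moment_params(
                              k1 = 1, k2 = 15,
                              q_lower = deg2rad(-40), q_upper = deg2rad(25),
                              b = 1, k_lin = 300),
                            shank_mass_frac = 0.6, foot_mass_frac = 0.6) {
  stopifnot_scalar(d_mpk, "d_mpk", nonneg = TRUE)
  stopifnot_scalar(tau_mpk, "tau_mpk", positive = TRUE)
  structure(list(d_mpk = d_mpk, tau_mpk = tau_mpk, mpk_passive = mpk_passive,
                 esr_passive = esr_passive, shank_mass_frac = shank_mass_frac,
                 foot_mass_frac = foot_mass_frac), class = "prosthesis_spec")
}

default_joint_passive <- function(joint) {
  switch(joint,
    hip   = passive_moment_params(k1 = 1, k2 = 15, q_lower = deg2rad(-20),
                                  q_upper = deg2rad(120), b = 0.5),
    knee  = passive_moment_params(k1 = 1, k2 = 15, q_lower = deg2rad(-5),
                                  q_upper = deg2rad(137.5), b = 0.5),
    ankle = passive_moment_params(k1 = 1, k2 = 15, q_lower = deg2rad(-50),
                                  q_upper = deg2rad(30), b = 0.5),
    stop("unknown joint kind: ", joint))
}

default_contact_spheres <- function(foot_len) {
  # two spheres per foot (heel, toe), locations in the foot frame
  # (origin at the ankle, x forward, y up)
  data.frame(
    name = c("heel", "toe"),
    x = c(-0.035, 0.75 * foot_len),
    y = c(-0.045, -0.045),
    radius = c(0.035, 0.025),
    stiffness = c(3e5, 3e5),        # N m^-1.5
    dissipation = c(1, 1),          # s/m
    mu = c(0.9, 0.9),
    v_t = c(0.2, 0.2),              # m/s friction transition velocity
    stringsAsFactors = FALSE
  )
}

#' Build the scaled reference (healthy) model
#'
#' Scales the reference anthropometry to the subject's mass and height and
#' assembles the bilateral planar model: pelvis x/y translation + tilt and
#' hip/knee/ankle pin joints per leg, nine muscles per leg, two contact
#' spheres per foot, and exponential passive joint-limit moments on every
#' pin joint.
#'
#' @param mass Body mass in kg.
#' @param height Body height in m.
#' @param config Optional named list of overrides (`muscle_table`,
#'   `contact`, `gravity`).
#' @return An object of class `model_spec`.
#' @examples
#' m <- build_reference_model(77.8, 1.81)
#' total_mass(m)
#' @export
build_reference_model <- function(mass, height, config = list()) {
  stopifnot_scalar(mass, "mass", positive = TRUE)
  stopifnot_scalar(height, "height", positive = TRUE)
  ref <- reference_anthropometry()
  seg <- function(which, side = NA) {
    r <- ref[ref$segment == which, ]
    m <- mass * r$mass_frac
    L <- height * r$len_frac
    list(name = if (is.na(side)) which else paste(which, side, sep = "_"),
         mass = m, length = L, com_offset = r$com_frac * L,
         inertia_zz = m * (r$rog_frac * L)^2)
  }
  segments <- c(list(seg("hat")),
                lapply(c("il", "cl"), function(s) seg("thigh", s)),
                lapply(c("il", "cl"), function(s) seg("shank", s)),
                lapply(c("il", "cl"), function(s) seg("foot", s)))
  names(segments) <- vapply(segments, `[[`, "", "name")

  joints <- list()
  for (side in c("il", "cl")) {
    joints[[paste0("hip_", side)]] <- list(
      name = paste0("hip_", side), kind = "pin", parent = "hat",
      child = paste0("thigh_", side), range = deg2rad(c(-40, 130)),
      locked = FALSE, passive = default_joint_passive("hip"))
    joints[[paste0("knee_", side)]] <- list(
      name = paste0("knee_", side), kind = "pin",
      parent = paste0("thigh_", side), child = paste0("shank_", side),
      range = deg2rad(c(-10, 150)), locked = FALSE,
      passive = default_joint_passive("knee"))
    joints[[paste0("ankle_", side)]] <- list(
      name = paste0("ankle_", side), kind = "pin",
      parent = paste0("shank_", side), child = paste0("foot_", side),
      range = deg2rad(c(-60, 40)), locked = FALSE,
      passive = default_joint_passive("ankle"))
  }

  mt <- config$muscle_table %||% default_muscle_table()
  muscles <- list()
  for (side in c("il", "cl")) {
    for (i in seq_len(nrow(mt))) {
      row <- mt[i, ]
      spanned <- character(0)
      geom <- list()  # per-joint polynomial coefficients of L_mt(q)
      # L_mt(q) = c0 + sum_j (-r_j) * q_j   (constant moment arms)
      if (row$r_hip != 0) { spanned <- c(spanned, paste0("hip_", side))
        geom[[paste0("hip_", side)]] <- c(0, -row$r_hip) }
      if (row$r_knee != 0) { spanned <- c(spanned, paste0("knee_", side))
        geom[[paste0("knee_", side)]] <- c(0, -row$r_knee) }
      if (row$r_ankle != 0) { spanned <- c(spanned, paste0("ankle_", side))
        geom[[paste0("ankle_", side)]] <- c(0, -row$r_ankle) }
      l0 <- row$l_opt * cos(row$alpha_opt) + row$l_ts
      muscles[[paste(row$name, side, sep = "_")]] <- list(
        name = paste(row$name, side, sep = "_"), side = side,
        params = list(f_max_iso = row$f_max_iso, l_opt = row$l_opt,
                      l_ts = row$l_ts, alpha_opt = row$alpha_opt,
                      v_max = row$v_max),
        spanned_joints = spanned, l_mt0 = l0, geometry = geom)
    }
  }

  contact <- list()
  ct <- config$contact %||% default_contact_spheres(seg("foot")$length)
  for (side in c("il", "cl")) {
    for (i in seq_len(nrow(ct))) {
      r <- ct[i, ]
      contact[[paste(r$name, side, sep = "_")]] <- list(
        name = paste(r$name, side, sep = "_"),
        segment = paste0("foot_", side), location = c(r$x, r$y),
        radius = r$radius, stiffness = r$stiffness,
        dissipation = r$dissipation, mu = r$mu, v_t = r$v_t)
    }
  }

  model <- structure(list(
    variant = "healthy", mass = mass, height = height,
    gravity = 9.80665,
    segments = segments, joints = joints, muscles = muscles,
    contacts = contact, prosthesis = NULL,
    ankle_height = 0.06  # ankle joint height above the sole at standing
  ), class = "model_spec")
  validate_model(model)
  model
}

#' Total segment mass of a model
#' @param model A `model_spec`.
#' @export
total_mass <- function(model) {
  sum(vapply(model$segments, `[[`, 0, "mass"))
}

validate_model <- function(model) {
  tm <- total_mass(model)
  if (abs(tm - model$mass) > 1e-9)
    stop(sprintf("segment masses (%.12g) do not sum to body mass (%.12g)",
                 tm, model$mass))
  for (m in model$muscles) {
    for (j in m$spanned_joints) {
      if (is.null(model$joints[[j]]))
        stop("muscle ", m$name, " spans unknown joint ", j)
      if (model$joints[[j]]$locked)
        stop("muscle ", m$name, " spans locked joint ", j)
    }
  }
  if (identical(model$variant, "amputee")) {
    bad <- vapply(model$muscles, function(m) {
      m$side == "il" && any(grepl("^(knee|ankle)_il$", m$spanned_joints))
    }, TRUE)
    if (any(bad))
      stop("amputee variant has IL muscles spanning the knee or ankle: ",
           paste(names(model$muscles)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> variant=%s mass=%.1f kg height=%.2f m\n",
              x$variant, x$mass, x$height))
  cat(sprintf("  %d segments, %d joints, %d muscles, %d contact spheres\n",
              length(x$segments), length(x$joints), length(x$muscles),
              length(x$contacts)))
  if (!is.null(x$prosthesis))
    cat(sprintf("  prosthesis: D_MPK=%.2f N m s/rad, tau=%.0f ms\n",
                x$prosthesis$d_mpk, 1000 * x$prosthesis$tau_mpk))
  invisible(x)
}

#' Convert the model to the amputee variant (MPK + ESR foot)
#'
#' The IL knee becomes the prosthetic (MPK) degree of freedom, the IL shank
#' and foot are replaced by lighter prosthetic segments, and only muscles
#' spanning the IL hip are retained on the IL side.  Biarticular hip muscles
#' lose their distal attachment in a knee disarticulation, so their geometry
#' is truncated to the hip terms (they remain as uniarticular hip muscles);
#' consequently no IL muscle spans the knee or ankle.
#'
#' @param model A healthy `model_spec`.
#' @param prosthesis A `prosthesis_spec`.
#' @return The amputee `model_spec` (total mass reduced by the prosthetic
#'   segment mass deficit).
#' @export
apply_amputation <- function(model, prosthesis = prosthesis_spec()) {
  if (!identical(model$variant, "healthy"))
    stop("apply_amputation expects a healthy model")
  if (is.null(prosthesis)) stop("a prosthesis_spec is required")
  m <- model
  # prosthetic segment masses
  for (segn in c("shank_il", "foot_il")) {
    frac <- if (segn == "shank_il") prosthesis$shank_mass_frac else prosthesis$foot_mass_frac
    old <- m$segments[[segn]]$mass
    m$segments[[segn]]$mass <- frac * old
    m$segments[[segn]]$inertia_zz <- frac * m$segments[[segn]]$inertia_zz
  }
  m$mass <- total_mass(m)
  # MPK joint: passive moment replaced by the prosthetic stop/limit
  m$joints$knee_il$passive <- prosthesis$mpk_passive
  m$joints$knee_il$mpk <- TRUE
  # ESR ankle
  m$joints$ankle_il$passive <- prosthesis$esr_passive
  m$joints$ankle_il$esr <- TRUE
  # muscle pruning: keep IL muscles spanning the hip, truncated to hip-only
  keep <- list()
  for (mus in m$muscles) {
    if (mus$side == "cl" || any(grepl("^hip_il$", mus$spanned_joints))) {
      if (mus$side == "il") {
        mus$spanned_joints <- "hip_il"
        mus$geometry <- mus$geometry["hip_il"]
      }
      keep[[mus$name]] <- mus
    }
  }
  m$muscles <- keep
  m$prosthesis <- prosthesis
  m$variant <- "amputee"
  validate_model(m)
  m
}

#' Mirror the contralateral side to a hypothetical healthy model
#'
#' Replaces the IL (prosthetic) side by a mirror image of the CL side,
#' removes the prosthesis, and rescales all segment masses so the total
#' equals `healthy_mass` (intact limbs weigh more than the prosthesis, so
#' the hypothetical healthy mass is larger than the amputee mass).
#'
#' @param model An amputee `model_spec`.
#' @param healthy_mass Target total mass in kg.
#' @export
mirror_to_hypothetical_healthy <- function(model, healthy_mass) {
  if (!model$variant %in% c("amputee", "hypothetical_healthy"))
    stop("mirror_to_hypothetical_healthy expects an amputee (or already mirrored) model")
  stopifnot_scalar(healthy_mass, "healthy_mass", positive = TRUE)
  if (identical(model$variant, "amputee") && healthy_mass <= model$mass)
    warning("healthy_mass is not larger than the amputee mass; ",
            "intact limbs normally weigh more than the prosthesis")
  m <- model
  mirror_name <- function(nm) sub("_cl$", "_il", nm)
  # segments and joints: copy cl -> il
  for (segn in grep("_cl$", names(m$segments), value = TRUE)) {
    tgt <- mirror_name(segn)
    m$segments[[tgt]] <- m$segments[[segn]]
    m$segments[[tgt]]$name <- tgt
  }
  for (jn in grep("_cl$", names(m$joints), value = TRUE)) {
    tgt <- mirror_name(jn)
    j <- m$joints[[jn]]
    j$name <- tgt
    j$parent <- sub("_cl$", "_il", j$parent)
    j$child <- sub("_cl$", "_il", j$child)
    j$mpk <- NULL; j$esr <- NULL
    m$joints[[tgt]] <- j
  }
  muscles <- list()
  for (mus in m$muscles) {
    if (mus$side == "il") next
    muscles[[mus$name]] <- mus
    il <- mus
    il$name <- mirror_name(mus$name)
    il$side <- "il"
    il$spanned_joints <- sub("_cl$", "_il", mus$spanned_joints)
    names(il$geometry) <- sub("_cl$", "_il", names(mus$geometry))
    muscles[[il$name]] <- il
  }
  m$muscles <- muscles
  m$prosthesis <- NULL
  # rescale masses proportionally to hit the healthy total
  scale <- healthy_mass / total_mass(m)
  for (segn in names(m$segments)) {
    m$segments[[segn]]$mass <- m$segments[[segn]]$mass * scale
    m$segments[[segn]]$inertia_zz <- m$segments[[segn]]$inertia_zz * scale
  }
  m$mass <- healthy_mass
  m$variant <- "hypothetical_healthy"
  validate_model(m)
  m
}

#' Impose a stiff-knee-gait condition
#'
#' Lowers the flexion angle limit of the IL knee's (or MPK's) passive moment,
#' so that flexion beyond the limit meets a steep resistive moment.  The
#' reference flexion limit is 137.5 degrees; the SKG conditions use 14.9, 30
#' or 35 degrees.
#'
#' @param model A `model_spec`.
#' @param limit_deg Flexion limit in degrees, in (0, 137.5].
#' @export
apply_skg_condition <- function(model, limit_deg) {
  stopifnot_scalar(limit_deg, "limit_deg")
  if (limit_deg <= 0 || limit_deg > 137.5)
    stop("limit_deg must be in (0, 137.5]")
  m <- model
  m$joints$knee_il$passive$q_upper <- deg2rad(limit_deg)
  m$condition_limit_deg <- limit_deg
  m
}

#' Fit a flexion-limiting knee orthosis to a healthy model
#'
#' Adds the orthosis mass to the IL thigh and shank segments and constrains
#' IL knee flexion through the passive-moment limit (the experimental
#' orthosis constrained knee flexion to 20 degrees).
#'
#' @param model A healthy `model_spec`.
#' @param limit_deg Knee flexion limit in degrees.
#' @param thigh_mass_add,shank_mass_add Orthosis mass added to the thigh and
#'   shank segments (kg, >= 0).
#' @export
apply_orthosis <- function(model, limit_deg = 20, thigh_mass_add = 0.3,
                           shank_mass_add = 0.3) {
  if (!identical(model$variant, "healthy"))
    stop("apply_orthosis expects a healthy model")
  if (thigh_mass_add < 0 || shank_mass_add < 0)
    stop("orthosis masses must be >= 0")
  m <- model
  m$segments$thigh_il$mass <- m$segments$thigh_il$mass + thigh_mass_add
  m$segments$shank_il$mass <- m$segments$shank_il$mass + shank_mass_add
  m$mass <- total_mass(m)
  m$joints$knee_il$passive$q_upper <- deg2rad(limit_deg)
  m$variant <- if (thigh_mass_add == 0 && shank_mass_add == 0 && limit_deg >= 137.5)
    m$variant else "orthosis"
  m$condition_limit_deg <- limit_deg
  validate_model(m)
  m
}

#' Build an amputee model with a given measured total mass
#'
#' Convenience constructor: scales the healthy reference so that after
#' amputation (prosthetic shank/foot replacing the intact segments) the
#' total mass equals the measured mass of the subject wearing the
#' prosthesis.
#'
#' @param mass Measured total mass (kg, subject + prosthesis).
#' @param height Height (m).
#' @param prosthesis A `prosthesis_spec`.
#' @param config Passed to [build_reference_model()].
#' @export
build_amputee_model <- function(mass, height, prosthesis = prosthesis_spec(),
                                config = list()) {
  ref <- reference_anthropometry()
  deficit <- (1 - prosthesis$shank_mass_frac) *
    ref$mass_frac[ref$segment == "shank"] +
    (1 - prosthesis$foot_mass_frac) * ref$mass_frac[ref$segment == "foot"]
  healthy_mass <- mass / (1 - deficit)
  m <- build_reference_model(healthy_mass, height, config)
  apply_amputation(m, prosthesis)
}

#' Degrees of freedom of the planar model, in canonical order
#' @param model A `model_spec`.
#' @export
model_dof_names <- function(model) {
  c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
    "hip_il", "knee_il", "ankle_il", "hip_cl", "knee_cl", "ankle_cl")
}
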