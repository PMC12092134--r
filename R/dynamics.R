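# Forward dynamics: R-level force-element operations (documented reference
# implementations of the curves the compiled engine uses), the model ->
# engine bridge, simulation driver and trajectory I/O.

#' Hill-type fibre force
#'
#' Active force is `activation * F_max * f_L(L) * f_V(v)` with a symmetric
#' quadratic force-length curve about the optimal length and the Hill
#' hyperbola for shortening (`f_V(0) = 1`, `f_V(vmax) = 0`, eccentric
#' plateau at 1).  A linear parallel elastic force engages beyond the
#' engagement strain.
#'
#' @param params list with `fmax` (N), `lopt_mm`, `vmax` (fibre lengths
#'   s^-1), `fv_shape` (Hill a/F0), `fl_width`, `pe_k_rel`, `pe_engage`.
#'   [hill_params()] builds one from an actuator.
#' @param activation activation level in \[0, 1\].
#' @param lce_mm contractile-element length, mm.
#' @param vce_Ls shortening velocity in fibre lengths per second
#'   (positive = shortening).
#' @return fibre force (CE + PE) in N.
#' @export
hill_force <- function(params, activation, lce_mm, vce_Ls) {
  if (any(activation < 0 | activation > 1))
    stop("activation must be in [0, 1]", call. = FALSE)
  u <- (lce_mm - params$lopt_mm) / (params$fl_width * params$lopt_mm)
  fl <- pmax(0, 1 - u^2)
  vr <- vce_Ls / params$vmax
  fv <- ifelse(vr <= 0, 1,
        ifelse(vr >= 1, 0, (1 - vr) * params$fv_shape / (params$fv_shape + vr)))
  strain <- (lce_mm - params$lopt_mm) / params$lopt_mm - params$pe_engage
  fpe <- ifelse(strain > 0, params$pe_k_rel * params$fmax * strain, 0)
  activation * params$fmax * fl * fv + fpe
}

#' Hill parameters of a model actuator
#'
#' @param model a `jump_model`.
#' @param actuator actuator name.
#' @return parameter list consumable by [hill_force()].
#' @export
hill_params <- function(model, actuator) {
  a <- model$actuators[[actuator]]
  if (is.null(a)) stop("unknown actuator: ", actuator, call. = FALSE)
  list(fmax = a$sigma_max * a$pcsa, lopt_mm = a$fl, vmax = a$vmax,
       fv_shape = a$fv_shape, fl_width = a$fl_width,
       pe_k_rel = a$pe_stiffness_rel, pe_engage = a$pe_engage_strain)
}

#' Soft joint-limit torque
#'
#' Zero inside the admissible range; beyond it, a restoring spring-damper
#' torque toward the range.
#'
#' @param angle_deg,rate_deg_s joint angle (deg) and rate (deg s^-1).
#' @param joint joint description with `angle_lo`, `angle_hi` (deg),
#'   `soft_limit_stiffness` (N m rad^-1), `soft_limit_damping`
#'   (N m s rad^-1).
#' @return torque in N m about the joint axis.
#' @export
joint_limit_torque <- function(angle_deg, rate_deg_s, joint) {
  q <- angle_deg * pi / 180
  qd <- rate_deg_s * pi / 180
  lo <- joint$angle_lo * pi / 180
  hi <- joint$angle_hi * pi / 180
  ifelse(q > hi, -joint$soft_limit_stiffness * (q - hi) - joint$soft_limit_damping * qd,
  ifelse(q < lo, -joint$soft_limit_stiffness * (q - lo) - joint$soft_limit_damping * qd,
         0))
}

#' Unilateral spring-damper contact force
#'
#' Vertical force `max(0, k * penetration - c * v_z)` while penetrating
#' (never adhesive), horizontal force a smoothed Coulomb friction bounded
#' by `mu * Fz`.
#'
#' @param height point height above ground, m (negative = penetrating).
#' @param v_z,v_x vertical and horizontal point velocity, m s^-1.
#' @param stiffness,damping,friction_mu contact parameters.
#' @param slip_scale tanh regularisation velocity for friction, m s^-1.
#' @return named vector `c(Fz, Fx)` in N.
#' @export
contact_force <- function(height, v_z, v_x, stiffness, damping,
                          friction_mu = 1, slip_scale = 0.01) {
  if (height >= 0) return(c(Fz = 0, Fx = 0))
  Fz <- max(0, -stiffness * height - damping * v_z)
  Fx <- -friction_mu * Fz * tanh(v_x / slip_scale)
  c(Fz = Fz, Fx = Fx)
}

#' Midshaft bone stress (axial plus bending)
#'
#' Peak compressive stress magnitude of a beam section:
#' `|F|/A + |M| c / I`.
#'
#' @param axial_force axial force, N.
#' @param bending_moment bending moment, N m.
#' @param section bone section with `area` (m^2), `second_moment` (m^4)
#'   and outer-fibre distance `c` (m).
#' @return stress in Pa.
#' @export
bone_stress <- function(axial_force, bending_moment, section) {
  abs(axial_force) / section$area +
    abs(bending_moment) * section$c / section$second_moment
}

# ---- model -> engine bridge ----------------------------------------------

# Flatten a jump_model into the list consumed by the compiled engine.
# Bodies are ordered root-first; joint i belongs to body i+1.
as_engine_list <- function(model) {
  topo <- model_topology(model)
  ord <- topo$order
  segs <- model$segments[ord]
  bidx <- setNames(seq_along(ord) - 1L, ord)  # 0-based engine index

  anchor_x <- anchor_z <- offset <- numeric(length(ord))
  jlo <- jhi <- jk <- jc <- numeric(max(0, length(ord) - 1L))
  joint_names <- character(max(0, length(ord) - 1L))
  for (i in seq_along(ord)[-1]) {
    j <- model$joints[[topo$joint[i]]]
    anchor_x[i] <- j$anchor[1]; anchor_z[i] <- j$anchor[2]
    offset[i] <- j$offset_deg * pi / 180
    jlo[i - 1L] <- j$angle_lo * pi / 180
    jhi[i - 1L] <- j$angle_hi * pi / 180
    jk[i - 1L] <- j$soft_limit_stiffness
    jc[i - 1L] <- j$soft_limit_damping
    joint_names[i - 1L] <- j$name
  }

  muscles <- lapply(model$actuators, function(a) {
    tl <- a$tendon_length
    list(body = unname(vapply(a$path$anchors, function(p) bidx[[p$segment]], 0L)),
         px = vapply(a$path$anchors, function(p) p$pos[1], 0),
         pz = vapply(a$path$anchors, function(p) p$pos[2], 0),
         wraps = lapply(a$path$wraps, function(w)
           list(after = as.integer(w$after) - 1L, body = bidx[[w$segment]],
                cx = w$centre[1], cz = w$centre[2], r = w$radius,
                dir = as.integer(w$direction))),
         fmax = a$sigma_max * a$pcsa,
         lopt = a$fl / 1000,
         tl = if (is.na(tl)) 0 else tl / 1000,
         vmax_abs = a$vmax * a$fl / 1000,
         fv_shape = a$fv_shape, fl_width = a$fl_width,
         se_strain = a$se_strain_at_fmax,
         pe_k_rel = a$pe_stiffness_rel, pe_engage = a$pe_engage_strain)
  })

  contacts <- lapply(model$contacts, function(ct)
    list(body = bidx[[ct$segment]], px = ct$local_pos[1], pz = ct$local_pos[2],
         k = ct$stiffness, c = ct$damping, mu = ct$friction_mu))

  bones <- lapply(model$bone_sections, function(b)
    list(body = bidx[[b$segment]], frac = b$pos, A = b$area,
         I = b$second_moment, c = b$c, fail = b$failure_stress))

  list(nb = length(ord), gravity = model$gravity,
       fixed_base = isTRUE(model$fixed_base),
       parent = ifelse(is.na(topo$parent), -1L, topo$parent - 1L),
       anchor_x = anchor_x, anchor_z = anchor_z, offset = offset,
       joint_lo = jlo, joint_hi = jhi, limit_k = jk, limit_c = jc,
       mass = vapply(segs, `[[`, 0, "mass"),
       moi = vapply(segs, `[[`, 0, "moi"),
       com_x = vapply(segs, `[[`, 0, "com_offset"),
       com_z = rep(0, length(ord)),
       seg_length = vapply(segs, function(s) s$shape$length, 0),
       contacts = unname(contacts), muscles = unname(muscles),
       bones = unname(bones),
       joint_names = joint_names, body_names = ord,
       actuator_names = names(model$actuators))
}

# Build (and finalize) an engine handle.  Tendon lengths that are NA are
# filled from the reference pose (the starting pose, else neutral) via
# tendon_length_from_reference() before the final engine is built.
engine_handle <- function(model) {
  el <- as_engine_list(model)
  need_tl <- vapply(model$actuators, function(a) is.na(a$tendon_length), TRUE)
  if (any(need_tl)) {
    eng0 <- engine_create(el)
    pose <- rep(0, length(el$joint_names))
    names(pose) <- el$joint_names
    ref <- model$tendon_reference_pose
    if (is.null(ref)) ref <- model$starting_pose
    if (!is.null(ref)) {
      keep <- intersect(names(ref), el$joint_names)
      pose[keep] <- ref[keep]
    }
    lens <- engine_path_lengths(eng0, matrix(pose * pi / 180, nrow = 1))
    for (i in which(need_tl)) {
      fl <- model$actuators[[i]]$fl
      tl <- suppressMessages(tendon_length_from_reference(lens[1, i] * 1000, fl))
      el$muscles[[i]]$tl <- tl / 1000
    }
  }
  engine_create(el)
}

# Fill NA tendon lengths in the model itself (used by fixture builders so
# the stored model carries explicit tendon slack lengths).
resolve_tendon_lengths <- function(model, reference_pose = NULL) {
  el <- as_engine_list(model)
  eng0 <- engine_create(el)
  pose <- rep(0, length(el$joint_names))
  names(pose) <- el$joint_names
  ref <- reference_pose
  if (is.null(ref)) ref <- model$tendon_reference_pose
  if (is.null(ref)) ref <- model$starting_pose
  if (!is.null(ref)) {
    keep <- intersect(names(ref), el$joint_names)
    pose[keep] <- unlist(ref)[keep]
  }
  lens <- engine_path_lengths(eng0, matrix(pose * pi / 180, nrow = 1))
  for (i in seq_along(model$actuators)) {
    if (is.na(model$actuators[[i]]$tendon_length)) {
      fl <- model$actuators[[i]]$fl
      model$actuators[[i]]$tendon_length <-
        suppressMessages(tendon_length_from_reference(lens[1, i] * 1000, fl))
    }
  }
  model
}

#' Initial generalized coordinates for a starting posture
#'
#' Places the model in the given joint posture with the contact-bearing
#' (most distal) segment level with the ground, and lowers the base so the
#' contact springs carry the body weight at rest.
#'
#' @param model a `jump_model`.
#' @param pose named joint angles in degrees (default the model's
#'   `starting_pose`).
#' @param foot_angle_deg target world angle of the contact segment.
#' @param settle if TRUE (default), pre-compress the contacts by the
#'   static penetration `m g / sum(k)`.
#' @return numeric vector `q0` of length 3 + n_joints (base x, z,
#'   orientation in rad, then joint angles in rad, engine order).
#' @export
initial_state <- function(model, pose = NULL, foot_angle_deg = 0,
                          settle = TRUE) {
  el <- as_engine_list(model)
  if (is.null(pose)) pose <- model$starting_pose
  if (is.null(pose)) pose <- setNames(rep(0, length(el$joint_names)),
                                      el$joint_names)
  q <- rep(0, 3 + length(el$joint_names))
  keep <- intersect(names(pose), el$joint_names)
  q[3 + match(keep, el$joint_names)] <- unlist(pose)[keep] * pi / 180

  eng <- engine_handle(model)
  fk <- engine_fk(eng, q)
  if (length(model$contacts)) {
    cseg <- vapply(model$contacts, `[[`, "", "segment")
    depth <- vapply(cseg, function(s) {
      d <- 0; cur <- s
      repeat {
        par <- NA_character_
        for (j in model$joints) if (j$child == cur) par <- j$parent
        if (is.na(par)) break
        cur <- par; d <- d + 1
      }
      d
    }, 0)
    foot <- cseg[which.max(depth)]
    fi <- match(foot, el$body_names)
    q[3] <- q[3] + (foot_angle_deg * pi / 180 - fk$body_angle[fi])
    fk <- engine_fk(eng, q)
    minz <- min(fk$contact_pos[, 2])
    pen <- if (settle) {
      touching <- fk$contact_pos[, 2] < minz + 1e-3
      ktot <- sum(vapply(model$contacts, `[[`, 0, "stiffness")[touching])
      model$body_mass * model$gravity / ktot
    } else 0
    q[2] <- q[2] - minz - pen
  }
  names(q) <- c("base_x", "base_z", "base_phi",
                paste0("q_", el$joint_names))
  q
}

#' Piecewise-constant activation controller
#'
#' @param model a `jump_model`.
#' @param levels either a single activation applied to every actuator, a
#'   named vector of per-actuator levels, or a matrix (actuators x phases).
#' @param durations phase durations in s (recycled across actuators when a
#'   vector); default one long phase.
#' @return a `jump_controller` list of `durations` and `levels` matrices.
#' @export
constant_controller <- function(model, levels = 0, durations = 1e6) {
  na <- length(model$actuators)
  if (is.matrix(levels)) {
    lev <- levels
  } else if (!is.null(names(levels))) {
    v <- setNames(rep(0, na), names(model$actuators))
    v[names(levels)] <- levels
    lev <- matrix(v, ncol = 1)
  } else {
    lev <- matrix(rep(levels[1], na), ncol = 1)
  }
  np <- ncol(lev)
  dur <- matrix(rep(durations, length.out = np), nrow = na, ncol = np,
                byrow = TRUE)
  clamped <- pmin(1, pmax(0, lev))
  dim(clamped) <- dim(lev)
  structure(list(durations = dur, levels = clamped),
            class = "jump_controller")
}

#' Simulate a jump
#'
#' Integrates the full model forward under a piecewise-constant activation
#' controller and records the trajectory: centre of mass, ground reaction
#' forces, cumulative vertical GRF impulse, energies, generalized
#' coordinates, per-actuator muscle state and work components, and
#' midshaft bone stresses.  The simulation stops early (with a flag) if a
#' bone section exceeds its failure stress or the state stops being
#' finite.
#'
#' @param model a `jump_model`.
#' @param controller a `jump_controller` (see [constant_controller()]) or
#'   a list with `durations` and `levels` matrices (actuators x phases)
#'   and optionally `tendon_scale`.
#' @param duration simulated time, s.
#' @param dt integration step, s (default from `model$sim`).
#' @param record_dt output sampling interval, s.
#' @param integrator `"semi_implicit"` (symplectic Euler, default) or
#'   `"rk4"`.
#' @param q0,qd0 optional initial state overrides (engine coordinates).
#' @param check_stress evaluate the bone-stress constraint each step.
#' @return a `jump_trajectory`: data frame of sampled time series with
#'   attributes `flags` (stress/blow-up), `model_taxon`, `body_mass`.
#' @export
simulate_jump <- function(model, controller, duration, dt = NULL,
                          record_dt = NULL, integrator = NULL,
                          q0 = NULL, qd0 = NULL, check_stress = TRUE) {
  stopifnot(duration > 0)
  if (is.null(dt)) dt <- model$sim$dt
  if (is.null(record_dt)) record_dt <- model$sim$record_dt
  if (is.null(integrator)) integrator <- model$sim$integrator
  stopifnot(dt > 0)
  el <- as_engine_list(model)
  eng <- engine_handle(model)
  if (is.null(q0)) q0 <- initial_state(model)
  if (is.null(qd0)) qd0 <- rep(0, length(q0))
  na <- length(model$actuators)
  ts <- controller$tendon_scale
  if (is.null(ts)) ts <- rep(1, na)
  res <- engine_simulate(eng, q0, qd0, controller$durations,
                         controller$levels, ts, duration, dt, record_dt,
                         integrator, check_stress, TRUE)
  traj <- res$trajectory[seq_len(res$nrec), , drop = FALSE]
  jn <- el$joint_names
  an <- el$actuator_names
  bn <- vapply(model$bone_sections, `[[`, "", "segment")
  cols <- c("time", "com_x", "com_z", "com_vx", "com_vz", "grf_x", "grf_z",
            "grf_impulse_z", "energy_kinetic", "energy_potential",
            c("base_x", "base_z", "base_phi",
              if (length(jn)) paste0("q_", jn) else character()),
            c("based_x", "based_z", "based_phi",
              if (length(jn)) paste0("qd_", jn) else character()),
            unlist(lapply(an, function(a)
              paste0(gsub("[^a-z0-9]+", "_", tolower(a)),
                     c("_act", "_force", "_lce", "_vce", "_wce", "_wse",
                       "_wpe", "_wmtu")))),
            if (length(bn)) paste0("stress_", make.unique(bn)) else character())
  colnames(traj) <- cols
  out <- as.data.frame(traj)
  structure(out,
            class = c("jump_trajectory", "data.frame"),
            flags = list(stress_exceeded = res$stress_exceeded,
                         stress_time = res$stress_time,
                         blowup = res$blowup, blowup_time = res$blowup_time,
                         end_time = res$end_time),
            max_com_z = res$max_com_z,
            model_taxon = model$taxon,
            body_mass = model$body_mass,
            gravity = model$gravity)
}

#' @export
`[.jump_trajectory` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.jump_trajectory <- function(x, ...) {
  fl <- attr(x, "flags")
  cat("<jump_trajectory> ", attr(x, "model_taxon"), ", ",
      nrow(x), " samples over ", format(round(fl$end_time, 4)), " s\n", sep = "")
  cat("  max CoM height: ", format(round(attr(x, "max_com_z"), 4)), " m\n", sep = "")
  if (isTRUE(fl$stress_exceeded))
    cat("  ! bone stress limit exceeded at t = ", format(fl$stress_time), " s\n", sep = "")
  if (isTRUE(fl$blowup))
    cat("  ! integration diverged at t = ", format(fl$blowup_time), " s\n", sep = "")
  invisible(x)
}

#' Write / read a trajectory as tab-separated text
#'
#' @param traj a `jump_trajectory` (or any data frame of samples).
#' @param path file path.
#' @param downsample keep every n-th row (default 1 = all).
#' @return `path` (write) or a data frame (read).
#' @export
write_trajectory <- function(traj, path, downsample = 1) {
  d <- as.data.frame(traj)
  if (downsample > 1) d <- d[seq(1, nrow(d), by = downsample), ]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
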