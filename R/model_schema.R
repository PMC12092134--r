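# Musculoskeletal model schema: planar segments, hinge joints, aggregated
# Hill-type actuators, unilateral contacts and midshaft bone sections.
#
# Conventions (documented in the methods vignette):
#  * world frame: x horizontal (facing direction), z vertical up, angles CCW;
#  * each segment has a local frame at its proximal end with the segment axis
#    along local +x; joints attach the child origin to an anchor point given
#    in the parent frame;
#  * joint angle 0 is the anatomical neutral; the fixed `offset_deg` carries
#    the neutral relative orientation of child vs parent so that printed
#    posture angles can be used directly;
#  * `extension_sign` is the direction of the joint coordinate that extends
#    the joint (+1 or -1), used to classify extensor/flexor actions;
#  * SI units throughout except fibre length (mm) and PCSA (mm^2), matching
#    the conventional muscle-architecture units.

#' Mass, inertia and centre of mass of a uniform primitive segment
#'
#' Computes the mass, the moment of inertia about the out-of-plane axis
#' through the centre of mass, and the centre-of-mass offset along the
#' segment axis for a uniform solid primitive.
#'
#' @param shape list with `type` ("cylinder" or "cuboid") and dimensions in
#'   metres: `length` plus `radius` (cylinder) or `width` and `depth`
#'   (cuboid, `width` out of plane, `depth` the in-plane thickness).
#' @param density density in kg m^-3.
#' @return list with `mass` (kg), `moi` (kg m^2, transverse axis through the
#'   CoM) and `com_offset` (m along the segment axis; half the length).
#' @examples
#' segment_properties(list(type = "cylinder", length = 0.4, radius = 0.05), 1000)
#' @export
segment_properties <- function(shape, density) {
  if (!is.list(shape) || is.null(shape$type))
    stop("shape must be a list with a 'type' field", call. = FALSE)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) || density <= 0)
    stop("density must be a single positive number", call. = FALSE)
  L <- shape$length
  if (is.null(L) || !is.finite(L) || L <= 0)
    stop("shape length must be positive", call. = FALSE)
  if (identical(shape$type, "cylinder")) {
    r <- shape$radius
    if (is.null(r) || !is.finite(r) || r <= 0)
      stop("cylinder radius must be positive", call. = FALSE)
    vol <- pi * r^2 * L
    mass <- density * vol
    moi <- mass * (3 * r^2 + L^2) / 12
  } else if (identical(shape$type, "cuboid")) {
    w <- shape$width
    d <- shape$depth
    if (is.null(w) || is.null(d) || !is.finite(w) || !is.finite(d) || w <= 0 || d <= 0)
      stop("cuboid width and depth must be positive", call. = FALSE)
    vol <- L * w * d
    mass <- density * vol
    moi <- mass * (L^2 + d^2) / 12
  } else {
    stop("unknown primitive type: ", shape$type, call. = FALSE)
  }
  list(mass = mass, moi = moi, com_offset = L / 2)
}

# Default Hill-curve constants shared by all actuators unless overridden.
default_muscle_params <- function() {
  list(
    sigma_max = 0.3,          # N mm^-2, conventional vertebrate max isometric stress
    fv_shape = 0.25,          # Hill a/F0
    fl_width = 0.5,           # zero active force at L_opt * (1 +/- fl_width)
    se_strain_at_fmax = 0.04, # series element strain at F_max
    pe_engage_strain = 0,     # parallel element engages past L_opt
    pe_stiffness_rel = 0.1    # parallel element stiffness, F_max per unit strain (soft)
  )
}

norm_segment <- function(s) {
  need <- c("name", "shape", "density")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("segment is missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  props <- segment_properties(s$shape, s$density)
  if (is.null(s$mass)) s$mass <- props$mass
  if (is.null(s$com_offset)) s$com_offset <- props$com_offset
  if (is.null(s$moi)) {
    # scale the uniform-solid inertia if the mass was overridden
    s$moi <- props$moi * s$mass / props$mass
  }
  s
}

norm_joint <- function(j) {
  need <- c("name", "parent", "child", "anchor", "angle_lo", "angle_hi")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop("joint '", if (is.null(j$name)) "?" else j$name,
         "' is missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(j$offset_deg)) j$offset_deg <- 0
  if (is.null(j$extension_sign)) j$extension_sign <- -1
  if (is.null(j$soft_limit_stiffness)) j$soft_limit_stiffness <- 200
  if (is.null(j$soft_limit_damping)) j$soft_limit_damping <- 2
  j$anchor <- as.numeric(unlist(j$anchor))
  j
}

norm_actuator <- function(a, muscle_defaults) {
  need <- c("name", "path", "fl", "pcsa", "vmax", "actions")
  miss <- setdiff(need, names(a))
  if (length(miss))
    stop("actuator '", if (is.null(a$name)) "?" else a$name,
         "' is missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (f in names(muscle_defaults))
    if (is.null(a[[f]])) a[[f]] <- muscle_defaults[[f]]
  if (is.null(a$region)) a$region <- "proximal"
  if (is.null(a$tendon_length)) a$tendon_length <- NA_real_
  a$path$anchors <- lapply(a$path$anchors, function(p) {
    p$pos <- as.numeric(unlist(p$pos)); p
  })
  if (is.null(a$path$wraps)) a$path$wraps <- list()
  a$path$wraps <- lapply(a$path$wraps, function(w) {
    w$centre <- as.numeric(unlist(w$centre))
    if (is.null(w$direction)) w$direction <- 1
    w
  })
  a$actions <- lapply(a$actions, function(ac) {
    if (is.null(ac$joint) || is.null(ac$role))
      stop("actuator '", a$name, "': each action needs 'joint' and 'role'",
           call. = FALSE)
    ac
  })
  a
}

norm_contact <- function(ct) {
  need <- c("segment", "local_pos", "stiffness", "damping")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("contact is missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(ct$friction_mu)) ct$friction_mu <- 1.0
  ct$local_pos <- as.numeric(unlist(ct$local_pos))
  ct
}

norm_bone_section <- function(b) {
  need <- c("segment", "area", "second_moment", "c")
  miss <- setdiff(need, names(b))
  if (length(miss))
    stop("bone section is missing field(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(b$pos)) b$pos <- 0.5
  if (is.null(b$failure_stress)) b$failure_stress <- 3e8  # 300 MPa
  b
}

#' Construct a planar musculoskeletal model
#'
#' Assembles and validates the complete model description used by the
#' forward-dynamics engine.  Derived segment masses and inertias are filled
#' from the primitive geometry; the linkage must be a tree rooted at the one
#' segment that is not the child of any joint.
#'
#' @param taxon label for the modelled taxon.
#' @param body_mass total body mass in kg.
#' @param segments,joints,actuators,contacts,bone_sections lists of
#'   component descriptions (see the package vignette for the schema).
#' @param starting_pose named numeric vector/list of joint angles in degrees.
#' @param tendon_reference_pose named joint angles (degrees) at which tendon
#'   slack lengths are resolved (path length minus fibre length); defaults
#'   to the starting pose.  Keeping this fixed across starting postures
#'   keeps muscle properties posture-independent.
#' @param gravity gravitational acceleration, m s^-2.
#' @param muscle_defaults overrides for the shared Hill-curve constants.
#' @param sim list of integrator settings (`dt`, `integrator`).
#' @param fixed_base if TRUE the base segment is pinned to the world
#'   (useful for bench-test rigs such as pendulums); default FALSE.
#' @param check if TRUE (default) stop on any validation error.
#' @return an object of class `jump_model`.
#' @export
jump_model <- function(taxon, body_mass, segments, joints, actuators = list(),
                       contacts = list(), bone_sections = list(),
                       starting_pose = NULL, tendon_reference_pose = NULL,
                       gravity = 9.81, muscle_defaults = list(), sim = list(),
                       fixed_base = FALSE, check = TRUE) {
  md <- modifyList(default_muscle_params(), muscle_defaults)
  segments <- lapply(segments, norm_segment)
  names(segments) <- vapply(segments, `[[`, "", "name")
  joints <- lapply(joints, norm_joint)
  names(joints) <- vapply(joints, `[[`, "", "name")
  actuators <- lapply(actuators, norm_actuator, muscle_defaults = md)
  names(actuators) <- vapply(actuators, `[[`, "", "name")
  contacts <- lapply(contacts, norm_contact)
  bone_sections <- lapply(bone_sections, norm_bone_section)

  for (j in joints) {
    for (s in c(j$parent, j$child))
      if (!s %in% names(segments))
        stop("joint '", j$name, "' references unknown segment '", s, "'",
             call. = FALSE)
  }

  children <- vapply(joints, `[[`, "", "child")
  roots <- setdiff(names(segments), children)
  if (length(roots) != 1L)
    stop("linkage must have exactly one root segment (found: ",
         paste(roots, collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(children))
    stop("linkage is not a tree: a segment has two parent joints", call. = FALSE)

  sim <- modifyList(list(dt = 1e-4, integrator = "semi_implicit",
                         record_dt = 1e-3), sim)

  m <- structure(
    list(taxon = taxon, body_mass = body_mass, gravity = gravity,
         segments = segments, joints = joints, actuators = actuators,
         contacts = contacts, bone_sections = bone_sections,
         starting_pose = if (is.null(starting_pose)) NULL
                         else unlist(starting_pose),
         tendon_reference_pose = if (is.null(tendon_reference_pose)) NULL
                                 else unlist(tendon_reference_pose),
         muscle_defaults = md, sim = sim, root = roots,
         fixed_base = isTRUE(fixed_base)),
    class = "jump_model")

  if (check) {
    rep <- validate_model(m)
    if (nrow(rep))
      stop("invalid model:\n", paste0("  - ", rep$message, collapse = "\n"),
           call. = FALSE)
  }
  m
}

#' @export
print.jump_model <- function(x, ...) {
  cat("<jump_model> ", x$taxon, "\n", sep = "")
  cat("  body mass : ", format(x$body_mass), " kg (segments sum to ",
      format(round(sum(vapply(x$segments, `[[`, 0, "mass")), 3)), " kg)\n", sep = "")
  cat("  segments  : ", length(x$segments), " (root: ", x$root, ")\n", sep = "")
  cat("  joints    : ", paste(names(x$joints), collapse = ", "), "\n", sep = "")
  cat("  actuators : ", length(x$actuators), "\n", sep = "")
  cat("  contacts  : ", length(x$contacts), "; bone sections: ",
      length(x$bone_sections), "\n", sep = "")
  if (!is.null(x$starting_pose))
    cat("  pose (deg): ",
        paste(names(x$starting_pose), round(x$starting_pose, 1),
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a model and report every invariant violation
#'
#' Reporting companion to [jump_model()]: runs all structural and physical
#' invariant checks and returns them as a data frame instead of stopping.
#' An empty report means the model is simulatable.
#'
#' @param m a `jump_model`.
#' @return data.frame with columns `component`, `name`, `message`;
#'   zero rows if the model is valid.
#' @export
validate_model <- function(m) {
  bad <- list()
  note <- function(component, name, message)
    bad[[length(bad) + 1L]] <<- data.frame(component = component, name = name,
                                           message = message,
                                           stringsAsFactors = FALSE)

  for (s in m$segments) {
    if (!is.finite(s$mass) || s$mass <= 0)
      note("segment", s$name, paste0("segment '", s$name, "': mass must be > 0"))
    if (!is.finite(s$density) || s$density <= 0)
      note("segment", s$name, paste0("segment '", s$name, "': density must be > 0"))
    if (!is.finite(s$shape$length) || s$shape$length <= 0)
      note("segment", s$name, paste0("segment '", s$name, "': length must be > 0"))
  }

  for (j in m$joints) {
    if (j$angle_lo >= j$angle_hi)
      note("joint", j$name, paste0("joint '", j$name,
           "': angle_lo must be < angle_hi"))
    if (j$soft_limit_stiffness < 0 || j$soft_limit_damping < 0)
      note("joint", j$name, paste0("joint '", j$name,
           "': soft limit stiffness/damping must be >= 0"))
    if (identical(j$parent, j$child))
      note("joint", j$name, paste0("joint '", j$name, "': parent equals child"))
  }

  for (a in m$actuators) {
    if (!is.finite(a$fl) || a$fl <= 0)
      note("actuator", a$name, paste0("actuator '", a$name, "': fibre length must be > 0"))
    if (!is.finite(a$pcsa) || a$pcsa < 0)
      note("actuator", a$name, paste0("actuator '", a$name, "': pcsa must be >= 0"))
    if (!is.finite(a$vmax) || a$vmax <= 0)
      note("actuator", a$name, paste0("actuator '", a$name, "': vmax must be > 0"))
    if (length(a$actions) < 1L)
      note("actuator", a$name, paste0("actuator '", a$name, "': needs at least one action"))
    for (ac in a$actions)
      if (!ac$joint %in% names(m$joints))
        note("actuator", a$name, paste0("actuator '", a$name,
             "': action references unknown joint '", ac$joint, "'"))
    for (p in a$path$anchors)
      if (!p$segment %in% names(m$segments))
        note("actuator", a$name, paste0("actuator '", a$name,
             "': path anchor on unknown segment '", p$segment, "'"))
    if (length(a$path$anchors) < 2L)
      note("actuator", a$name, paste0("actuator '", a$name,
           "': path needs at least two anchors"))
  }

  for (ct in m$contacts) {
    if (!ct$segment %in% names(m$segments))
      note("contact", ct$segment, paste0("contact on unknown segment '", ct$segment, "'"))
    if (!is.finite(ct$stiffness) || ct$stiffness <= 0)
      note("contact", ct$segment, "contact stiffness must be > 0")
  }

  for (b in m$bone_sections) {
    if (!b$segment %in% names(m$segments))
      note("bone_section", b$segment,
           paste0("bone section on unknown segment '", b$segment, "'"))
    if (any(!is.finite(c(b$area, b$second_moment, b$c))) ||
        b$area <= 0 || b$second_moment <= 0 || b$c <= 0)
      note("bone_section", b$segment,
           paste0("bone section on '", b$segment, "': A, I and c must be > 0"))
  }

  total <- sum(vapply(m$segments, `[[`, 0, "mass"))
  if (abs(total - m$body_mass) / m$body_mass > 0.01)
    note("model", m$taxon,
         sprintf("segment masses sum to %.3f kg, body_mass is %.3f kg (>1%% mismatch)",
                 total, m$body_mass))

  if (!is.null(m$starting_pose)) {
    for (jn in names(m$starting_pose)) {
      if (!jn %in% names(m$joints)) {
        note("pose", jn, paste0("starting pose references unknown joint '", jn, "'"))
        next
      }
      j <- m$joints[[jn]]
      ang <- m$starting_pose[[jn]]
      if (ang < j$angle_lo || ang > j$angle_hi)
        note("pose", jn,
             sprintf("starting angle %s = %.1f deg outside [%.1f, %.1f]",
                     jn, ang, j$angle_lo, j$angle_hi))
    }
  }

  if (length(bad)) do.call(rbind, bad)
  else data.frame(component = character(), name = character(),
                  message = character(), stringsAsFactors = FALSE)
}

#' Read a model configuration file
#'
#' Loads the YAML model schema, fills in derived masses and inertias, and
#' validates the result.  The schema is documented in the package vignette;
#' shipped examples live under `system.file("extdata", package = "jumpsim")`.
#'
#' @param path path to a YAML model configuration.
#' @return a validated `jump_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  model_from_config(cfg)
}

# Build a jump_model from a parsed configuration list.
model_from_config <- function(cfg, check = TRUE) {
  need <- c("taxon", "body_mass", "segments", "joints")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("model config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  jump_model(
    taxon = cfg$taxon, body_mass = cfg$body_mass,
    segments = cfg$segments, joints = cfg$joints,
    actuators = if (is.null(cfg$actuators)) list() else cfg$actuators,
    contacts = if (is.null(cfg$contacts)) list() else cfg$contacts,
    bone_sections = if (is.null(cfg$bone_sections)) list() else cfg$bone_sections,
    starting_pose = cfg$starting_pose,
    tendon_reference_pose = cfg$tendon_reference_pose,
    gravity = if (is.null(cfg$gravity)) 9.81 else cfg$gravity,
    muscle_defaults = if (is.null(cfg$muscle_defaults)) list() else cfg$muscle_defaults,
    sim = if (is.null(cfg$sim)) list() else cfg$sim,
    fixed_base = isTRUE(cfg$fixed_base),
    check = check)
}

#' Write a model back to a configuration file
#'
#' Inverse of [load_model()]; a load/save/load round trip yields an
#' identical model.
#'
#' @param m a `jump_model`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  cfg <- list(
    taxon = m$taxon, body_mass = m$body_mass, gravity = m$gravity,
    sim = m$sim, muscle_defaults = m$muscle_defaults,
    tendon_reference_pose = as.list(m$tendon_reference_pose),
    segments = unname(m$segments), joints = unname(m$joints),
    actuators = unname(m$actuators), contacts = m$contacts,
    bone_sections = m$bone_sections,
    starting_pose = as.list(m$starting_pose))
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

# ---- internal topology helpers -------------------------------------------

# Order segments root-first so every parent precedes its children, and
# return indexing tables used by the engine.
model_topology <- function(m) {
  segs <- names(m$segments)
  parent_of <- setNames(rep(NA_character_, length(segs)), segs)
  joint_of <- setNames(rep(NA_character_, length(segs)), segs)
  for (j in m$joints) {
    parent_of[[j$child]] <- j$parent
    joint_of[[j$child]] <- j$name
  }
  order <- m$root
  repeat {
    nxt <- segs[!segs %in% order & parent_of[segs] %in% order]
    if (!length(nxt)) break
    order <- c(order, nxt)
  }
  if (length(order) != length(segs))
    stop("linkage contains segments unreachable from the root", call. = FALSE)
  list(order = order,
       parent = match(parent_of[order], order),  # NA for root
       joint = joint_of[order])
}

# Joints on the kinematic chain between two segments (names).
chain_joints <- function(m, seg_a, seg_b) {
  topo <- model_topology(m)
  path_up <- function(s) {
    out <- character()
    while (!is.na(topo$joint[match(s, topo$order)])) {
      out <- c(out, topo$joint[match(s, topo$order)])
      s <- topo$order[topo$parent[match(s, topo$order)]]
    }
    out
  }
  a_up <- path_up(seg_a)
  b_up <- path_up(seg_b)
  union(setdiff(a_up, b_up), setdiff(b_up, a_up))
}
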