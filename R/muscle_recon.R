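# Muscle reconstruction: PCSA <-> mass conversion, range-of-motion fibre
# lengths, tendon lengths, fibre tuning, schematic mass partitioning,
# regression prediction, and joint-extensor aggregation tables.

MUSCLE_DENSITY <- 1056  # kg m^-3, mammalian/avian skeletal muscle

#' Physiological cross-sectional area from muscle mass
#'
#' PCSA is muscle volume divided by fibre length.  The mass (kg) is
#' converted to a volume in mm^3 using the muscle density and divided by
#' the fibre length in mm.
#'
#' @param mass muscle mass, kg.
#' @param fl fibre (fascicle) length, mm.
#' @param density muscle density, kg m^-3 (default 1056).
#' @return PCSA in mm^2.
#' @seealso [mass_from_pcsa()] for the exact inverse.
#' @examples
#' pcsa_from_mass(1.056, 100)  # 1e6 mm^3 of muscle, 100 mm fibres -> 10000 mm^2
#' @export
pcsa_from_mass <- function(mass, fl, density = MUSCLE_DENSITY) {
  stopifnot(is.numeric(mass), is.numeric(fl), is.numeric(density))
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("mass must be > 0", call. = FALSE)
  if (any(!is.finite(fl)) || any(fl <= 0)) stop("fibre length must be > 0", call. = FALSE)
  if (any(!is.finite(density)) || any(density <= 0)) stop("density must be > 0", call. = FALSE)
  volume_mm3 <- mass / density * 1e9
  volume_mm3 / fl
}

#' Muscle mass from PCSA and fibre length
#'
#' Exact inverse of [pcsa_from_mass()]: mass = pcsa * fl * density.
#'
#' @param pcsa PCSA, mm^2.
#' @param fl fibre length, mm.
#' @param density muscle density, kg m^-3.
#' @return mass in kg.
#' @export
mass_from_pcsa <- function(pcsa, fl, density = MUSCLE_DENSITY) {
  if (any(!is.finite(pcsa)) || any(pcsa < 0)) stop("pcsa must be >= 0", call. = FALSE)
  if (any(!is.finite(fl)) || any(fl <= 0)) stop("fibre length must be > 0", call. = FALSE)
  pcsa * fl * 1e-9 * density
}

#' Fibre length by the range-of-motion method
#'
#' Estimates fibre length as the total excursion of the actuator path over
#' the admissible joint range(s): the difference between the maximum and
#' minimum path length found by a grid search over every joint the actuator
#' crosses.
#'
#' @param model a `jump_model`.
#' @param actuator actuator name.
#' @param resolution_deg grid resolution per joint, degrees (default 1).
#' @param floor_mm fibre-length floor returned (with a warning) when the
#'   path length is constant over the range, mm.
#' @return fibre length in mm.
#' @export
fibre_length_rom <- function(model, actuator, resolution_deg = 1, floor_mm = 1) {
  a <- model$actuators[[actuator]]
  if (is.null(a)) stop("unknown actuator: ", actuator, call. = FALSE)
  segs <- unique(vapply(a$path$anchors, `[[`, "", "segment"))
  crossed <- character()
  for (i in seq_len(length(segs) - 1L))
    crossed <- union(crossed, chain_joints(model, segs[i], segs[i + 1L]))
  crossed <- intersect(names(model$joints), crossed)
  if (!length(crossed)) {
    warning("actuator '", actuator, "' does not cross any joint; zero excursion",
            call. = FALSE)
    return(floor_mm)
  }
  grids <- lapply(crossed, function(jn) {
    j <- model$joints[[jn]]
    seq(j$angle_lo, j$angle_hi, by = resolution_deg)
  })
  poses <- as.matrix(expand.grid(grids))
  colnames(poses) <- crossed
  len <- actuator_path_length(model, actuator, poses)
  excursion <- (max(len) - min(len)) * 1000
  if (excursion < .Machine$double.eps^0.5 * 1000 || excursion < 1e-9) {
    warning("actuator '", actuator, "' has zero path excursion over its range",
            call. = FALSE)
    return(floor_mm)
  }
  excursion
}

#' Path length of an actuator at one or more poses
#'
#' Evaluates the actuator's geometric path (straight segments plus planar
#' wrap circles) at the given joint angles.  Joints not named in `poses`
#' are held at 0 (anatomical neutral).
#'
#' @param model a `jump_model`.
#' @param actuator actuator name.
#' @param poses named numeric vector of joint angles (degrees), or a matrix
#'   with one named column per joint and one row per pose.
#' @return path length(s) in metres.
#' @export
actuator_path_length <- function(model, actuator, poses) {
  a <- model$actuators[[actuator]]
  if (is.null(a)) stop("unknown actuator: ", actuator, call. = FALSE)
  if (is.null(dim(poses))) poses <- matrix(poses, nrow = 1,
                                           dimnames = list(NULL, names(poses)))
  jn <- names(model$joints)
  full <- matrix(0, nrow(poses), length(jn), dimnames = list(NULL, jn))
  keep <- intersect(colnames(poses), jn)
  full[, keep] <- poses[, keep, drop = FALSE]
  eng <- engine_handle(model)
  idx <- match(actuator, names(model$actuators))
  out <- engine_path_lengths(eng, full * pi / 180)
  out[, idx]
}

#' Tendon (series element) slack length from a reference pose
#'
#' Tendon length is defined relative to fibre length: the actuator path
#' length in the reference pose minus the fibre length, floored at zero.
#' Shortening the fibre therefore lengthens the tendon and vice versa.
#'
#' @param reference_length_mm actuator path length at the reference pose, mm.
#' @param fl fibre length, mm.
#' @return tendon slack length in mm; clamping to zero is signalled with a
#'   message.
#' @export
tendon_length_from_reference <- function(reference_length_mm, fl) {
  if (any(!is.finite(reference_length_mm)) || any(reference_length_mm <= 0))
    stop("reference path length must be > 0", call. = FALSE)
  tl <- reference_length_mm - fl
  if (any(tl < 0)) {
    message(sum(tl < 0), " tendon length(s) clamped to 0 (fibre longer than path)")
    tl <- pmax(tl, 0)
  }
  tl
}

#' Apply a fibre-length tuning factor to an actuator
#'
#' Multiplies the fibre length by `factor` and divides PCSA by the same
#' factor, conserving muscle volume (and hence mass).  If the actuator has
#' a stored tendon length it is recomputed against the unchanged reference
#' path length (`tl' = tl + fl - fl'`, floored at zero).
#'
#' @param actuator an actuator description (as stored in a `jump_model`).
#' @param factor positive tuning factor (2 doubles fibre length).
#' @return the modified actuator.
#' @export
apply_fibre_tuning <- function(actuator, factor) {
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0", call. = FALSE)
  fl_old <- actuator$fl
  actuator$fl <- actuator$fl * factor
  actuator$pcsa <- actuator$pcsa / factor
  if (!is.null(actuator$tendon_length) && !is.na(actuator$tendon_length)) {
    ref <- actuator$tendon_length + fl_old
    actuator$tendon_length <- max(0, ref - actuator$fl)
  }
  actuator
}

#' Schematic partitioning scheme for limb muscle mass
#'
#' Parameters of the schematic ("bipedal intermediate") reconstruction:
#' total limb muscle is a fraction of body mass, partitioned
#' proximo-distally across joints and then split between extensors and
#' flexors.
#'
#' @param total_limb_fraction fraction of body mass that is limb muscle
#'   (both limbs; default 0.35).
#' @param joint_fractions named fractions per joint (default hip 0.40,
#'   knee 0.30, ankle 0.20, tmtp 0.10).
#' @param extensor_fraction,flexor_fraction split between actions at each
#'   joint (default 0.65 / 0.35); must sum to 1.
#' @param biarticular_policy how multi-joint actuators accumulate mass:
#'   `"sum-of-joint-shares"` (default; an actuator receives its equal share
#'   from every pool it belongs to) or `"equal-within-action"`.
#' @param missing_joint_policy what to do with the share of a joint absent
#'   from the model: `"drop"` (default) or `"renormalize"`.
#' @return a `partition_scheme` list.
#' @export
partition_scheme <- function(total_limb_fraction = 0.35,
                             joint_fractions = c(hip = 0.40, knee = 0.30,
                                                 ankle = 0.20, tmtp = 0.10),
                             extensor_fraction = 0.65,
                             flexor_fraction = 0.35,
                             biarticular_policy = c("sum-of-joint-shares",
                                                    "equal-within-action"),
                             missing_joint_policy = c("drop", "renormalize")) {
  if (abs(extensor_fraction + flexor_fraction - 1) > 1e-9)
    stop("extensor_fraction + flexor_fraction must equal 1", call. = FALSE)
  if (abs(sum(joint_fractions) - 1) > 1e-9)
    stop("joint_fractions must sum to 1", call. = FALSE)
  structure(list(total_limb_fraction = total_limb_fraction,
                 joint_fractions = joint_fractions,
                 extensor_fraction = extensor_fraction,
                 flexor_fraction = flexor_fraction,
                 biarticular_policy = match.arg(biarticular_policy),
                 missing_joint_policy = match.arg(missing_joint_policy)),
            class = "partition_scheme")
}

#' Partition body mass into per-actuator muscle masses (schematic scheme)
#'
#' Allocates `body_mass * total_limb_fraction / 2` of muscle per limb,
#' splits it across joints and extensor/flexor actions per the scheme, and
#' divides each (joint, action) pool equally among the actuators acting
#' there.  Under the default sum-of-joint-shares policy a biarticular
#' actuator accumulates a share from every pool it belongs to, so the
#' per-limb pool is conserved exactly.
#'
#' @param body_mass total body mass, kg.
#' @param scheme a [partition_scheme()].
#' @param actions named list: for each actuator, a list of
#'   `(joint, role)` pairs (as stored in `jump_model` actuators).
#' @return named numeric vector of per-actuator muscle masses (kg, single
#'   limb).
#' @export
partition_masses_schematic <- function(body_mass, scheme, actions) {
  stopifnot(inherits(scheme, "partition_scheme"))
  per_limb <- body_mass * scheme$total_limb_fraction / 2
  joints_present <- unique(unlist(lapply(actions, function(a)
    vapply(a, `[[`, "", "joint"))))
  jf <- scheme$joint_fractions[names(scheme$joint_fractions) %in% joints_present]
  if (!length(jf))
    stop("no scheme joint is present in the action map", call. = FALSE)
  if (scheme$missing_joint_policy == "renormalize") jf <- jf / sum(jf)

  af <- c(extensor = scheme$extensor_fraction, flexor = scheme$flexor_fraction)
  masses <- setNames(numeric(length(actions)), names(actions))
  for (jn in names(jf)) {
    for (role in names(af)) {
      pool <- per_limb * jf[[jn]] * af[[role]]
      members <- names(actions)[vapply(actions, function(a)
        any(vapply(a, function(ac)
          identical(ac$joint, jn) && identical(ac$role, role), TRUE)), TRUE)]
      if (!length(members))
        stop("empty pool: no actuator acts as ", role, " at joint '", jn, "'",
             call. = FALSE)
      if (scheme$biarticular_policy == "sum-of-joint-shares") {
        masses[members] <- masses[members] + pool / length(members)
      } else {
        # equal-within-action: each pool is still split equally, but a
        # biarticular actuator keeps only its largest single share
        masses[members] <- pmax(masses[members], pool / length(members))
      }
    }
  }
  masses
}

#' Predict muscle mass or PCSA from a bone/attachment area
#'
#' Evaluates a published-style allometric regression
#' `response = 10^(a + b log10(area))` (log-log form) or `a + b * area`
#' (linear form).  Coefficients are user-supplied data.
#'
#' @param area predictor area, mm^2.
#' @param spec list with `a` (intercept), `b` (slope) and logical
#'   `log_log` (default TRUE).
#' @return predicted response (mass in kg or PCSA in mm^2, per the source
#'   equation).
#' @export
predict_regression <- function(area, spec) {
  if (is.null(spec$a) || is.null(spec$b))
    stop("regression spec must provide coefficients 'a' and 'b'", call. = FALSE)
  if (any(!is.finite(area)) || any(area <= 0))
    stop("predictor area must be > 0", call. = FALSE)
  log_log <- if (is.null(spec$log_log)) TRUE else isTRUE(spec$log_log)
  if (log_log) 10^(spec$a + spec$b * log10(area)) else spec$a + spec$b * area
}

#' Read a regression coefficient file
#'
#' Delimited text with columns `actuator`, `a`, `b` and optionally
#' `log_log`.
#'
#' @param path TSV path.
#' @return named list of regression specs keyed by actuator.
#' @export
read_regression_specs <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("actuator", "a", "b")
  if (!all(need %in% names(d)))
    stop("regression file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(d$log_log)) d$log_log <- TRUE
  out <- lapply(seq_len(nrow(d)), function(i)
    list(a = d$a[i], b = d$b[i], log_log = as.logical(d$log_log[i])))
  setNames(out, d$actuator)
}

# round half away from zero, matching table formatting
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Joint-extensor PCSA aggregation table
#'
#' Sums actuator PCSAs into the standard comparison table: total PCSA,
#' total extensor PCSA (each extensor actuator counted exactly once), and
#' per-joint extensor PCSA (a biarticular extensor counted at every joint
#' it extends).  Percentages are extensor share of the total and per-joint
#' share of the extensor total, rounded half away from zero to integers.
#'
#' @param actuators list of actuator descriptions, each with `pcsa` and
#'   `actions` fields (e.g. `model$actuators`).
#' @return list with `pcsa_total`, `ext_total`, `ext_percent`,
#'   `joint_totals` (named vector), `joint_percent` (named integer vector).
#' @export
joint_extensor_totals <- function(actuators) {
  pcsa <- vapply(actuators, `[[`, 0, "pcsa")
  is_ext <- vapply(actuators, function(a)
    any(vapply(a$actions, function(ac) identical(ac$role, "extensor"), TRUE)), TRUE)
  joints <- unique(unlist(lapply(actuators, function(a)
    vapply(a$actions, `[[`, "", "joint"))))
  joint_totals <- setNames(numeric(length(joints)), joints)
  for (jn in joints) {
    at <- vapply(actuators, function(a)
      any(vapply(a$actions, function(ac)
        identical(ac$joint, jn) && identical(ac$role, "extensor"), TRUE)), TRUE)
    joint_totals[[jn]] <- sum(pcsa[at])
  }
  ext_total <- sum(pcsa[is_ext])
  pcsa_total <- sum(pcsa)
  list(pcsa_total = pcsa_total,
       ext_total = ext_total,
       ext_percent = round_half_away(100 * ext_total / pcsa_total),
       joint_totals = joint_totals,
       joint_percent = round_half_away(100 * joint_totals / ext_total))
}

#' Read an actuator parameter table
#'
#' Delimited text with columns `actuator`, `fl` (mm) and one PCSA column
#' per reconstruction variant (`m1`, `m2`, `m3`, mm^2), optionally with
#' printed percent columns `m2_pct`, `m3_pct` used by checksum tests.
#'
#' @param path TSV path.
#' @return data.frame of the table.
#' @export
read_actuator_table <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("actuator", "fl", "m1")
  if (!all(need %in% names(d)))
    stop("actuator table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}
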