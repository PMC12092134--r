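# Reference fixtures and synthetic data: paper-scale human and guineafowl
# models (actuator parameter tables shipped as delimited text, geometry as
# YAML configs), the sensitivity variants, a small "toy" biped for
# optimization experiments, and force/CoM trace synthesis with analytically
# known ground-truth metrics.

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "jumpsim")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  if (!file.exists(p)) stop("fixture file not found: ", file, call. = FALSE)
  p
}

#' Named starting postures
#'
#' Human postures are the measured experimental starting joint angles
#' (degrees; hip flexion positive, knee extension 0 with flexion negative,
#' ankle dorsiflexion positive).  Guineafowl postures are documented
#' estimates built on the hip-starts-horizontal convention (the exact
#' experimental angles are not published); the deeper crouch approximates
#' the deepest countermovement depth.
#'
#' @param taxon "human" or "guineafowl".
#' @return named list of named angle vectors (degrees).
#' @export
posture_table <- function(taxon = c("human", "guineafowl")) {
  taxon <- match.arg(taxon)
  if (taxon == "human") {
    list(full_extension = c(hip = 10, knee = 0, ankle = -5),
         shallow_crouch = c(hip = 67, knee = -58, ankle = 6),
         deep_crouch = c(hip = 114, knee = -95, ankle = 11))
  } else {
    list(crouched = c(hip = 150, knee = -105, ankle = 45, tmtp = -20),
         deeper_crouch = c(hip = 160, knee = -120, ankle = 60, tmtp = -25))
  }
}

VARIANT_NAMES <- c("model1", "model2", "model3", "deeper_crouch",
                   "optimized_tendons", "fl_half", "fl_x2", "fl_x2_tendons")

# apply the PCSA column / tuning / tendon-gene overrides of a variant.
# Tendon lengths are resolved against the reference (starting) pose first
# so fibre tuning recomputes them, mirroring the reconstruction workflow.
apply_variant <- function(model, tab, variant) {
  if (!variant %in% VARIANT_NAMES)
    stop("unknown variant: ", variant, call. = FALSE)
  pcsa_col <- switch(variant, model2 = "m2", model3 = "m3", "m1")
  idx <- match(names(model$actuators), tab$actuator)
  if (anyNA(idx))
    stop("actuator table does not cover: ",
         paste(names(model$actuators)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  for (i in seq_along(model$actuators)) {
    model$actuators[[i]]$fl <- tab$fl[idx[i]]
    model$actuators[[i]]$pcsa <- tab[[pcsa_col]][idx[i]]
    model$actuators[[i]]$region <- tab$region[idx[i]]
  }
  model <- resolve_tendon_lengths(model)
  if (variant %in% c("fl_x2", "fl_x2_tendons")) {
    for (i in seq_along(model$actuators))
      model$actuators[[i]] <- apply_fibre_tuning(model$actuators[[i]], 2)
  }
  if (variant == "fl_half") {
    for (i in seq_along(model$actuators))
      if (identical(model$actuators[[i]]$region, "distal"))
        model$actuators[[i]] <- apply_fibre_tuning(model$actuators[[i]], 0.5)
  }
  model$tendon_genes <- variant %in% c("optimized_tendons", "fl_x2_tendons")
  model$variant <- variant
  model
}

#' Reference human model
#'
#' Builds the 9-actuator planar human model (68.33 kg; bilateral actuator
#' pairs fused with doubled PCSA, contacts pooled per foot) with the
#' requested muscle reconstruction variant and starting posture.  Actuator
#' fibre lengths and PCSAs come from the shipped single-limb parameter
#' table (doubled for the fused planar actuators); Vmax is 8.4 fibre
#' lengths per second.
#'
#' @param variant "model1" (measured masses), "model2" (schematic
#'   partitioning) or "model3" (regression-predicted).
#' @param posture one of the names in `posture_table("human")`.
#' @return a validated `jump_model`.
#' @export
make_reference_human <- function(variant = "model1",
                                 posture = c("full_extension",
                                             "shallow_crouch",
                                             "deep_crouch")) {
  posture <- match.arg(posture)
  if (!variant %in% c("model1", "model2", "model3"))
    stop("unknown variant for the human model: ", variant, call. = FALSE)
  model <- load_model(extdata_path("human_model.yaml"))
  tab <- read_actuator_table(extdata_path("human_actuators.tsv"))
  tab$m1 <- tab$m1 * 2; tab$m2 <- tab$m2 * 2; tab$m3 <- tab$m3 * 2
  model$starting_pose <- posture_table("human")[[posture]]
  model <- apply_variant(model, tab, variant)
  model$posture <- posture
  model
}

#' Reference guineafowl model
#'
#' Builds the 11-actuator planar guineafowl model (1.38 kg, TMTP joint
#' included, Vmax 14 fibre lengths per second) with the requested variant:
#' the three reconstruction models plus the sensitivity variants
#' (`deeper_crouch`, `optimized_tendons`, `fl_half` which tunes distal
#' fibres by 0.5, `fl_x2` which doubles all fibre lengths and halves
#' PCSAs, and `fl_x2_tendons`).
#'
#' @param variant one of `model1`, `model2`, `model3`, `deeper_crouch`,
#'   `optimized_tendons`, `fl_half`, `fl_x2`, `fl_x2_tendons`.
#' @return a validated `jump_model`.
#' @export
make_reference_guineafowl <- function(variant = "model1") {
  model <- load_model(extdata_path("guineafowl_model.yaml"))
  tab <- read_actuator_table(extdata_path("guineafowl_actuators.tsv"))
  tab$m1 <- tab$m1 * 2; tab$m2 <- tab$m2 * 2; tab$m3 <- tab$m3 * 2
  postures <- posture_table("guineafowl")
  model$starting_pose <- if (variant == "deeper_crouch")
    postures$deeper_crouch else postures$crouched
  apply_variant(model, tab, variant)
}

#' Single-limb actuator parameter table of a reference model
#'
#' @param taxon "human" or "guineafowl".
#' @return data frame with fibre lengths and per-variant PCSAs (mm, mm^2).
#' @export
reference_actuator_table <- function(taxon = c("human", "guineafowl")) {
  taxon <- match.arg(taxon)
  read_actuator_table(extdata_path(paste0(taxon, "_actuators.tsv")))
}

#' Toy human-like biped for optimization experiments
#'
#' A deliberately small 4-segment model (trunk, fused thighs, shanks and
#' feet; 6 actuators) whose muscle masses come from the schematic
#' partitioning scheme and whose fibre lengths come from the
#' range-of-motion method applied to its own geometry -- i.e. the toy is
#' built by the package's own reconstruction pipeline.  Integration
#' defaults are coarser than the reference models (dt 1 ms) because the
#' toy exists to make thousands of GA fitness evaluations affordable.
#'
#' @param posture starting posture name (human posture set).
#' @param body_mass body mass, kg.
#' @return a validated `jump_model`.
#' @export
make_toy_biped <- function(posture = c("deep_crouch", "full_extension",
                                       "shallow_crouch"),
                           body_mass = 68.33) {
  posture <- match.arg(posture)
  model <- load_model(extdata_path("toy_biped.yaml"))
  model$body_mass <- body_mass
  model$starting_pose <- posture_table("human")[[posture]]

  # schematic masses -> PCSA through the package's own pipeline
  actions <- lapply(model$actuators, `[[`, "actions")
  scheme <- partition_scheme()   # tmtp share dropped (no such joint)
  masses <- partition_masses_schematic(body_mass, scheme, actions)
  for (nm in names(model$actuators)) {
    fl <- fibre_length_rom(model, nm, resolution_deg = 5)
    model$actuators[[nm]]$fl <- fl
    # fused bilateral pair: double the single-limb mass share
    model$actuators[[nm]]$pcsa <- pcsa_from_mass(2 * masses[[nm]], fl)
  }
  model <- resolve_tendon_lengths(model)
  model$posture <- posture
  model
}

# ---- synthetic force/CoM traces ------------------------------------------

#' Synthesize a force-plate jump trace with known ground truth
#'
#' Constructs a piecewise-smooth vertical GRF profile (quiet standing,
#' optional countermovement unweighting, push-off, decline to take-off,
#' ballistic flight), integrates it into the CoM trace, and returns both
#' the trace and the ground-truth performance metrics computed directly
#' from the constructed profile (the construction is the oracle).  The
#' push amplitude is solved in closed form so the take-off velocity equals
#' `v_takeoff`.
#'
#' @param strategy "CMJ" or "SJ".
#' @param body_mass body mass, kg.
#' @param v_takeoff target vertical take-off velocity, m s^-1.  A value
#'   <= 0 produces a no-flight trace (the force never reaches zero).
#' @param durations list of phase durations in s: `quiet`, `unweight`
#'   (CMJ only), `push`, `decline`.
#' @param unweight_frac unweighting amplitude as a fraction of body
#'   weight (CMJ only).
#' @param noise_sd Gaussian noise added to the force trace, N.
#' @param seed RNG seed for the noise.
#' @param dt sample interval, s.
#' @param com_start initial CoM height, m.
#' @return list with `trace` (data frame `time`, `Fz`, `CoM_z`), `truth`
#'   (ground-truth metric list incl. phase times) and `body_mass`.
#' @export
synth_trace <- function(strategy = c("CMJ", "SJ"), body_mass = 68.4,
                        v_takeoff = 2.75,
                        durations = list(quiet = 0.5, unweight = 0.35,
                                         push = 0.30, decline = 0.08),
                        unweight_frac = 0.3, noise_sd = 0, seed = 1,
                        dt = 1e-3, com_start = 1.0) {
  strategy <- match.arg(strategy)
  g <- 9.81
  BW <- body_mass * g
  d <- modifyList(list(quiet = 0.5, unweight = 0.35, push = 0.30,
                       decline = 0.08), durations)
  U <- if (strategy == "CMJ") unweight_frac * BW else 0
  Tu <- if (strategy == "CMJ") d$unweight else 0
  if (U > BW)
    stop("unweighting amplitude exceeds body weight: Fz would be negative",
         call. = FALSE)

  if (v_takeoff <= 0) {
    # no-flight trace: a small push bump that never approaches zero force
    tt <- seq(0, d$quiet + d$push, by = dt)
    Fz <- BW + 0.1 * BW * sin(pi * pmax(0, tt - d$quiet) / d$push)^2
    acc <- Fz / body_mass - g
    v <- cumsum(c(0, (acc[-1] + acc[-length(acc)]) / 2 * dt))
    z <- com_start + cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * dt))
    tr <- data.frame(time = tt, Fz = Fz, CoM_z = z)
    return(list(trace = tr, truth = NULL, body_mass = body_mass))
  }

  # solve the push amplitude P for the target take-off velocity:
  # dv = [-U Tu/2 + P d3/2 + (P - BW) Td/2] / m
  d3 <- d$push; Td <- d$decline
  P <- (body_mass * v_takeoff + U * Tu / 2 + BW * Td / 2) / ((d3 + Td) / 2)

  seg_force <- function(t) {
    # piecewise profile, t relative to trace start
    f <- rep(BW, length(t))
    t1 <- d$quiet; t2 <- t1 + Tu; t3 <- t2 + d3; t4 <- t3 + Td
    iu <- t > t1 & t <= t2
    f[iu] <- BW - U * sin(pi * (t[iu] - t1) / Tu)^2
    ip <- t > t2 & t <= t3
    f[ip] <- BW + P * sin(pi * (t[ip] - t2) / (2 * d3))^2
    idd <- t > t3 & t <= t4
    f[idd] <- (BW + P) * (1 + cos(pi * (t[idd] - t3) / Td)) / 2
    f[t > t4] <- 0
    f
  }

  t_to <- d$quiet + Tu + d3 + Td
  flight <- v_takeoff / g + 0.15
  tt <- seq(0, t_to + flight, by = dt)
  Fz_clean <- seg_force(tt)
  acc <- Fz_clean / body_mass - g
  v <- cumsum(c(0, (acc[-1] + acc[-length(acc)]) / 2 * dt))
  z <- com_start + cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * dt))

  i_to <- which(tt >= t_to)[1]
  thr <- 0.05 * BW
  i_start <- if (strategy == "CMJ") which(Fz_clean < BW - thr)[1]
             else which(Fz_clean > BW + thr)[1]
  i_low <- if (strategy == "CMJ")
    (i_start:i_to)[which.min(z[i_start:i_to])] else i_start
  seg <- i_low:i_to
  imp <- sum(diff(tt[seg]) * (Fz_clean[seg][-1] + Fz_clean[seg][-length(seg)]) / 2)
  truth <- list(
    t_start = tt[i_start], t_low = tt[i_low], t_takeoff = tt[i_to],
    strategy = strategy,
    max_com_height = z[i_to] + v[i_to]^2 / (2 * g),
    concentric_distance = z[i_to] - z[i_low],
    takeoff_velocity = v[i_to],
    contact_time = tt[i_to] - tt[i_start],
    rnvi = imp / body_mass - g * (tt[i_to] - tt[i_low]))

  Fz <- Fz_clean
  if (noise_sd > 0) {
    set.seed(seed)
    Fz <- Fz + rnorm(length(Fz), sd = noise_sd)
    Fz[tt > t_to] <- 0  # aerial samples stay identically zero
    Fz <- pmax(Fz, 0)
  }
  list(trace = data.frame(time = tt, Fz = Fz, CoM_z = z),
       truth = truth, body_mass = body_mass)
}
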