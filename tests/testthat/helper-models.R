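# Shared fixtures, built in code.  Reference models are cached per session
# because tendon resolution walks the muscle geometry.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

ref_human <- function(variant = "model1", posture = "full_extension")
  cached(paste("h", variant, posture), function()
    make_reference_human(variant, posture))

ref_gf <- function(variant = "model1")
  cached(paste("g", variant), function() make_reference_guineafowl(variant))

toy_biped <- function(posture = "deep_crouch")
  cached(paste("t", posture), function() make_toy_biped(posture))

# minimal two-segment hopper: a body over a leg with one contact
hopper_model <- function() jump_model(
  taxon = "hopper", body_mass = 11,
  segments = list(
    list(name = "body", shape = list(type = "cuboid", length = 0.3,
                                     width = 0.2, depth = 0.1667), density = 1000),
    list(name = "leg", shape = list(type = "cylinder", length = 0.4,
                                    radius = 0.02), density = 1989.4)),
  joints = list(list(name = "hip", parent = "body", child = "leg",
                     anchor = c(0, 0), offset_deg = -90,
                     angle_lo = -60, angle_hi = 60,
                     soft_limit_stiffness = 50, soft_limit_damping = 1)),
  contacts = list(list(segment = "leg", local_pos = c(0.4, 0),
                       stiffness = 2e4, damping = 500, friction_mu = 1)),
  starting_pose = c(hip = 0), check = FALSE)

# single free body (no joints, no contacts): ballistic test mass
ball_model <- function(radius = 0.05, length = 0.4, density = 1000) jump_model(
  taxon = "ball", body_mass = density * pi * radius^2 * length,
  segments = list(list(name = "b",
                       shape = list(type = "cylinder", length = length,
                                    radius = radius), density = density)),
  joints = list(), check = TRUE)

# fixed-base physical pendulum: uniform rod pivoting about one end
pendulum_model <- function(rod_length = 1) jump_model(
  taxon = "pendulum", body_mass = 1000.0314,
  segments = list(
    list(name = "anchor", shape = list(type = "cuboid", length = 0.1,
                                       width = 0.1, depth = 1), density = 1e5),
    list(name = "rod", shape = list(type = "cylinder", length = rod_length,
                                    radius = 0.0031623), density = 1000)),
  joints = list(list(name = "pivot", parent = "anchor", child = "rod",
                     anchor = c(0, 0), offset_deg = -90,
                     angle_lo = -180, angle_hi = 180,
                     soft_limit_stiffness = 0, soft_limit_damping = 0)),
  fixed_base = TRUE, check = FALSE)

# constant-moment-arm rig: wrap circle at the joint, anchors close to it,
# engaged throughout [-95, 0] degrees
const_arm_rig <- function(r = 0.04, lo = -95, hi = 0, dir = 1) jump_model(
  taxon = "rig", body_mass = 1000.785,
  segments = list(
    list(name = "a", shape = list(type = "cuboid", length = 0.3, width = 0.3,
                                  depth = 1.0), density = 1.1e4),
    list(name = "b", shape = list(type = "cylinder", length = 0.3,
                                  radius = 0.02), density = 1000)),
  joints = list(list(name = "j", parent = "a", child = "b", anchor = c(0.3, 0),
                     angle_lo = lo, angle_hi = hi, offset_deg = 0)),
  actuators = list(list(name = "mus", fl = 50, pcsa = 100, vmax = 8,
                        actions = list(list(joint = "j", role = "extensor")),
                        path = list(
                          anchors = list(list(segment = "a", pos = c(0.245, 0)),
                                         list(segment = "b", pos = c(0.055, 0))),
                          wraps = list(list(after = 1, segment = "b",
                                            centre = c(0, 0), radius = r,
                                            direction = dir))),
                        tendon_length = 10)),
  fixed_base = TRUE, check = FALSE)
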