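# Muscle reconstruction: mass/PCSA conversion, range-of-motion fibre
# lengths, tendon lengths, tuning, schematic partitioning, regression
# prediction and the joint-extensor aggregation tables.

test_that("pcsa <-> mass conversion is exact and self-inverse", {
  # 1.056 kg at density 1056 is 1e6 mm^3 by construction
  expect_equal(pcsa_from_mass(1.056, 100, 1056), 10000, tolerance = 1e-12)

  # inverse relation: the mass that yields the measured human hip-extensor
  # PCSA at its fibre length (oracle: mass = pcsa * fl * rho)
  mass <- mass_from_pcsa(5534.583, 172.295)
  expect_equal(mass, 5534.583 * 172.295 * 1e-9 * 1056, tolerance = 1e-12)
  expect_equal(pcsa_from_mass(mass, 172.295), 5534.583, tolerance = 1e-9)

  # property: round trip exact for random fl/density
  set.seed(42)
  for (i in 1:20) {
    fl <- runif(1, 5, 300); rho <- runif(1, 900, 1200); m <- runif(1, 0.01, 5)
    expect_equal(mass_from_pcsa(pcsa_from_mass(m, fl, rho), fl, rho), m,
                 tolerance = 1e-9)
  }

  expect_error(pcsa_from_mass(1, 0), "fibre length")
  expect_error(pcsa_from_mass(-1, 10), "mass")
})

test_that("range-of-motion fibre length matches the r*dtheta closed form", {
  # constant moment arm 0.04 m over a 95 degree range -> 66.32 mm
  rig <- const_arm_rig(r = 0.04, lo = -95, hi = 0, dir = 1)
  fl <- fibre_length_rom(rig, "mus", resolution_deg = 1)
  expect_equal(fl, 0.04 * 95 * pi / 180 * 1000, tolerance = 0.05)

  # moment arm is constant (wrap engaged) across the working range
  th <- seq(-90, -2, by = 2)
  L <- vapply(th, function(a) actuator_path_length(rig, "mus", c(j = a)), 0)
  dL <- diff(L) / diff(th * pi / 180)
  expect_true(all(abs(abs(dL) - 0.04) < 1e-6))
})

test_that("two-joint excursions add for constant moment arms", {
  # separate single-joint rigs give r1*dth1 and r2*dth2; a grid search over
  # a two-joint path must find the sum (additivity of the line integral)
  m <- jump_model(
    taxon = "rig2", body_mass = 1001.57,
    segments = list(
      list(name = "a", shape = list(type = "cuboid", length = 0.3, width = 0.3,
                                    depth = 1.0), density = 1.1e4),
      list(name = "b", shape = list(type = "cylinder", length = 0.3,
                                    radius = 0.02), density = 1000),
      list(name = "c", shape = list(type = "cylinder", length = 0.3,
                                    radius = 0.02), density = 1000)),
    joints = list(
      list(name = "j1", parent = "a", child = "b", anchor = c(0.3, 0),
           angle_lo = -95, angle_hi = 0, offset_deg = 0),
      list(name = "j2", parent = "b", child = "c", anchor = c(0.3, 0),
           angle_lo = -80, angle_hi = 0, offset_deg = 0)),
    actuators = list(list(
      name = "bi", fl = 50, pcsa = 100, vmax = 8,
      actions = list(list(joint = "j1", role = "extensor"),
                     list(joint = "j2", role = "extensor")),
      path = list(
        anchors = list(list(segment = "a", pos = c(0.245, 0)),
                       list(segment = "b", pos = c(0.055, 0)),
                       list(segment = "b", pos = c(0.245, 0)),
                       list(segment = "c", pos = c(0.055, 0))),
        wraps = list(list(after = 1, segment = "b", centre = c(0, 0),
                          radius = 0.04, direction = 1),
                     list(after = 3, segment = "c", centre = c(0, 0),
                          radius = 0.03, direction = 1))),
      tendon_length = 10)),
    fixed_base = TRUE, check = FALSE)
  fl <- fibre_length_rom(m, "bi", resolution_deg = 2.5)
  expect_equal(fl, (0.04 * 95 + 0.03 * 80) * pi / 180 * 1000, tolerance = 0.3)
})

test_that("an actuator crossing no joint warns and floors", {
  m <- hopper_model()
  m$actuators <- list(`flat` = jumpsim:::norm_actuator(list(
    name = "flat", fl = 10, pcsa = 10, vmax = 8,
    actions = list(list(joint = "hip", role = "extensor")),
    path = list(anchors = list(list(segment = "leg", pos = c(0.1, 0)),
                               list(segment = "leg", pos = c(0.3, 0))))),
    jumpsim:::default_muscle_params()))
  expect_warning(fl <- fibre_length_rom(m, "flat"), "zero")
  expect_equal(fl, 1)
})

test_that("tendon length is reference path length minus fibre length", {
  expect_equal(tendon_length_from_reference(300, 66.32), 233.68)
  expect_equal(tendon_length_from_reference(100, 100), 0)
  expect_message(tl <- tendon_length_from_reference(80, 100), "clamped")
  expect_equal(tl, 0)
  expect_error(tendon_length_from_reference(0, 10), "positive|> 0")
})

test_that("fibre tuning conserves muscle volume and recomputes the tendon", {
  a <- list(fl = 10, pcsa = 100, tendon_length = 40)
  a2 <- apply_fibre_tuning(a, 2)
  expect_equal(a2$fl, 20)
  expect_equal(a2$pcsa, 50)
  expect_equal(a2$fl * a2$pcsa, a$fl * a$pcsa)     # volume conserved
  expect_equal(a2$tendon_length, 30)               # reference 50 kept fixed

  expect_identical(apply_fibre_tuning(a, 1), a)

  # property: volume conserved for any factor
  set.seed(7)
  for (f in runif(10, 0.2, 5)) {
    af <- apply_fibre_tuning(a, f)
    expect_equal(af$fl * af$pcsa, 1000, tolerance = 1e-9)
  }
  expect_error(apply_fibre_tuning(a, 0), "factor")
})

test_that("distal-only tuning leaves proximal actuators untouched", {
  g1 <- ref_gf("model1")
  gh <- ref_gf("fl_half")
  for (nm in names(g1$actuators)) {
    r <- g1$actuators[[nm]]$region
    f <- gh$actuators[[nm]]$fl / g1$actuators[[nm]]$fl
    expect_equal(f, if (r == "distal") 0.5 else 1, tolerance = 1e-9)
  }
})

test_that("schematic partitioning reproduces the stated arithmetic", {
  # four-joint biped, one actuator per (joint, action) pool
  joints <- c("hip", "knee", "ankle", "tmtp")
  actions <- list()
  for (j in joints) for (r in c("extensor", "flexor"))
    actions[[paste(j, r)]] <- list(list(joint = j, role = r))
  sch <- partition_scheme()
  masses <- partition_masses_schematic(100, sch, actions)
  expect_equal(sum(masses), 17.5)                       # per-limb pool
  expect_equal(sum(masses[grepl("^hip", names(masses))]), 7.0)
  expect_equal(masses[["hip extensor"]], 4.55)          # 17.5 * 0.4 * 0.65

  # degenerate scheme: all mass at the hip, split 65:35
  sch2 <- partition_scheme(joint_fractions = c(hip = 1))
  m2 <- partition_masses_schematic(100, sch2,
                                   actions[c("hip extensor", "hip flexor")])
  expect_equal(unname(m2), 17.5 * c(0.65, 0.35))

  # human-style model without a TMTP joint: drop discards the 10% share,
  # renormalize redistributes it
  a3 <- actions[!grepl("^tmtp", names(actions))]
  drop <- partition_masses_schematic(100, sch, a3)
  ren <- partition_masses_schematic(
    100, partition_scheme(missing_joint_policy = "renormalize"), a3)
  expect_equal(sum(drop), 17.5 * 0.9)
  expect_equal(sum(ren), 17.5)
  expect_equal(sum(ren) - sum(drop), 17.5 * 0.1)

  expect_error(partition_masses_schematic(100, sch, actions["hip extensor"]),
               "empty pool")
})

test_that("per-limb pool is conserved under sum-of-joint-shares", {
  # property test over random schemes and random biarticular action maps
  set.seed(11)
  joints <- c("hip", "knee", "ankle", "tmtp")
  for (rep in 1:10) {
    jf <- runif(4); jf <- jf / sum(jf); names(jf) <- joints
    ef <- runif(1, 0.4, 0.9)
    sch <- partition_scheme(total_limb_fraction = runif(1, 0.2, 0.5),
                            joint_fractions = jf,
                            extensor_fraction = ef, flexor_fraction = 1 - ef)
    actions <- list()
    for (j in joints) for (r in c("extensor", "flexor"))
      actions[[paste(j, r)]] <- list(list(joint = j, role = r))
    # add two random biarticulars
    for (b in 1:2) {
      js <- sample(joints, 2)
      actions[[paste0("bi", b)]] <-
        list(list(joint = js[1], role = sample(c("extensor", "flexor"), 1)),
             list(joint = js[2], role = sample(c("extensor", "flexor"), 1)))
    }
    masses <- partition_masses_schematic(60, sch, actions)
    expect_equal(sum(masses), 60 * sch$total_limb_fraction / 2,
                 tolerance = 1e-9)
  }
})

test_that("regression prediction evaluates the allometric form", {
  expect_equal(predict_regression(123.4, list(a = 0, b = 1)), 123.4)
  expect_equal(predict_regression(100, list(a = -2, b = 1.5)), 10)
  expect_equal(predict_regression(50, list(a = 1, b = 0.5, log_log = FALSE)),
               26)
  expect_error(predict_regression(-1, list(a = 0, b = 1)), "area")
  expect_error(predict_regression(10, list(b = 1)), "coefficients")

  f <- tempfile(fileext = ".tsv")
  writeLines(c("actuator\ta\tb", "hip ext\t-2\t1.5"), f)
  specs <- read_regression_specs(f)
  expect_equal(predict_regression(100, specs[["hip ext"]]), 10)
})
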