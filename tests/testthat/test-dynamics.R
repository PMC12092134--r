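# Forward-dynamics engine: force-element unit checks against closed forms,
# and integration-level conservation/consistency properties.

test_that("Hill force endpoints and hyperbola values are exact", {
  p <- list(fmax = 0.3 * 1000, lopt_mm = 100, vmax = 8, fv_shape = 0.25,
            fl_width = 0.5, pe_k_rel = 0.1, pe_engage = 0)
  # fully active, isometric, optimal length: F = sigma_max * pcsa
  expect_equal(hill_force(p, 1, 100, 0), 300)
  # shortening at vmax: zero force
  expect_equal(hill_force(p, 1, 100, 8), 0)
  # Hill hyperbola at v = vmax/3 with a/F0 = 0.25: (1 - 1/3)/(1 + (1/3)/0.25)
  expect_equal(hill_force(p, 1, 100, 8 / 3) / 300, 2 / 7, tolerance = 1e-12)
  # eccentric plateau at 1
  expect_equal(hill_force(p, 1, 100, -5), 300)
  # force-length: zero beyond the half-width, symmetric
  expect_equal(hill_force(p, 1, 150, 0), 0.1 * 300 * 0.5)  # PE only
  expect_equal(hill_force(p, 1, 50, 0), 0)
  expect_equal(hill_force(p, 1, 125, 0) - 0.1 * 300 * 0.25,
               hill_force(p, 1, 75, 0), tolerance = 1e-12)
  expect_error(hill_force(p, 1.2, 100, 0), "activation")
})

test_that("R and compiled Hill curves agree over a state grid", {
  p <- list(fmax = 500, lopt_mm = 80, vmax = 10, fv_shape = 0.25,
            fl_width = 0.5, pe_k_rel = 0.1, pe_engage = 0)
  grid <- expand.grid(act = c(0, 0.3, 1), lce = seq(30, 150, by = 15),
                      vce = seq(-5, 12, by = 2.4))
  for (i in seq_len(nrow(grid))) {
    r_val <- hill_force(p, grid$act[i], grid$lce[i], grid$vce[i])
    c_val <- jumpsim:::engine_hill_force(p, grid$act[i], grid$lce[i],
                                         grid$vce[i])
    expect_equal(r_val, c_val, tolerance = 1e-12)
  }
})

test_that("peak shortening power sits near 0.3 vmax for a/F0 = 0.25", {
  p <- list(fmax = 1000, lopt_mm = 100, vmax = 8, fv_shape = 0.25,
            fl_width = 0.5, pe_k_rel = 0, pe_engage = 0)
  v <- seq(0.01, 7.99, by = 0.002)
  pow <- vapply(v, function(vi) hill_force(p, 1, 100, vi) * vi, 0)
  v_opt <- v[which.max(pow)] / p$vmax
  # analytic optimum sqrt(a (1 + a)) - a = 0.309
  expect_equal(v_opt, sqrt(0.25 * 1.25) - 0.25, tolerance = 0.005)
  expect_equal(v_opt, 0.3, tolerance = 0.05)
})

test_that("joint limit torque is zero inside and restoring outside", {
  j <- list(angle_lo = -30, angle_hi = 60, soft_limit_stiffness = 100,
            soft_limit_damping = 2)
  expect_equal(joint_limit_torque(0, 50, j), 0)
  expect_equal(joint_limit_torque(62, 0, j), -100 * 2 * pi / 180)
  expect_equal(joint_limit_torque(62, 10, j),
               -100 * 2 * pi / 180 - 2 * 10 * pi / 180)
  # restoring torque always opposes further violation
  expect_gt(joint_limit_torque(-35, 0, j), 0)
  expect_lt(joint_limit_torque(65, 0, j), 0)
})

test_that("contact force is unilateral with spring-damper loading", {
  expect_equal(contact_force(0.01, -1, 0, 1e5, 100), c(Fz = 0, Fx = 0))
  expect_equal(contact_force(-0.001, 0, 0, 1e5, 100)[["Fz"]], 100)
  # damping pull-off exceeding the spring force clamps to zero (no adhesion)
  expect_equal(contact_force(-0.001, 10, 0, 1e5, 100)[["Fz"]], 0)
  # friction bounded by mu * Fz and opposing slip
  f <- contact_force(-0.001, 0, 0.5, 1e5, 100, friction_mu = 0.8)
  expect_lt(abs(f[["Fx"]]), 0.8 * f[["Fz"]] + 1e-9)
  expect_lt(f[["Fx"]], 0)
})

test_that("bone stress follows the axial-plus-bending beam formula", {
  r <- 0.01
  sec <- list(area = pi * r^2, second_moment = pi * r^4 / 4, c = r)
  expect_equal(bone_stress(1000, 0, sec), 1000 / (pi * r^2))      # 3.183 MPa
  expect_equal(bone_stress(1000, 0, sec) / 1e6, 3.1831, tolerance = 1e-4)
  expect_equal(bone_stress(0, 10, sec) / 1e6, 12.7324, tolerance = 1e-4)
  expect_equal(bone_stress(0, 0, sec), 0)
  expect_equal(bone_stress(-1000, -10, sec),
               bone_stress(1000, 10, sec))  # magnitude convention
})

test_that("a resting model without gravity stays exactly at rest", {
  m <- hopper_model()
  m$gravity <- 0
  q0 <- initial_state(m, settle = FALSE)
  tr <- simulate_jump(m, constant_controller(m, 0), duration = 1, dt = 1e-4,
                      q0 = q0)
  qcols <- grep("^q_|^base_", names(tr), value = TRUE)
  for (cc in qcols)
    expect_lt(max(abs(tr[[cc]] - tr[[cc]][1])), 1e-9)
})

test_that("free fall reproduces sqrt(2 g h) impact speed", {
  m <- ball_model()
  tr <- simulate_jump(m, constant_controller(m, 0), duration = 0.4518,
                      dt = 1e-4, q0 = c(0, 1, 0), qd0 = c(0, 0, 0))
  # after falling 1 m the speed is sqrt(2 * 9.81 * 1) = 4.429 m/s
  drop <- 1 - (tr$com_z - tr$com_z[1]) - 1
  i <- which.min(abs(tr$com_z[1] - tr$com_z - 1))
  expect_equal(abs(tr$com_vz[i]), sqrt(2 * 9.81), tolerance = 1e-3)
})

test_that("a passive pendulum swings with the physical period", {
  m <- pendulum_model()
  q0 <- c(0, 0, 0, 5 * pi / 180)
  tr <- simulate_jump(m, constant_controller(m, 0), duration = 4, dt = 1e-4,
                      q0 = q0, qd0 = rep(0, 4))
  th <- tr$q_pivot
  pk <- which(diff(sign(diff(th))) != 0) + 1
  period <- mean(diff(tr$time[pk])) * 2
  # uniform rod about its end: T = 2 pi sqrt( (L^2/3) / (g L/2) )
  expect_equal(period, 2 * pi * sqrt((1 / 3) / (9.81 / 2)), tolerance = 0.005)
})

test_that("conservative submodel drifts less than 0.1% energy over 1 s", {
  m <- pendulum_model()
  q0 <- c(0, 0, 0, 60 * pi / 180)   # large-amplitude, still conservative
  for (integ in c("semi_implicit", "rk4")) {
    tr <- simulate_jump(m, constant_controller(m, 0), duration = 1, dt = 1e-4,
                        q0 = q0, qd0 = rep(0, 4), integrator = integ)
    E <- tr$energy_kinetic + tr$energy_potential
    scale <- max(E) - min(tr$energy_potential)  # energy swing of the motion
    expect_lt((max(E) - min(E)) / scale, 0.001)
  }
})

test_that("impulse-momentum holds to 1 mm/s on a simulated hop", {
  # the identity is exact in continuous time; the residual of the discrete
  # staggered-velocity measurement is first-order in dt, so a fine step is
  # used for the check
  toy <- toy_biped("deep_crouch")
  ctl <- constant_controller(
    toy, c(`hip ext` = 1, `knee ext` = 1, `ankle ext` = 1))
  tr <- simulate_jump(toy, ctl, duration = 0.5, dt = 2e-5,
                      check_stress = FALSE)
  g <- attr(tr, "gravity"); M <- attr(tr, "body_mass")
  # integral of (sum Fz - m g) dt / m vs change in vertical CoM velocity
  lhs <- tr$grf_impulse_z / M - g * tr$time
  rhs <- tr$com_vz - tr$com_vz[1]
  expect_lt(max(abs(lhs - rhs)), 1e-3)
})

test_that("aerial apex equals the ballistic prediction from take-off", {
  # finite push (extensors on for 0.3 s, then off) -> one clean jump
  toy <- toy_biped("deep_crouch")
  lev <- matrix(0, 6, 2)
  lev[match(c("hip ext", "knee ext", "ankle ext"), names(toy$actuators)), 1] <- 1
  ctl <- list(durations = matrix(c(0.3, 5), 6, 2, byrow = TRUE), levels = lev)
  # fine step: the discrete CoM momentum of the articulated body drifts at
  # first order in dt while the limbs swing in flight
  tr <- simulate_jump(toy, ctl, duration = 0.9, dt = 1e-5,
                      record_dt = 1e-4, check_stress = FALSE)
  ia <- which.max(tr$com_z)
  i <- max(which(tr$grf_z > 0.5 & seq_len(nrow(tr)) < ia)) + 1L
  expect_gt(tr$time[ia] - tr$time[i], 0.05)  # genuine flight phase
  # reference point fully inside the aerial phase so the central-difference
  # velocity stencil is purely ballistic
  j <- i + 2L
  v_j <- (tr$com_z[j + 1] - tr$com_z[j - 1]) / (tr$time[j + 1] - tr$time[j - 1])
  apex <- max(tr$com_z)
  expect_equal(ballistic_height(tr$com_z[j], v_j, 9.81), apex,
               tolerance = 1e-6 / apex)
})

test_that("muscle work components sum to total actuator work", {
  toy <- toy_biped("deep_crouch")
  ctl <- constant_controller(
    toy, c(`hip ext` = 0.8, `knee ext` = 0.8, `ankle ext` = 0.8))
  tr <- simulate_jump(toy, ctl, duration = 0.4, dt = 1e-4,
                      check_stress = FALSE)
  last <- nrow(tr)
  for (mus in c("hip_ext", "knee_ext", "ankle_ext")) {
    wce <- tr[[paste0(mus, "_wce")]][last]
    wse <- tr[[paste0(mus, "_wse")]][last]
    wpe <- tr[[paste0(mus, "_wpe")]][last]
    wmtu <- tr[[paste0(mus, "_wmtu")]][last]
    expect_equal(wce + wse + wpe, wmtu,
                 tolerance = max(1e-3, abs(wmtu)) * 0.001 / max(1e-3, abs(wmtu)))
  }
})

test_that("ground reaction force is never negative", {
  toy <- toy_biped("deep_crouch")
  ctl <- constant_controller(
    toy, c(`hip ext` = 1, `knee ext` = 1, `ankle ext` = 1))
  tr <- simulate_jump(toy, ctl, duration = 0.8, dt = 1e-3,
                      check_stress = FALSE)
  expect_true(all(tr$grf_z >= 0))
})

test_that("the bone-stress constraint stops the simulation with a flag", {
  toy <- make_toy_biped("deep_crouch")
  for (i in seq_along(toy$bone_sections))
    toy$bone_sections[[i]]$failure_stress <- 1e6   # absurdly fragile bones
  ctl <- constant_controller(
    toy, c(`hip ext` = 1, `knee ext` = 1, `ankle ext` = 1))
  tr <- simulate_jump(toy, ctl, duration = 0.8, dt = 1e-3)
  fl <- attr(tr, "flags")
  expect_true(fl$stress_exceeded)
  expect_lt(fl$end_time, 0.8)
})

test_that("trajectories round-trip through tab-separated text", {
  m <- ball_model()
  tr <- simulate_jump(m, constant_controller(m, 0), duration = 0.1,
                      q0 = c(0, 1, 0))
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_identical(names(back), names(as.data.frame(tr)))
  expect_equal(back$com_z, tr$com_z, tolerance = 1e-9)
})
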