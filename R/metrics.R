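# Jump performance analysis: phase detection from force/position criteria,
# strategy classification (countermovement vs squat), and the discrete
# performance parameters used to compare simulations with experiments.
# Applies identically to simulated trajectories and force-plate style
# traces (columns time, Fz, CoM_z).

as_trace <- function(trace) {
  d <- as.data.frame(trace)
  if (all(c("grf_z", "com_z") %in% names(d)) && !"Fz" %in% names(d)) {
    d <- data.frame(time = d$time, Fz = d$grf_z, CoM_z = d$com_z)
  }
  need <- c("time", "Fz", "CoM_z")
  if (!all(need %in% names(d)))
    stop("trace needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  d
}

#' Detect the phases of a jump from force and position criteria
#'
#' The jump start is the first crossing of body weight by +/-5% (a drop
#' below `(1 - start_threshold) * BW` indicates countermovement
#' unweighting, a rise above `(1 + start_threshold) * BW` squat
#' mechanics); take-off is the first sample at which the vertical force
#' reaches zero (below `takeoff_epsilon`); the eccentric-concentric
#' transition of a countermovement is the lowest CoM position between
#' start and take-off; the apex is the CoM maximum after take-off.
#'
#' @param trace data frame with columns `time`, `Fz` (N), `CoM_z` (m); a
#'   `jump_trajectory` is accepted directly.
#' @param body_weight body weight in N; estimated from the quiet-standing
#'   samples before the start when NULL.
#' @param start_threshold relative force-change threshold (default 0.05).
#' @param takeoff_epsilon force level treated as zero, N (default 0.5).
#' @param takeoff_hold number of consecutive samples a threshold condition
#'   must persist before the start or take-off is called (debounces sensor
#'   noise; on noise-free traces the first sample of the persistent block
#'   is returned either way).
#' @param min_quiet minimum initial quiet-standing period used for the
#'   body-weight estimate, s.
#' @return a `jump_phases` list: `t_start`, `t_low`, `t_takeoff`,
#'   `t_apex`, `strategy` ("CMJ" or "SJ") and the body weight used.
#' @export
detect_phases <- function(trace, body_weight = NULL, start_threshold = 0.05,
                          takeoff_epsilon = 0.5, takeoff_hold = 3,
                          min_quiet = 0) {
  d <- as_trace(trace)
  n <- nrow(d)
  if (is.null(body_weight)) {
    quiet <- d$time - d$time[1] <= max(min_quiet, 0.1)
    body_weight <- mean(d$Fz[quiet])
  }
  hi <- body_weight * (1 + start_threshold)
  lo <- body_weight * (1 - start_threshold)
  hold <- max(1L, min(takeoff_hold, n))
  runlen <- function(flag) {
    r <- stats::filter(as.numeric(flag), rep(1, hold), sides = 1)
    which(r == hold)[1] - hold + 1L
  }
  i_start <- runlen(d$Fz > hi | d$Fz < lo)
  if (is.na(i_start))
    stop("no-jump: vertical force never departs from body weight by ",
         100 * start_threshold, "%", call. = FALSE)
  strategy <- if (d$Fz[i_start] < lo) "CMJ" else "SJ"
  i_to <- runlen(seq_len(n) > i_start & d$Fz <= takeoff_epsilon)
  if (is.na(i_to))
    stop("no-takeoff: vertical force never reaches zero", call. = FALSE)
  if (strategy == "CMJ") {
    seg <- i_start:i_to
    i_low <- seg[which.min(d$CoM_z[seg])]
  } else {
    i_low <- i_start
  }
  post <- i_to:n
  i_apex <- post[which.max(d$CoM_z[post])]
  structure(list(t_start = d$time[i_start], t_low = d$time[i_low],
                 t_takeoff = d$time[i_to], t_apex = d$time[i_apex],
                 i_start = i_start, i_low = i_low, i_takeoff = i_to,
                 i_apex = i_apex,
                 strategy = strategy, body_weight = body_weight),
            class = "jump_phases")
}

#' @export
print.jump_phases <- function(x, ...) {
  cat("<jump_phases> ", x$strategy, "\n", sep = "")
  cat(sprintf("  start %.4f s | low %.4f s | take-off %.4f s | apex %.4f s\n",
              x$t_start, x$t_low, x$t_takeoff, x$t_apex))
  invisible(x)
}

# central-difference vertical velocity of the CoM at sample i
com_velocity_at <- function(d, i) {
  n <- nrow(d)
  i0 <- max(1, i - 1)
  i1 <- min(n, i + 1)
  (d$CoM_z[i1] - d$CoM_z[i0]) / (d$time[i1] - d$time[i0])
}

#' Discrete jump performance metrics
#'
#' Computes the standard force-plate performance parameter set:
#' \describe{
#'   \item{max_com_height}{maximum vertical CoM position (jump height), m.}
#'   \item{concentric_distance}{vertical CoM travel from its lowest
#'     position to take-off, m.}
#'   \item{takeoff_velocity}{vertical CoM velocity at take-off
#'     (central difference), m s^-1.}
#'   \item{contact_time}{time from jump start to take-off, s.}
#'   \item{rnvi}{relative net vertical impulse over the concentric phase:
#'     the vertical GRF impulse net of body weight divided by body mass
#'     (numerically m s^-1); by impulse-momentum this equals the CoM
#'     velocity change over the same window.}
#' }
#'
#' @param trace as in [detect_phases()].
#' @param phases a `jump_phases` from [detect_phases()].
#' @param body_mass body mass in kg (default from the phases' body
#'   weight and `g`).
#' @param g gravitational acceleration, m s^-2.
#' @return a `jump_metrics` list (includes the strategy label).
#' @export
compute_metrics <- function(trace, phases, body_mass = NULL, g = 9.81) {
  if (!inherits(phases, "jump_phases"))
    stop("phases must come from detect_phases()", call. = FALSE)
  d <- as_trace(trace)
  if (is.null(body_mass)) body_mass <- phases$body_weight / g
  i_low <- phases$i_low; i_to <- phases$i_takeoff
  seg <- i_low:i_to
  t <- d$time[seg]
  imp <- sum(diff(t) * (d$Fz[seg][-1] + d$Fz[seg][-length(seg)]) / 2)
  rnvi <- imp / body_mass - g * (phases$t_takeoff - phases$t_low)
  structure(list(
    max_com_height = d$CoM_z[phases$i_apex],
    concentric_distance = d$CoM_z[i_to] - d$CoM_z[i_low],
    takeoff_velocity = com_velocity_at(d, i_to),
    contact_time = phases$t_takeoff - phases$t_start,
    rnvi = rnvi,
    strategy = phases$strategy,
    body_mass = body_mass), class = "jump_metrics")
}

#' @export
print.jump_metrics <- function(x, ...) {
  cat("<jump_metrics> ", x$strategy, "\n", sep = "")
  cat(sprintf("  max CoM height      %.3f m\n", x$max_com_height))
  cat(sprintf("  concentric distance %.3f m\n", x$concentric_distance))
  cat(sprintf("  take-off velocity   %.3f m/s\n", x$takeoff_velocity))
  cat(sprintf("  contact time        %.3f s\n", x$contact_time))
  cat(sprintf("  RNVI                %.3f m/s\n", x$rnvi))
  invisible(x)
}

#' Ballistic centre-of-mass apex prediction
#'
#' `com_max = com_takeoff + v_takeoff^2 / (2 g)`: the maximum height the
#' CoM reaches after leaving the ground with the given vertical velocity.
#'
#' @param com_takeoff CoM height at take-off, m.
#' @param v_takeoff vertical CoM velocity at take-off, m s^-1.
#' @param g gravitational acceleration, m s^-2.
#' @return predicted maximum CoM height, m.
#' @examples
#' ballistic_height(0.25, 3.3)  # 0.805 m
#' @export
ballistic_height <- function(com_takeoff, v_takeoff, g = 9.81) {
  if (any(g <= 0)) stop("g must be > 0", call. = FALSE)
  com_takeoff + v_takeoff^2 / (2 * g)
}

#' Classify the kinematic strategy of a jump
#'
#' Countermovement (CMJ) if the CoM descends below its starting height by
#' more than `depth_threshold` before take-off (the transient use of a
#' more flexed posture); squat jump (SJ) otherwise.  A descent exactly at
#' the threshold classifies as CMJ (">=" rule).
#'
#' @param trace as in [detect_phases()].
#' @param phases optional `jump_phases`; when NULL only the CoM descent
#'   criterion is used with take-off taken as the CoM apex.
#' @param depth_threshold countermovement depth threshold, m (default
#'   0.005, distinguishing numerical jitter from a real countermovement).
#' @return `"CMJ"` or `"SJ"`.
#' @export
classify_strategy <- function(trace, phases = NULL, depth_threshold = 0.005) {
  d <- as_trace(trace)
  i_end <- if (!is.null(phases)) phases$i_takeoff else which.max(d$CoM_z)
  start_z <- d$CoM_z[1]
  depth <- start_z - min(d$CoM_z[seq_len(i_end)])
  if (depth >= depth_threshold) "CMJ" else "SJ"
}

#' Full metric pipeline for a simulated trajectory
#'
#' Convenience wrapper: phase detection, metric computation and strategy
#' classification on a `jump_trajectory`.
#'
#' @param traj a `jump_trajectory` from [simulate_jump()].
#' @param ... passed to [detect_phases()].
#' @return a `jump_metrics`, or NULL (with a message) if no take-off is
#'   found.
#' @export
trajectory_metrics <- function(traj, ...) {
  bw <- attr(traj, "body_mass") * attr(traj, "gravity")
  ph <- tryCatch(detect_phases(traj, body_weight = bw, ...),
                 error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(ph)) return(NULL)
  mt <- compute_metrics(traj, ph, body_mass = attr(traj, "body_mass"),
                        g = attr(traj, "gravity"))
  mt$strategy <- classify_strategy(traj, ph)
  mt
}
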