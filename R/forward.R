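#' Initial condition for a walking trial
#'
#' State at right heel strike derived from a gait template: right leg in
#' its heel-strike configuration, left leg half a cycle later (late
#' stance), HAT slightly leaned forward, forward velocity set on the hip
#' translation, and joint rates from the template's phase derivative. The
#' hip height is adjusted so the lowest contact point rests just below
#' ground (small initial penetration carrying part of body weight).
#'
#' @param model a `skeleton`
#' @param template a `gait_template`
#' @param speed forward velocity of the hip, m/s
#' @param stride_period stride duration, s
#' @param hat_lean HAT angle, rad
#' @param penetration initial penetration of the lowest contact point, m
#' @return list with `state` (a `skeleton_state`) and `activation` (18)
#' @export
default_initial_condition <- function(model, template = gait_template("30s"),
                                      speed = 1.3, stride_period = 1.12,
                                      hat_lean = -0.17,
                                      penetration = 0.002) {
  jfun <- function(ph) eval_template(template, ph) * pi / 180
  to_q <- function(j) c(j[1, "hip"], -j[1, "knee"], j[1, "ankle"])
  jr <- jfun(0); jl <- jfun(0.5)
  q <- c(0, model$standing_hip_height, hat_lean, to_q(jr), to_q(jl))
  # rates from the template's phase derivative
  dph <- 1e-4
  drate <- function(ph) (to_q(jfun(ph + dph)) - to_q(jfun(ph - dph))) /
    (2 * dph) / stride_period
  qd <- c(speed, 0, 0, drate(0), drate(0.5))
  st <- skeleton_state(q, qd)
  k <- cpp_kinematics(model$cpp, st$q, st$qdot)
  low <- min(k$points[2, c("heelR", "toeR", "heelL", "toeL")])
  q[2] <- q[2] - (low + penetration)
  list(state = skeleton_state(q, qd), activation = rep(0.05, 18))
}

#' Simulate a walking trial
#'
#' Integrates the coupled activation, muscle-contraction and rigid-body
#' dynamics with a fixed-step 4th-order Runge-Kutta scheme. CE lengths are
#' initialized at the isometric equilibrium for the initial activation.
#' The trial terminates early with status `"fell"` when the HAT CoM drops
#' below `fall_fraction` of its standing height, or `"diverged"` on a
#' non-finite state.
#'
#' @param model a `skeleton`
#' @param muscles a `muscle_set` (18 muscles)
#' @param contact a `contact_params`
#' @param profile a `stimulation_profile`
#' @param init initial condition from [default_initial_condition()] (the
#'   default builds one from the 30s template)
#' @param duration simulated time, s (default four 0.56 s steps)
#' @param dt integration step, s (must be <= 1 ms)
#' @param passive passive-moment coefficients ([default_passive_params()])
#' @param fall_fraction fall threshold as a fraction of standing HAT CoM
#'   height
#' @param min_event_separation debounce window for gait-event detection, s
#' @return object of class `gait_trial`
#' @export
simulate_walking <- function(model, muscles, contact = contact_params(),
                             profile = nominal_profile(),
                             init = NULL,
                             duration = 2.24, dt = 1e-3,
                             passive = default_passive_params(),
                             fall_fraction = 0.7,
                             min_event_separation = 0.05) {
  stopifnot(inherits(model, "skeleton"), inherits(muscles, "muscle_set"),
            inherits(contact, "contact_params"),
            inherits(profile, "stimulation_profile"))
  if (duration <= 0) stop("duration must be positive")
  if (dt > 1e-3 + 1e-12) stop("dt must be <= 1 ms")
  if (is.null(init)) init <- default_initial_condition(model)
  q0 <- init$state$q; qd0 <- init$state$qdot
  a0 <- init$activation
  if (length(a0) == 1) a0 <- rep(a0, 18)

  mspec <- muscle_cpp_spec(muscles)
  geo <- cpp_muscle_geometry(model$cpp, mspec, q0)
  lce0 <- init$ce_length
  if (is.null(lce0)) {
    df <- muscles$muscles
    lce0 <- vapply(seq_len(18), function(i)
      cpp_init_lce(c(fmax = df$fmax[i], lopt = df$lopt[i],
                     pennation = df$pennation[i],
                     tendon_slack = df$tendon_slack[i], vmax = df$vmax[i]),
                   muscles$curves, a0[i], geo$length[i]), numeric(1))
  }

  fall_height <- if (fall_fraction > 0)
    fall_fraction * model$standing_hat_com_height else -Inf
  raw <- cpp_simulate(model$cpp, mspec, unlist(contact), passive,
                      profile_cpp_spec(profile), muscles$curves,
                      q0, qd0, a0, lce0, duration, dt, fall_height)

  status <- c("completed", "fell", "diverged")[raw$status + 1]
  colnames(raw$q) <- colnames(raw$qdot) <- c("x", "y", "phi", JOINT_NAMES)
  labs <- muscles$muscles$label
  colnames(raw$activation) <- colnames(raw$ce_length) <-
    colnames(raw$see_force) <- colnames(raw$stimulation) <- labs
  colnames(raw$grf) <- c("heelR_Fx", "heelR_Fy", "toeR_Fx", "toeR_Fy",
                         "heelL_Fx", "heelL_Fy", "toeL_Fx", "toeL_Fy")
  grf_R <- raw$grf[, "heelR_Fy"] + raw$grf[, "toeR_Fy"]
  grf_L <- raw$grf[, "heelL_Fy"] + raw$grf[, "toeL_Fy"]

  trial <- structure(list(
    kind = "simulated",
    time = raw$time, q = raw$q, qdot = raw$qdot,
    activation = raw$activation, ce_length = raw$ce_length,
    see_force = raw$see_force, stimulation = raw$stimulation,
    grf = raw$grf, grf_vertical = cbind(R = grf_R, L = grf_L),
    metabolic_power = raw$metabolic_power,
    status = status, n_fv_clamped = raw$n_fv_clamped,
    skeleton = model, muscle_labels = labs,
    profile = profile, dt = dt, duration = duration,
    body_weight = model$total_mass * model$gravity
  ), class = "gait_trial")
  trial$events <- detect_gait_events(trial, min_event_separation)
  trial
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("Gait trial (", x$kind, "): status ", x$status, sep = "")
  if (!is.null(x$time))
    cat(", ", round(max(x$time), 3), " s, ", length(x$time), " samples", sep = "")
  cat("\n")
  if (!is.null(x$events) && nrow(x$events))
    print(x$events, row.names = FALSE)
  invisible(x)
}

#' Toe-off and heel-strike times from a vertical GRF trace
#'
#' Events are threshold crossings of 0.05% of body weight: toe-off at
#' downward crossings, heel strike at upward crossings, with linear
#' interpolation between samples for sub-sample timing. Contact or flight
#' phases shorter than `min_separation` are treated as noise and removed
#' before the crossings are extracted.
#'
#' @param grf_vertical_trace vertical GRF of one foot over time, N
#' @param body_weight body weight, N
#' @param time sample times, s
#' @param min_separation debounce window, s (0 keeps all crossings)
#' @return list with `toe_off` and `heel_strike` times (s)
#' @export
detect_toe_off <- function(grf_vertical_trace, body_weight, time,
                           min_separation = 0) {
  thr <- 5e-4 * body_weight
  x <- grf_vertical_trace
  n <- length(x)
  if (n != length(time)) stop("trace and time grid differ in length")
  contact <- x > thr
  if (!any(contact)) return(list(toe_off = numeric(0), heel_strike = numeric(0)))
  if (min_separation > 0) {
    r <- rle(contact)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (k == length(r$lengths)) next
      if (time[ends[k]] - time[starts[k]] < min_separation) {
        # short blips flip to the surrounding state; a short run at the
        # trial start adopts the following state (the pre-trial state is
        # unobserved, so a 20 ms lift-then-touch at t = 0 is stance, not
        # a fresh contact)
        contact[starts[k]:ends[k]] <-
          if (k == 1) contact[ends[k] + 1] else contact[starts[k] - 1]
      }
    }
  }
  cross <- function(i, j) {       # interpolated crossing between samples
    time[i] + (thr - x[i]) / (x[j] - x[i]) * (time[j] - time[i])
  }
  d <- diff(contact)
  up <- which(d == 1); down <- which(d == -1)
  hs <- vapply(up, function(i) cross(i, i + 1), numeric(1))
  to <- vapply(down, function(i) cross(i, i + 1), numeric(1))
  list(toe_off = unname(to), heel_strike = unname(hs))
}

# assemble the event table with step indexing; a step is the period
# between successive foot contacts of the right and left limbs, so step
# boundaries are heel strikes of ALTERNATING sides (same-side re-contacts
# are stumbles, not new steps). The trial start counts as the first
# boundary when a foot is already loaded; its side is the foot carrying
# the lighter load (the freshly contacting one).
detect_gait_events <- function(trial, min_separation = 0.05) {
  ev <- data.frame(type = character(0), side = character(0),
                   time = numeric(0), step = integer(0))
  for (side in c("R", "L")) {
    e <- detect_toe_off(trial$grf_vertical[, side], trial$body_weight,
                        trial$time, min_separation)
    if (length(e$toe_off))
      ev <- rbind(ev, data.frame(type = "toe_off", side = side,
                                 time = e$toe_off, step = NA_integer_))
    if (length(e$heel_strike))
      ev <- rbind(ev, data.frame(type = "heel_strike", side = side,
                                 time = e$heel_strike, step = NA_integer_))
  }
  if (!nrow(ev)) return(ev)
  ev <- ev[order(ev$time), ]
  rownames(ev) <- NULL
  thr <- 5e-4 * trial$body_weight
  g0 <- trial$grf_vertical[1, ]
  b_time <- numeric(0); b_side <- character(0)
  if (any(g0 > thr)) {
    b_time <- trial$time[1]
    loaded <- names(g0)[g0 > thr]
    b_side <- loaded[which.min(g0[loaded])]
  }
  hs <- ev[ev$type == "heel_strike", , drop = FALSE]
  for (k in seq_len(nrow(hs))) {
    if (!length(b_side) || hs$side[k] != b_side[length(b_side)]) {
      b_time <- c(b_time, hs$time[k])
      b_side <- c(b_side, hs$side[k])
    }
  }
  ev$step <- findInterval(ev$time, b_time)
  attr(ev, "step_bounds") <- data.frame(step = seq_along(b_time),
                                        time = b_time, side = b_side)
  ev
}

# landmark traces (CoM, toes, ankles) for every sample of a trial
trial_landmarks <- function(trial) {
  if (!is.null(trial$landmarks)) return(trial$landmarks)
  cpp_landmark_traces(trial$skeleton$cpp, trial$q, trial$qdot)
}

# linear interpolation of a landmark matrix at time t
interp_rows <- function(time, mat, t) {
  c(stats::approx(time, mat[, 1], t, rule = 2)$y,
    stats::approx(time, mat[, 2], t, rule = 2)$y)
}

# segment angles at an arbitrary trial time (linear interpolation in q)
trial_segment_angles <- function(trial, t) {
  q <- vapply(seq_len(ncol(trial$q)),
              function(j) stats::approx(trial$time, trial$q[, j], t, rule = 2)$y,
              numeric(1))
  segment_angles(skeleton_state(q))
}

#' Write a trial to CSV
#'
#' Wide-format trajectory export: one row per sample with time, generalized
#' coordinates and velocities, per-element and summed GRFs and the summed
#' metabolic power. Events, status and profile go to a JSON sidecar of the
#' same name.
#'
#' @param trial a simulated `gait_trial`
#' @param path CSV path (`.json` sidecar written next to it)
#' @return `path`, invisibly
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time = trial$time, trial$q, trial$qdot, trial$grf,
                   grf_R_Fy = trial$grf_vertical[, "R"],
                   grf_L_Fy = trial$grf_vertical[, "L"],
                   metabolic_power = trial$metabolic_power,
                   check.names = FALSE)
  names(df)[2:10] <- paste0("q_", colnames(trial$q))
  names(df)[11:19] <- paste0("qd_", colnames(trial$qdot))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(status = trial$status, duration = trial$duration, dt = trial$dt,
         events = trial$events,
         profile = list(onset = as.list(trial$profile$onset),
                        offset = as.list(trial$profile$offset),
                        amplitude = as.list(trial$profile$amplitude),
                        stride_period = trial$profile$stride_period,
                        baseline = trial$profile$baseline)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
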