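#' Posture-tracking error at toe-off
#'
#' For each of the first four steps (delimited by successive right/left
#' foot contacts) the seven absolute segment angles at that step's
#' toe-off instant are compared with the target toe-off posture; each
#' step contributes `sqrt(sum((theta - theta_target)^2) / 7)` (radians)
#' and the contributions are summed over steps. The target describes a
#' right toe-off; at left toe-offs the mirrored target (leg segments
#' swapped) is used. Steps without a toe-off - the trial fell early, or
#' the gait never produced an alternating step - contribute a fixed
#' worst-case term.
#'
#' @param trial a `gait_trial`
#' @param target a `target_posture` (7 segment angles, rad)
#' @param n_steps number of toe-off postures entering the sum
#' @param worst_case contribution of a missing step, rad
#' @return tracking error, rad
#' @export
rms_ang <- function(trial, target, n_steps = 4, worst_case = 1.0) {
  ev <- trial$events
  to <- ev[!is.null(ev) & ev$type == "toe_off", , drop = FALSE]
  total <- 0
  for (i in seq_len(n_steps)) {
    in_step <- to[!is.na(to$step) & to$step == i, , drop = FALSE]
    if (!nrow(in_step)) {
      total <- total + worst_case
      next
    }
    tgt <- if (in_step$side[1] == "L") mirror_posture(target) else target
    th <- trial_segment_angles(trial, in_step$time[1])
    total <- total + sqrt(sum((th - unclass(tgt))^2) / 7)
  }
  total
}

#' Mirror a target posture
#'
#' Swaps the right- and left-leg segment angles (HAT unchanged); the
#' left-toe-off counterpart of a right-toe-off posture.
#' @param target a `target_posture`
#' @return a `target_posture`
#' @export
mirror_posture <- function(target) {
  x <- unclass(target)
  structure(stats::setNames(x[c(1, 5, 6, 7, 2, 3, 4)], SEGMENT_NAMES),
            class = "target_posture")
}

#' Objective value of a walking trial
#'
#' Two-term objective `omega1 * RMSang + omega2 * WBEmeter` plus a penalty
#' for trials that fall, diverge, or fail to travel: such candidates must
#' always score worse than any completed walk. For a completed trial with
#' meaningful forward CoM travel the penalty is zero.
#'
#' @param trial a `gait_trial`
#' @param target a `target_posture`
#' @param weights `c(omega1, omega2)`, both >= 0
#' @param min_displacement forward CoM displacement (m) below which the
#'   energy-per-meter term is undefined and replaced by a penalty
#' @param shaping_template optional `gait_template`: when supplied, trials
#'   that end early are additionally penalized by their joint-angle
#'   deviation from the template over the lived portion, which smooths the
#'   search landscape for the optimizer without altering the objective of
#'   completed walks
#' @return object of class `objective_value`: list with `total`,
#'   `rms_ang`, `wbe_meter`, `penalty`, `displacement`, `status`
#' @export
objective_value <- function(trial, target, weights = c(1, 1),
                            min_displacement = 0.10,
                            shaping_template = NULL) {
  if (any(weights < 0)) stop("objective weights must be >= 0")
  lm <- trial_landmarks(trial)
  n <- length(trial$time)
  disp <- lm$com[n, 1] - lm$com[1, 1]
  rms <- rms_ang(trial, target)

  penalty <- 0
  if (trial$status != "completed") {
    t_alive <- trial$time[n]
    penalty <- penalty + 18 * (1 - t_alive / trial$duration)
    # how badly it fell: mean-square trunk deviation from near-vertical
    penalty <- penalty + 8 * mean((trial$q[, "phi"] + 0.08)^2)
    if (!is.null(shaping_template)) {
      ph <- (trial$time / (2 * 0.56)) %% 1
      refR <- eval_template(shaping_template, ph) * pi / 180
      refL <- eval_template(shaping_template, ph - 0.5) * pi / 180
      dev <- abs(trial$q[, 4] - refR[, "hip"]) +
        abs(trial$q[, 5] + refR[, "knee"]) +
        abs(trial$q[, 6] - refR[, "ankle"]) +
        abs(trial$q[, 7] - refL[, "hip"]) +
        abs(trial$q[, 8] + refL[, "knee"]) +
        abs(trial$q[, 9] - refL[, "ankle"])
      penalty <- penalty + 2 * mean(dev)
    }
  }
  if (disp < 2.0) penalty <- penalty + 5 * (2.0 - max(disp, 0))

  if (disp > min_displacement) {
    wbe <- wbe_per_meter(trial$metabolic_power,
                         trial$skeleton$total_mass,
                         lm$com[1, 1], lm$com[n, 1], trial$time)
    wbe <- min(wbe, 50)
  } else {
    wbe <- 0
    penalty <- penalty + 25
  }
  structure(list(
    total = weights[1] * rms + weights[2] * wbe + penalty,
    rms_ang = rms, wbe_meter = wbe, penalty = penalty,
    displacement = disp, status = trial$status
  ), class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf(
    "objective %.4f = tracking %.4f + energy %.4f + penalty %.2f (%s, %+.2f m)\n",
    x$total, x$rms_ang, x$wbe_meter, x$penalty, x$status, x$displacement))
  invisible(x)
}
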