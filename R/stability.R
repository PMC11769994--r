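#' Extrapolated center of mass
#'
#' Velocity-adjusted CoM position of the inverted-pendulum framework:
#' `XCoM = P_CoM + V_CoM * sqrt(l / g)`, with `l` the pendulum length
#' (distance from the stance ankle to the CoM). Anteroposterior scalar
#' form.
#'
#' @param p_com anteroposterior CoM position, m
#' @param v_com anteroposterior CoM velocity, m/s
#' @param pendulum_length ankle-to-CoM distance, m (> 0)
#' @param g gravitational acceleration, m/s^2 (> 0)
#' @return XCoM, m (vectorized)
#' @export
extrapolated_com <- function(p_com, v_com, pendulum_length, g = 9.81) {
  if (any(pendulum_length <= 0)) stop("pendulum_length must be positive")
  if (any(g <= 0)) stop("g must be positive")
  p_com + v_com * sqrt(pendulum_length / g)
}

# the left toe-off instant used for the stability outcome: the left
# toe-off within step 2 if one exists, otherwise the second left toe-off
mos_event_time <- function(trial) {
  ev <- trial$events
  lt <- ev[ev$type == "toe_off" & ev$side == "L", , drop = FALSE]
  if (!nrow(lt))
    stop("trial contains no left toe-off events; cannot compute the margin of stability")
  in2 <- lt[!is.na(lt$step) & lt$step == 2, , drop = FALSE]
  if (nrow(in2)) return(in2$time[1])
  if (nrow(lt) >= 2) return(lt$time[2])
  stop("trial lacks the left toe-off of the second step (only ", nrow(lt),
       " left toe-off found)")
}

#' Margin of stability of a walking trial
#'
#' At the left toe-off of the second step the anterior boundary of the
#' base of support is the right toe; the margin of stability is
#' `MoS = BoS - XCoM` with the extrapolated CoM computed from the
#' anteroposterior CoM state and the right-ankle-to-CoM pendulum length.
#' Positive MoS means the extrapolated CoM lies within the base of support
#' (dynamically stable); negative means it has passed the toe.
#'
#' @param trial a `gait_trial` (simulated or toy) with events
#' @param model a `skeleton` (for gravity; defaults to the trial's)
#' @return object of class `stability_metrics`: list with `mos`, `xcom`,
#'   `bos_boundary`, `step_length`, `vcom_at_toe_off`, `pendulum_length`,
#'   `toe_off_time`
#' @export
margin_of_stability <- function(trial, model = trial$skeleton) {
  g <- if (!is.null(model)) model$gravity else 9.81
  t0 <- mos_event_time(trial)
  lm <- trial_landmarks(trial)
  com <- interp_rows(trial$time, lm$com, t0)
  vcom <- interp_rows(trial$time, lm$vcom, t0)
  toe_r <- interp_rows(trial$time, lm$toe_R, t0)
  toe_l <- interp_rows(trial$time, lm$toe_L, t0)
  ankle_r <- interp_rows(trial$time, lm$ankle_R, t0)
  l <- sqrt(sum((com - ankle_r)^2))
  xcom <- extrapolated_com(com[1], vcom[1], l, g)
  bos <- toe_r[1]
  structure(list(
    mos = bos - xcom, xcom = xcom, bos_boundary = bos,
    step_length = toe_r[1] - toe_l[1],
    vcom_at_toe_off = vcom[1],
    pendulum_length = l, toe_off_time = t0
  ), class = "stability_metrics")
}

#' @export
print.stability_metrics <- function(x, ...) {
  cat(sprintf(
    "MoS %.3f m (XCoM %.3f, BoS %.3f) | step length %.3f m | VCoM %.3f m/s | at t = %.3f s\n",
    x$mos, x$xcom, x$bos_boundary, x$step_length, x$vcom_at_toe_off,
    x$toe_off_time))
  invisible(x)
}

#' Step length and CoM velocity at the stability toe-off
#'
#' Anteroposterior distance between the right and left toes and the
#' anteroposterior CoM velocity, both at the toe-off instant used by
#' [margin_of_stability()].
#'
#' @param trial a `gait_trial`
#' @return list with `step_length` (m) and `vcom` (m/s)
#' @export
step_length_and_vcom <- function(trial) {
  m <- margin_of_stability(trial)
  list(step_length = m$step_length, vcom = m$vcom_at_toe_off)
}

#' Joint-angle curves of a trial over one gait cycle
#'
#' Right hip, knee and ankle flexion-extension angles (degrees, flexion /
#' dorsiflexion positive) resampled to 101 points over a gait cycle
#' delimited by successive right heel strikes.
#'
#' @param trial a simulated `gait_trial`
#' @param cycle which right-contact-to-right-contact cycle (default: the
#'   last complete one, the steadiest part of a short trial)
#' @return matrix 101 x 3 with columns `hip`, `knee`, `ankle`
#' @export
trial_gait_cycle_curves <- function(trial, cycle = NULL) {
  ev <- trial$events
  sb <- attr(ev, "step_bounds")
  hs <- if (!is.null(sb)) sb$time[sb$side == "R"]
        else ev$time[ev$type == "heel_strike" & ev$side == "R"]
  if (is.null(cycle)) cycle <- max(1, length(hs) - 1)   # last full cycle
  if (length(hs) < cycle + 1) {
    # fall back to the stride period from the profile
    if (is.null(trial$profile))
      stop("not enough right heel strikes to delimit a gait cycle")
    t0 <- if (length(hs)) hs[min(cycle, length(hs))] else trial$time[1]
    t1 <- t0 + trial$profile$stride_period
    if (t1 > max(trial$time)) stop("trial too short for the requested cycle")
  } else {
    t0 <- hs[cycle]; t1 <- hs[cycle + 1]
  }
  ts <- seq(t0, t1, length.out = 101)
  ang <- t(vapply(ts, function(t) {
    q <- vapply(4:6, function(j) stats::approx(trial$time, trial$q[, j], t, rule = 2)$y,
                numeric(1))
    c(hip = q[1], knee = -q[2], ankle = q[3]) * 180 / pi
  }, numeric(3)))
  colnames(ang) <- c("hip", "knee", "ankle")
  ang
}

#' Cross-correlation validation against reference curves
#'
#' Zero-lag Pearson correlation per joint between simulated gait-cycle
#' curves and the reference mean curves, plus their unweighted mean.
#'
#' @param sim_curves 101 x 3 matrix (columns hip, knee, ankle), e.g. from
#'   [trial_gait_cycle_curves()]
#' @param ref a `reference_gait_curves`
#' @return list with `per_joint` (named length 3) and `overall`
#' @export
cross_correlation_validation <- function(sim_curves, ref) {
  joints <- c("hip", "knee", "ankle")
  r <- vapply(joints, function(j) {
    a <- sim_curves[, j]; b <- ref[[j]]$mean
    if (length(a) != length(b)) stop("curve lengths differ")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance curve: correlation undefined")
    stats::cor(a, b)
  }, numeric(1))
  list(per_joint = r, overall = mean(r))
}
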