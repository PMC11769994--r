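#' Metabolic energy rate of one muscle
#'
#' Heat + work rate in the style of the Umberger muscle energetics model:
#' activation/maintenance heat depending on the fiber-type mix and an
#' effective activation `A` (`A = u` when `u > a`, else `(u + a)/2`),
#' shortening/lengthening heat proportional to normalized CE velocity, and
#' the positive (concentric) mechanical work rate of the CE. Eccentric work
#' enters only through the lengthening-heat term; the summed heat rate is
#' clamped at zero so the total is never negative. Basal metabolism is
#' excluded (a constant offset cannot differentiate candidate gaits of
#' fixed duration).
#'
#' @param params one row of `muscle_set$muscles` (needs `lopt`, `vmax`,
#'   `pennation`, `mass`, `ft_frac`)
#' @param activation muscle activation a in `[0, 1]`
#' @param stimulation neural stimulation u in `[0, 1]`
#' @param ce_length CE length, m
#' @param ce_velocity CE velocity, m/s (lengthening positive)
#' @param ce_force force transmitted by the tendon, N (converted to fiber
#'   force with the pennation angle for the work term)
#' @param curves Hill-curve constants (for the force-length scaling of the
#'   velocity-dependent heat)
#' @return metabolic power in W (>= 0)
#' @export
muscle_energy_rate <- function(params, activation, stimulation,
                               ce_length, ce_velocity, ce_force,
                               curves = hill_curves()) {
  u <- stimulation; a <- activation
  A <- ifelse(u > a, u, 0.5 * (u + a))
  if (A <= 0) return(0)
  am <- A^0.6
  f <- params$ft_frac
  fla <- fl_active(ce_length / params$lopt, curves)
  h_am <- (128 * f + 25) * am
  vnorm <- ce_velocity / params$lopt
  vmax_st <- params$vmax / 2.5
  a_st <- 100 / vmax_st
  a_ft <- 153 / params$vmax
  h_sl <- if (vnorm <= 0)
    (a_st * (1 - f) + a_ft * f) * (-vnorm) * A^2 * fla
  else
    a_st * vnorm * A * fla
  fce <- ce_force / cos(params$pennation)
  w <- max(0, -fce * ce_velocity)
  params$mass * max(0, h_am + h_sl) + w
}

#' Whole-body energy expenditure per meter traveled
#'
#' Trapezoidal time-integral of the summed muscle metabolic power, divided
#' by body mass and the net forward displacement of the whole-body center
#' of mass; the energy term of the gait optimization objective.
#'
#' @param total_rate_trace summed metabolic power over time, W
#' @param model_mass body mass, kg
#' @param com_x_initial,com_x_final anteroposterior CoM positions at the
#'   start and end of the trial, m
#' @param time sample times, s, or a single duration (uniform sampling)
#' @return energy cost in J/(kg m)
#' @export
wbe_per_meter <- function(total_rate_trace, model_mass,
                          com_x_initial, com_x_final, time) {
  disp <- com_x_final - com_x_initial
  if (abs(disp) < 1e-9)
    stop("zero net CoM displacement: energy per meter undefined (failed walk)")
  n <- length(total_rate_trace)
  if (length(time) == 1) {
    if (time <= 0) stop("duration must be positive")
    time <- seq(0, time, length.out = n)
  }
  if (length(time) != n) stop("time grid does not match the rate trace")
  e <- sum(diff(time) * (total_rate_trace[-n] + total_rate_trace[-1]) / 2)
  e / (model_mass * disp)
}
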