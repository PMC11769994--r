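#' Ground contact parameters
#'
#' Heel/toe point-contact model on flat ground (y = 0): the vertical force
#' is a damped quadratic spring in the penetration depth,
#' `Fy = stiffness * d^2 * (1 + damping_coefficient * ddot)`, clipped at
#' zero so withdrawal never produces adhesion; the shear force approximates
#' Coulomb friction with a tanh-smoothed velocity dependence,
#' `Fx = -friction_coefficient * Fy * tanh(vt / velocity_smoothing)`.
#' Defaults are tuned so the standing model penetrates less than 1 cm.
#'
#' @param stiffness quadratic spring constant, N/m^2
#' @param damping_coefficient penetration-rate coefficient, s/m
#' @param friction_coefficient Coulomb friction coefficient
#' @param velocity_smoothing regularization scale of the friction
#'   approximation, m/s
#' @return object of class `contact_params`
#' @export
contact_params <- function(stiffness = 2.5e6, damping_coefficient = 2.0,
                           friction_coefficient = 0.9,
                           velocity_smoothing = 0.1) {
  if (stiffness <= 0) stop("stiffness must be positive")
  if (friction_coefficient < 0) stop("friction coefficient must be >= 0")
  if (velocity_smoothing <= 0) stop("velocity_smoothing must be positive")
  structure(list(stiffness = stiffness,
                 damping_coefficient = damping_coefficient,
                 friction_coefficient = friction_coefficient,
                 velocity_smoothing = velocity_smoothing),
            class = "contact_params")
}

#' Contact force at one element
#'
#' @param params a `contact_params`
#' @param penetration penetration depth below ground, m (<= 0 means no
#'   contact)
#' @param penetration_rate time derivative of the penetration, m/s
#' @param tangential_velocity sliding velocity of the contact point, m/s
#' @return force vector `c(Fx, Fy)` in N (vectorized over inputs)
#' @export
contact_force <- function(params, penetration, penetration_rate = 0,
                          tangential_velocity = 0) {
  n <- max(length(penetration), length(penetration_rate),
           length(tangential_velocity))
  penetration <- rep_len(penetration, n)
  penetration_rate <- rep_len(penetration_rate, n)
  tangential_velocity <- rep_len(tangential_velocity, n)
  fy <- ifelse(penetration > 0,
               pmax(0, params$stiffness * penetration^2 *
                      (1 + params$damping_coefficient * penetration_rate)),
               0)
  fx <- -params$friction_coefficient * fy *
    tanh(tangential_velocity / params$velocity_smoothing)
  if (n == 1) c(Fx = fx, Fy = fy) else cbind(Fx = fx, Fy = fy)
}
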