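#' Read a model configuration file
#'
#' YAML configuration with nested sections `body` (height, mass, gravity),
#' `contact`, `passive` (rows of the coefficient matrix), `simulation`
#' (duration, dt, stride_period) and `optimization` (budget, seeds,
#' weights). Missing sections fall back to package defaults; the returned
#' list always carries the fully resolved values plus a stable hash of
#' them, so every output can be traced to its configuration.
#'
#' @param path YAML file, or `NULL` for the pure defaults
#' @return list with `body`, `contact`, `passive`, `simulation`,
#'   `optimization`, `hash`
#' @export
read_model_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  def <- list(
    body = list(height = 1.74, mass = 72.80, gravity = 9.81),
    contact = unclass(contact_params()),
    passive = apply(default_passive_params(), 1, as.list, simplify = FALSE),
    simulation = list(duration = 2.24, dt = 1e-3, stride_period = 1.12,
                      fall_fraction = 0.7),
    optimization = list(budget = 2000, seeds = 1:3, weights = c(1, 1),
                        sigma0 = 0.06)
  )
  cfg <- utils::modifyList(def, user)
  cfg$hash <- config_hash(cfg)
  cfg
}

# deterministic short hash of a configuration list (no digest dependency:
# polynomial rolling hash of the serialized bytes mod 2^31 - 1)
config_hash <- function(x) {
  x$hash <- NULL
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build an assembly from a configuration
#'
#' @param config list from [read_model_config()]
#' @return a `gait_assembly`
#' @export
assembly_from_config <- function(config = read_model_config()) {
  cp <- do.call(contact_params, config$contact)
  gait_assembly(total_height = config$body$height,
                total_mass = config$body$mass,
                contact = cp,
                stride_period = config$simulation$stride_period)
}
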