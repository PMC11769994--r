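#' Hill-curve shape constants
#'
#' Shape constants of the four muscle-tendon curves: Gaussian active
#' force-length (width `gw` in optimal-fiber-length units), exponential
#' passive force-length (`kpe`, engagement strain `e0`), exponential-toe
#' tendon force-length reaching maximum isometric force at strain `eps0`,
#' and a Hill hyperbola force-velocity curve (`af` = a/F0 shape factor) with
#' a smooth eccentric extension plateauing at `fecc`. `vclo`/`vchi` clamp
#' the normalized CE velocity returned by the force-velocity inversion
#' (in units of `vmax`); clamping is flagged in simulation output.
#'
#' @param gw,kpe,e0,eps0,Ftoe,ktoe,af,fecc,gecc,vclo,vchi numeric overrides
#' @return named numeric vector of curve constants
#' @export
hill_curves <- function(gw = 0.35, kpe = 4, e0 = 0.6,
                        eps0 = 0.04, Ftoe = 0.33, ktoe = 3,
                        af = 0.25, fecc = 1.5, gecc = 0.1,
                        vclo = -1, vchi = 1.5) {
  epstoe <- 0.609 * eps0
  klin <- (1 - Ftoe) / (eps0 - epstoe)
  c(gw = gw, kpe = kpe, e0 = e0, eps0 = eps0, Ftoe = Ftoe, ktoe = ktoe,
    epstoe = epstoe, klin = klin, af = af, fecc = fecc, gecc = gecc,
    vclo = vclo, vchi = vchi)
}

#' Active force-length curve
#' @param l_norm CE length / optimal fiber length
#' @param curves constants from [hill_curves()]
#' @return normalized force (1 at the optimum)
#' @export
fl_active <- function(l_norm, curves = hill_curves()) {
  exp(-((l_norm - 1) / curves[["gw"]])^2)
}

#' Passive force-length curve
#' @inheritParams fl_active
#' @export
fl_passive <- function(l_norm, curves = hill_curves()) {
  ifelse(l_norm <= 1, 0,
         (exp(curves[["kpe"]] * (l_norm - 1) / curves[["e0"]]) - 1) /
           (exp(curves[["kpe"]]) - 1))
}

#' Tendon force-length curve
#' @param strain tendon strain (length / slack length - 1)
#' @param curves constants from [hill_curves()]
#' @return tendon force normalized by maximum isometric force
#' @export
ft_tendon <- function(strain, curves = hill_curves()) {
  ifelse(strain <= 0, 0,
    ifelse(strain < curves[["epstoe"]],
      curves[["Ftoe"]] * (exp(curves[["ktoe"]] * strain / curves[["epstoe"]]) - 1) /
        (exp(curves[["ktoe"]]) - 1),
      curves[["klin"]] * (strain - curves[["epstoe"]]) + curves[["Ftoe"]]))
}

#' Force-velocity curve
#'
#' Hill hyperbola on the concentric side (force 1 at zero velocity, 0 at
#' maximum shortening velocity) with a smooth eccentric branch plateauing at
#' `fecc`; velocity is normalized by `vmax * lopt`, lengthening positive.
#' @param v_norm CE velocity / (vmax * lopt), lengthening positive
#' @param curves constants from [hill_curves()]
#' @export
fv_curve <- function(v_norm, curves = hill_curves()) {
  af <- curves[["af"]]; fe <- curves[["fecc"]]; ge <- curves[["gecc"]]
  ifelse(v_norm <= -1, 0,
    ifelse(v_norm <= 0, (1 + v_norm) / (1 - v_norm / af),
           1 + (fe - 1) * v_norm / (v_norm + ge)))
}

#' Inverse force-velocity curve
#' @param f_norm force-velocity factor (CE force / maximum isometric force at
#'   the current activation and length)
#' @param curves constants from [hill_curves()]
#' @return normalized CE velocity, clamped to `[vclo, vchi]`
#' @export
fv_inverse <- function(f_norm, curves = hill_curves()) {
  af <- curves[["af"]]; fe <- curves[["fecc"]]; ge <- curves[["gecc"]]
  v <- ifelse(f_norm < 0, -1,
    ifelse(f_norm < 1, (f_norm - 1) / (1 + f_norm / af),
           ge * (pmin(f_norm, fe - 0.01) - 1) / (fe - pmin(f_norm, fe - 0.01))))
  pmin(pmax(v, curves[["vclo"]]), curves[["vchi"]])
}

#' Read a muscle parameter table
#'
#' The shipped default (`inst/extdata/muscle_table.tsv`) lists the nine
#' right-leg muscle groups with PCSA at the reference cadaver body size
#' (1.83 m, 91 kg), optimal fiber length and pennation at a 1.74 m body
#' height, fiber-type mix, and the muscle path as semicolon-separated
#' `segment:x:y` triplets in segment frames (thigh/HAT origin at the hip,
#' shank at the knee, foot at the ankle). The coordinates are nominal planar
#' approximations assembled for this model family, not measurements of any
#' single published specimen. `tendon_slack = NA` means "derive the slack
#' length from the standing posture" (CE at its optimal length).
#'
#' @param path TSV file; default is the shipped table
#' @return data.frame with a `path` list-column of 2-3 point matrices
#' @export
read_muscle_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "muscle_table.tsv", package = "plangait")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "side", "pcsa", "lopt", "pennation", "tendon_slack",
            "ft_frac", "path")
  if (!all(need %in% names(tab))) stop("muscle table missing columns")
  tab$path_points <- lapply(tab$path, function(s) {
    pts <- strsplit(strsplit(s, ";")[[1]], ":")
    m <- t(vapply(pts, function(p) {
      seg <- match(p[1], c("HAT", "upper_leg", "lower_leg", "foot")) - 1L
      if (is.na(seg)) stop("unknown path segment '", p[1], "'")
      c(seg, as.numeric(p[2]), as.numeric(p[3]))
    }, numeric(3)))
    colnames(m) <- c("seg", "x", "y")
    if (nrow(m) < 2) stop("muscle path needs at least 2 points")
    m
  })
  if (any(tab$pcsa <= 0) || any(tab$lopt <= 0))
    stop("pcsa and lopt must be positive")
  tab
}

#' Aging-related model variants
#'
#' Parameter transforms applied to the young-adult (YA) muscle set:
#' `dT` extends the deactivation time constant by 20%, `dF` reduces maximum
#' isometric force by 30%, `dV` reduces maximum contraction velocity by 20%,
#' and `OA` applies all three. `YA` is the identity.
#'
#' @param tag one of `"YA"`, `"OA"`, `"dT"`, `"dF"`, `"dV"`
#' @return list with `tag`, `deact_scale`, `fmax_scale`, `vmax_scale`
#' @export
model_variant <- function(tag = c("YA", "OA", "dT", "dF", "dV")) {
  tag <- match.arg(tag)
  sc <- switch(tag,
    YA = c(1.0, 1.0, 1.0),
    dT = c(1.2, 1.0, 1.0),
    dF = c(1.0, 0.7, 1.0),
    dV = c(1.0, 1.0, 0.8),
    OA = c(1.2, 0.7, 0.8))
  list(tag = tag, deact_scale = sc[1], fmax_scale = sc[2], vmax_scale = sc[3])
}

#' Build the 18-muscle set
#'
#' Scales the reference muscle table to the target body size and assembles
#' the full bilateral muscle set. PCSA is scaled from the reference specimen
#' (1.83 m, 91 kg) by `(mass/91) / (height/1.83)` (muscle volume scales with
#' body mass, fiber length with height); maximum isometric force is
#' `specific_tension * PCSA`; maximum contraction velocity is 12 optimal
#' fiber lengths per second; activation/deactivation time constants are
#' 55/65 ms. Path coordinates and fiber lengths scale linearly with height
#' from the 1.74 m table. Left-leg muscles mirror the right exactly.
#'
#' @param model_height body height in m
#' @param model_mass body mass in kg
#' @param specific_tension N/cm^2
#' @param table muscle table from [read_muscle_table()]
#' @param vmax_lopt_per_s maximum shortening velocity in lopt/s
#' @param tau_act,tau_deact activation/deactivation time constants in s
#' @param curves Hill-curve constants ([hill_curves()])
#' @param muscle_density kg/m^3 (for muscle mass in the energy model)
#' @return object of class `muscle_set`
#' @export
build_muscle_set <- function(model_height, model_mass, specific_tension = 60,
                             table = read_muscle_table(),
                             vmax_lopt_per_s = 12,
                             tau_act = 0.055, tau_deact = 0.065,
                             curves = hill_curves(),
                             muscle_density = 1059.7) {
  if (model_height <= 0 || model_mass <= 0 || specific_tension <= 0)
    stop("height, mass and specific tension must be positive")
  missing <- setdiff(MUSCLE_NAMES, table$name)
  if (length(missing))
    stop("muscle table is missing: ", paste(missing, collapse = ", "))
  tab <- table[match(MUSCLE_NAMES, table$name), ]

  pcsa_scale <- (model_mass / 91) / (model_height / 1.83)
  len_scale <- model_height / 1.74

  one_side <- function(side, seg_offset) {
    df <- data.frame(
      name = tab$name, side = side,
      pcsa = tab$pcsa * pcsa_scale,
      fmax = specific_tension * tab$pcsa * pcsa_scale,
      lopt = tab$lopt * len_scale,
      pennation = tab$pennation,
      tendon_slack = tab$tendon_slack,
      vmax = vmax_lopt_per_s,
      tau_act = tau_act, tau_deact = tau_deact,
      ft_frac = tab$ft_frac,
      stringsAsFactors = FALSE)
    df$mass <- df$pcsa * 1e-4 * df$lopt * muscle_density
    paths <- lapply(tab$path_points, function(m) {
      m2 <- m
      m2[, 2:3] <- m[, 2:3] * len_scale
      m2[, 1] <- ifelse(m[, 1] == 0, 0, m[, 1] + seg_offset)
      m2
    })
    list(df = df, paths = paths)
  }
  r <- one_side("R", 0L)
  l <- one_side("L", 3L)
  df <- rbind(r$df, l$df)
  paths <- c(r$paths, l$paths)
  df$label <- paste(df$name, df$side, sep = "_")

  ms <- structure(list(
    muscles = df, paths = paths, curves = curves,
    specific_tension = specific_tension,
    model_height = model_height, model_mass = model_mass,
    variant = model_variant("YA")
  ), class = "muscle_set")

  # derive slack lengths from the standing posture where not supplied
  na_slack <- is.na(df$tendon_slack)
  if (any(na_slack)) {
    skel <- build_skeleton(model_height, model_mass)
    st <- skeleton_state(c(0, skel$standing_hip_height, rep(0, 7)))
    geo <- cpp_muscle_geometry(skel$cpp, muscle_cpp_spec(ms), st$q)
    slack <- geo$length - df$lopt * cos(df$pennation)
    if (any(slack[na_slack] <= 0)) stop("derived tendon slack length not positive")
    ms$muscles$tendon_slack[na_slack] <- slack[na_slack]
  }
  if (any(ms$muscles$tendon_slack <= 0)) stop("tendon slack lengths must be positive")
  ms
}

# flat spec handed to the C++ core
muscle_cpp_spec <- function(ms) {
  df <- ms$muscles
  slack <- df$tendon_slack
  slack[is.na(slack)] <- 1.0   # placeholder while deriving slack at build time
  par <- cbind(df$fmax, df$lopt, df$pennation, slack, df$vmax,
               df$tau_act, df$tau_deact, df$mass, df$ft_frac)
  list(par = par, paths = ms$paths)
}

#' @export
print.muscle_set <- function(x, ...) {
  cat("Hill-type muscle set:", nrow(x$muscles), "muscle-tendon units, variant",
      x$variant$tag, "\n")
  print(x$muscles[x$muscles$side == "R",
                  c("name", "pcsa", "fmax", "lopt", "pennation",
                    "tendon_slack", "vmax", "tau_act", "tau_deact")],
        digits = 4, row.names = FALSE)
  cat("(left side mirrors the right)\n")
  invisible(x)
}

#' Apply an aging variant to a muscle set
#'
#' Scales deactivation time, maximum isometric force and maximum contraction
#' velocity by the variant's factors; all other parameters (including the
#' activation time constant) are unchanged.
#'
#' @param muscles a `muscle_set` (or a single-muscle parameter list with
#'   `fmax`, `vmax`, `tau_deact`)
#' @param variant a variant from [model_variant()] or its tag
#' @return the transformed object
#' @export
apply_aging <- function(muscles, variant) {
  if (is.character(variant)) variant <- model_variant(variant)
  if (inherits(muscles, "muscle_set")) {
    muscles$muscles$tau_deact <- muscles$muscles$tau_deact * variant$deact_scale
    muscles$muscles$fmax <- muscles$muscles$fmax * variant$fmax_scale
    muscles$muscles$vmax <- muscles$muscles$vmax * variant$vmax_scale
    muscles$variant <- variant
    return(muscles)
  }
  muscles$tau_deact <- muscles$tau_deact * variant$deact_scale
  muscles$fmax <- muscles$fmax * variant$fmax_scale
  muscles$vmax <- muscles$vmax * variant$vmax_scale
  muscles
}

#' Activation dynamics derivative
#'
#' First-order lag between neural stimulation and activation with separate
#' activation and deactivation time constants: `da/dt = (u - a) / tau`,
#' `tau = tau_act` when `u >= a` and `tau_deact` otherwise. Solutions
#' starting in `[0, 1]` stay there.
#'
#' @param stimulation neural stimulation u in `[0, 1]`
#' @param activation activation a in `[0, 1]`
#' @param tau_act,tau_deact time constants in s
#' @return da/dt in 1/s (vectorized)
#' @export
activation_derivative <- function(stimulation, activation,
                                  tau_act = 0.055, tau_deact = 0.065) {
  tau <- ifelse(stimulation >= activation, tau_act, tau_deact)
  (stimulation - activation) / tau
}

#' Muscle-tendon length and moment arms
#'
#' Total path length (sum of straight-line distances along the attachment
#' polyline) and moment arms about each spanned joint, computed as the
#' negative partial derivative of path length with respect to the joint
#' angle by central finite differences.
#'
#' @param muscles a `muscle_set`
#' @param model a `skeleton`
#' @param state a `skeleton_state`
#' @param fd_step finite-difference step in rad
#' @return list with `length` (18) and `moment_arms` (18 x 6, columns named
#'   by joint; zero where the muscle does not span the joint)
#' @export
mtu_length_and_moment_arms <- function(muscles, model, state, fd_step = 1e-5) {
  geo <- cpp_muscle_geometry(model$cpp, muscle_cpp_spec(muscles), state$q, fd_step)
  rownames(geo$moment_arms) <- muscles$muscles$label
  names(geo$length) <- muscles$muscles$label
  geo
}

#' Muscle-tendon contraction dynamics
#'
#' Series-elastic (tendon) force and CE velocity for one muscle at a given
#' activation, CE length and total muscle-tendon length. The tendon force
#' follows from the tendon curve at strain `(lmtu - lce cos(pennation)) /
#' slack - 1`; the CE velocity inverts the force-velocity relation so that
#' the fiber force `(a fl_active fv + fl_passive) fmax cos(pennation)`
#' balances the tendon force. Out-of-range inversions are clamped and
#' flagged.
#'
#' @param params one row of `muscle_set$muscles` (or a named list with
#'   `fmax`, `lopt`, `pennation`, `tendon_slack`, `vmax`)
#' @param curves Hill-curve constants
#' @param activation activation in `[0, 1]`
#' @param ce_length CE length in m
#' @param mtu_length total muscle-tendon length in m
#' @return list with `see_force` (N), `ce_velocity` (m/s, lengthening
#'   positive) and `clamped`
#' @export
mtu_dynamics <- function(params, curves = hill_curves(), activation,
                         ce_length, mtu_length) {
  if (mtu_length <= 0.5 * params$tendon_slack)
    stop("mtu_length implausibly short relative to tendon slack length")
  mp <- c(fmax = params$fmax, lopt = params$lopt, pennation = params$pennation,
          tendon_slack = params$tendon_slack, vmax = params$vmax)
  cpp_mtu_dynamics(mp, curves, activation, ce_length, mtu_length)
}

#' Isometric-equilibrium CE length
#'
#' CE length at which fiber and tendon forces balance for a fixed
#' muscle-tendon length and activation; used to initialize simulations.
#' @inheritParams mtu_dynamics
#' @return CE length in m
#' @export
equilibrium_ce_length <- function(params, curves = hill_curves(),
                                  activation, mtu_length) {
  mp <- c(fmax = params$fmax, lopt = params$lopt, pennation = params$pennation,
          tendon_slack = params$tendon_slack, vmax = params$vmax)
  cpp_init_lce(mp, curves, activation, mtu_length)
}
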