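#' Anthropometric segment proportions
#'
#' Standard sagittal-plane segment proportions (fractions of body height for
#' lengths, fractions of body mass for masses, center-of-mass position as a
#' fraction of segment length from the proximal end, radius of gyration about
#' the segment CoM as a fraction of segment length). The table is shipped as
#' a plain-text fixture (`inst/extdata/segment_proportions.tsv`) and treated
#' as configuration: it follows the classic gait-analysis anthropometry
#' tables, not any single subject.
#'
#' @return data.frame with one row per segment type (`HAT`, `upper_leg`,
#'   `lower_leg`, `foot`) and columns `length_frac`, `mass_frac`,
#'   `com_frac`, `rog_frac`.
#' @export
default_proportions <- function() {
  path <- system.file("extdata", "segment_proportions.tsv", package = "plangait")
  if (nzchar(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$segment
    return(tab)
  }
  # fallback used only before installation
  data.frame(
    segment = c("HAT", "upper_leg", "lower_leg", "foot"),
    length_frac = c(0.470, 0.245, 0.246, 0.152),
    mass_frac = c(0.678, 0.100, 0.0465, 0.0145),
    com_frac = c(0.450, 0.433, 0.433, 0.500),
    rog_frac = c(0.496, 0.323, 0.302, 0.475),
    row.names = c("HAT", "upper_leg", "lower_leg", "foot")
  )
}

#' Build the planar 7-segment skeleton
#'
#' Constructs the rigid-body model (head-arms-trunk, right/left thigh, shank
#' and foot) with segment lengths proportional to body height and masses and
#' moments of inertia scaled from total body mass, using the proportion
#' table from [default_proportions()]. The model has 9 generalized
#' coordinates: hip-point translation (x forward, y up), HAT orientation
#' (counterclockwise from vertical), and 6 joint angles (hip, knee, ankle on
#' each side, distal-minus-proximal segment angle; hip flexion, knee
#' extension and ankle dorsiflexion are positive).
#'
#' @param total_height body height in m (reference configuration: 1.74 m)
#' @param total_mass body mass in kg (reference configuration: 72.80 kg)
#' @param gravity gravitational acceleration in m/s^2
#' @param proportions optional proportion table overriding
#'   [default_proportions()]
#' @param ankle_height_frac ankle joint height above ground as a fraction of
#'   body height (flat foot)
#' @param heel_frac horizontal heel position behind the ankle as a fraction
#'   of foot length
#' @return an object of class `skeleton`
#' @export
build_skeleton <- function(total_height, total_mass, gravity = 9.81,
                           proportions = default_proportions(),
                           ankle_height_frac = 0.039,
                           heel_frac = 0.25) {
  if (!is.numeric(total_height) || length(total_height) != 1 || total_height <= 0)
    stop("total_height must be a positive number")
  if (!is.numeric(total_mass) || length(total_mass) != 1 || total_mass <= 0)
    stop("total_mass must be a positive number")
  pr <- proportions
  need <- c("HAT", "upper_leg", "lower_leg", "foot")
  if (!all(need %in% rownames(pr))) stop("proportion table must cover ", paste(need, collapse = ", "))

  len <- pr[need, "length_frac"] * total_height
  mas <- pr[need, "mass_frac"] * total_mass
  com <- pr[need, "com_frac"] * len
  moi <- mas * (pr[need, "rog_frac"] * len)^2
  names(len) <- names(mas) <- names(com) <- names(moi) <- need

  segs <- data.frame(
    name = SEGMENT_NAMES,
    length = len[c(1, 2, 3, 4, 2, 3, 4)],
    mass = c(mas[1], mas[2], mas[3], mas[4], mas[2], mas[3], mas[4]),
    com_offset = com[c(1, 2, 3, 4, 2, 3, 4)],
    moment_of_inertia = moi[c(1, 2, 3, 4, 2, 3, 4)],
    row.names = NULL, stringsAsFactors = FALSE
  )
  msum <- sum(segs$mass)
  if (abs(msum - total_mass) > 1e-3 * total_mass)
    stop("segment masses sum to ", signif(msum, 6), " kg, not total body mass")

  h_ank <- ankle_height_frac * total_height
  Lf <- len["foot"]
  heel <- c(-heel_frac * Lf, -h_ank)
  toe <- c((1 - heel_frac) * Lf, -h_ank)
  footcom <- c((pr["foot", "com_frac"] - heel_frac) * Lf, -0.5 * h_ank)

  cpp <- list(
    m = unname(segs$mass), I = unname(segs$moment_of_inertia),
    Lt = unname(len["upper_leg"]), Ls = unname(len["lower_leg"]),
    cH = unname(com["HAT"]), ct = unname(com["upper_leg"]), cs = unname(com["lower_leg"]),
    heel = unname(heel), toe = unname(toe), footcom = unname(footcom),
    g = gravity
  )
  standing_hip <- cpp$Lt + cpp$Ls + h_ank

  structure(list(
    segments = segs,
    joints = JOINT_NAMES,
    total_height = total_height,
    total_mass = total_mass,
    gravity = gravity,
    ankle_height = h_ank,
    foot_length = unname(Lf),
    standing_hip_height = standing_hip,
    standing_hat_com_height = standing_hip + cpp$cH,
    cpp = cpp
  ), class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat("Planar 7-segment skeleton: height", x$total_height, "m, mass",
      x$total_mass, "kg, 9 DOF\n")
  print(x$segments, digits = 4)
  invisible(x)
}

#' Skeleton generalized state
#'
#' @param q generalized coordinates, length 9: hip x, hip y, HAT angle,
#'   hip/knee/ankle R, hip/knee/ankle L (m and rad)
#' @param qdot their time derivatives
#' @return object of class `skeleton_state`
#' @export
skeleton_state <- function(q, qdot = rep(0, 9)) {
  q <- as.numeric(q); qdot <- as.numeric(qdot)
  if (length(q) != 9 || length(qdot) != 9)
    stop("q and qdot must have length 9 (the model's DOF count)")
  if (!all(is.finite(q)) || !all(is.finite(qdot)))
    stop("state must be finite")
  names(q) <- names(qdot) <- c("x", "y", "phi", JOINT_NAMES)
  structure(list(q = q, qdot = qdot), class = "skeleton_state")
}

#' Absolute segment angles of a state
#'
#' Converts the generalized coordinates to the 7 absolute segment angles
#' (counterclockwise from vertical), in the order HAT, thigh/shank/foot R,
#' thigh/shank/foot L.
#' @param state a `skeleton_state`
#' @return named numeric vector of length 7 (rad)
#' @export
segment_angles <- function(state) {
  q <- state$q
  th <- c(q[3],
          q[3] + q[4], q[3] + q[4] + q[5], q[3] + q[4] + q[5] + q[6],
          q[3] + q[7], q[3] + q[7] + q[8], q[3] + q[7] + q[8] + q[9])
  stats::setNames(unname(th), SEGMENT_NAMES)
}

#' Joint angles from segment angles
#'
#' Inverse of the mapping used by [segment_angles()]: returns the 6 joint
#' coordinates (distal minus proximal segment angle).
#' @param seg_angles named or ordered numeric vector of 7 segment angles
#' @return named numeric vector of 6 joint angles (rad)
#' @export
joint_angles_from_segments <- function(seg_angles) {
  s <- unname(seg_angles)
  stats::setNames(
    c(s[2] - s[1], s[3] - s[2], s[4] - s[3],
      s[5] - s[1], s[6] - s[5], s[7] - s[6]),
    JOINT_NAMES)
}

#' Default passive joint moment coefficients
#'
#' Double-exponential joint-limit moments plus linear damping, in the
#' Riener-Edrich family: `M = e1 exp(-s1 (q - t1)) - e2 exp(s2 (q - t2))
#' - damp * qdot`. The exponentials are negligible in the physiological
#' mid-range and engage steeply beyond it. Coefficients are configuration,
#' shared by both sides.
#'
#' @return 3 x 7 numeric matrix with rows `hip`, `knee`, `ankle` and columns
#'   `e1, s1, t1, e2, s2, t2, damp`
#' @export
default_passive_params <- function() {
  m <- rbind(
    hip   = c(1.5, 10, -0.50, 1.5, 10, 1.70, 1.5),
    knee  = c(1.5, 10, -2.10, 2.0, 30, 0.02, 1.5),
    ankle = c(1.5, 12, -0.90, 1.5, 12, 0.50, 1.5)
  )
  colnames(m) <- c("e1", "s1", "t1", "e2", "s2", "t2", "damp")
  m
}

#' Passive joint moment
#'
#' Angle-dependent double-exponential joint-limit moment with linear
#' damping. Positive moments accelerate the joint coordinate positively
#' (hip flexion, knee extension, ankle dorsiflexion).
#'
#' @param joint one of `"hip"`, `"knee"`, `"ankle"`
#' @param angle joint angle in rad (vectorized)
#' @param angular_velocity joint angular velocity in rad/s
#' @param params coefficient matrix as in [default_passive_params()]
#' @return moment in N m
#' @export
passive_joint_moment <- function(joint, angle, angular_velocity = 0,
                                 params = default_passive_params()) {
  joint <- sub("_[RL]$", "", joint)
  if (!joint %in% rownames(params))
    stop("unknown joint '", joint, "'; expected one of ",
         paste(rownames(params), collapse = ", "))
  p <- params[joint, ]
  p[["e1"]] * exp(-p[["s1"]] * (angle - p[["t1"]])) -
    p[["e2"]] * exp(p[["s2"]] * (angle - p[["t2"]])) -
    p[["damp"]] * angular_velocity
}

#' Forward dynamics of the skeleton
#'
#' Solves the planar multibody equations of motion `M(q) qdd = Q(q, qd)`
#' for the generalized accelerations, given applied joint moments and
#' external point forces. Gravity is always applied; muscles and ground
#' contact are not (supply their resultants through the arguments).
#'
#' @param model a `skeleton`
#' @param state a `skeleton_state`
#' @param joint_moments numeric vector of length 6 (order `hip_R, knee_R,
#'   ankle_R, hip_L, knee_L, ankle_L`), N m
#' @param external_forces optional data.frame with columns `segment`
#'   (name from `model$segments$name`), `px`, `py` (application point in the
#'   segment frame, m) and `fx`, `fy` (global force components, N)
#' @return generalized accelerations, length 9
#' @export
compute_dynamics <- function(model, state, joint_moments = rep(0, 6),
                             external_forces = NULL) {
  stopifnot(inherits(model, "skeleton"), inherits(state, "skeleton_state"))
  jm <- as.numeric(joint_moments)
  if (length(jm) != 6 || !all(is.finite(jm)))
    stop("joint_moments must be 6 finite values")
  if (is.null(external_forces)) {
    ef <- matrix(numeric(0), ncol = 5)
  } else {
    idx <- match(external_forces$segment, SEGMENT_NAMES) - 1L
    if (anyNA(idx)) stop("unknown segment in external_forces")
    ef <- cbind(idx, external_forces$px, external_forces$py,
                external_forces$fx, external_forces$fy)
    if (!all(is.finite(ef))) stop("external forces must be finite")
  }
  acc <- cpp_eom(model$cpp, state$q, state$qdot, jm, ef)
  stats::setNames(as.numeric(acc), c("x", "y", "phi", JOINT_NAMES))
}

#' Whole-body center of mass
#'
#' Mass-weighted mean of the 7 segment CoM positions and velocities.
#'
#' @param model a `skeleton`
#' @param state a `skeleton_state`
#' @return list with `position` and `velocity`, each `c(x, y)`
#' @export
whole_body_com <- function(model, state) {
  k <- cpp_kinematics(model$cpp, state$q, state$qdot)
  list(position = stats::setNames(k$com, c("x", "y")),
       velocity = stats::setNames(k$vcom, c("x", "y")))
}

#' Landmark kinematics of a state
#'
#' Global positions and velocities of the joints, heel/toe contact points,
#' segment CoMs and a head marker, plus absolute segment angles and the
#' whole-body CoM.
#' @param model a `skeleton`
#' @param state a `skeleton_state`
#' @return list with `points` (2 x 17), `velocities`, `segment_angles`,
#'   `com`, `vcom`
#' @export
skeleton_kinematics <- function(model, state) {
  cpp_kinematics(model$cpp, state$q, state$qdot)
}

#' Total mechanical energy of a state
#'
#' Kinetic plus gravitational potential energy of all segments; used by
#' the ballistic conservation checks.
#' @param model a `skeleton`
#' @param state a `skeleton_state`
#' @return energy in J
#' @export
mechanical_energy <- function(model, state) {
  k <- cpp_kinematics(model$cpp, state$q, state$qdot)
  segs <- model$segments
  om <- cumsum_omegas(state$qdot)
  idx <- match(paste0("com", c("HAT", "ThighR", "ShankR", "FootR",
                               "ThighL", "ShankL", "FootL")),
               colnames(k$points))
  ke <- sum(0.5 * segs$mass * colSums(k$velocities[, idx, drop = FALSE]^2)) +
    sum(0.5 * segs$moment_of_inertia * om^2)
  pe <- sum(segs$mass * model$gravity * k$points[2, idx])
  ke + pe
}

# absolute segment angular velocities from qdot
cumsum_omegas <- function(qd) {
  c(qd[3],
    qd[3] + qd[4], qd[3] + qd[4] + qd[5], qd[3] + qd[4] + qd[5] + qd[6],
    qd[3] + qd[7], qd[3] + qd[7] + qd[8], qd[3] + qd[7] + qd[8] + qd[9])
}
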