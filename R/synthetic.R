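#' Synthetic gait-cycle template
#'
#' Smooth hip/knee/ankle flexion-extension curves over the gait cycle
#' (phase 0 = right heel strike), represented as Fourier series with at
#' most 5 harmonics fitted to hand-placed textbook-shaped keypoints. Two
#' templates are shipped: a `"30s"` (younger) template and a `"70s"`
#' (older) template with reduced range of motion and a markedly reduced
#' ankle push-off excursion. These curves are synthetic stand-ins for
#' group-mean gait data; they are explicitly not measurements.
#'
#' @param group `"30s"` or `"70s"`
#' @param n_harmonics number of Fourier harmonics (max 5)
#' @return object of class `gait_template` with a 3 x (2 n + 1) coefficient
#'   matrix (rows hip, knee, ankle; angles in degrees: hip and knee flexion
#'   positive, ankle dorsiflexion positive) and an inter-subject SD scale
#' @export
gait_template <- function(group = c("30s", "70s"), n_harmonics = 5) {
  group <- match.arg(group)
  if (n_harmonics < 1 || n_harmonics > 5) stop("n_harmonics must be 1..5")
  kp <- if (group == "30s") list(
    hip   = cbind(c(0, .10, .30, .50, .60, .75, .85, .95), c(30, 25, 5, -10, -8, 15, 30, 31)),
    knee  = cbind(c(0, .12, .40, .55, .65, .75, .85, .95), c(4, 18, 5, 25, 55, 60, 30, 6)),
    ankle = cbind(c(0, .10, .45, .55, .62, .70, .85, .95), c(0, -5, 10, 5, -18, -10, 2, 1))
  ) else list(
    hip   = cbind(c(0, .10, .30, .50, .60, .75, .85, .95), c(27, 23, 5, -7, -5, 14, 27, 28)),
    knee  = cbind(c(0, .12, .40, .55, .65, .75, .85, .95), c(4, 15, 5, 22, 50, 55, 27, 6)),
    ankle = cbind(c(0, .10, .45, .55, .62, .70, .85, .95), c(0, -4, 8, 4, -10, -6, 2, 1))
  )
  phase <- seq(0, 1, length.out = 201)[-201]
  basis <- fourier_basis(phase, n_harmonics)
  coefs <- t(vapply(kp, function(k) {
    # periodic spline through the keypoints, then least-squares Fourier fit
    kx <- c(k[, 1], k[1, 1] + 1)
    ky <- c(k[, 2], k[1, 2])
    dense <- stats::spline(kx, ky, method = "periodic", xout = phase)$y
    unname(stats::lsfit(basis, dense, intercept = FALSE)$coef)
  }, numeric(2 * n_harmonics + 1)))
  rownames(coefs) <- c("hip", "knee", "ankle")
  structure(list(coefficients = coefs, n_harmonics = n_harmonics,
                 sd_scale = c(hip = 4, knee = 5, ankle = 3), group = group),
            class = "gait_template")
}

fourier_basis <- function(phase, n_harmonics) {
  b <- matrix(1, length(phase), 1)
  for (h in seq_len(n_harmonics))
    b <- cbind(b, cos(2 * pi * h * phase), sin(2 * pi * h * phase))
  b
}

#' Evaluate a gait template
#' @param template a `gait_template`
#' @param phase gait-cycle fraction(s) in `[0, 1)` (values outside wrap)
#' @return matrix with columns `hip`, `knee`, `ankle` (degrees)
#' @export
eval_template <- function(template, phase) {
  b <- fourier_basis(phase %% 1, template$n_harmonics)
  out <- b %*% t(template$coefficients)
  colnames(out) <- c("hip", "knee", "ankle")
  out
}

#' Target toe-off posture from a template
#'
#' Evaluates the template at the toe-off phase (trailing leg = right) and
#' half a cycle earlier (leading leg = left) and converts the joint angles
#' to the 7 absolute segment angles under the package's kinematic
#' convention (HAT with a small forward lean).
#'
#' @param template a `gait_template`
#' @param toe_off_fraction gait-cycle fraction of right toe-off, in (0, 1)
#' @param hat_lean HAT segment angle, rad (negative = forward lean)
#' @return object of class `target_posture`: named numeric vector of 7
#'   segment angles, rad
#' @export
make_target_posture <- function(template, toe_off_fraction = 0.60,
                                hat_lean = -0.15) {
  if (!is.numeric(toe_off_fraction) || toe_off_fraction <= 0 ||
      toe_off_fraction >= 1)
    stop("toe_off_fraction must lie in (0, 1)")
  jr <- eval_template(template, toe_off_fraction) * pi / 180
  jl <- eval_template(template, toe_off_fraction - 0.5) * pi / 180
  seg <- function(hat, j) {
    th_t <- hat + j[1, "hip"]
    th_s <- th_t - j[1, "knee"]     # knee flexion positive in the template
    th_f <- th_s + j[1, "ankle"]
    c(th_t, th_s, th_f)
  }
  ang <- c(hat_lean, seg(hat_lean, jr), seg(hat_lean, jl))
  structure(stats::setNames(ang, SEGMENT_NAMES), class = "target_posture")
}

#' Synthetic reference joint-angle curves
#'
#' Simulates `n_subjects` per-subject gait curves (template plus smooth
#' correlated Fourier noise) and returns their mean and SD on 101
#' gait-cycle points, mimicking group-mean reference data for a younger
#' ("30s") and an older ("70s") group.
#'
#' @param group `"30s"` or `"70s"`
#' @param n_subjects number of simulated subjects (>= 2)
#' @param seed integer seed; output is a pure function of
#'   `(group, n_subjects, seed)`
#' @return object of class `reference_gait_curves`: list per joint with
#'   `mean` and `sd` (length 101, degrees), plus `group`, `n_subjects`
#' @export
make_reference_curves <- function(group = c("30s", "70s"), n_subjects = 10,
                                  seed = 1) {
  group <- match.arg(group)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  tpl <- gait_template(group)
  phase <- seq(0, 1, length.out = 101)
  base <- eval_template(tpl, phase)
  rng <- local_rng(seed)
  joints <- c("hip", "knee", "ankle")
  subj <- array(0, dim = c(101, 3, n_subjects), dimnames = list(NULL, joints, NULL))
  nh <- 4
  for (s in seq_len(n_subjects)) {
    for (j in seq_along(joints)) {
      amp <- tpl$sd_scale[[joints[j]]]
      co <- rng$rnorm(2 * nh + 1) * amp / (1.5 * c(1, rep(rep(1:nh, each = 2), 1)))
      noise <- fourier_basis(phase, nh) %*% co
      subj[, j, s] <- base[, j] + noise
    }
  }
  out <- lapply(seq_along(joints), function(j) {
    list(mean = rowMeans(subj[, j, , drop = TRUE]),
         sd = apply(subj[, j, , drop = TRUE], 1, stats::sd))
  })
  names(out) <- joints
  structure(c(out, list(group = group, n_subjects = n_subjects,
                        phase = phase, subjects = subj)),
            class = "reference_gait_curves")
}

# small self-contained RNG wrapper: deterministic, does not touch the
# global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  nxt <- function() {
    # Park-Miller minimal standard generator
    env$state <- as.integer((as.double(env$state) * 48271) %% 2147483647)
    if (env$state <= 0) env$state <- env$state + 2147483646L
    env$state / 2147483647
  }
  list(
    runif = function(n) vapply(seq_len(n), function(i) nxt(), numeric(1)),
    rnorm = function(n) {
      u1 <- vapply(seq_len(n), function(i) nxt(), numeric(1))
      u2 <- vapply(seq_len(n), function(i) nxt(), numeric(1))
      sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
    }
  )
}

#' Scripted toy gait trial
#'
#' Builds a minimal `gait_trial` with prescribed CoM, toe and ankle
#' trajectories and gait events, bypassing the dynamics; used to exercise
#' the stability analysis against hand-computable cases.
#'
#' @param spec list with `time` (increasing grid, s), `com` (n x 2),
#'   `vcom` (n x 2), `toe_R`, `toe_L`, `ankle_R`, `ankle_L` (each n x 2,
#'   m; constants are recycled), and `events` (data.frame with `type`
#'   (`"heel_strike"`/`"toe_off"`), `side` (`"R"`/`"L"`), `time`, `step`)
#' @return object of class `gait_trial` (kind `"toy"`)
#' @export
make_toy_trial <- function(spec) {
  time <- spec$time
  if (is.unsorted(time, strictly = TRUE)) stop("spec time grid must be strictly increasing")
  n <- length(time)
  expand <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, n, 2, byrow = TRUE)
    if (nrow(x) != n) stop("trace length does not match the time grid")
    x
  }
  ev <- spec$events
  if (!is.null(ev)) {
    if (is.unsorted(ev$time)) stop("events must be time-ordered")
    if (any(ev$time < time[1] | ev$time > time[n]))
      stop("event times fall outside the time grid")
  }
  structure(list(
    kind = "toy", time = time,
    landmarks = list(com = expand(spec$com), vcom = expand(spec$vcom),
                     toe_R = expand(spec$toe_R), toe_L = expand(spec$toe_L),
                     ankle_R = expand(spec$ankle_R),
                     ankle_L = expand(spec$ankle_L)),
    events = ev, status = "completed"
  ), class = "gait_trial")
}
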