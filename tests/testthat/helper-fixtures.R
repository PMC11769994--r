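# shared fixtures: built once per test run

ref_skeleton <- function() build_skeleton(1.74, 72.80)

ref_muscles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_muscle_set(1.74, 72.80)
    cache
  }
})

standing_state <- function(sk = ref_skeleton()) {
  skeleton_state(c(0, sk$standing_hip_height, rep(0, 7)))
}

# independent forward kinematics written from scratch (position-level
# oracle for CoM / point checks): rotation by angle t of local (x, y)
rot <- function(t, v) c(cos(t) * v[1] - sin(t) * v[2],
                        sin(t) * v[1] + cos(t) * v[2])

oracle_segment_coms <- function(sk, q) {
  L <- sk$segments$length
  cH <- sk$segments$com_offset[1]
  ct <- sk$segments$com_offset[2]
  cs <- sk$segments$com_offset[3]
  hip <- q[1:2]
  th <- c(q[3],
          q[3] + q[4], q[3] + q[4] + q[5], q[3] + q[4] + q[5] + q[6],
          q[3] + q[7], q[3] + q[7] + q[8], q[3] + q[7] + q[8] + q[9])
  fc <- sk$cpp$footcom
  kneeR <- hip + rot(th[2], c(0, -sk$cpp$Lt))
  ankR <- kneeR + rot(th[3], c(0, -sk$cpp$Ls))
  kneeL <- hip + rot(th[5], c(0, -sk$cpp$Lt))
  ankL <- kneeL + rot(th[6], c(0, -sk$cpp$Ls))
  rbind(HAT = hip + rot(th[1], c(0, sk$cpp$cH)),
        thR = hip + rot(th[2], c(0, -ct)),
        shR = kneeR + rot(th[3], c(0, -cs)),
        ftR = ankR + rot(th[4], fc),
        thL = hip + rot(th[5], c(0, -ct)),
        shL = kneeL + rot(th[6], c(0, -cs)),
        ftL = ankL + rot(th[7], fc))
}

oracle_whole_body_com <- function(sk, q) {
  coms <- oracle_segment_coms(sk, q)
  colSums(coms * sk$segments$mass) / sum(sk$segments$mass)
}

# a fake "simulated" trial with prescribed constant posture and toe-off
# events; enough structure for rms_ang / objective_value
constant_posture_trial <- function(q_const, n_toe_offs = 4, sides = "R",
                                   duration = 2.24, n = 57,
                                   metabolic = 0, forward = 0,
                                   skeleton = ref_skeleton(),
                                   status = "completed") {
  time <- seq(0, duration, length.out = n)
  q <- matrix(rep(q_const, each = n), n, 9)
  q[, 1] <- q[, 1] + seq(0, forward, length.out = n)
  qd <- matrix(0, n, 9)
  qd[, 1] <- if (n > 1) forward / duration else 0
  colnames(q) <- colnames(qd) <- c("x", "y", "phi",
                                   c("hip_R", "knee_R", "ankle_R",
                                     "hip_L", "knee_L", "ankle_L"))
  sides <- rep_len(sides, n_toe_offs)
  ev <- if (n_toe_offs > 0)
    data.frame(type = "toe_off", side = sides,
               time = seq(0.2, 0.8, length.out = n_toe_offs) * duration,
               step = seq_len(n_toe_offs))
  else data.frame(type = character(0), side = character(0),
                  time = numeric(0), step = integer(0))
  structure(list(kind = "simulated", time = time, q = q, qdot = qd,
                 metabolic_power = rep(metabolic, n), events = ev,
                 status = status, duration = duration, skeleton = skeleton,
                 body_weight = skeleton$total_mass * skeleton$gravity),
            class = "gait_trial")
}

# posture whose segment angles are all zero except as overridden
posture_from_segments <- function(seg) {
  structure(stats::setNames(seg, c("HAT", "upper_leg_R", "lower_leg_R",
                                   "foot_R", "upper_leg_L", "lower_leg_L",
                                   "foot_L")),
            class = "target_posture")
}
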