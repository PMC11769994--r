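test_that("anthropometric scaling distributes mass and length correctly", {
  sk <- ref_skeleton()
  expect_equal(sum(sk$segments$mass), 72.80, tolerance = 1e-12)
  expect_equal(nrow(sk$segments), 7)

  # doubling mass doubles every segment mass; lengths unchanged
  sk2 <- build_skeleton(1.74, 2 * 72.80)
  expect_equal(sk2$segments$mass, 2 * sk$segments$mass)
  expect_equal(sk2$segments$length, sk$segments$length)

  # lengths scale elementwise with height (recomputed from the table)
  sk3 <- build_skeleton(1.83, 91.0)
  pr <- default_proportions()
  expect_equal(unname(sk3$segments$length[1:4]),
               unname(pr[c("HAT", "upper_leg", "lower_leg", "foot"),
                         "length_frac"] * 1.83))
  expect_equal(sk3$segments$length, sk$segments$length * 1.83 / 1.74)

  expect_error(build_skeleton(-1, 70), "positive")
  expect_error(build_skeleton(1.7, 0), "positive")
})

test_that("passive joint moments are small mid-range and restore at limits", {
  expect_lt(abs(passive_joint_moment("knee", -0.3, 0)), 1)
  expect_lt(abs(passive_joint_moment("hip", 0.3, 0)), 1)
  # extreme dorsiflexion: plantar-flexing (negative) restoring moment
  expect_lt(passive_joint_moment("ankle", 0.8, 0), -5)
  # extreme plantarflexion: dorsiflexing moment
  expect_gt(passive_joint_moment("ankle", -1.2, 0), 5)
  # hand-evaluated double exponential, 10 degrees beyond the hip limit
  p <- default_passive_params()
  ang <- -0.5 - 10 * pi / 180
  expected <- p["hip", "e1"] * exp(-p["hip", "s1"] * (ang - p["hip", "t1"])) -
    p["hip", "e2"] * exp(p["hip", "s2"] * (ang - p["hip", "t2"]))
  expect_equal(passive_joint_moment("hip", ang, 0), expected)
  # damping opposes motion
  expect_lt(passive_joint_moment("knee", -0.3, 2),
            passive_joint_moment("knee", -0.3, 0))
  expect_error(passive_joint_moment("elbow", 0, 0), "unknown joint")
})

test_that("free fall accelerates the body as a whole at -g", {
  sk <- ref_skeleton()
  set.seed(11)
  for (i in 1:5) {
    q <- c(rnorm(1), 1.2, rnorm(7, 0, 0.5))
    st <- skeleton_state(q)            # at rest
    acc <- compute_dynamics(sk, st)
    expect_equal(unname(acc), c(0, -sk$gravity, rep(0, 7)), tolerance = 1e-9)
  }
})

test_that("dynamics matches a finite-difference Lagrangian oracle", {
  sk <- ref_skeleton()
  m <- sk$segments$mass; I <- sk$segments$moment_of_inertia
  om_of <- function(qd) c(qd[3], qd[3] + qd[4], qd[3] + qd[4] + qd[5],
                          qd[3] + qd[4] + qd[5] + qd[6],
                          qd[3] + qd[7], qd[3] + qd[7] + qd[8],
                          qd[3] + qd[7] + qd[8] + qd[9])
  kinetic <- function(q, qd) {
    h <- 1e-6
    v <- (oracle_segment_coms(sk, q + h * qd) -
            oracle_segment_coms(sk, q - h * qd)) / (2 * h)
    sum(0.5 * m * rowSums(v^2)) + sum(0.5 * I * om_of(qd)^2)
  }
  potential <- function(q) sum(m * sk$gravity * oracle_segment_coms(sk, q)[, 2])
  set.seed(21)
  for (rep in 1:3) {
    q <- c(0.2, 1.1, rnorm(7, 0, 0.4)); qd <- rnorm(9, 0, 0.4)
    qdd <- compute_dynamics(sk, skeleton_state(q, qd))
    # Euler-Lagrange residual: d/dt (dT/dqd) - dT/dq + dV/dq = 0
    # (finite differences limit the achievable accuracy to ~1e-3 of the
    # term magnitudes; the machine-precision energy-conservation test
    # below is the sharp companion check)
    h <- 1e-4
    for (j in c(1, 3, 5, 8)) {
      e <- rep(0, 9); e[j] <- h
      dT_dqd <- function(q., qd.)
        (kinetic(q., qd. + e) - kinetic(q., qd. - e)) / (2 * h)
      lhs1 <- (dT_dqd(q + h * qd, qd + h * qdd) -
                 dT_dqd(q - h * qd, qd - h * qdd)) / (2 * h)
      lhs2 <- (kinetic(q + e, qd) - kinetic(q - e, qd)) / (2 * h)
      lhs3 <- (potential(q + e) - potential(q - e)) / (2 * h)
      expect_lt(abs(lhs1 - lhs2 + lhs3),
                0.05 + 5e-3 * (abs(lhs1) + abs(lhs3)))
    }
  }
})

test_that("ballistic motion conserves mechanical energy to machine precision", {
  sk <- ref_skeleton()
  set.seed(5)
  q <- c(0, 2.5, rnorm(7, 0, 0.5)); qd <- rnorm(9, 0, 0.6)
  dt <- 5e-4
  E0 <- mechanical_energy(sk, skeleton_state(q, qd))
  deriv <- function(q, qd)
    list(qd = qd, qdd = compute_dynamics(sk, skeleton_state(q, qd)))
  for (i in 1:500) {
    k1 <- deriv(q, qd)
    k2 <- deriv(q + dt / 2 * k1$qd, qd + dt / 2 * k1$qdd)
    k3 <- deriv(q + dt / 2 * k2$qd, qd + dt / 2 * k2$qdd)
    k4 <- deriv(q + dt * k3$qd, qd + dt * k3$qdd)
    q <- q + dt / 6 * (k1$qd + 2 * k2$qd + 2 * k3$qd + k4$qd)
    qd <- qd + dt / 6 * (k1$qdd + 2 * k2$qdd + 2 * k3$qdd + k4$qdd)
  }
  E1 <- mechanical_energy(sk, skeleton_state(q, qd))
  expect_lt(abs(E1 - E0) / abs(E0), 1e-10)   # far inside the 0.1% contract
})

test_that("joint moments and external forces enter the dynamics consistently", {
  sk <- ref_skeleton()
  st <- standing_state(sk)
  # a pure vertical force through every CoM cancels gravity exactly
  segs <- sk$segments
  fc <- sk$cpp$footcom
  ef <- data.frame(
    segment = segs$name,
    px = c(0, 0, 0, fc[1], 0, 0, fc[1]),
    py = c(sk$cpp$cH, -sk$cpp$ct, -sk$cpp$cs, fc[2],
           -sk$cpp$ct, -sk$cpp$cs, fc[2]),
    fx = 0, fy = segs$mass * sk$gravity)
  acc <- compute_dynamics(sk, st, external_forces = ef)
  expect_equal(max(abs(acc)), 0, tolerance = 1e-8)
  expect_error(compute_dynamics(sk, st, joint_moments = rep(NA, 6)), "finite")
})

test_that("pinned compound pendulum matches the closed-form angular acceleration", {
  # legs made numerically massless: the body is one rigid HAT pivoted at
  # the hip; the pivot is enforced by solving for the hip force that
  # zeroes the base acceleration (exact by linearity of the EoM in forces)
  pr <- default_proportions()
  pr$mass_frac <- c(1 - 6e-9, 1e-9, 1e-9, 1e-9)
  sk <- build_skeleton(1.74, 72.80, proportions = pr)
  th0 <- 0.6
  st <- skeleton_state(c(0, 1.0, th0, rep(0, 6)))
  probe <- function(fx, fy) {
    ef <- data.frame(segment = "HAT", px = 0, py = 0, fx = fx, fy = fy)
    compute_dynamics(sk, st, external_forces = ef)
  }
  a0 <- probe(0, 0)
  ax <- probe(1, 0) - a0
  ay <- probe(0, 1) - a0
  A <- cbind(ax[1:2], ay[1:2])
  f <- solve(A, -a0[1:2])
  apin <- a0 + f[1] * ax + f[2] * ay
  expect_equal(unname(apin[1:2]), c(0, 0), tolerance = 1e-9)
  # compound pendulum about the hip: alpha = m g d sin(theta) / (I + m d^2)
  m <- sk$segments$mass[1]; d <- sk$segments$com_offset[1]
  I <- sk$segments$moment_of_inertia[1]
  alpha <- m * sk$gravity * d * sin(th0) / (I + m * d^2)
  # theta is CCW from vertical with the CoM above the pivot: gravity
  # accelerates the tilt
  expect_equal(unname(apin[3]), alpha, tolerance = 1e-6 * abs(alpha))
})

test_that("whole-body CoM is the mass-weighted segment mean", {
  sk <- ref_skeleton()
  set.seed(31)
  q <- c(0.4, 1.1, rnorm(7, 0, 0.4))
  st <- skeleton_state(q)
  com <- whole_body_com(sk, st)
  expect_equal(unname(com$position), unname(oracle_whole_body_com(sk, q)),
               tolerance = 1e-12)
  expect_equal(unname(com$velocity), c(0, 0))
  # split-leg posture mirror-symmetric about x = 0 (feet flat, foot CoM
  # above the ankle so the segment mass distribution is x-symmetric):
  # the CoM sits exactly midway between the two feet
  pr <- default_proportions()
  pr["foot", "com_frac"] <- 0.25          # = heel_frac: CoM above the ankle
  sks <- build_skeleton(1.74, 72.80, proportions = pr)
  qs <- c(0, 1.0, 0, 0.3, 0, -0.3, -0.3, 0, 0.3)
  ks <- skeleton_kinematics(sks, skeleton_state(qs))
  expect_equal(unname(ks$points[1, "ankleR"]), -unname(ks$points[1, "ankleL"]))
  expect_equal(ks$com[1],
               mean(ks$points[1, c("ankleR", "ankleL")]), tolerance = 1e-12)
  # translating the state translates the CoM exactly
  q2 <- q; q2[1] <- q2[1] + 1.37
  com2 <- whole_body_com(sk, skeleton_state(q2))
  expect_equal(com2$position[["x"]], com$position[["x"]] + 1.37)
  expect_equal(com2$position[["y"]], com$position[["y"]])
})

test_that("segment-angle conversions invert each other", {
  set.seed(41)
  q <- c(0, 1, rnorm(7, 0, 0.7))
  st <- skeleton_state(q)
  seg <- segment_angles(st)
  expect_equal(unname(joint_angles_from_segments(seg)), unname(q[4:9]))
})
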