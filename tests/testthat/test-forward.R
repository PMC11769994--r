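test_that("the default trial grid spans four steps at 1 ms", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  ms$muscles$fmax <- 1e-9
  # passive flight with the fall cutoff disabled: the grid runs to the end
  quiet <- stimulation_profile(rep(0, 9), rep(0.01, 9), rep(0.011, 9))
  init <- list(state = skeleton_state(c(0, 3.5, rep(0, 7))),
               activation = rep(0, 18))
  tr <- simulate_walking(sk, ms, contact_params(1e-9), quiet, init = init,
                         fall_fraction = 0)
  expect_length(tr$time, 2241)
  expect_equal(max(tr$time), 2.24)
  expect_equal(unique(round(diff(tr$time), 12)), 1e-3)
  expect_error(simulate_walking(sk, ms, contact_params(), quiet, dt = 2e-3),
               "dt")
  expect_error(simulate_walking(sk, ms, contact_params(), quiet,
                                duration = -1), "duration")
})

test_that("an unpowered model collapses and is flagged as fallen", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  quiet <- stimulation_profile(rep(0, 9), rep(0.01, 9), rep(0.011, 9))
  init <- list(state = standing_state(sk), activation = rep(0.01, 18))
  init$state$q[2] <- init$state$q[2] - 0.003
  tr <- simulate_walking(sk, ms, contact_params(), quiet, init = init)
  expect_equal(tr$status, "fell")
  expect_lt(max(tr$time), 2.24)
})

test_that("airborne passive flight conserves mechanical energy", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  ms$muscles$fmax <- 1e-9          # muscles effectively off
  quiet <- stimulation_profile(rep(0, 9), rep(0.01, 9), rep(0.011, 9))
  soft <- contact_params(stiffness = 1e-9)
  nopass <- default_passive_params() * 0
  set.seed(8)
  q0 <- c(0, 2.8, rnorm(7, 0, 0.4))
  qd0 <- rnorm(9, 0, 0.5)
  init <- list(state = skeleton_state(q0, qd0), activation = rep(0, 18))
  tr <- simulate_walking(sk, ms, soft, quiet, init = init, duration = 0.5,
                         passive = nopass, fall_fraction = 0)
  E <- vapply(c(1, nrow(tr$q)), function(i)
    mechanical_energy(sk, skeleton_state(tr$q[i, ], tr$qdot[i, ])),
    numeric(1))
  expect_lt(abs(E[2] - E[1]) / abs(E[1]), 1e-3)    # < 0.1% contract
  expect_lt(abs(E[2] - E[1]) / abs(E[1]), 1e-8)    # and in fact far tighter
})

test_that("toe-off detection interpolates the 0.05% body-weight threshold", {
  bw <- 72.80 * 9.81
  thr <- 5e-4 * bw
  expect_equal(thr, 0.357, tolerance = 1e-3)
  # linear ramp crossing the threshold between samples
  time <- seq(0, 1, by = 0.01)
  tr <- pmax(0, 100 - 200 * time)        # hits the threshold at t ~ 0.4982
  ev <- detect_toe_off(tr, bw, time)
  expect_length(ev$toe_off, 1)
  expect_equal(ev$toe_off, (100 - thr) / 200, tolerance = 1e-9)
  # half-sine bursts: one toe-off per cycle at the analytic crossing
  t2 <- seq(0, 2.4, by = 1e-3)
  g <- pmax(0, sin(pi * t2 / 0.6)) * 800
  ev2 <- detect_toe_off(g, bw, t2)
  t_down <- 0.6 - (0.6 / pi) * asin(thr / 800)
  expect_equal(length(ev2$toe_off), 2)
  expect_lt(abs(ev2$toe_off[1] - t_down), 1e-3)
  expect_lt(abs(ev2$heel_strike[2] - (1.2 + (0.6 / pi) * asin(thr / 800))),
            1e-3)
  # silent trace: no events
  ev3 <- detect_toe_off(rep(0, 100), bw, seq(0, 1, length.out = 100))
  expect_length(ev3$toe_off, 0)
  expect_length(ev3$heel_strike, 0)
  # debouncing removes sub-threshold blips
  gb <- g
  gb[600:602] <- 0                        # 3 ms dropout inside a burst
  evb <- detect_toe_off(gb, bw, t2, min_separation = 0.05)
  expect_equal(length(evb$toe_off), 2)
})

test_that("simulation is bitwise deterministic", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  tr1 <- simulate_walking(sk, ms, contact_params(), nominal_profile(),
                          duration = 0.8)
  tr2 <- simulate_walking(sk, ms, contact_params(), nominal_profile(),
                          duration = 0.8)
  expect_identical(tr1$q, tr2$q)
  expect_identical(tr1$activation, tr2$activation)
  expect_identical(tr1$grf, tr2$grf)
  expect_identical(tr1$metabolic_power, tr2$metabolic_power)
})

test_that("halving the step converges in the smooth regime", {
  # foot-ground impacts make individual trajectories sensitively dependent
  # on the step size (as for any nonsmooth contact model); the integrator's
  # order is therefore checked on the smooth (flight) dynamics, where
  # halving dt must leave the state unchanged to RK4 accuracy
  sk <- ref_skeleton()
  ms <- ref_muscles()
  ms$muscles$fmax <- 1e-9
  quiet <- stimulation_profile(rep(0, 9), rep(0.01, 9), rep(0.011, 9))
  soft <- contact_params(stiffness = 1e-9)
  nopass <- default_passive_params() * 0
  init <- list(state = skeleton_state(c(0, 3.0, rep(0.1, 7)),
                                      c(1, 0, rep(0.3, 7))),
               activation = rep(0, 18))
  tr1 <- simulate_walking(sk, ms, soft, quiet, init = init,
                          duration = 0.4, passive = nopass,
                          fall_fraction = 0)
  tr2 <- simulate_walking(sk, ms, soft, quiet, init = init,
                          duration = 0.4, dt = 5e-4, passive = nopass,
                          fall_fraction = 0)
  expect_lt(max(abs(tr1$q[nrow(tr1$q), ] - tr2$q[nrow(tr2$q), ])), 1e-6)
  # with contact, halving dt keeps the gross motion consistent even though
  # individual impact sequences decorrelate
  tc1 <- simulate_walking(sk, ms, contact_params(), nominal_profile(),
                          duration = 0.5, fall_fraction = 0)
  tc2 <- simulate_walking(sk, ms, contact_params(), nominal_profile(),
                          duration = 0.5, dt = 5e-4, fall_fraction = 0)
  expect_lt(abs(tc1$q[nrow(tc1$q), "x"] - tc2$q[nrow(tc2$q), "x"]), 0.1)
})

test_that("trial CSV export writes the documented schema plus sidecar", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  tr <- simulate_walking(sk, ms, contact_params(), nominal_profile(),
                         duration = 0.3)
  f <- file.path(tempdir(), "trial.csv")
  write_trial_csv(tr, f)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), nrow(tr$q))
  expect_true(all(c("time", "q_x", "q_y", "q_phi", "qd_x", "heelR_Fy",
                    "toeL_Fy", "grf_R_Fy", "metabolic_power") %in% names(df)))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                              simplifyVector = TRUE)
  expect_equal(side$status, tr$status)
  expect_equal(side$dt, tr$dt)
})
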