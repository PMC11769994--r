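# a toy trial whose stability quantities are hand-computable
toy_trial <- function(com_x = 0.46, vcom_x = 0, toe_r = 0.40, toe_l = -0.27,
                      ankle_r = c(0.35, 0.05)) {
  time <- seq(0, 2.24, by = 0.02)
  n <- length(time)
  ev <- data.frame(
    type = c("heel_strike", "toe_off", "heel_strike", "toe_off",
             "heel_strike", "toe_off"),
    side = c("R", "L", "L", "R", "R", "L"),
    time = c(0.05, 0.15, 0.61, 0.71, 1.17, 1.27),
    step = c(1, 1, 1, 2, 2, 3))
  make_toy_trial(list(
    time = time,
    com = c(com_x, 0.97), vcom = c(vcom_x, 0),
    toe_R = c(toe_r, 0), toe_L = c(toe_l, 0),
    ankle_R = ankle_r, ankle_L = c(-0.3, 0.05),
    events = ev))
}

test_that("extrapolated CoM follows the inverted-pendulum formula", {
  expect_equal(extrapolated_com(0.3, 0, 1, 9.81), 0.3)
  expect_equal(extrapolated_com(0, 1.32, 0.998, 9.81),
               1.32 * sqrt(0.998 / 9.81))
  expect_equal(extrapolated_com(0, 1.32, 0.998, 9.81), 0.4210, tolerance = 1e-3)
  # quadrupling the pendulum length doubles the velocity contribution
  expect_equal(extrapolated_com(0, 1, 4 * 0.9, 9.81) /
                 extrapolated_com(0, 1, 0.9, 9.81), 2)
  expect_error(extrapolated_com(0, 1, -1, 9.81), "positive")
  expect_error(extrapolated_com(0, 1, 1, 0), "positive")
})

test_that("margin of stability reproduces hand-computed cases", {
  # zero CoM velocity: XCoM = P_CoM; BoS 0.40, XCoM 0.46 -> MoS = -0.06
  tr <- toy_trial(com_x = 0.46, vcom_x = 0, toe_r = 0.40)
  m <- margin_of_stability(tr, model = NULL)
  expect_equal(m$xcom, 0.46)
  expect_equal(m$bos_boundary, 0.40)
  expect_equal(m$mos, -0.06)
  # XCoM exactly at the toe: MoS = 0
  tr0 <- toy_trial(com_x = 0.40, vcom_x = 0)
  expect_equal(margin_of_stability(tr0, model = NULL)$mos, 0)
  # nonzero velocity: full formula with the right-ankle pendulum length
  tr1 <- toy_trial(com_x = 0.30, vcom_x = 1.2, ankle_r = c(0.35, 0.05))
  l <- sqrt((0.30 - 0.35)^2 + (0.97 - 0.05)^2)
  expect_equal(margin_of_stability(tr1, model = NULL)$pendulum_length, l)
  expect_equal(margin_of_stability(tr1, model = NULL)$mos,
               0.40 - (0.30 + 1.2 * sqrt(l / 9.81)))
  # identity MoS + XCoM = BoS holds exactly
  expect_equal(m$mos + m$xcom, m$bos_boundary)
  # step length and CoM velocity at the same instant
  sv <- step_length_and_vcom(tr1)
  expect_equal(sv$step_length, 0.40 - (-0.27))
  expect_equal(sv$vcom, 1.2)
  expect_equal(step_length_and_vcom(toy_trial())$vcom, 0)
})

test_that("stability metrics are invariant to forward translation", {
  tr <- toy_trial(com_x = 0.30, vcom_x = 1.2)
  m0 <- margin_of_stability(tr, model = NULL)
  dx <- 3.7
  tr2 <- toy_trial(com_x = 0.30 + dx, vcom_x = 1.2, toe_r = 0.40 + dx,
                   toe_l = -0.27 + dx, ankle_r = c(0.35 + dx, 0.05))
  m2 <- margin_of_stability(tr2, model = NULL)
  expect_equal(m2$mos, m0$mos)
  expect_equal(m2$step_length, m0$step_length)
  expect_equal(m2$vcom_at_toe_off, m0$vcom_at_toe_off)
})

test_that("MoS decreases strictly with forward CoM velocity", {
  mos_at <- function(v)
    margin_of_stability(toy_trial(com_x = 0.30, vcom_x = v), model = NULL)$mos
  vs <- seq(0, 1.6, by = 0.2)
  expect_true(all(diff(vapply(vs, mos_at, numeric(1))) < 0))
})

test_that("the stability event is the left toe-off of the second step", {
  tr <- toy_trial()
  # events place left toe-offs at 0.15 (step 1) and 1.27 (step 3): the
  # fallback picks the second left toe-off
  expect_equal(margin_of_stability(tr, model = NULL)$toe_off_time, 1.27)
  # a left toe-off inside step 2 takes precedence
  ev <- tr$events
  ev <- rbind(ev, data.frame(type = "toe_off", side = "L", time = 0.90,
                             step = 2))
  ev <- ev[order(ev$time), ]
  tr$events <- ev
  expect_equal(margin_of_stability(tr, model = NULL)$toe_off_time, 0.90)
  # trials without left toe-offs are rejected informatively
  tr$events <- tr$events[tr$events$side != "L", ]
  expect_error(margin_of_stability(tr, model = NULL), "left toe-off")
})

test_that("cross-correlation validation behaves on canonical curves", {
  ref <- make_reference_curves("30s", n_subjects = 8, seed = 2)
  sim <- cbind(hip = ref$hip$mean, knee = ref$knee$mean,
               ankle = ref$ankle$mean)
  cc <- cross_correlation_validation(sim, ref)
  expect_equal(unname(cc$per_joint), c(1, 1, 1))
  expect_equal(cc$overall, 1)
  # negated curves correlate at -1
  cc2 <- cross_correlation_validation(-sim + 10, ref)
  expect_equal(unname(cc2$per_joint), c(-1, -1, -1))
  # quadrature sinusoids are uncorrelated on 101 points
  ph <- seq(0, 1, length.out = 101)
  fake <- list(hip = list(mean = cos(2 * pi * ph)),
               knee = list(mean = cos(2 * pi * ph)),
               ankle = list(mean = cos(2 * pi * ph)))
  simq <- cbind(hip = sin(2 * pi * ph), knee = sin(2 * pi * ph),
                ankle = sin(2 * pi * ph))
  ccq <- cross_correlation_validation(simq, fake)
  expect_lt(max(abs(ccq$per_joint)), 0.02)
  # zero-variance input is rejected
  simz <- simq; simz[, "hip"] <- 5
  expect_error(cross_correlation_validation(simz, fake), "zero-variance")
})
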