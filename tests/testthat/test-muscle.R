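test_that("muscle set construction applies the documented scaling rules", {
  ms <- ref_muscles()
  df <- ms$muscles
  expect_equal(nrow(df), 18)
  expect_equal(sum(df$side == "R"), 9)
  # fmax = specific tension x scaled PCSA, PCSA scaled from the 1.83 m /
  # 91 kg reference by (mass/91)/(height/1.83)
  tab <- read_muscle_table()
  scale <- (72.80 / 91) / (1.74 / 1.83)
  i <- match(df$name[df$side == "R"], tab$name)
  expect_equal(df$fmax[df$side == "R"], 60 * tab$pcsa[i] * scale)
  expect_equal(df$pcsa * 60, df$fmax)
  # vmax fixed at 12 lopt/s, time constants 55 / 65 ms
  expect_true(all(df$vmax == 12))
  expect_true(all(df$tau_act == 0.055))
  expect_true(all(df$tau_deact == 0.065))
  # left mirrors right exactly
  expect_equal(df$fmax[df$side == "L"], df$fmax[df$side == "R"])
  expect_equal(df$tendon_slack[df$side == "L"], df$tendon_slack[df$side == "R"])
  expect_true(all(df$tendon_slack > 0))
  # missing muscle rejected by name
  bad <- tab[tab$name != "SOLEU", ]
  expect_error(build_muscle_set(1.74, 72.8, table = bad), "SOLEU")
})

test_that("aging variants scale exactly the printed factors", {
  ms <- ref_muscles()
  base <- ms$muscles
  dF <- apply_aging(ms, "dF")$muscles
  expect_equal(dF$fmax, 0.7 * base$fmax)
  expect_equal(dF$vmax, base$vmax)
  expect_equal(dF$tau_deact, base$tau_deact)
  dV <- apply_aging(ms, "dV")$muscles
  expect_equal(dV$vmax, 0.8 * base$vmax)
  dT <- apply_aging(ms, "dT")$muscles
  expect_equal(dT$tau_deact, 1.2 * base$tau_deact)
  expect_equal(dT$tau_act, base$tau_act)   # activation time untouched
  oa <- apply_aging(ms, "OA")$muscles
  expect_equal(oa$fmax, 0.7 * base$fmax)
  expect_equal(oa$vmax, 0.8 * base$vmax)
  expect_equal(oa$tau_deact, 1.2 * base$tau_deact)
  # single-muscle arithmetic: 1000 N -> 700 N; 0.065 s -> 0.078 s
  one <- list(fmax = 1000, vmax = 12, tau_deact = 0.065)
  expect_equal(apply_aging(one, "dF")$fmax, 700)
  expect_equal(apply_aging(one, "OA")$tau_deact, 0.078)
  # YA is the identity
  expect_identical(apply_aging(ms, "YA")$muscles, base)
  # OA equals the three single transforms composed in any order
  via1 <- apply_aging(apply_aging(apply_aging(ms, "dT"), "dF"), "dV")$muscles
  via2 <- apply_aging(apply_aging(apply_aging(ms, "dV"), "dT"), "dF")$muscles
  expect_equal(via1[c("fmax", "vmax", "tau_deact")], oa[c("fmax", "vmax", "tau_deact")])
  expect_equal(via2[c("fmax", "vmax", "tau_deact")], oa[c("fmax", "vmax", "tau_deact")])
})

test_that("activation dynamics follows the two-time-constant first-order law", {
  expect_equal(activation_derivative(0.5, 0.5), 0)
  expect_equal(activation_derivative(1, 0, 0.055, 0.065), 1 / 0.055)
  expect_equal(activation_derivative(0, 1, 0.055, 0.065), -1 / 0.065)
  # Euler integration stays inside [0, 1] for arbitrary stimulation traces
  set.seed(3)
  dt <- 1e-3
  for (rep in 1:3) {
    u <- runif(800)
    a <- numeric(length(u) + 1)
    a[1] <- runif(1)
    for (k in seq_along(u))
      a[k + 1] <- a[k] + dt * activation_derivative(u[k], a[k])
    expect_gte(min(a), 0)
    expect_lte(max(a), 1)
  }
})

test_that("Hill curves honor their limit values and shapes", {
  cv <- hill_curves()
  expect_equal(fl_active(1, cv), 1)
  expect_lt(fl_active(0.5, cv), 0.2)
  expect_equal(fl_passive(1, cv), 0)
  expect_equal(fl_passive(1 + cv[["e0"]], cv), 1)
  expect_equal(ft_tendon(0, cv), 0)
  expect_equal(ft_tendon(-0.01, cv), 0)
  expect_equal(ft_tendon(cv[["eps0"]], cv), 1, tolerance = 1e-12)
  st <- seq(0.001, 0.1, by = 0.001)
  expect_true(all(diff(ft_tendon(st, cv)) > 0))   # strictly increasing
  # force-velocity: 1 at rest, 0 at max shortening, eccentric plateau <= 1.5
  expect_equal(fv_curve(0, cv), 1)
  expect_equal(fv_curve(-1, cv), 0)
  expect_lte(fv_curve(100, cv), cv[["fecc"]])
  v <- seq(-1, 1.5, by = 0.01)
  expect_true(all(diff(fv_curve(v, cv)) > 0))     # monotone in velocity
  # Hill hyperbola with a/F0 = 0.25 at half the maximum shortening speed:
  # (1 - 0.5) / (1 + 0.5/0.25) = 1/6
  expect_equal(fv_curve(-0.5, cv), 0.5 / (1 + 0.5 / 0.25))
  # inversion round-trips across both branches
  phis <- seq(0.02, 1.45, by = 0.01)
  expect_equal(fv_curve(fv_inverse(phis, cv), cv), phis, tolerance = 1e-10)
})

test_that("muscle-tendon equilibrium reproduces isometric contracts", {
  cv <- hill_curves()
  # zero pennation: tendon stretched to the strain where f_t = 1 carries
  # exactly fmax and the CE at lopt is stationary at full activation
  p0 <- list(fmax = 1000, lopt = 0.1, pennation = 0, tendon_slack = 0.2,
             vmax = 12)
  lmtu <- p0$lopt + p0$tendon_slack * (1 + cv[["eps0"]])
  out <- mtu_dynamics(p0, cv, activation = 1, ce_length = p0$lopt,
                      mtu_length = lmtu)
  expect_equal(out$see_force, 1000, tolerance = 1e-9)
  expect_equal(out$ce_velocity, 0, tolerance = 1e-12)
  # with pennation: tendon force fmax cos(penn) balances the fiber
  pen <- 0.3
  p1 <- modifyList(p0, list(pennation = pen))
  strain <- cv[["epstoe"]] + (cos(pen) - cv[["Ftoe"]]) / cv[["klin"]]
  lmtu1 <- p1$lopt * cos(pen) + p1$tendon_slack * (1 + strain)
  out1 <- mtu_dynamics(p1, cv, 1, p1$lopt, lmtu1)
  expect_equal(out1$see_force, 1000 * cos(pen), tolerance = 1e-6)
  expect_equal(out1$ce_velocity, 0, tolerance = 1e-9)
  # slack tendon produces no force and maximal shortening
  out2 <- mtu_dynamics(p0, cv, 1, p0$lopt, p0$lopt + 0.5 * p0$tendon_slack)
  expect_equal(out2$see_force, 0)
  expect_lt(out2$ce_velocity, 0)
  expect_error(mtu_dynamics(p0, cv, 1, p0$lopt, 0.01), "implausibly short")
})

test_that("isometric CE dynamics converge to the force balance", {
  cv <- hill_curves()
  p <- list(fmax = 2000, lopt = 0.09, pennation = 0.1, tendon_slack = 0.25,
            vmax = 12)
  lmtu <- p$lopt * cos(p$pennation) + p$tendon_slack * 1.02
  # start away from equilibrium at full activation and integrate
  lce <- 0.8 * p$lopt
  dt <- 2e-4
  for (i in 1:4000) {
    o <- mtu_dynamics(p, cv, 1, lce, lmtu)
    lce <- lce + dt * o$ce_velocity
  }
  o <- mtu_dynamics(p, cv, 1, lce, lmtu)
  # residual between CE and SEE force at the fixed point
  ltil <- lce / p$lopt
  fce <- (1 * fl_active(ltil, cv) * fv_curve(0, cv) + fl_passive(ltil, cv)) *
    p$fmax * cos(p$pennation)
  expect_lt(abs(o$ce_velocity), 1e-6 * p$vmax * p$lopt)
  expect_lt(abs(fce - o$see_force), 1e-4 * p$fmax)
  # equilibrium solver agrees with the integrated fixed point
  expect_equal(equilibrium_ce_length(p, cv, 1, lmtu), lce,
               tolerance = 1e-3)
})

test_that("muscle paths yield correct lengths and moment arms", {
  sk <- ref_skeleton()
  ms <- ref_muscles()
  st <- standing_state(sk)
  geo <- mtu_length_and_moment_arms(ms, sk, st)
  arms <- geo$moment_arms
  # anatomy sign contracts at the neutral posture
  expect_gt(arms["ILIA_R", "hip_R"], 0)      # hip flexor
  expect_lt(arms["GMAXI_R", "hip_R"], 0)     # hip extensor
  expect_lt(arms["HAM_R", "hip_R"], 0)       # biarticular: hip extensor ...
  expect_lt(arms["HAM_R", "knee_R"], 0)      # ... and knee flexor
  expect_gt(arms["VASTI_R", "knee_R"], 0)    # knee extensor
  expect_lt(arms["SOLEU_R", "ankle_R"], 0)   # plantarflexor
  expect_gt(arms["TIBAN_R", "ankle_R"], 0)   # dorsiflexor
  # biarticular muscles span exactly two joints, others one
  spanned <- rowSums(arms != 0)
  expect_equal(unname(spanned[c("HAM_R", "RECTF_R", "GAMS_R")]), c(2, 2, 2))
  expect_equal(unname(spanned[c("ILIA_R", "VASTI_R", "SOLEU_R", "TIBAN_R")]),
               c(1, 1, 1, 1))
  # left side mirrors the right at the symmetric posture
  expect_equal(unname(arms[10:18, 4:6]), unname(arms[1:9, 1:3]))

  # single-joint toy muscle against the closed-form chord geometry:
  # origin on the thigh at radius a above the knee, insertion on the
  # shank at radius b below it
  a <- 0.15; b <- 0.12
  L_of <- function(qk) sqrt(a^2 + b^2 - 2 * a * b * cos(pi - qk))
  arm_of <- function(qk) -(L_of(qk + 1e-6) - L_of(qk - 1e-6)) / 2e-6
  tab <- read_muscle_table()
  tab$path[tab$name == "VASTI"] <-
    sprintf("upper_leg:0:%f;lower_leg:0:%f", -(sk$cpp$Lt - a), -b)
  tab$path_points <- NULL
  tmp <- tempfile(fileext = ".tsv")
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  ms2 <- build_muscle_set(1.74, 72.80, table = read_muscle_table(tmp))
  for (qk in c(-0.9, -0.4, -0.1)) {
    st2 <- skeleton_state(c(0, 1, 0, 0, qk, 0, 0, 0, 0))
    g2 <- mtu_length_and_moment_arms(ms2, sk, st2)
    expect_equal(unname(g2$length[["VASTI_R"]]), L_of(qk), tolerance = 1e-9)
    expect_equal(unname(g2$moment_arms["VASTI_R", "knee_R"]), arm_of(qk),
                 tolerance = 1e-4)
  }

  # a two-point path on a single segment spans no joint: constant length,
  # all moment arms zero
  tab2 <- read_muscle_table()
  tab2$path[tab2$name == "BFES"] <- "upper_leg:0.01:-0.1;upper_leg:0.02:-0.3"
  tab2$path_points <- NULL
  tmp2 <- tempfile(fileext = ".tsv")
  write.table(tab2, tmp2, sep = "\t", row.names = FALSE, quote = FALSE)
  ms3 <- build_muscle_set(1.74, 72.80, table = read_muscle_table(tmp2))
  set.seed(9)
  lens <- vapply(1:5, function(i) {
    st3 <- skeleton_state(c(0, 1, rnorm(7, 0, 0.5)))
    g3 <- mtu_length_and_moment_arms(ms3, sk, st3)
    expect_true(all(g3$moment_arms["BFES_R", ] == 0))
    g3$length[["BFES_R"]]
  }, numeric(1))
  expect_equal(diff(range(lens)), 0, tolerance = 1e-12)
})
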