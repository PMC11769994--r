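#' Assemble a walking model
#'
#' Convenience constructor bundling skeleton, young-adult muscle set,
#' contact parameters, target posture, reference initial condition and the
#' optimizer warm-start profile for a given body size.
#'
#' @param total_height body height, m
#' @param total_mass body mass, kg
#' @param template gait template used for the target posture and the
#'   initial condition
#' @param contact a `contact_params`
#' @param stride_period stride duration, s
#' @return list of model components (class `gait_assembly`)
#' @export
gait_assembly <- function(total_height = 1.74, total_mass = 72.80,
                          template = gait_template("30s"),
                          contact = contact_params(),
                          stride_period = 1.12) {
  skeleton <- build_skeleton(total_height, total_mass)
  muscles <- build_muscle_set(total_height, total_mass)
  structure(list(
    skeleton = skeleton, muscles = muscles, contact = contact,
    template = template,
    target = make_target_posture(template),
    init = default_initial_condition(skeleton, template,
                                     stride_period = stride_period),
    profile0 = if (stride_period == 1.12) reference_profile()
               else nominal_profile(stride_period),
    stride_period = stride_period
  ), class = "gait_assembly")
}

#' Optimize stimulation profiles for walking
#'
#' Runs CMA-ES over the 27-dimensional normalized decision space (onset,
#' offset, amplitude per right-leg muscle; the left leg mirrors with a
#' half-cycle shift) to minimize the posture-tracking + energy objective
#' of a four-step forward simulation. The aging variant is applied to the
#' muscle set before optimization.
#'
#' @param assembly a `gait_assembly`
#' @param variant variant tag or [model_variant()] list
#' @param budget number of objective evaluations (>= one population)
#' @param seed integer seed for the optimizer
#' @param weights objective weights `c(omega1, omega2)`
#' @param duration,dt simulation duration and step, s
#' @param sigma0 initial CMA-ES step size (the default is sized for
#'   refinement around the shipped reference profile; raise it for
#'   from-scratch searches)
#' @param x0 optional start vector (default: encoded warm-start profile)
#' @param verbose print per-generation progress
#' @return list with `profile` (best `stimulation_profile`), `objective`
#'   (its `objective_value`), `trial` (its simulated trial), `history`,
#'   `evaluations`, `variant`, `seed`
#' @export
optimize_gait <- function(assembly, variant = "YA", budget = 2000, seed = 1,
                          weights = c(1, 1), duration = 2.24, dt = 1e-3,
                          sigma0 = 0.06, x0 = NULL, verbose = FALSE) {
  if (is.character(variant)) variant <- model_variant(variant)
  muscles <- apply_aging(assembly$muscles, variant)
  target <- assembly$target
  if (is.null(x0)) x0 <- encode_profile(assembly$profile0)

  audit <- new.env(); audit$rows <- vector("list", 0)
  evalfun <- function(x) {
    prof <- decode_profile(x, stride_period = assembly$stride_period)
    trial <- simulate_walking(assembly$skeleton, muscles, assembly$contact,
                              prof, assembly$init, duration, dt)
    ob <- objective_value(trial, target, weights,
                          shaping_template = assembly$template)
    audit$rows[[length(audit$rows) + 1]] <-
      c(total = ob$total, rms_ang = ob$rms_ang, wbe_meter = ob$wbe_meter,
        penalty = ob$penalty, displacement = ob$displacement)
    ob$total
  }
  cb <- if (verbose) function(g, bf, mf, s)
    message(sprintf("[%s seed %d] gen %3d best %.4f mean %.4f sigma %.3f",
                    variant$tag, seed, g, bf, mf, s)) else NULL
  res <- cma_es(evalfun, x0, sigma0 = sigma0, budget = budget, seed = seed,
                callback = cb)

  best_prof <- decode_profile(res$par, stride_period = assembly$stride_period)
  best_trial <- simulate_walking(assembly$skeleton, muscles, assembly$contact,
                                 best_prof, assembly$init, duration, dt)
  best_obj <- objective_value(best_trial, target, weights)
  if (best_trial$status != "completed")
    warning("no candidate produced a completed walk; returning the best penalized one")
  list(profile = best_prof, objective = best_obj, trial = best_trial,
       history = res$history, evaluations = res$evaluations,
       audit = do.call(rbind, audit$rows),
       variant = variant, seed = seed, muscles = muscles)
}

#' Fit a walking gait for a model variant
#'
#' The package's main entry point: builds the model assembly, applies the
#' aging variant, optimizes the muscle stimulation profile over one or
#' more optimizer seeds, keeps the best solution, and computes the
#' stability outcomes of the resulting four-step walk.
#'
#' @param variant `"YA"`, `"OA"`, `"dT"`, `"dF"` or `"dV"`
#' @param budget objective evaluations per seed
#' @param seeds integer vector of optimizer seeds (best-of is kept)
#' @param assembly optional prebuilt `gait_assembly`
#' @param x0 optional warm-start decision vector
#' @param ... further arguments to [optimize_gait()]
#' @return object of class `gait_fit`
#' @export
fit_gait <- function(variant = "YA", budget = 2000, seeds = 1:3,
                     assembly = NULL, x0 = NULL, ...) {
  if (is.null(assembly)) assembly <- gait_assembly()
  runs <- lapply(seeds, function(s)
    optimize_gait(assembly, variant, budget = budget, seed = s, x0 = x0, ...))
  totals <- vapply(runs, function(r) r$objective$total, numeric(1))
  best <- runs[[which.min(totals)]]
  stab <- tryCatch(margin_of_stability(best$trial), error = function(e) NULL)
  structure(list(
    variant = best$variant, profile = best$profile,
    objective = best$objective, trial = best$trial,
    stability = stab, assembly = assembly,
    seeds = seeds, seed_best = best$seed, budget = budget,
    seed_totals = stats::setNames(totals, seeds),
    history = best$history, audit = best$audit
  ), class = "gait_fit")
}

#' @export
print.gait_fit <- function(x, ...) {
  cat("Optimized walking gait -- variant", x$variant$tag, "\n")
  cat(sprintf("  objective %.4f (tracking %.4f, energy %.4f J/(kg m), penalty %.2f)\n",
              x$objective$total, x$objective$rms_ang, x$objective$wbe_meter,
              x$objective$penalty))
  cat(sprintf("  trial: %s, forward CoM travel %.2f m\n",
              x$trial$status, x$objective$displacement))
  if (!is.null(x$stability))
    print(x$stability)
  cat(sprintf("  best of seeds {%s}: seed %d, %d evaluations/seed\n",
              paste(x$seeds, collapse = ", "), x$seed_best, x$budget))
  invisible(x)
}

#' @export
summary.gait_fit <- function(object, ...) {
  x <- object
  wv <- walking_velocity(x$trial)
  out <- list(
    variant = x$variant$tag,
    objective = unclass(x$objective),
    mos = if (!is.null(x$stability)) x$stability$mos else NA_real_,
    step_length = if (!is.null(x$stability)) x$stability$step_length else NA_real_,
    vcom = if (!is.null(x$stability)) x$stability$vcom_at_toe_off else NA_real_,
    walking_velocity = wv,
    status = x$trial$status,
    seed_totals = x$seed_totals
  )
  class(out) <- "summary.gait_fit"
  out
}

#' @export
print.summary.gait_fit <- function(x, ...) {
  cat("Gait fit summary --", x$variant, "\n")
  cat(sprintf("  MoS %.3f m | step length %.3f m | VCoM %.3f m/s | walking velocity %.3f m/s\n",
              x$mos, x$step_length, x$vcom, x$walking_velocity))
  cat(sprintf("  objective %.4f (tracking %.4f + energy %.4f + penalty %.2f), %s\n",
              x$objective$total, x$objective$rms_ang, x$objective$wbe_meter,
              x$objective$penalty, x$status))
  invisible(x)
}

#' @export
coef.gait_fit <- function(object, ...) {
  p <- object$profile
  stats::setNames(c(p$onset, p$offset, p$amplitude),
                  c(paste0("onset.", MUSCLE_NAMES),
                    paste0("offset.", MUSCLE_NAMES),
                    paste0("amplitude.", MUSCLE_NAMES)))
}

#' Re-simulate a fitted gait
#'
#' Runs the forward simulation of the fitted profile again (optionally at
#' a different duration or step size) and returns the trial.
#' @param object a `gait_fit`
#' @param nsim unused (one deterministic trial)
#' @param seed unused (the simulation is deterministic)
#' @param duration,dt simulation settings
#' @param ... ignored
#' @export
simulate.gait_fit <- function(object, nsim = 1, seed = NULL,
                              duration = 2.24, dt = 1e-3, ...) {
  a <- object$assembly
  muscles <- apply_aging(a$muscles, object$variant)
  simulate_walking(a$skeleton, muscles, a$contact, object$profile, a$init,
                   duration, dt)
}

#' Residual joint-angle curves of a fitted gait
#'
#' Difference (degrees, 101 gait-cycle points) between the fitted model's
#' hip/knee/ankle curves and the reference group-mean curves (30s group
#' for YA, 70s for the other variants unless given).
#' @param object a `gait_fit`
#' @param ref optional `reference_gait_curves`
#' @param ... ignored
#' @export
residuals.gait_fit <- function(object, ref = NULL, ...) {
  if (is.null(ref)) {
    grp <- if (object$variant$tag == "YA") "30s" else "70s"
    ref <- make_reference_curves(grp, seed = 1)
  }
  sim <- trial_gait_cycle_curves(object$trial)
  res <- sim
  for (j in c("hip", "knee", "ankle")) res[, j] <- sim[, j] - ref[[j]]$mean
  res
}

#' Plot a fitted gait
#'
#' Stick-figure snapshots of the walk and the hip/knee/ankle joint-angle
#' curves over one gait cycle.
#' @param x a `gait_fit` or `gait_trial`
#' @param ... ignored
#' @export
plot.gait_fit <- function(x, ...) plot(x$trial, ...)

#' @export
plot.gait_trial <- function(x, n_snapshots = 8, ...) {
  if (x$kind != "simulated") stop("can only plot simulated trials")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  idx <- round(seq(1, length(x$time), length.out = n_snapshots))
  lms <- c("head", "hip", "kneeR", "ankleR", "heelR", "toeR")
  graphics::plot(NULL, xlim = range(x$q[, "x"]) + c(-0.6, 0.6),
                 ylim = c(-0.05, 1.85), asp = 1,
                 xlab = "x [m]", ylab = "y [m]")
  graphics::abline(h = 0, col = "grey")
  for (i in idx) {
    k <- cpp_kinematics(x$skeleton$cpp, x$q[i, ], x$qdot[i, ])
    p <- k$points
    seg <- function(a, b, col) graphics::lines(p[1, c(a, b)], p[2, c(a, b)], col = col)
    seg("head", "hip", "black")
    seg("hip", "kneeR", "firebrick"); seg("kneeR", "ankleR", "firebrick")
    seg("heelR", "toeR", "firebrick"); seg("ankleR", "heelR", "firebrick")
    seg("hip", "kneeL", "steelblue"); seg("kneeL", "ankleL", "steelblue")
    seg("heelL", "toeL", "steelblue"); seg("ankleL", "heelL", "steelblue")
  }
  crv <- tryCatch(trial_gait_cycle_curves(x), error = function(e) NULL)
  if (!is.null(crv)) {
    graphics::matplot(seq(0, 100), crv, type = "l", lty = 1,
                      col = c("black", "firebrick", "steelblue"),
                      xlab = "gait cycle [%]", ylab = "angle [deg]")
    graphics::legend("topleft", c("hip", "knee", "ankle"), lty = 1,
                     col = c("black", "firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}

#' Average forward walking velocity
#'
#' Mean anteroposterior CoM velocity over the second and third steps (or
#' the whole trial when the events do not delimit them).
#' @param trial a simulated `gait_trial`
#' @return velocity, m/s
#' @export
walking_velocity <- function(trial) {
  lm <- trial_landmarks(trial)
  ev <- trial$events
  sb <- attr(ev, "step_bounds")
  hs <- if (!is.null(sb)) sb$time else ev$time[ev$type == "heel_strike"]
  t0 <- if (length(hs) >= 2) hs[2] else trial$time[1]
  t1 <- if (length(hs) >= 4) hs[4] else max(trial$time)
  sel <- trial$time >= t0 & trial$time <= t1
  if (sum(sel) < 2) sel <- rep(TRUE, length(trial$time))
  mean(lm$vcom[sel, 1])
}

#' Run the five-variant experiment
#'
#' For each requested variant and seed: apply the aging transform,
#' optimize the stimulation profile, simulate the best candidate and
#' compute the stability outcomes; returns one summary row per variant
#' (best seed by objective).
#'
#' @param variants character vector of variant tags
#' @param budget objective evaluations per seed
#' @param seeds optimizer seeds per variant
#' @param assembly optional prebuilt `gait_assembly`
#' @param out_dir optional directory for per-run trial CSVs and profiles
#' @param verbose print progress
#' @param ... further arguments to [optimize_gait()]
#' @return data.frame with columns variant, mos, step_length, vcom,
#'   walking_velocity, rms_ang, wbe_meter, objective, status, seed
#' @export
run_experiment <- function(variants = c("YA", "OA", "dT", "dF", "dV"),
                           budget = 2000, seeds = 1:3, assembly = NULL,
                           out_dir = NULL, verbose = FALSE, ...) {
  if (is.null(assembly)) assembly <- gait_assembly()
  rows <- lapply(variants, function(v) {
    fit <- fit_gait(v, budget = budget, seeds = seeds, assembly = assembly,
                    verbose = verbose, ...)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_trial_csv(fit$trial, file.path(out_dir, paste0("trial_", v, ".csv")))
      write_profile_json(fit$profile, file.path(out_dir, paste0("profile_", v, ".json")))
    }
    s <- summary(fit)
    data.frame(variant = v, mos = s$mos, step_length = s$step_length,
               vcom = s$vcom, walking_velocity = s$walking_velocity,
               rms_ang = fit$objective$rms_ang,
               wbe_meter = fit$objective$wbe_meter,
               objective = fit$objective$total,
               status = fit$trial$status, seed = fit$seed_best)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  out
}
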