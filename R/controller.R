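#' Muscle stimulation profile
#'
#' Open-loop square-pulse stimulation: each of the nine right-leg muscles
#' has one burst per stride described by onset time, offset time and
#' amplitude; outside the burst the stimulation sits at a small baseline
#' floor (avoids zero-activation singularities in the contraction
#' dynamics). When `offset < onset` the burst wraps across the cycle
#' boundary. Left-leg muscles replay the right-leg profile delayed by half
#' a stride. The stride period is fixed at 1.12 s (two 0.56 s steps) and is
#' not a decision variable.
#'
#' @param onset,offset numeric length 9, s within the stride cycle, in
#'   `[0, stride_period)`
#' @param amplitude numeric length 9 in `[baseline, 1]`
#' @param stride_period stride duration, s
#' @param baseline stimulation floor outside the burst
#' @return object of class `stimulation_profile`
#' @export
stimulation_profile <- function(onset, offset, amplitude,
                                stride_period = 1.12, baseline = 0.01) {
  onset <- as.numeric(onset); offset <- as.numeric(offset)
  amplitude <- as.numeric(amplitude)
  if (length(onset) != 9 || length(offset) != 9 || length(amplitude) != 9)
    stop("onset, offset and amplitude must each have length 9")
  if (any(onset < 0 | onset >= stride_period) ||
      any(offset < 0 | offset >= stride_period))
    stop("onset/offset times must lie in [0, stride_period)")
  if (any(amplitude < baseline - 1e-12 | amplitude > 1))
    stop("amplitudes must lie in [baseline, 1]")
  structure(list(onset = stats::setNames(onset, MUSCLE_NAMES),
                 offset = stats::setNames(offset, MUSCLE_NAMES),
                 amplitude = stats::setNames(amplitude, MUSCLE_NAMES),
                 stride_period = stride_period, baseline = baseline),
            class = "stimulation_profile")
}

#' @export
print.stimulation_profile <- function(x, ...) {
  cat("Stimulation profile (stride", x$stride_period, "s, baseline",
      x$baseline, "):\n")
  print(data.frame(muscle = MUSCLE_NAMES, onset = round(x$onset, 3),
                   offset = round(x$offset, 3),
                   amplitude = round(x$amplitude, 3), row.names = NULL))
  cat("(left leg = right delayed by half a stride)\n")
  invisible(x)
}

#' Encode a profile as a 27-vector in the unit cube
#'
#' Bijective map used by the optimizer: onsets and offsets normalized by
#' the stride period, amplitudes mapped linearly from
#' `[baseline, 1]` to `[0, 1]`. Order: onset(9), offset(9), amplitude(9).
#'
#' @param profile a `stimulation_profile`
#' @return numeric vector of length 27 in `[0, 1]`
#' @export
encode_profile <- function(profile) {
  T <- profile$stride_period; b <- profile$baseline
  unname(c(profile$onset / T, profile$offset / T,
           (profile$amplitude - b) / (1 - b)))
}

#' Decode a 27-vector into a stimulation profile
#'
#' Inverse of [encode_profile()]; components are clamped to `[0, 1]` first.
#'
#' @param x numeric vector of length 27
#' @param stride_period stride duration, s
#' @param baseline stimulation floor
#' @return a `stimulation_profile`
#' @export
decode_profile <- function(x, stride_period = 1.12, baseline = 0.01) {
  if (length(x) != 27) stop("decision vector must have length 27")
  x <- pmin(pmax(as.numeric(x), 0), 1)
  onfrac <- pmin(x[1:9], 1 - 1e-9)
  offrac <- pmin(x[10:18], 1 - 1e-9)
  stimulation_profile(onset = onfrac * stride_period,
                      offset = offrac * stride_period,
                      amplitude = baseline + x[19:27] * (1 - baseline),
                      stride_period = stride_period, baseline = baseline)
}

#' Stimulation value of one muscle at one time
#'
#' Right-leg muscles return the burst amplitude when `t mod stride` falls
#' in the onset-to-offset window (wrapping across the cycle boundary when
#' `offset < onset`) and the baseline otherwise; left-leg muscles evaluate
#' the right-leg profile at `t - stride_period / 2`.
#'
#' @param profile a `stimulation_profile`
#' @param muscle label such as `"SOLEU_R"` or `"SOLEU_L"` (a bare name
#'   means the right side)
#' @param t time in s (vectorized)
#' @return stimulation in `[0, 1]`
#' @export
stimulation_at <- function(profile, muscle, t) {
  side <- ifelse(grepl("_L$", muscle), "L", "R")
  name <- sub("_[RL]$", "", muscle)
  if (!name %in% MUSCLE_NAMES)
    stop("unknown muscle '", muscle, "'")
  T <- profile$stride_period
  tt <- if (side == "L") t - T / 2 else t
  tt <- tt %% T
  on <- profile$onset[[name]]; off <- profile$offset[[name]]
  inside <- if (on <= off) tt >= on & tt < off else tt >= on | tt < off
  ifelse(inside, profile$amplitude[[name]], profile$baseline)
}

#' Hand-tuned nominal walking profile
#'
#' A physiologically timed starting profile (stride beginning at right
#' heel strike): hip/knee extensors around heel strike, plantarflexors
#' through mid and late stance, hip flexors and dorsiflexors in swing.
#' Used as the optimizer's warm start; the amplitudes and timings are
#' nominal, not fitted to data.
#'
#' @param stride_period stride duration, s
#' @return a `stimulation_profile`
#' @export
nominal_profile <- function(stride_period = 1.12) {
  fr <- function(x) x * stride_period
  #          ILIA GMAXI  HAM RECTF VASTI BFES GAMS SOLEU TIBAN
  onset  <- fr(c(0.58, 0.90, 0.80, 0.58, 0.92, 0.58, 0.30, 0.20, 0.55))
  offset <- fr(c(0.80, 0.25, 0.15, 0.72, 0.20, 0.75, 0.60, 0.60, 0.15))
  amp    <-    c(0.50, 0.50, 0.40, 0.20, 0.35, 0.40, 0.70, 0.80, 0.35)
  stimulation_profile(onset, offset, amp, stride_period = stride_period)
}

# full 18-muscle stimulation matrix on a time grid (rows = times)
stimulation_matrix <- function(profile, t) {
  labs <- c(paste0(MUSCLE_NAMES, "_R"), paste0(MUSCLE_NAMES, "_L"))
  vapply(labs, function(m) stimulation_at(profile, m, t), numeric(length(t)))
}

# profile in the flat list form consumed by the C++ integrator
profile_cpp_spec <- function(profile) {
  list(onset = unname(profile$onset), offset = unname(profile$offset),
       amplitude = unname(profile$amplitude),
       stride_period = profile$stride_period, baseline = profile$baseline)
}

#' Write / read a stimulation profile as JSON
#'
#' Flat text serialization (27 named scalars plus stride period and
#' baseline), written alongside every optimization result.
#' @param profile a `stimulation_profile`
#' @param path file path
#' @return `read_profile_json` returns a `stimulation_profile`
#' @export
write_profile_json <- function(profile, path) {
  obj <- list(stride_period = profile$stride_period,
              baseline = profile$baseline,
              onset = as.list(profile$onset),
              offset = as.list(profile$offset),
              amplitude = as.list(profile$amplitude))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulation_profile(obj$onset[MUSCLE_NAMES], obj$offset[MUSCLE_NAMES],
                      obj$amplitude[MUSCLE_NAMES],
                      stride_period = obj$stride_period,
                      baseline = obj$baseline)
}

#' Packaged reference walking profile
#'
#' A young-adult stimulation profile optimized with this package's own
#' pipeline (staged CMA-ES from the hand-tuned [nominal_profile()]),
#' shipped as a plain-text fixture. It serves as the default warm start
#' for variant fits and the packaged experiment, which keeps desk-scale
#' budgets productive; it is a starting point, not a ground truth.
#'
#' @return a `stimulation_profile`
#' @export
reference_profile <- function() {
  path <- system.file("extdata", "walking_profile_ya.json",
                      package = "plangait")
  if (!nzchar(path)) return(nominal_profile())
  read_profile_json(path)
}
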