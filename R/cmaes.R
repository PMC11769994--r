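#' Covariance matrix adaptation evolution strategy
#'
#' Minimal standard CMA-ES minimizer (rank-mu update, cumulative step-size
#' adaptation) with box constraints handled by clamping candidates to
#' `[lower, upper]` before evaluation. Deterministic for a fixed seed. Used
#' for the 27-dimensional stimulation-profile search; also usable on plain
#' test functions.
#'
#' @param fn objective function mapping a numeric vector to a scalar
#' @param x0 initial mean
#' @param sigma0 initial step size
#' @param budget maximum number of function evaluations
#' @param seed integer seed (an independent RNG stream; the global RNG
#'   state is untouched)
#' @param lower,upper box bounds (scalars or vectors)
#' @param lambda population size (default `4 + floor(3 log n)`)
#' @param callback optional function called once per generation with
#'   `(generation, best_f, mean_f, sigma)`
#' @return list with `par`, `value`, `history` (best-so-far per
#'   generation), `evaluations`
#' @export
cma_es <- function(fn, x0, sigma0 = 0.15, budget = 2000, seed = 1,
                   lower = 0, upper = 1, lambda = NULL, callback = NULL) {
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  xmean <- pmin(pmax(as.numeric(x0), lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  eigen_stale <- 0

  rng <- local_rng(seed)
  best_x <- xmean; best_f <- Inf
  hist <- numeric(0)
  evals <- 0; gen <- 0

  while (evals + lambda <= budget) {
    gen <- gen + 1
    Z <- matrix(rng$rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    Xc <- pmin(pmax(X, lower), upper)
    f <- apply(Xc, 2, fn)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- Xc[, ord[1]] }
    hist <- c(hist, best_f)
    if (!is.null(callback)) callback(gen, best_f, mean(f), sigma)

    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ybar <- as.numeric(ysel %*% w)
    xmean <- xmean + sigma * ybar
    zsel <- Z[, ord[seq_len(mu)], drop = FALSE]
    zbar <- as.numeric(zsel %*% w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(B %*% zbar)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (ysel %*% (w * t(ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1)   # bounded search cube; keep steps sane

    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / (10 * n * (c1 + cmu))))) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
    }
  }
  list(par = best_x, value = best_f, history = hist, evaluations = evals)
}
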