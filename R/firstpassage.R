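#' Kinetic parameters for the drift-diffusion insertion model
#'
#' Parameters of the one-dimensional drift-diffusion process that stands in
#' for the approach of a solute toward the membrane surface: constant drift
#' `v` toward the bilayer and diffusion coefficient `D`, started a distance
#' `d` above the absorbing surface (the proximal phosphate plane). With
#' `start_above_center = 29` and the default POPC plane at 18.5 A, the travel
#' distance is d = 10.5 A.
#'
#' @param v Drift speed toward the bilayer, A/ns (>= 0).
#' @param D Diffusion coefficient, A^2/ns (>= 0). `v` and `D` cannot both be
#'   zero.
#' @param d Start height above the absorbing surface, A (> 0). Exactly one of
#'   `d` or `start_above_center` is used; when `start_above_center` is given,
#'   `d` is derived from a bilayer model at trajectory-generation time.
#' @param start_above_center Start height above the bilayer center, A
#'   (default 29).
#' @param n_replicates Number of independent repeats (default 12).
#' @param max_time Length of each repeat in ns (default 100); first-passage
#'   draws beyond it are censored.
#' @param frame_interval Frame spacing in ns (default 0.1); must divide
#'   `max_time`.
#' @param seed Optional base seed; replicate r uses `seed + r`.
#'
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(v, D, d = NULL, start_above_center = 29,
                           n_replicates = 12, max_time = 100,
                           frame_interval = 0.1, seed = NULL) {
  stopifnot(
    "`v` must be a single number >= 0" = is.numeric(v) && length(v) == 1 && v >= 0,
    "`D` must be a single number >= 0" = is.numeric(D) && length(D) == 1 && D >= 0,
    "`v` and `D` cannot both be zero" = v > 0 || D > 0,
    "`max_time` must be > 0" = is.numeric(max_time) && max_time > 0,
    "`frame_interval` must be > 0" = is.numeric(frame_interval) && frame_interval > 0,
    "`n_replicates` must be >= 1" = n_replicates >= 1
  )
  if (!is.null(d)) {
    stopifnot("`d` must be > 0" = is.numeric(d) && length(d) == 1 && d > 0)
  }
  n_frames <- max_time / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("`frame_interval` must divide `max_time`")
  }
  structure(
    list(
      v = v, D = D, d = d, start_above_center = start_above_center,
      n_replicates = n_replicates, max_time = max_time,
      frame_interval = frame_interval, seed = seed
    ),
    class = "kinetic_params"
  )
}

# Inverse-Gaussian sampler (Michael, Schucany & Haas 1976 transform).
# mean mu > 0, shape lambda > 0.
rinvgauss_fp <- function(n, mu, lambda) {
  nu <- rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Sample first-passage insertion times
#'
#' Draws replicate first-passage times W of a drift-diffusion process over
#' distance `d`: for `v > 0` and `D > 0` these follow the inverse-Gaussian
#' law with mean d/v and shape d^2/(2D); the limit `D = 0` is the
#' deterministic drift time d/v, and `v = 0` is the drift-free (Levy)
#' first-passage law. Draws exceeding `max_time` are censored at `max_time`.
#'
#' @param params A [kinetic_params()] object; `d` must be set (directly or
#'   pass `d` here).
#' @param d Travel distance in A, overriding `params$d`.
#' @param seed Seed overriding `params$seed`.
#' @return A tibble with columns `replicate`, `W` (ns), `censored` (logical).
#' @examples
#' p <- kinetic_params(v = 2, D = 0, d = 20, n_replicates = 3)
#' sample_first_passage_times(p)$W  # all exactly 10 ns
#' @export
sample_first_passage_times <- function(params, d = NULL, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  d <- d %||% params$d
  if (is.null(d)) abort("travel distance `d` is not set")
  stopifnot("`d` must be > 0" = d > 0)
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)

  n <- params$n_replicates
  v <- params$v
  D <- params$D
  if (D == 0) {
    w <- rep(d / v, n)
  } else if (v == 0) {
    # drift-free Brownian first passage: W = c / Z^2, c = d^2 / (2D)
    w <- (d^2 / (2 * D)) / rnorm(n)^2
  } else {
    w <- rinvgauss_fp(n, mu = d / v, lambda = d^2 / (2 * D))
  }
  censored <- w > params$max_time
  if (v == 0 && any(censored)) {
    warn("zero drift: some first-passage draws are censored at `max_time`")
  }
  tibble(
    replicate = seq_len(n),
    W = ifelse(censored, params$max_time, w),
    censored = censored
  )
}
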