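#' Diel vertical migration configuration
#'
#' Migrating krill swim between a shallow night-time target depth and a
#' deeper daytime target depth at a fixed vertical speed.  The default
#' swim speed, 0.014 m s^-1, is the product of a 43 mm body length and an
#' observed late-spring vertical swimming rate of 0.335 body lengths per
#' second (see [swim_speed_from_body_length()]).
#'
#' @param max_depth daytime target depth in m; the simulated behaviours
#'   use one of 25, 50, 75, 100 or 150 m.
#' @param min_depth night-time target depth in m (default 10).
#' @param swim_speed vertical swim speed in m s^-1 (default 0.014).
#' @param enabled `FALSE` gives a passive (non-migrating) run.
#' @return an object of class `kf_dvm_config`.
#' @export
dvm_config <- function(max_depth, min_depth = 10, swim_speed = 0.014,
                       enabled = TRUE) {
  stopifnot(is.numeric(max_depth), length(max_depth) == 1L,
            min_depth < max_depth, swim_speed >= 0)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 swim_speed = swim_speed, enabled = isTRUE(enabled)),
            class = "kf_dvm_config")
}

#' @rdname dvm_config
#' @param release_depth fixed release depth in m for a passive run.
#' @export
passive_config <- function(release_depth) {
  cfg <- dvm_config(max_depth = release_depth + 1, enabled = FALSE)
  cfg$release_depth <- release_depth
  cfg
}

#' Vertical random-walk (turbulence) configuration
#'
#' Parameterizes unresolved vertical turbulence as a random walk with
#' (possibly depth-dependent) diffusivity `K(z)`.  The default profile is
#' a summer stratified-shelf shape: mixed-layer diffusivity 1e-3 m^2 s^-1
#' above 20 m tapering linearly to 1e-5 m^2 s^-1 below 50 m (quiet
#' interior under the pycnocline).
#'
#' Two schemes are available: `"naive"` takes a plain diffusive step
#' \eqn{R\sqrt{2 K(z) \Delta t}}; `"gradient_corrected"` (default) adds
#' the deterministic drift \eqn{K'(z)\Delta t} and evaluates the
#' diffusivity at the offset depth \eqn{z + K'(z)\Delta t/2}, the standard
#' correction that keeps an initially well-mixed particle distribution
#' well mixed under spatially varying `K`.
#'
#' @param depths,K numeric vectors defining a piecewise-linear `K(z)`
#'   profile (constant extrapolation beyond the ends); a single `K` value
#'   gives a constant profile.
#' @param dt time step in s (default 50, the advection step).
#' @param scheme `"gradient_corrected"` or `"naive"`.
#' @return an object of class `kf_rw_config`.
#' @export
rw_config <- function(depths = c(0, 20, 50, 400),
                      K = c(1e-3, 1e-3, 1e-5, 1e-5),
                      dt = 50, scheme = c("gradient_corrected", "naive")) {
  scheme <- match.arg(scheme)
  if (length(K) == 1L) {
    depths <- c(0, 1000)
    K <- rep(K, 2L)
  }
  stopifnot(length(depths) == length(K), !is.unsorted(depths),
            dt > 0)
  if (any(K < 0)) stop("diffusivity K must be non-negative", call. = FALSE)
  structure(list(depths = as.numeric(depths), K = as.numeric(K),
                 dt = dt, scheme = scheme),
            class = "kf_rw_config")
}

#' @rdname rw_config
#' @export
rw_off <- function(dt = 50) rw_config(K = 0, dt = dt)

# piecewise-linear K(z), constant extrapolation
eval_K <- function(config, depth) {
  stats::approx(config$depths, config$K, xout = depth, rule = 2)$y
}

# numerical dK/dz (central difference, 0.1 m) - matches the C++ kernel
eval_dK <- function(config, depth) {
  (eval_K(config, depth + 0.1) - eval_K(config, depth - 0.1)) / 0.2
}

#' Vertical swim speed from body length
#'
#' Converts an observed swimming rate in body lengths per second to
#' m s^-1, rounded to 3 decimal places (the precision at which such
#' speeds are conventionally reported).  43 mm krill swimming at
#' 0.335 BL s^-1 gives the default migration speed of 0.014 m s^-1.
#'
#' @param body_length_mm krill body length in mm.
#' @param rate_bl_s swimming rate in body lengths per second.
#' @return speed in m s^-1.
#' @examples
#' swim_speed_from_body_length(43, 0.335) # 0.014
#' @export
swim_speed_from_body_length <- function(body_length_mm, rate_bl_s) {
  if (any(body_length_mm <= 0) || any(rate_bl_s <= 0))
    stop("body length and swimming rate must be positive", call. = FALSE)
  round(body_length_mm / 1000 * rate_bl_s, 3)
}

#' Behavioural vertical velocity of a migrating krill
#'
#' While the sun is up, krill above the daytime target depth swim down;
#' while the sun is down, krill below the night-time target depth (10 m)
#' swim up; otherwise no behavioural velocity is added.  Positive values
#' are downward.
#'
#' @param depth current depth(s) in m, positive down (vectorized).
#' @param sun_up logical: is the sun above the horizon?
#' @param config a [dvm_config()].
#' @return vertical velocity in m s^-1, positive down.
#' @export
dvm_swim_velocity <- function(depth, sun_up, config) {
  stopifnot(inherits(config, "kf_dvm_config"))
  if (!config$enabled) return(rep(0, length(depth)))
  ifelse(rep(isTRUE(sun_up), length(depth)),
         ifelse(depth < config$max_depth, config$swim_speed, 0),
         ifelse(depth > config$min_depth, -config$swim_speed, 0))
}

#' One vertical random-walk displacement
#'
#' Draws the turbulent vertical displacement for one time step from the
#' configured scheme (see [rw_config()]).  Uses R's random number stream.
#'
#' @param depth current depth(s) in m (vectorized).
#' @param config a [rw_config()].
#' @return displacement(s) in m, positive down.
#' @export
vertical_random_walk_step <- function(depth, config) {
  stopifnot(inherits(config, "kf_rw_config"))
  n <- length(depth)
  R <- stats::rnorm(n)
  dt <- config$dt
  if (config$scheme == "naive")
    return(R * sqrt(2 * eval_K(config, depth) * dt))
  dK <- eval_dK(config, depth)
  K_off <- eval_K(config, depth + 0.5 * dK * dt)
  dK * dt + R * sqrt(2 * K_off * dt)
}
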