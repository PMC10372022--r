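#' Interpolate the velocity field at a point
#'
#' Trilinear interpolation in `(x, y, depth)` and linear interpolation in
#' time.  Land nodes carry zero velocity, so coastal interpolation decays
#' smoothly to zero toward the mask.  Depth queries outside the z-level
#' range use constant extrapolation; horizontal or temporal queries
#' outside the field raise an out-of-bounds condition (class
#' `kf_out_of_bounds`) so callers can mark particles as exited.
#'
#' @param field a `kf_field`.
#' @param x,y position in km.
#' @param depth depth in m.
#' @param time_hours time in hours since season start.
#' @return named numeric `(u, v, w)` in m s^-1.
#' @export
interpolate_velocity <- function(field, x, y, depth, time_hours) {
  stopifnot(inherits(field, "kf_field"))
  g <- field$grid
  if (x < min(g$x) || x > max(g$x) || y < min(g$y) || y > max(g$y) ||
      time_hours < min(field$time_hours) ||
      time_hours > max(field$time_hours)) {
    cond <- structure(
      class = c("kf_out_of_bounds", "error", "condition"),
      list(message = "query outside the field's spatial/temporal span",
           call = sys.call()))
    stop(cond)
  }
  out <- kf_interp(field$u, field$v,
                   if (is.null(field$w)) NULL else field$w,
                   g$x, g$y, g$depth, field$time_hours,
                   x, y, depth, time_hours)
  c(u = out[1, 1], v = out[1, 2], w = out[1, 3])
}

# shared argument marshalling for the compiled kernel
kernel_args <- function(field) {
  g <- field$grid
  list(u = field$u, v = field$v,
       w = if (is.null(field$w)) NULL else field$w,
       xax = g$x, yax = g$y, zax = g$depth, tax = field$time_hours,
       land = g$land_mask, seabed = g$seabed_m,
       ref_lon = g$ref_lon, ref_lat = g$ref_lat,
       start_doy = as.POSIXlt(field$season_start)$yday + 1L)
}

#' Advance particles one advection step
#'
#' One 50 s (by default) step of the same compiled kernel the full
#' simulation uses: 4th-order Runge-Kutta on the horizontal velocities,
#' an explicitly supplied behavioural vertical velocity and random-walk
#' displacement, reflective depth clamping to `[0.5, seabed - 0.5]` m,
#' beaching on land contact (particle freezes at its last water
#' position) and exit detection at the domain boundary.
#'
#' @param state list with numeric vectors `x`, `y` (km), `depth` (m) and
#'   integer `status` (0 active, 1 beached, 2 exited).
#' @param field a `kf_field`.
#' @param behavior_w behavioural vertical velocity, m s^-1 positive down
#'   (scalar or per particle).
#' @param random_w random-walk displacement for this step, m (scalar or
#'   per particle).
#' @param dt step length in s (default 50).
#' @param t_hours time of the step start, hours since season start.
#' @return updated state list.
#' @export
advect_step <- function(state, field, behavior_w = 0, random_w = 0,
                        dt = 50, t_hours = 0) {
  np <- length(state$x)
  if (is.null(state$status)) state$status <- integer(np)
  ka <- kernel_args(field)
  res <- kf_advance(ka$u, ka$v, ka$w, ka$xax, ka$yax, ka$zax, ka$tax,
                    ka$land, ka$seabed,
                    state$x, state$y, state$depth,
                    as.integer(state$status),
                    t_hours, dt, 1L, 1L,
                    FALSE, 0, 0, 0,
                    FALSE, c(0, 1), c(0, 0), TRUE,
                    TRUE, rep_len(as.numeric(behavior_w), np),
                    rep_len(as.numeric(random_w), np),
                    ka$ref_lon, ka$ref_lat, ka$start_doy)
  list(x = res$x[, 2], y = res$y[, 2], depth = res$depth[, 2],
       status = res$status[, 2])
}

#' Run a full particle-tracking simulation
#'
#' Integrates every release cohort from its release date to `end_date`
#' (default: 31 March, the season end, which guarantees at least 30
#' tracked days even for the final mid-February release) at a fixed
#' advection step, storing positions every hour.  Migrating cohorts swim
#' down while the sun is above the horizon and up while it is below
#' (see [dvm_config()]); all cohorts receive the vertical random walk.
#'
#' @param field a `kf_field`.
#' @param plan a [release_plan()].
#' @param behavior a [dvm_config()] or [passive_config()].
#' @param rw a [rw_config()] (use [rw_off()] to disable turbulence).
#' @param end_date end of tracking (`Date` or string); default 31 March
#'   following the season start.
#' @param seed integer seed making the run reproducible; draws are
#'   consumed in fixed particle order, one cohort at a time.
#' @param dt advection step in s (default 50; must divide 3600).
#' @return an object of class `kf_trajectories`: matrices `x`, `y`,
#'   `depth` and integer `status` of dimension (particle, hour), the
#'   global hourly time axis `hours`, per-particle release metadata and
#'   the behaviour tag.
#' @export
run_simulation <- function(field, plan, behavior, rw = rw_config(),
                           end_date = NULL, seed = NULL, dt = 50) {
  stopifnot(inherits(field, "kf_field"),
            inherits(plan, "kf_release_plan"),
            inherits(behavior, "kf_dvm_config"),
            inherits(rw, "kf_rw_config"))
  if (3600 %% dt != 0)
    stop("`dt` must divide 3600 s (hourly archiving)", call. = FALSE)
  start <- field$season_start
  if (is.null(end_date)) {
    yr <- as.integer(format(start, "%Y")) + 1L
    end_date <- as.Date(sprintf("%d-03-31", yr))
  }
  end_date <- as.Date(end_date)
  if (any(plan$dates < start))
    stop("release dates precede the field's season start", call. = FALSE)
  span_days <- max(field$time_hours) / 24
  if (as.numeric(max(plan$dates) - start) > span_days + 1)
    stop("release dates extend beyond the field's time span", call. = FALSE)
  if (end_date < max(plan$dates))
    stop("`end_date` precedes the last release", call. = FALSE)
  if (as.numeric(end_date - max(plan$dates)) < 30)
    warning("less than 30 tracked days for the final release cohort",
            call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  depth0 <- plan$depth
  if (is.null(depth0))
    depth0 <- if (behavior$enabled) behavior$min_depth
              else behavior$release_depth
  if (is.null(depth0))
    stop("release depth not given by plan or behaviour", call. = FALSE)
  seeds <- seed_particles(field$grid, plan$spacing_km, depth0,
                          plan$exclusion_mask, plan$box)
  n_per_event <- nrow(seeds)
  n_events <- length(plan$dates)
  end_hour <- as.numeric(end_date - start) * 24
  hours <- 0:end_hour
  np <- n_per_event * n_events
  X <- matrix(NA_real_, np, length(hours))
  Y <- matrix(NA_real_, np, length(hours))
  Zm <- matrix(NA_real_, np, length(hours))
  S <- matrix(NA_integer_, np, length(hours))
  ka <- kernel_args(field)
  save_every <- as.integer(3600 / dt)
  steps_per_hour <- save_every
  tag <- if (behavior$enabled) paste0("dvm_", behavior$max_depth)
         else paste0("passive_", behavior$release_depth)
  release_event <- rep(seq_len(n_events), each = n_per_event)
  release_hour <- rep(as.numeric(plan$dates - start) * 24,
                      each = n_per_event)
  for (ev in seq_len(n_events)) {
    h0 <- as.numeric(plan$dates[ev] - start) * 24
    n_hours_ev <- end_hour - h0
    if (n_hours_ev < 1) next
    res <- kf_advance(ka$u, ka$v, ka$w, ka$xax, ka$yax, ka$zax, ka$tax,
                      ka$land, ka$seabed,
                      seeds$x, seeds$y, seeds$depth,
                      integer(n_per_event),
                      h0, dt, as.integer(n_hours_ev * steps_per_hour),
                      save_every,
                      behavior$enabled, behavior$min_depth,
                      behavior$max_depth, behavior$swim_speed,
                      any(rw$K > 0), rw$depths, rw$K,
                      rw$scheme == "gradient_corrected",
                      FALSE, numeric(n_per_event), numeric(n_per_event),
                      ka$ref_lon, ka$ref_lat, ka$start_doy)
    rows <- (ev - 1L) * n_per_event + seq_len(n_per_event)
    cols <- (h0 + 1L):(end_hour + 1L)
    X[rows, cols] <- res$x
    Y[rows, cols] <- res$y
    Zm[rows, cols] <- res$depth
    S[rows, cols] <- res$status
  }
  structure(list(
    x = X, y = Y, depth = Zm, status = S, hours = hours,
    release_event = release_event, release_hour = release_hour,
    release_x = rep(seeds$x, n_events), release_y = rep(seeds$y, n_events),
    release_depth = rep(seeds$depth, n_events),
    behavior_tag = tag, season_id = field$season_id,
    season_start = start, grid = field$grid),
    class = "kf_trajectories")
}

#' @export
print.kf_trajectories <- function(x, ...) {
  fin <- x$status[cbind(seq_len(nrow(x$status)), ncol(x$status))]
  cat(sprintf(
    "<kf_trajectories> %s season %s: %d particles x %d hourly samples\n",
    x$behavior_tag, x$season_id, nrow(x$x), ncol(x$x)))
  cat(sprintf("  final status: %d active, %d beached, %d exited\n",
              sum(fin == 0, na.rm = TRUE), sum(fin == 1, na.rm = TRUE),
              sum(fin == 2, na.rm = TRUE)))
  invisible(x)
}
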