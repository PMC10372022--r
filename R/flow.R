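#' Flow components for the synthetic shelf circulation
#'
#' A velocity field is composed from analytic stream-function components,
#' so every field is divergence-free by construction.  Three component
#' kinds are supported:
#'
#' * `eddy` — a Gaussian stream-function bump
#'   \eqn{\psi = A \exp(-r^2 / 2\sigma^2)}; a closed loop current whose
#'   peak azimuthal speed is \eqn{A / (\sigma \sqrt{e})} (with \eqn{\sigma}
#'   in metres).
#' * `jet` — a ribbon current along a polyline whose *velocity* has a
#'   Gaussian cross-section of width `width_km`; the stream function is the
#'   corresponding error-function step of height `amplitude`.
#' * `channel` — identical construction to `jet`; the label marks
#'   cross-shelf channel flows in presets.
#'
#' The stream-function step of a finite jet necessarily closes through a
#' broad, weak return circulation.  `clean_side` selects on which side of
#' the flow direction that return circulation is placed (`"left"` or
#' `"right"` relative to the direction of travel); the opposite side is
#' left free of far-field flow.  `envelope_km` bounds the lateral extent of
#' the return circulation.
#'
#' @param center length-2 numeric, eddy centre in km.
#' @param polyline 2-column matrix of km coordinates (at least 2 rows),
#'   ordered in the direction of flow.
#' @param peak_speed peak current speed in m s^-1 (alternative to
#'   `amplitude`); typical persistent shelf features run 0.10-0.20 m s^-1.
#' @param amplitude stream-function peak in m^2 s^-1 (overrides
#'   `peak_speed` when given).
#' @param width_km lateral length scale \eqn{\sigma} in km.
#' @param rotation_sign +1 (anticlockwise) or -1 (clockwise) for eddies.
#' @param clean_side `"left"` or `"right"`: side kept free of the jet's
#'   return circulation.
#' @param taper_km along-track Gaussian rolloff scale beyond the polyline
#'   ends (default `2 * width_km`).
#' @param envelope_km lateral Gaussian envelope scale confining the return
#'   circulation (default 100 km; `Inf` disables).
#' @param name optional label.
#' @return an object of class `kf_flow_component`.
#' @export
flow_eddy <- function(center, peak_speed = NULL, width_km,
                      rotation_sign = 1, amplitude = NULL, name = "eddy") {
  if (is.null(amplitude)) {
    stopifnot(is.numeric(peak_speed), peak_speed >= 0)
    amplitude <- peak_speed * width_km * 1000 * sqrt(exp(1))
  }
  stopifnot(is.finite(amplitude), width_km > 0,
            rotation_sign %in% c(-1, 1))
  structure(list(kind = "eddy", name = name, center = as.numeric(center),
                 amplitude = amplitude, width_km = width_km,
                 rotation_sign = rotation_sign),
            class = "kf_flow_component")
}

#' @rdname flow_eddy
#' @export
flow_jet <- function(polyline, peak_speed = NULL, width_km,
                     clean_side = "right", taper_km = 2 * width_km,
                     envelope_km = 100, amplitude = NULL, name = "jet",
                     kind = "jet") {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2L, nrow(polyline) >= 2L,
            clean_side %in% c("left", "right"), width_km > 0,
            kind %in% c("jet", "channel"))
  if (is.null(amplitude)) {
    stopifnot(is.numeric(peak_speed), peak_speed >= 0)
    amplitude <- peak_speed * width_km * 1000 * sqrt(2 * pi)
  }
  stopifnot(is.finite(amplitude))
  structure(list(kind = kind, name = name, polyline = polyline,
                 amplitude = amplitude, width_km = width_km,
                 clean_side = clean_side, taper_km = taper_km,
                 envelope_km = envelope_km),
            class = "kf_flow_component")
}

#' @rdname flow_eddy
#' @export
flow_channel <- function(polyline, peak_speed = NULL, width_km,
                         clean_side = "right", taper_km = 2 * width_km,
                         envelope_km = 100, amplitude = NULL,
                         name = "channel") {
  flow_jet(polyline, peak_speed, width_km, clean_side, taper_km,
           envelope_km, amplitude, name, kind = "channel")
}

#' Reportable peak speed of a component
#'
#' Analytic maximum current speed implied by the component's
#' stream-function amplitude and width.
#'
#' @param component a `kf_flow_component`.
#' @return peak speed in m s^-1.
#' @export
component_peak_speed <- function(component) {
  A <- component$amplitude
  s_m <- component$width_km * 1000
  if (component$kind == "eddy") abs(A) / (s_m * sqrt(exp(1)))
  else abs(A) / (s_m * sqrt(2 * pi))
}

# stream function of one component on the grid nodes, m^2 s^-1 (nx x ny)
component_psi <- function(component, grid) {
  xk <- grid$x
  yk <- grid$y
  X <- matrix(xk, length(xk), length(yk))
  Y <- matrix(yk, length(xk), length(yk), byrow = TRUE)
  if (component$kind == "eddy") {
    cx <- component$center[1]; cy <- component$center[2]
    if (cx < min(xk) || cx > max(xk) || cy < min(yk) || cy > max(yk))
      stop("eddy centre outside grid", call. = FALSE)
    r2 <- (X - cx)^2 + (Y - cy)^2
    s2 <- component$width_km^2
    return(component$rotation_sign * component$amplitude *
             exp(-r2 / (2 * s2)))
  }
  pl <- component$polyline
  if (any(pl[, 1] < min(xk)) || any(pl[, 1] > max(xk)) ||
      any(pl[, 2] < min(yk)) || any(pl[, 2] > max(yk)))
    stop("component polyline outside grid", call. = FALSE)
  # nearest-segment parametrization: signed lateral distance s (left of
  # travel positive) and cumulative along-track coordinate l
  npt <- length(X)
  p <- cbind(as.vector(X), as.vector(Y))
  nseg <- nrow(pl) - 1L
  seg_len <- sqrt(rowSums((pl[-1, , drop = FALSE] -
                             pl[-nrow(pl), , drop = FALSE])^2))
  cum0 <- c(0, cumsum(seg_len))[seq_len(nseg)]
  best_d2 <- rep(Inf, npt)
  s_lat <- numeric(npt)
  l_along <- numeric(npt)
  for (k in seq_len(nseg)) {
    a <- pl[k, ]; b <- pl[k + 1L, ]
    d <- (b - a) / seg_len[k]
    rel <- cbind(p[, 1] - a[1], p[, 2] - a[2])
    t_raw <- rel[, 1] * d[1] + rel[, 2] * d[2]
    t_cl <- pmin(pmax(t_raw, 0), seg_len[k])
    dx <- rel[, 1] - t_cl * d[1]
    dy <- rel[, 2] - t_cl * d[2]
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      # signed distance: positive to the left of travel direction
      s_lat[upd] <- rel[upd, 1] * (-d[2]) + rel[upd, 2] * d[1]
      l_along[upd] <- cum0[k] + t_raw[upd]
    }
  }
  L <- sum(seg_len)
  sg <- component$width_km
  tp <- component$taper_km
  taper <- rep(1, npt)
  below <- l_along < 0
  above <- l_along > L
  taper[below] <- exp(-(l_along[below])^2 / (2 * tp^2))
  taper[above] <- exp(-(l_along[above] - L)^2 / (2 * tp^2))
  env <- if (is.finite(component$envelope_km))
    exp(-s_lat^2 / (2 * component$envelope_km^2)) else rep(1, npt)
  # clean-left: psi = A*Phi(-s/sigma); clean-right: psi = -A*Phi(s/sigma).
  # Both give flow along the polyline direction with a Gaussian
  # cross-section of peak A / (sigma * sqrt(2*pi)).
  psi <- if (component$clean_side == "left")
    component$amplitude * stats::pnorm(-s_lat / sg)
  else
    -component$amplitude * stats::pnorm(s_lat / sg)
  matrix(psi * taper * env, length(xk), length(yk))
}

# centered-difference velocities from a stream function (km grid -> m)
psi_to_uv <- function(psi, spacing_km) {
  h <- spacing_km * 1000
  nx <- nrow(psi); ny <- ncol(psi)
  u <- matrix(0, nx, ny)
  v <- matrix(0, nx, ny)
  # u = -dpsi/dy, v = +dpsi/dx; one-sided at the boundary rows/columns
  u[, 2:(ny - 1)] <- -(psi[, 3:ny] - psi[, 1:(ny - 2)]) / (2 * h)
  u[, 1] <- -(psi[, 2] - psi[, 1]) / h
  u[, ny] <- -(psi[, ny] - psi[, ny - 1]) / h
  v[2:(nx - 1), ] <- (psi[3:nx, ] - psi[1:(nx - 2), ]) / (2 * h)
  v[1, ] <- (psi[2, ] - psi[1, ]) / h
  v[nx, ] <- (psi[nx, ] - psi[nx - 1, ]) / h
  list(u = u, v = v)
}

#' Velocity slice of a single flow component
#'
#' Evaluates the component's stream function on the grid nodes and
#' differentiates it (centred differences) into a horizontal velocity
#' slice.  Velocities on land nodes are zeroed.
#'
#' @param component a `kf_flow_component`.
#' @param grid a [make_grid()] grid.
#' @return list with `u`, `v` (m s^-1, `nx` x `ny` matrices) and `psi`
#'   (m^2 s^-1).
#' @export
streamfunction_velocity <- function(component, grid) {
  stopifnot(inherits(component, "kf_flow_component"),
            inherits(grid, "kf_grid"))
  psi <- component_psi(component, grid)
  uv <- psi_to_uv(psi, grid$spacing_km)
  uv$u[grid$land_mask] <- 0
  uv$v[grid$land_mask] <- 0
  list(u = uv$u, v = uv$v, psi = psi)
}

#' Compose a multi-day synthetic velocity field
#'
#' Sums the stream functions of all components, modulates each by a daily
#' multiplicative lognormal factor (mean 1, log-sd `noise_sigma`) so that
#' feature *speeds* vary from day to day while directions persist, and
#' differentiates into daily velocity snapshots.  The horizontal field is
#' replicated in depth with a two-layer shear profile: uniform above the
#' pycnocline, scaled by `deep_factor` below — the vertical structure of a
#' summer shelf where flow is uniform down to the pycnocline.  Vertical
#' velocity is zero (behavioural and turbulent vertical motion dominate).
#'
#' @param components list of `kf_flow_component`s (at least one).
#' @param grid a [make_grid()] grid.
#' @param n_days number of daily snapshots.
#' @param seed integer seed for the daily noise (`NULL` = leave RNG
#'   alone); identical seed and configuration give identical fields.
#' @param noise_sigma log-sd of the daily multiplicative noise (0
#'   disables; default 0.2).
#' @param pycnocline_m depth separating surface from deep layer (default
#'   80 m).
#' @param deep_factor velocity scale below the pycnocline (default 0.5).
#' @param season_id label for the simulated season, e.g. `"2008"`.
#' @param season_start ISO date (`Date` or string) of field time zero.
#' @return an object of class `kf_field`: arrays `u`, `v` of dimension
#'   `(x, y, depth, time)` in m s^-1 (`w` implicitly zero), `time_hours`
#'   (hours since season start, one snapshot per day), the `grid`,
#'   `season_id`, `season_start`.
#' @export
compose_flow <- function(components, grid, n_days, seed = NULL,
                         noise_sigma = 0.2, pycnocline_m = 80,
                         deep_factor = 0.5, season_id = "synthetic",
                         season_start = "2008-11-01") {
  stopifnot(inherits(grid, "kf_grid"), n_days >= 1)
  if (length(components) == 0L)
    stop("at least one flow component is required", call. = FALSE)
  if (inherits(components, "kf_flow_component"))
    components <- list(components)
  lapply(components, function(cc)
    stopifnot(inherits(cc, "kf_flow_component")))
  nx <- length(grid$x); ny <- length(grid$y)
  nz <- length(grid$depth); nc <- length(components)
  psi_c <- lapply(components, component_psi, grid = grid)
  mods <- matrix(1, n_days, nc)
  if (noise_sigma > 0) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
      } else {
        on.exit(suppressWarnings(
          rm(".Random.seed", envir = globalenv())), add = TRUE)
      }
      set.seed(seed)
    }
    mods[] <- exp(stats::rnorm(n_days * nc, -noise_sigma^2 / 2,
                               noise_sigma))
  }
  zfac <- ifelse(grid$depth <= pycnocline_m, 1, deep_factor)
  u <- array(0, c(nx, ny, nz, n_days))
  v <- array(0, c(nx, ny, nz, n_days))
  land <- grid$land_mask
  for (d in seq_len(n_days)) {
    psi <- matrix(0, nx, ny)
    for (k in seq_len(nc)) psi <- psi + mods[d, k] * psi_c[[k]]
    uv <- psi_to_uv(psi, grid$spacing_km)
    uv$u[land] <- 0
    uv$v[land] <- 0
    for (iz in seq_len(nz)) {
      u[, , iz, d] <- uv$u * zfac[iz]
      v[, , iz, d] <- uv$v * zfac[iz]
    }
  }
  structure(list(u = u, v = v, w = NULL,
                 time_hours = (seq_len(n_days) - 1) * 24,
                 grid = grid, season_id = season_id,
                 season_start = as.Date(season_start),
                 pycnocline_m = pycnocline_m, deep_factor = deep_factor,
                 daily_modulation = mods),
            class = "kf_field")
}

#' @export
print.kf_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf(
    "<kf_field> season %s: %d x %d nodes, %d z-levels, %d daily snapshots\n",
    x$season_id, d[1], d[2], d[3], d[4]))
  cat(sprintf("  max speed %.3f m s-1, start %s\n",
              max(sqrt(x$u^2 + x$v^2)), format(x$season_start)))
  invisible(x)
}

#' Discrete horizontal divergence of a field snapshot
#'
#' Centred-difference divergence `du/dx + dv/dy` (s^-1) at interior grid
#' nodes.  For stream-function-built fields this vanishes to round-off at
#' every interior node whose four neighbours are water; nodes adjacent to
#' the land mask see the zeroed land velocities and are excluded from the
#' `clean` mask.
#'
#' @param field a `kf_field`.
#' @param depth_index,time_index which slice to evaluate (defaults 1, 1).
#' @return list with `div` (`(nx-2)` x `(ny-2)` matrix of s^-1) and
#'   `clean` (logical matrix: interior water nodes with all-water
#'   stencils).
#' @export
horizontal_divergence <- function(field, depth_index = 1L,
                                  time_index = 1L) {
  stopifnot(inherits(field, "kf_field"))
  u <- field$u[, , depth_index, time_index]
  v <- field$v[, , depth_index, time_index]
  h <- field$grid$spacing_km * 1000
  nx <- nrow(u); ny <- ncol(u)
  ix <- 2:(nx - 1); iy <- 2:(ny - 1)
  div <- (u[ix + 1, iy] - u[ix - 1, iy]) / (2 * h) +
    (v[ix, iy + 1] - v[ix, iy - 1]) / (2 * h)
  water <- !field$grid$land_mask
  clean <- water[ix, iy] & water[ix + 1, iy] & water[ix - 1, iy] &
    water[ix, iy + 1] & water[ix, iy - 1]
  list(div = div, clean = clean)
}
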