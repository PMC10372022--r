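#' Build a regular model grid
#'
#' Constructs the horizontal/vertical grid on which synthetic velocity
#' fields are generated and through which particles are advected.
#' Horizontal coordinates are kilometres on a local tangent plane anchored
#' at `anchor` (lon/lat in degrees); depths are metres, positive down.
#'
#' @param extent_km length-2 numeric, domain size in km `(x, y)`.
#' @param spacing_km horizontal node spacing in km (uniform; must divide
#'   both extents). Default 1.5 km.
#' @param depths numeric vector of z-levels in m, positive down, strictly
#'   increasing, first level no deeper than 10 m.
#' @param anchor length-2 numeric `(lon, lat)` in degrees; geographic
#'   position of the grid origin `(x = 0, y = 0)`, used for solar-angle
#'   computations. `x` increases eastward, `y` northward.
#' @param seabed_m uniform seabed depth in m (vertical clamp for
#'   particles). Default 400.
#' @return An object of class `kf_grid`: list with `x`, `y` (node
#'   coordinates, km), `depth` (m), `spacing_km`, `ref_lon`, `ref_lat`,
#'   `seabed_m` and `land_mask` (logical `nx` x `ny` matrix, `TRUE` =
#'   land; all-water initially — see [paint_land()]).
#' @examples
#' g <- make_grid(c(300, 300), 1.5)
#' length(g$x) # 201 nodes
#' @export
make_grid <- function(extent_km, spacing_km = 1.5,
                      depths = c(10, 25, 50, 75, 100, 150),
                      anchor = c(-62, -64), seabed_m = 400) {
  if (length(extent_km) == 1L) extent_km <- rep(extent_km, 2L)
  stopifnot(length(extent_km) == 2L, all(is.finite(extent_km)))
  if (!is.numeric(spacing_km) || length(spacing_km) != 1L ||
      !is.finite(spacing_km) || spacing_km <= 0)
    stop("`spacing_km` must be a single positive number", call. = FALSE)
  if (any(extent_km <= 0))
    stop("`extent_km` must be positive", call. = FALSE)
  n <- extent_km / spacing_km
  if (any(abs(n - round(n)) > 1e-8))
    stop("`spacing_km` must divide both extents", call. = FALSE)
  depths <- as.numeric(depths)
  if (is.unsorted(depths, strictly = TRUE))
    stop("`depths` must be strictly increasing", call. = FALSE)
  if (depths[1] > 10)
    stop("shallowest z-level must be at or above 10 m", call. = FALSE)
  if (seabed_m < max(depths))
    stop("`seabed_m` must be at least the deepest z-level", call. = FALSE)
  x <- seq(0, extent_km[1], by = spacing_km)
  y <- seq(0, extent_km[2], by = spacing_km)
  g <- list(
    x = x, y = y, depth = depths, spacing_km = spacing_km,
    ref_lon = anchor[1], ref_lat = anchor[2], seabed_m = seabed_m,
    land_mask = matrix(FALSE, length(x), length(y))
  )
  class(g) <- "kf_grid"
  g
}

#' @export
print.kf_grid <- function(x, ...) {
  cat(sprintf(
    "<kf_grid> %d x %d nodes, %.1f km spacing, %d z-levels (%g-%g m)\n",
    length(x$x), length(x$y), x$spacing_km, length(x$depth),
    min(x$depth), max(x$depth)))
  cat(sprintf("  anchor lon %.2f lat %.2f; %.1f%% land\n",
              x$ref_lon, x$ref_lat, 100 * mean(x$land_mask)))
  invisible(x)
}

#' Mark grid cells as land
#'
#' @param grid a [make_grid()] object.
#' @param predicate function of `(x, y)` (km, vectorized over equal-length
#'   vectors) returning `TRUE` where there is land.
#' @return the grid with an updated `land_mask`.
#' @export
paint_land <- function(grid, predicate) {
  stopifnot(inherits(grid, "kf_grid"), is.function(predicate))
  xy <- expand.grid(x = grid$x, y = grid$y)
  m <- matrix(as.logical(predicate(xy$x, xy$y)),
              length(grid$x), length(grid$y))
  if (anyNA(m)) stop("land predicate returned NA", call. = FALSE)
  grid$land_mask <- grid$land_mask | m
  grid
}

#' Map grid coordinates to geographic longitude/latitude
#'
#' Local tangent-plane approximation at the grid anchor: one degree of
#' latitude is 110.574 km; one degree of longitude is 111.320 km scaled by
#' `cos(lat)` at the anchor.
#'
#' @param grid a [make_grid()] object.
#' @param x,y positions in km (vectorized).
#' @return list with numeric `lon` and `lat` in degrees.
#' @export
grid_lonlat <- function(grid, x, y) {
  lat <- grid$ref_lat + y / 110.574
  lon <- grid$ref_lon + x / (111.320 * cos(grid$ref_lat * pi / 180))
  list(lon = lon, lat = lat)
}

# nearest grid node indices for positions in km (clamped to the grid)
nearest_node <- function(grid, x, y) {
  ix <- pmin(pmax(round((x - grid$x[1]) / grid$spacing_km) + 1L, 1L),
             length(grid$x))
  iy <- pmin(pmax(round((y - grid$y[1]) / grid$spacing_km) + 1L, 1L),
             length(grid$y))
  list(ix = ix, iy = iy)
}

#' Is a position on land?
#'
#' Nearest-node land-mask lookup, the same convention the advection kernel
#' uses for beaching.
#'
#' @inheritParams grid_lonlat
#' @return logical vector.
#' @export
is_land_at <- function(grid, x, y) {
  idx <- nearest_node(grid, x, y)
  grid$land_mask[cbind(idx$ix, idx$iy)]
}
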