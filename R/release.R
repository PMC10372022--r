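#' Weekly release schedule
#'
#' Release dates at a fixed interval from `first_release` up to and
#' including the last date on or before `cutoff`.  The canonical summer
#' schedule — releases every 7 days from 1 November to mid-February —
#' yields 16 release events, the last on 14 February.
#'
#' @param first_release first release date (`Date` or ISO string).
#' @param interval_days days between releases (default 7).
#' @param cutoff latest admissible release date (default 15 February of
#'   the following calendar year).
#' @return vector of `Date`s.
#' @examples
#' length(build_release_schedule("2008-11-01", 7, "2009-02-15")) # 16
#' @export
build_release_schedule <- function(first_release, interval_days = 7,
                                   cutoff = NULL) {
  first_release <- as.Date(first_release)
  if (is.null(cutoff)) {
    yr <- as.integer(format(first_release, "%Y")) + 1L
    cutoff <- as.Date(sprintf("%d-02-15", yr))
  }
  cutoff <- as.Date(cutoff)
  if (!is.numeric(interval_days) || interval_days <= 0)
    stop("`interval_days` must be positive", call. = FALSE)
  if (cutoff < first_release)
    stop("`cutoff` must not precede `first_release`", call. = FALSE)
  seq(first_release, cutoff, by = interval_days)
}

#' Seed particles on a regular release lattice
#'
#' One particle per lattice node whose nearest grid cell is water and not
#' excluded; ordering is deterministic (x varying fastest, then y).
#'
#' @param grid a [make_grid()] grid.
#' @param spacing_km seed lattice spacing in km (the canonical set-up
#'   seeds on an approximately 8 km lattice; desk-scale runs use wider
#'   spacing).
#' @param depth release depth in m.
#' @param exclusion_mask optional logical `nx` x `ny` matrix of grid
#'   cells barred from seeding (e.g. water under ice shelves), in
#'   addition to the land mask.
#' @param box optional `c(xmin, xmax, ymin, ymax)` in km restricting the
#'   seed lattice (default: whole domain).
#' @return data.frame with columns `x`, `y` (km) and `depth` (m).
#' @export
seed_particles <- function(grid, spacing_km, depth,
                           exclusion_mask = NULL, box = NULL) {
  stopifnot(inherits(grid, "kf_grid"), spacing_km >= grid$spacing_km,
            depth >= 0)
  if (is.null(box)) box <- c(min(grid$x), max(grid$x),
                             min(grid$y), max(grid$y))
  xs <- seq(max(box[1], min(grid$x)), min(box[2], max(grid$x)),
            by = spacing_km)
  ys <- seq(max(box[3], min(grid$y)), min(box[4], max(grid$y)),
            by = spacing_km)
  pts <- expand.grid(x = xs, y = ys)
  bad <- is_land_at(grid, pts$x, pts$y)
  if (!is.null(exclusion_mask)) {
    stopifnot(identical(dim(exclusion_mask), dim(grid$land_mask)))
    idx <- nearest_node(grid, pts$x, pts$y)
    bad <- bad | exclusion_mask[cbind(idx$ix, idx$iy)]
  }
  out <- pts[!bad, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no water seed nodes: empty release", call. = FALSE)
  out$depth <- rep(depth, nrow(out))
  rownames(out) <- NULL
  out
}

#' Release plan: schedule plus seeding geometry
#'
#' @param dates release dates from [build_release_schedule()].
#' @param spacing_km seed lattice spacing in km.
#' @param depth release depth in m; if `NULL`, taken from the behaviour
#'   configuration at simulation time (10 m band start for migrating
#'   runs, the fixed release depth for passive runs).
#' @param exclusion_mask optional seeding exclusion mask (see
#'   [seed_particles()]).
#' @param box optional seeding box (see [seed_particles()]).
#' @return an object of class `kf_release_plan`.
#' @export
release_plan <- function(dates, spacing_km = 8, depth = NULL,
                         exclusion_mask = NULL, box = NULL) {
  dates <- as.Date(dates)
  stopifnot(length(dates) >= 1L, !is.unsorted(as.numeric(dates)))
  structure(list(dates = dates, spacing_km = spacing_km, depth = depth,
                 exclusion_mask = exclusion_mask, box = box),
            class = "kf_release_plan")
}
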