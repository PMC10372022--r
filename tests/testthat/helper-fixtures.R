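# Shared fixtures: small analytic fields, synthetic trajectory objects,
# and independent brute-force oracles used across the suite.

# steady solid-body rotation field about `center` (km), angular velocity
# omega (s^-1): u = -omega * (y - yc), v = omega * (x - xc) in m s^-1
solid_body_field <- function(omega = 1e-4, center = c(100, 100),
                             extent = c(200, 200), spacing = 5,
                             seabed = 400) {
  g <- make_grid(extent, spacing, depths = c(10, 50),
                 anchor = c(-62, -64), seabed_m = seabed)
  nx <- length(g$x); ny <- length(g$y)
  u <- array(0, c(nx, ny, 2, 2)); v <- array(0, c(nx, ny, 2, 2))
  for (iy in seq_len(ny)) u[, iy, , ] <- -omega * (g$y[iy] - center[2]) * 1000
  for (ix in seq_len(nx)) v[ix, , , ] <- omega * (g$x[ix] - center[1]) * 1000
  structure(list(u = u, v = v, w = NULL, time_hours = c(0, 24 * 60),
                 grid = g, season_id = "rot",
                 season_start = as.Date("2008-11-01"),
                 pycnocline_m = 80, deep_factor = 1,
                 daily_modulation = NULL), class = "kf_field")
}

# spatially uniform steady field
uniform_field <- function(u0 = 0.1, v0 = 0, extent = c(200, 200),
                          spacing = 10, n_hours = 24 * 60) {
  g <- make_grid(extent, spacing, depths = c(10, 50),
                 anchor = c(-62, -64))
  nx <- length(g$x); ny <- length(g$y)
  f <- structure(list(
    u = array(u0, c(nx, ny, 2, 2)), v = array(v0, c(nx, ny, 2, 2)),
    w = NULL, time_hours = c(0, n_hours), grid = g, season_id = "uni",
    season_start = as.Date("2008-11-01"), pycnocline_m = 80,
    deep_factor = 1, daily_modulation = NULL), class = "kf_field")
  f
}

# hand-built trajectory container (positions in km, hourly axis)
make_traj <- function(x, y, depth = NULL, hours = NULL,
                      release_hour = NULL, status = NULL,
                      season_start = as.Date("2008-11-01")) {
  x <- rbind(x); y <- rbind(y)
  if (is.null(depth)) depth <- matrix(20, nrow(x), ncol(x))
  if (is.null(hours)) hours <- 0:(ncol(x) - 1)
  if (is.null(release_hour)) release_hour <- rep(0, nrow(x))
  if (is.null(status)) {
    status <- matrix(NA_integer_, nrow(x), ncol(x))
    for (i in seq_len(nrow(x)))
      status[i, !is.na(x[i, ])] <- 0L
  }
  first_col <- release_hour - hours[1] + 1
  structure(list(
    x = x, y = y, depth = depth, status = status, hours = hours,
    release_event = rep(1L, nrow(x)), release_hour = release_hour,
    release_x = x[cbind(seq_len(nrow(x)), first_col)],
    release_y = y[cbind(seq_len(nrow(x)), first_col)],
    release_depth = depth[cbind(seq_len(nrow(x)), first_col)],
    behavior_tag = "dvm_50", season_id = "t",
    season_start = season_start, grid = NULL),
    class = "kf_trajectories")
}

# small two-region lattice fixture: regions A (one colony) and B (one
# colony two cells away) on a 400 x 400 km domain
two_region_set <- function() {
  g <- make_grid(c(400, 400), 10, anchor = c(-62, -64))
  cells <- build_region_cells(g, 40)
  colonies <- data.frame(
    colony_id = c("a1", "b1"), region = c("A", "B"),
    species = c("adelie", "gentoo"),
    x = c(60, 300), y = c(60, 300), nests = c(100, 200))
  regions_from_colonies(colonies, cells)
}

# independent exhaustive two-sided rank-sum p-value by enumeration of
# all assignments of the pooled ranks to the first group
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  mu <- mean(sums)
  p <- mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
  min(1, p)
}

# brute-force region membership oracle built on sp::point.in.polygon
# (the reference routine): a point is in a study region iff it is in
# any of that region's cell rectangles, in a source region iff inside
# its polygon; first match in region order wins
oracle_locate <- function(x, y, regions) {
  out <- rep("offshore", length(x))
  todo <- seq_along(x)
  for (r in seq_along(regions$region_names)) {
    nm <- regions$region_names[r]
    if (regions$roles[r] == "study") {
      rects <- region_cell_rects(regions, nm)
      for (k in seq_len(nrow(rects))) {
        if (!length(todo)) break
        px <- c(rects[k, "xmin"], rects[k, "xmax"], rects[k, "xmax"],
                rects[k, "xmin"])
        py <- c(rects[k, "ymin"], rects[k, "ymin"], rects[k, "ymax"],
                rects[k, "ymax"])
        hit <- sp::point.in.polygon(x[todo], y[todo], px, py) > 0
        out[todo[hit]] <- nm
        todo <- todo[!hit]
      }
    } else {
      pg <- regions$source_polygons[[nm]]
      hit <- sp::point.in.polygon(x[todo], y[todo], pg[, 1], pg[, 2]) > 0
      out[todo[hit]] <- nm
      todo <- todo[!hit]
    }
  }
  out
}

# brute-force trajectory reduction: per-sample scan using the oracle
# membership test, re-deriving transit/residence from first principles
oracle_reduce <- function(traj, regions) {
  np <- nrow(traj$x)
  rows <- list()
  for (i in seq_len(np)) {
    ok <- which(!is.na(traj$status[i, ]) & traj$status[i, ] == 0L)
    labs <- rep(NA_character_, ncol(traj$x))
    labs[ok] <- oracle_locate(traj$x[i, ok], traj$y[i, ok], regions)
    origin <- oracle_locate(traj$release_x[i], traj$release_y[i], regions)
    for (nm in setdiff(unique(labs[!is.na(labs)]), "offshore")) {
      fi <- which(labs == nm)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        particle_id = i, origin = origin, region = nm,
        released_within = nm == origin,
        first_entry_h = if (nm == origin) NA_real_ else
          traj$hours[fi] - traj$release_hour[i],
        residence_h = sum(labs == nm, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}
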