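#' Build the region cell lattice
#'
#' Axis-aligned lattice of square cells (default side 40 km, i.e.
#' 1600 km^2) covering the model domain.  Study regions are unions of
#' these cells around penguin colonies; 40 km approximates the maximum
#' summer foraging range of breeding *Pygoscelis* penguins.  Partial
#' edge cells are retained, clipped to the domain.
#'
#' @param grid a [make_grid()] grid (the lattice covers its extent).
#' @param cell_side_km cell side in km (default 40).
#' @return an object of class `kf_cell_lattice`: cell edge coordinates
#'   and counts.
#' @export
build_region_cells <- function(grid, cell_side_km = 40) {
  stopifnot(inherits(grid, "kf_grid"), cell_side_km > 0)
  x0 <- min(grid$x); x1 <- max(grid$x)
  y0 <- min(grid$y); y1 <- max(grid$y)
  if (x1 - x0 < cell_side_km || y1 - y0 < cell_side_km)
    stop("domain smaller than one cell", call. = FALSE)
  ncx <- ceiling((x1 - x0) / cell_side_km)
  ncy <- ceiling((y1 - y0) / cell_side_km)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 side = cell_side_km, ncx = ncx, ncy = ncy),
            class = "kf_cell_lattice")
}

# cell indices (1-based) for points; 0 when outside the domain
cell_index <- function(lattice, x, y) {
  ix <- floor((x - lattice$x0) / lattice$side) + 1
  iy <- floor((y - lattice$y0) / lattice$side) + 1
  # the domain's upper edges belong to the last cell
  ix[x == lattice$x1] <- lattice$ncx
  iy[y == lattice$y1] <- lattice$ncy
  out <- ix >= 1 & ix <= lattice$ncx & iy >= 1 & iy <= lattice$ncy &
    x >= lattice$x0 & x <= lattice$x1 & y >= lattice$y0 & y <= lattice$y1
  ix[!out] <- 0
  iy[!out] <- 0
  list(ix = as.integer(ix), iy = as.integer(iy))
}

# rectangle (clipped to the domain) of cell (ix, iy)
cell_rect <- function(lattice, ix, iy) {
  ix <- unname(ix); iy <- unname(iy)
  c(xmin = lattice$x0 + (ix - 1) * lattice$side,
    xmax = min(lattice$x0 + ix * lattice$side, lattice$x1),
    ymin = lattice$y0 + (iy - 1) * lattice$side,
    ymax = min(lattice$y0 + iy * lattice$side, lattice$y1))
}

#' Construct named study regions from colony locations
#'
#' Every cell containing at least one colony of a region, plus the 8
#' neighbours of each such cell, belongs to that region.  A cell claimed
#' by several regions is resolved to the region of the nearest colony
#' (distance from the cell centre), so regions are pairwise disjoint.
#'
#' @param colonies data.frame with columns `colony_id`, `region`,
#'   `species`, `x`, `y` (km) and `nests` (see [read_colonies()]).
#' @param cells a [build_region_cells()] lattice.
#' @return an object of class `kf_regionset`: the lattice, an integer
#'   cell-to-region assignment matrix, region names/roles, and an
#'   (initially empty) list of free source polygons — see
#'   [add_source_region()].
#' @export
regions_from_colonies <- function(colonies, cells) {
  stopifnot(inherits(cells, "kf_cell_lattice"),
            all(c("colony_id", "region", "x", "y") %in% names(colonies)))
  ci <- cell_index(cells, colonies$x, colonies$y)
  if (any(ci$ix == 0)) {
    bad <- colonies$colony_id[ci$ix == 0]
    stop("colonies outside the domain: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  region_names <- unique(as.character(colonies$region))
  assign <- matrix(0L, cells$ncx, cells$ncy)
  claim_dist <- matrix(Inf, cells$ncx, cells$ncy)
  for (r in seq_along(region_names)) {
    sel <- colonies$region == region_names[r]
    cx <- colonies$x[sel]; cy <- colonies$y[sel]
    core <- unique(cbind(ci$ix[sel], ci$iy[sel]))
    cand <- unique(do.call(rbind, lapply(seq_len(nrow(core)), function(k) {
      expand.grid(ix = core[k, 1] + (-1:1), iy = core[k, 2] + (-1:1))
    })))
    cand <- cand[cand$ix >= 1 & cand$ix <= cells$ncx &
                   cand$iy >= 1 & cand$iy <= cells$ncy, , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      rect <- cell_rect(cells, cand$ix[k], cand$iy[k])
      ctr <- c(mean(rect[1:2]), mean(rect[3:4]))
      d <- min(sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2))
      if (d < claim_dist[cand$ix[k], cand$iy[k]]) {
        claim_dist[cand$ix[k], cand$iy[k]] <- d
        assign[cand$ix[k], cand$iy[k]] <- r
      }
    }
  }
  structure(list(cells = cells, assign = assign,
                 region_names = region_names,
                 roles = rep("study", length(region_names)),
                 source_polygons = list()),
            class = "kf_regionset")
}

#' Add a free-polygon source region
#'
#' Source regions (e.g. the upstream seas supplying krill) are free
#' polygons rather than colony-cell unions: every release point inside
#' them counts, regardless of distance to shore.  The polygon must not
#' overlap any study-region cell.
#'
#' @param regions a [regions_from_colonies()] region set.
#' @param name region name.
#' @param polygon 2-column matrix of km vertex coordinates (closed
#'   implicitly).
#' @return the updated region set.
#' @export
add_source_region <- function(regions, name, polygon) {
  stopifnot(inherits(regions, "kf_regionset"))
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
  occ <- which(regions$assign > 0L, arr.ind = TRUE)
  for (k in seq_len(nrow(occ))) {
    rect <- cell_rect(regions$cells, occ[k, 1], occ[k, 2])
    ctr_in <- point_in_polygon(mean(rect[1:2]), mean(rect[3:4]), polygon)
    if (ctr_in)
      stop(sprintf("source polygon '%s' overlaps study-region cells",
                   name), call. = FALSE)
  }
  regions$region_names <- c(regions$region_names, name)
  regions$roles <- c(regions$roles, "source")
  regions$source_polygons[[name]] <- polygon
  regions
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting (even-odd rule) membership test with closed boundaries:
#' points on a polygon edge or vertex count as inside.
#'
#' @param x,y point coordinates (vectorized).
#' @param polygon 2-column vertex matrix (closed implicitly).
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, polygon) {
  px <- polygon[, 1]; py <- polygon[, 2]
  n <- length(px)
  jj <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- px[jj[k]]; y1 <- py[jj[k]]; x2 <- px[k]; y2 <- py[k]
    # boundary: point on segment (x1,y1)-(x2,y2)
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    within <- x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | (abs(cross) < 1e-9 & within)
    # even-odd crossing of the horizontal ray toward +x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Locate a point among the regions
#'
#' Study regions are resolved by exact cell lookup on the 40 km lattice
#' (equivalent to even-odd ray casting on the cell-union outline, with
#' boundaries inside); source polygons are tested by ray casting.  A
#' point in no region is `"offshore"`.
#'
#' @param x,y coordinates in km (vectorized).
#' @param regions a `kf_regionset`.
#' @return character vector of region names or `"offshore"`.
#' @export
locate_point <- function(x, y, regions) {
  stopifnot(inherits(regions, "kf_regionset"))
  ci <- cell_index(regions$cells, x, y)
  rid <- integer(length(x))
  ok <- ci$ix > 0L
  rid[ok] <- regions$assign[cbind(ci$ix[ok], ci$iy[ok])]
  # points exactly on a cell's upper/right edge also belong to the
  # region of the cell below/left of the edge (closed boundaries)
  need <- which(ok & rid == 0L)
  if (length(need)) {
    side <- regions$cells$side
    fx <- (x[need] - regions$cells$x0) / side
    fy <- (y[need] - regions$cells$y0) / side
    on_vx <- abs(fx - round(fx)) < 1e-9 & ci$ix[need] > 1L
    on_vy <- abs(fy - round(fy)) < 1e-9 & ci$iy[need] > 1L
    for (k in seq_along(need)) {
      i <- need[k]
      cand <- rbind(
        if (on_vx[k]) c(ci$ix[i] - 1L, ci$iy[i]),
        if (on_vy[k]) c(ci$ix[i], ci$iy[i] - 1L),
        if (on_vx[k] && on_vy[k]) c(ci$ix[i] - 1L, ci$iy[i] - 1L))
      for (cc in seq_len(NROW(cand))) {
        r <- regions$assign[cand[cc, 1], cand[cc, 2]]
        if (r > 0L) { rid[i] <- r; break }
      }
    }
  }
  out <- rep("offshore", length(x))
  out[rid > 0L] <- regions$region_names[rid[rid > 0L]]
  if (length(regions$source_polygons)) {
    rest <- which(out == "offshore")
    for (nm in names(regions$source_polygons)) {
      if (!length(rest)) break
      hit <- point_in_polygon(x[rest], y[rest],
                              regions$source_polygons[[nm]])
      out[rest[hit]] <- nm
      rest <- rest[!hit]
    }
  }
  out
}

#' Cell rectangles of a study region
#'
#' @param regions a `kf_regionset`.
#' @param name a study-region name.
#' @return matrix with columns `xmin`, `xmax`, `ymin`, `ymax`, one row
#'   per cell.
#' @export
region_cell_rects <- function(regions, name) {
  r <- match(name, regions$region_names)
  if (is.na(r) || regions$roles[r] != "study")
    stop("not a study region: ", name, call. = FALSE)
  idx <- which(regions$assign == r, arr.ind = TRUE)
  t(apply(idx, 1, function(k) cell_rect(regions$cells, k[1], k[2])))
}

#' Read a colony table
#'
#' CSV with columns `colony_id`, `region`, `species` (one of `adelie`,
#' `chinstrap`, `gentoo`), `x`, `y` (km) and `nests`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_colonies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("colony_id", "region", "species", "x", "y", "nests")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("colony table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$species), c("adelie", "chinstrap", "gentoo"))
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$nests < 0)) stop("negative nest counts", call. = FALSE)
  df
}
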