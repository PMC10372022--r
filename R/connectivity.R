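#' Origin region of every particle
#'
#' The origin is the region containing the release position; particles
#' released outside every named region originate from `"offshore"`
#' waters.
#'
#' @param traj a `kf_trajectories` object.
#' @param regions a `kf_regionset`.
#' @return character vector, one origin per particle.
#' @export
label_origins <- function(traj, regions) {
  stopifnot(inherits(traj, "kf_trajectories"))
  locate_point(traj$release_x, traj$release_y, regions)
}

#' Reduce trajectories to per-particle connectivity records
#'
#' Region membership is evaluated at every hourly sample while the
#' particle is active (beached and exited particles stop accumulating).
#' For every region a particle ever visits, the record notes the transit
#' time (hours from release to the first sample inside; defined only for
#' particles not released within that region) and the residence time
#' (number of hourly samples inside, i.e. hours).  Re-entries accumulate
#' into the one residence total.
#'
#' @param traj a `kf_trajectories` object (hourly sampling required).
#' @param regions a `kf_regionset`.
#' @return data.frame with one row per (particle, visited region):
#'   `particle_id`, `origin`, `region`, `released_within`,
#'   `first_entry_h` (`NA` when released within), `residence_h`.
#' @export
reduce_trajectories <- function(traj, regions) {
  stopifnot(inherits(traj, "kf_trajectories"))
  if (any(diff(traj$hours) != 1))
    stop("trajectories are not hourly-sampled", call. = FALSE)
  np <- nrow(traj$x)
  origins <- label_origins(traj, regions)
  # label all active samples in one vectorized pass
  act <- !is.na(traj$status) & traj$status == 0L
  lab <- matrix(NA_character_, np, ncol(traj$x))
  if (any(act))
    lab[act] <- locate_point(traj$x[act], traj$y[act], regions)
  rel_col <- traj$release_hour + 1L
  recs <- vector("list", np)
  for (i in seq_len(np)) {
    li <- lab[i, ]
    keep <- !is.na(li) & li != "offshore"
    if (!any(keep)) next
    visited <- unique(li[keep])
    first_idx <- vapply(visited, function(r) which(li == r)[1], 1L)
    res_h <- vapply(visited, function(r) sum(li == r, na.rm = TRUE), 1L)
    within <- visited == origins[i]
    recs[[i]] <- data.frame(
      particle_id = i, origin = origins[i], region = visited,
      released_within = within,
      first_entry_h = ifelse(within, NA_real_,
                             traj$hours[first_idx] - traj$release_hour[i]),
      residence_h = as.numeric(res_h), row.names = NULL)
  }
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(particle_id = integer(), origin = character(),
                      region = character(), released_within = logical(),
                      first_entry_h = numeric(), residence_h = numeric())
  attr(out, "n_particles") <- np
  attr(out, "origins") <- origins
  attr(out, "season_id") <- traj$season_id
  attr(out, "behavior_tag") <- traj$behavior_tag
  out
}

#' Origin-by-destination connectivity matrix
#'
#' Counts of distinct particles from each origin that ever entered each
#' destination study region (a particle contributes at most 1 to any
#' cell; the diagonal counts particles re-recorded in their origin
#' region through the released-within pathway).  Given a list of
#' per-season record frames, per-season matrices and their interannual
#' mean are returned.
#'
#' @param records a record frame from [reduce_trajectories()], or a list
#'   of them (one per season).
#' @param origins origin row names (default: all origins observed plus
#'   all destinations).
#' @param destinations destination column names (default: the study
#'   regions present in the records).
#' @return for a single record frame, an origin x destination count
#'   matrix; for a list, `list(per_season = <named list of matrices>,
#'   mean = <matrix>)`.
#' @export
connectivity_matrix <- function(records, origins = NULL,
                                destinations = NULL) {
  if (is.data.frame(records)) {
    if (is.null(destinations)) destinations <- sort(unique(records$region))
    if (is.null(origins))
      origins <- sort(unique(c(records$origin, destinations)))
    m <- matrix(0, length(origins), length(destinations),
                dimnames = list(origin = origins,
                                destination = destinations))
    sel <- records$region %in% destinations & records$origin %in% origins
    if (any(sel)) {
      tb <- table(factor(records$origin[sel], levels = origins),
                  factor(records$region[sel], levels = destinations))
      m[] <- as.numeric(tb)
    }
    return(m)
  }
  stopifnot(is.list(records), length(records) >= 1L)
  if (is.null(destinations))
    destinations <- sort(unique(unlist(lapply(records,
                                              function(r) r$region))))
  if (is.null(origins))
    origins <- sort(unique(c(unlist(lapply(records,
                                           function(r) r$origin)),
                             destinations)))
  per <- lapply(records, connectivity_matrix, origins = origins,
                destinations = destinations)
  names(per) <- vapply(records, function(r) {
    s <- attr(r, "season_id"); if (is.null(s)) "" else s
  }, "")
  list(per_season = per, mean = Reduce(`+`, per) / length(per))
}

#' Migrating-versus-passive connectivity contrast
#'
#' Per-cell difference (`passive - dvm`) and percent difference
#' (`100 * (passive - dvm) / dvm`, relative to the migrating count) of
#' two connectivity matrices sharing axes.  Cells with a zero migrating
#' count have an undefined percent difference and are flagged.
#'
#' @param matrix_dvm,matrix_passive origin x destination count matrices
#'   with identical dimnames.
#' @return list with `difference`, `percent` (NA where undefined) and
#'   logical `undefined`.
#' @export
dvm_contrast <- function(matrix_dvm, matrix_passive) {
  if (!identical(dimnames(matrix_dvm), dimnames(matrix_passive)))
    stop("matrices do not share axes", call. = FALSE)
  diffm <- matrix_passive - matrix_dvm
  undef <- matrix_dvm == 0
  pct <- 100 * diffm / matrix_dvm
  pct[undef] <- NA_real_
  list(difference = diffm, percent = pct, undefined = undef)
}

#' Current-rose statistics over a box
#'
#' Distribution of compass bearings of the flow (the direction water is
#' moving toward: 0 deg = north, clockwise positive) over all water grid
#' points in a box, all requested depths, and all stored times within a
#' window — by default the chick-rearing period, 1 December-31 March.
#' Bearings are binned into twelve 30 deg bins aligned at 0 deg; a
#' bearing exactly on a bin edge goes to the bin it closes (intervals
#' are left-open, right-closed, with due north reported in the
#' 330-360 deg bin).
#'
#' @param field a `kf_field`.
#' @param box `c(xmin, xmax, ymin, ymax)` in km (default: whole domain).
#' @param depths depths in m (default: all of the field's z-levels);
#'   intermediate depths are linearly interpolated.
#' @param window length-2 `Date` vector (default chick-rearing:
#'   1 December to 31 March).
#' @return list with `breaks` (deg), `freq` (12 relative frequencies
#'   summing to 1), `mean_speed` (m s^-1) and `n` (samples).
#' @export
rose_statistics <- function(field, box = NULL, depths = NULL,
                            window = NULL) {
  stopifnot(inherits(field, "kf_field"))
  g <- field$grid
  if (is.null(box)) box <- c(min(g$x), max(g$x), min(g$y), max(g$y))
  if (is.null(depths)) depths <- g$depth
  if (is.null(window)) {
    yr0 <- as.integer(format(field$season_start, "%Y"))
    window <- c(as.Date(sprintf("%d-12-01", yr0)),
                as.Date(sprintf("%d-03-31", yr0 + 1L)))
  }
  h0 <- as.numeric(as.Date(window[1]) - field$season_start) * 24
  h1 <- as.numeric(as.Date(window[2]) - field$season_start) * 24
  it <- which(field$time_hours >= h0 & field$time_hours <= h1)
  if (!length(it)) stop("empty averaging window", call. = FALSE)
  sx <- which(g$x >= box[1] & g$x <= box[2])
  sy <- which(g$y >= box[3] & g$y <= box[4])
  water <- !g$land_mask[sx, sy, drop = FALSE]
  # depth interpolation weights onto the stored z-levels
  us <- NULL; vs <- NULL
  for (d in depths) {
    if (d <= g$depth[1]) { iz <- 1L; wz <- 0 }
    else if (d >= g$depth[length(g$depth)]) {
      iz <- length(g$depth) - 1L; wz <- 1
    } else {
      iz <- max(which(g$depth <= d))
      iz <- min(iz, length(g$depth) - 1L)
      wz <- (d - g$depth[iz]) / (g$depth[iz + 1] - g$depth[iz])
    }
    for (tt in it) {
      u2 <- (1 - wz) * field$u[sx, sy, iz, tt] +
        wz * field$u[sx, sy, iz + 1L, tt]
      v2 <- (1 - wz) * field$v[sx, sy, iz, tt] +
        wz * field$v[sx, sy, iz + 1L, tt]
      us <- c(us, u2[water])
      vs <- c(vs, v2[water])
    }
  }
  speed <- sqrt(us^2 + vs^2)
  keep <- speed > 1e-12
  us <- us[keep]; vs <- vs[keep]
  bearing <- (atan2(us, vs) * 180 / pi) %% 360
  bearing[bearing == 0] <- 360
  bin <- ceiling(bearing / 30)
  freq <- tabulate(bin, nbins = 12L)
  freq <- freq / sum(freq)
  list(breaks = seq(0, 360, by = 30), freq = freq,
       mean_speed = mean(speed[keep]), n = sum(keep))
}
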