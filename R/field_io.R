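#' Write / read a velocity field as NetCDF
#'
#' Fields are stored with CF-style named dimensions `(time, depth, y, x)`,
#' variables `u`, `v`, `w` (m s-1), the land mask, and global attributes
#' carrying the season label, the geographic anchor and the season start
#' date, so files are self-describing and readable by any NetCDF tool.
#'
#' @param field a `kf_field` from [compose_flow()].
#' @param path output file path (`.nc`).
#' @return `write_field` returns `path` invisibly; `read_field` returns
#'   the reconstructed `kf_field` (numerically equal to the one written).
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "kf_field"))
  g <- field$grid
  dim_x <- ncdf4::ncdim_def("x", "km", g$x)
  dim_y <- ncdf4::ncdim_def("y", "km", g$y)
  dim_z <- ncdf4::ncdim_def("depth", "m", g$depth)
  dim_t <- ncdf4::ncdim_def("time", "hours since season start",
                            field$time_hours, unlim = TRUE)
  dims <- list(dim_x, dim_y, dim_z, dim_t)
  var_u <- ncdf4::ncvar_def("u", "m s-1", dims, prec = "double")
  var_v <- ncdf4::ncvar_def("v", "m s-1", dims, prec = "double")
  var_w <- ncdf4::ncvar_def("w", "m s-1", dims, prec = "double")
  var_m <- ncdf4::ncvar_def("mask_land", "1", list(dim_x, dim_y),
                            prec = "byte")
  nc <- ncdf4::nc_create(path, list(var_u, var_v, var_w, var_m),
                         force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var_u, field$u)
  ncdf4::ncvar_put(nc, var_v, field$v)
  w <- field$w
  if (is.null(w)) w <- array(0, dim(field$u))
  ncdf4::ncvar_put(nc, var_w, w)
  ncdf4::ncvar_put(nc, var_m, array(as.integer(g$land_mask),
                                    dim(g$land_mask)))
  ncdf4::ncatt_put(nc, 0, "season_id", field$season_id)
  ncdf4::ncatt_put(nc, 0, "ref_lon", g$ref_lon, prec = "double")
  ncdf4::ncatt_put(nc, 0, "ref_lat", g$ref_lat, prec = "double")
  ncdf4::ncatt_put(nc, 0, "seabed_m", g$seabed_m, prec = "double")
  ncdf4::ncatt_put(nc, 0, "pycnocline_m", field$pycnocline_m,
                   prec = "double")
  ncdf4::ncatt_put(nc, 0, "deep_factor", field$deep_factor,
                   prec = "double")
  ncdf4::ncatt_put(nc, 0, "season_start_date",
                   format(field$season_start, "%Y-%m-%d"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  need <- c("u", "v", "w", "mask_land")
  have <- names(nc$var)
  missing <- setdiff(need, have)
  if (length(missing))
    stop(sprintf("field file '%s' lacks required variable(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (dn in c("x", "y", "depth", "time"))
    if (!dn %in% names(nc$dim))
      stop(sprintf("field file '%s' lacks required dimension: %s",
                   path, dn), call. = FALSE)
  x <- nc$dim$x$vals
  y <- nc$dim$y$vals
  depth <- nc$dim$depth$vals
  time_hours <- as.numeric(nc$dim$time$vals)
  att <- function(a) ncdf4::ncatt_get(nc, 0, a)$value
  g <- make_grid(c(max(x) - min(x), max(y) - min(y)),
                 spacing_km = x[2] - x[1], depths = depth,
                 anchor = c(att("ref_lon"), att("ref_lat")),
                 seabed_m = att("seabed_m"))
  g$x <- g$x + min(x)
  g$y <- g$y + min(y)
  g$land_mask <- ncdf4::ncvar_get(nc, "mask_land",
                                  collapse_degen = FALSE) > 0
  nt <- length(time_hours)
  u <- ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE)
  w <- ncdf4::ncvar_get(nc, "w", collapse_degen = FALSE)
  dim4 <- c(length(x), length(y), length(depth), nt)
  dim(u) <- dim4; dim(v) <- dim4; dim(w) <- dim4
  if (all(w == 0)) w <- NULL
  structure(list(u = u, v = v, w = w, time_hours = time_hours,
                 grid = g, season_id = att("season_id"),
                 season_start = as.Date(att("season_start_date")),
                 pycnocline_m = att("pycnocline_m"),
                 deep_factor = att("deep_factor"),
                 daily_modulation = NULL),
            class = "kf_field")
}
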