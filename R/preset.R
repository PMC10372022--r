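#' Synthetic West Antarctic Peninsula-like circulation preset
#'
#' A desk-scale idealization of the WAP shelf: a 900 x 300 km domain
#' with the coast along the southern edge, and the persistent current
#' features that organize krill connectivity there, each as a
#' divergence-free stream-function component:
#'
#' * a fast, consistent *shelf-break jet* (ACC southern-boundary analog,
#'   0.22 m s^-1) flowing along-shelf at the offshore edge;
#' * a *coastal current* (0.15 m s^-1) flowing in the opposite
#'   direction along the coast, out of the eastern (Weddell-like)
#'   source;
#' * an offshore-flowing *barrier jet* (Low Island loop analog,
#'   0.20 m s^-1) at mid-domain (x = 400 km) whose return circulation
#'   closes entirely on its downstream side, so it blocks alongshore
#'   coastal exchange;
#' * a *strait jet* (Bransfield analog, 0.18 m s^-1) carrying water from
#'   the barrier junction along the island band to the northeast;
#' * two closed *loop eddies* retaining water in the gap and
#'   northern-shelf regions;
#' * two onshore *cross-shelf channels* (0.10 m s^-1) connecting the
#'   shelf break to the south-western coastal regions.
#'
#' @param spacing_km grid spacing in km (default 5; regional
#'   hydrodynamic models of this shelf run near 1.5 km, the preset
#'   trades resolution for desk-scale memory).
#' @return `wap_grid()`: a [make_grid()] grid with a coastal land strip
#'   (y < 30 km); `wap_components()`: named list of flow components.
#' @export
wap_grid <- function(spacing_km = 5) {
  g <- make_grid(c(900, 300), spacing_km,
                 depths = c(10, 25, 50, 75, 100, 150),
                 anchor = c(-62, -64), seabed_m = 400)
  paint_land(g, function(x, y) y < 30)
}

#' @rdname wap_grid
#' @export
wap_components <- function() {
  list(
    shelf_break_jet = flow_jet(rbind(c(0, 270), c(900, 270)),
                               peak_speed = 0.22, width_km = 15,
                               clean_side = "right", taper_km = 40,
                               envelope_km = Inf,
                               name = "shelf_break_jet"),
    coastal_current = flow_jet(rbind(c(900, 60), c(0, 60)),
                               peak_speed = 0.15, width_km = 12,
                               clean_side = "left", taper_km = 40,
                               envelope_km = Inf,
                               name = "coastal_current"),
    barrier_jet = flow_jet(rbind(c(400, 40), c(400, 160)),
                           peak_speed = 0.20, width_km = 15,
                           clean_side = "left", taper_km = 25,
                           envelope_km = 120, name = "barrier_jet"),
    strait_jet = flow_jet(rbind(c(430, 140), c(900, 140)),
                          peak_speed = 0.18, width_km = 15,
                          clean_side = "right", taper_km = 25,
                          envelope_km = 120, name = "strait_jet"),
    gap_eddy = flow_eddy(c(330, 90), peak_speed = 0.15, width_km = 20,
                         rotation_sign = -1, name = "gap_eddy"),
    north_eddy = flow_eddy(c(580, 70), peak_speed = 0.18, width_km = 25,
                           rotation_sign = 1, name = "north_eddy"),
    channel_a = flow_channel(rbind(c(120, 250), c(120, 70)),
                             peak_speed = 0.10, width_km = 10,
                             clean_side = "left", taper_km = 25,
                             envelope_km = 80, name = "channel_a"),
    channel_b = flow_channel(rbind(c(250, 250), c(250, 70)),
                             peak_speed = 0.10, width_km = 10,
                             clean_side = "left", taper_km = 25,
                             envelope_km = 80, name = "channel_b"))
}

#' One season of the synthetic WAP field
#'
#' Daily snapshots from the season start (1 November) through 31 March,
#' with per-feature daily lognormal speed modulation.
#'
#' @param season_id season label; the starting year, e.g. `"2008"`.
#' @param seed integer noise seed.
#' @param grid a [wap_grid()] (or compatible) grid.
#' @param noise_sigma daily speed-modulation log-sd (default 0.2).
#' @return a `kf_field`.
#' @export
wap_field <- function(season_id = "2008", seed = 1L, grid = wap_grid(),
                      noise_sigma = 0.2) {
  yr <- as.integer(season_id)
  start <- as.Date(sprintf("%d-11-01", yr))
  end <- as.Date(sprintf("%d-03-31", yr + 1L))
  n_days <- as.numeric(end - start) + 1
  compose_flow(wap_components(), grid, n_days = n_days, seed = seed,
               noise_sigma = noise_sigma, season_id = season_id,
               season_start = start)
}

#' Synthetic penguin colony table for the WAP preset
#'
#' Colony locations are synthetic (placed inside the preset's region
#' cells); the per-region, per-species nest counts mirror published
#' MAPPPD-derived regional totals for the six study regions.
#'
#' @return colony data.frame (see [read_colonies()]).
#' @export
wap_colonies <- function() {
  read_colonies(system.file("extdata", "colonies_synthetic.csv",
                            package = "krillflow", mustWork = TRUE))
}

#' Regions of the WAP preset
#'
#' Six colony-based study regions on the 40 km lattice plus the two
#' free-polygon source regions at the domain ends (Bellingshausen-like
#' in the west, Weddell-like in the east).
#'
#' @param grid a [wap_grid()] grid.
#' @param colonies a colony table (default [wap_colonies()]).
#' @return a `kf_regionset`.
#' @export
wap_regions <- function(grid = wap_grid(), colonies = wap_colonies()) {
  cells <- build_region_cells(grid, 40)
  rs <- regions_from_colonies(colonies, cells)
  rs <- add_source_region(rs, "bellingshausen_sea",
                          rbind(c(0, 30), c(38, 30), c(38, 260),
                                c(0, 260)))
  add_source_region(rs, "weddell_sea",
                    rbind(c(862, 30), c(900, 30), c(900, 260),
                          c(862, 260)))
}
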