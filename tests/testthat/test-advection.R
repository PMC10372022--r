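test_that("velocity interpolation is exact on nodes, linear between", {
  f <- uniform_field(0.1, 0)
  expect_equal(unname(interpolate_velocity(f, 37.3, 91.8, 30, 5)["u"]),
               0.1)
  # piecewise-linear field: u varies linearly in x between two nodes
  g <- make_grid(c(20, 20), 10, depths = c(10, 50))
  u <- array(0, c(3, 3, 2, 2)); v <- array(0, c(3, 3, 2, 2))
  u[2, , , ] <- 0.2  # node at x = 10
  f2 <- structure(list(u = u, v = v, w = NULL, time_hours = c(0, 24),
                       grid = g, season_id = "t",
                       season_start = as.Date("2008-11-01"),
                       pycnocline_m = 80, deep_factor = 1,
                       daily_modulation = NULL), class = "kf_field")
  expect_equal(unname(interpolate_velocity(f2, 10, 10, 10, 0)["u"]), 0.2)
  expect_equal(unname(interpolate_velocity(f2, 5, 10, 10, 0)["u"]), 0.1)
  expect_equal(unname(interpolate_velocity(f2, 7.5, 10, 10, 0)["u"]),
               0.15)
})

test_that("out-of-bounds queries raise the dedicated condition", {
  f <- uniform_field(0.1, 0)
  expect_error(interpolate_velocity(f, -5, 10, 10, 0),
               class = "kf_out_of_bounds")
  expect_error(interpolate_velocity(f, 10, 10, 10, 1e6),
               class = "kf_out_of_bounds")
  # depth outside the z-levels clamps instead (constant extrapolation)
  expect_equal(unname(interpolate_velocity(f, 10, 10, 3000, 0)["u"]),
               0.1)
})

test_that("a particle at rest stays at rest", {
  f <- uniform_field(0, 0)
  st <- list(x = 50, y = 60, depth = 30, status = 0L)
  st2 <- advect_step(st, f)
  expect_equal(st2$x, 50)
  expect_equal(st2$y, 60)
  expect_equal(st2$depth, 30)
  expect_equal(st2$status, 0L)
})

test_that("behavioural sinking moves 0.7 m per 50 s step", {
  f <- uniform_field(0, 0)
  st <- advect_step(list(x = 50, y = 60, depth = 30, status = 0L), f,
                    behavior_w = 0.014, dt = 50)
  expect_equal(st$depth, 30.7)
  st2 <- advect_step(list(x = 50, y = 60, depth = 30, status = 0L), f,
                     random_w = -2.5)
  expect_equal(st2$depth, 27.5)
})

test_that("RK4 closes a solid-body orbit to 1e-3 of its radius", {
  om <- 1e-4
  f <- solid_body_field(omega = om)
  period <- 2 * pi / om
  n <- ceiling(period / 50)
  st <- list(x = 150, y = 100, depth = 15, status = 0L)
  for (k in seq_len(n))
    st <- advect_step(st, f, dt = 50, t_hours = (k - 1) * 50 / 3600)
  th <- om * n * 50
  expect_lt(sqrt((st$x - (100 + 50 * cos(th)))^2 +
                   (st$y - (100 + 50 * sin(th)))^2),
            1e-3 * 50)
})

test_that("uniform-field displacement is u*t to round-off", {
  f <- uniform_field(0.12, -0.05)
  traj <- suppressWarnings(run_simulation(
    f, release_plan(as.Date("2008-11-01"), spacing_km = 200,
                    depth = 20, box = c(40, 40, 150, 150)),
    passive_config(20), rw = rw_off(),
    end_date = as.Date("2008-11-03"), seed = 1))
  tt <- 48 * 3600
  expect_equal(traj$x[1, ncol(traj$x)], 40 + 0.12 * tt / 1000,
               tolerance = 1e-9)
  expect_equal(traj$y[1, ncol(traj$y)], 150 - 0.05 * tt / 1000,
               tolerance = 1e-9)
})

test_that("30 tracked days produce 721 hourly samples", {
  f <- uniform_field(0, 0)
  suppressWarnings(
    traj <- run_simulation(
      f, release_plan(as.Date("2008-11-01"), spacing_km = 200,
                      depth = 20, box = c(100, 100, 100, 100)),
      passive_config(20), rw = rw_off(),
      end_date = as.Date("2008-12-01"), seed = 1))
  expect_equal(ncol(traj$x), 721)
  expect_equal(traj$hours, 0:720)
  expect_equal(traj$x[1, 1], 100)  # first sample = release position
})

test_that("identical seeds reproduce the whole trajectory set", {
  f <- solid_body_field()
  plan <- release_plan(as.Date("2008-11-01"), spacing_km = 50,
                       depth = 20)
  a <- suppressWarnings(
    run_simulation(f, plan, dvm_config(50), rw = rw_config(),
                   end_date = as.Date("2008-11-05"), seed = 42))
  b <- suppressWarnings(
    run_simulation(f, plan, dvm_config(50), rw = rw_config(),
                   end_date = as.Date("2008-11-05"), seed = 42))
  expect_identical(a$x, b$x)
  expect_identical(a$depth, b$depth)
})

test_that("a particle on a land node beaches at once and stays put", {
  g <- make_grid(c(100, 100), 10, depths = c(10, 50))
  g <- paint_land(g, function(x, y) x < 35)
  f <- compose_flow(list(flow_eddy(c(70, 50), peak_speed = 0.2,
                                   width_km = 15)), g, 5,
                    noise_sigma = 0, season_start = "2008-11-01")
  st <- list(x = 10, y = 50, depth = 20, status = 0L)
  for (k in 1:5) st <- advect_step(st, f)
  expect_equal(st$status, 1L)
  expect_equal(st$x, 10)
  # and the seeding path never creates such particles in the first place
  expect_warning(
    s <- seed_particles(g, 100, depth = 20, box = c(10, 10, 50, 50)),
    "empty")
  expect_equal(nrow(s), 0)
})

test_that("particle count is conserved across status classes", {
  f <- solid_body_field()
  # strong uniform drift pushes some particles out of the domain
  f$u[] <- f$u + 0.3
  traj <- suppressWarnings(run_simulation(
    f, release_plan(as.Date("2008-11-01"), spacing_km = 40, depth = 20),
    passive_config(20), rw = rw_off(),
    end_date = as.Date("2008-11-10"), seed = 1))
  for (k in c(1, 100, ncol(traj$status))) {
    s <- traj$status[, k]
    expect_equal(sum(s %in% 0:2), nrow(traj$x))
  }
  expect_true(any(traj$status[, ncol(traj$status)] == 2L))
})

test_that("no active sample sits on land or beyond the depth clamps", {
  g <- make_grid(c(100, 100), 5, depths = c(10, 50), seabed_m = 100)
  g <- paint_land(g, function(x, y) y < 20)
  f <- compose_flow(list(flow_jet(rbind(c(0, 60), c(100, 60)),
                                  peak_speed = 0.2, width_km = 10,
                                  envelope_km = 40)), g, 5,
                    noise_sigma = 0, season_start = "2008-11-01")
  traj <- suppressWarnings(run_simulation(
    f, release_plan(as.Date("2008-11-01"), spacing_km = 20, depth = 95),
    passive_config(95), rw = rw_config(K = 1e-3),
    end_date = as.Date("2008-11-04"), seed = 3))
  act <- !is.na(traj$status) & traj$status == 0L
  expect_true(all(traj$depth[act] >= 0.5 - 1e-9))
  expect_true(all(traj$depth[act] <= 99.5 + 1e-9))
  expect_false(any(is_land_at(g, traj$x[act], traj$y[act])))
})
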