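test_that("origins label release positions, offshore when unmatched", {
  rs <- two_region_set()
  traj <- make_traj(x = rbind(c(60, 61, 62), c(395, 395, 395)),
                    y = rbind(c(60, 60, 60), c(10, 10, 10)))
  expect_identical(label_origins(traj, rs), c("A", "offshore"))
})

test_that("a straight crossing yields transit 10 h and residence 11 h", {
  rs <- two_region_set()
  # region B's block spans x in [240, 360] (closed): at 12 km/h from
  # x = 120 the particle is inside for samples 10..20 (11 samples)
  xs <- 120 + 12 * (0:30)
  traj <- make_traj(x = xs, y = rep(300, 31))
  rec <- reduce_trajectories(traj, rs)
  rec_b <- rec[rec$region == "B", ]
  expect_equal(nrow(rec_b), 1)
  expect_false(rec_b$released_within)
  expect_equal(rec_b$first_entry_h, 10)
  expect_equal(rec_b$residence_h, 11)
})

test_that("a stationary offshore particle produces no records", {
  rs <- two_region_set()
  traj <- make_traj(x = rep(399, 50), y = rep(10, 50))
  expect_equal(nrow(reduce_trajectories(traj, rs)), 0)
})

test_that("a particle never leaving its origin region accrues full
           residence and no transit", {
  rs <- two_region_set()
  traj <- make_traj(x = rep(60, 721), y = rep(60, 721))
  rec <- reduce_trajectories(traj, rs)
  expect_equal(nrow(rec), 1)
  expect_true(rec$released_within)
  expect_true(is.na(rec$first_entry_h))
  expect_equal(rec$residence_h, 721)
})

test_that("re-entries accumulate into one residence total", {
  rs <- two_region_set()
  # in B (x 240-360) for hours 5..10 and 20..25 at y = 300
  xs <- c(rep(100, 5), rep(300, 6), rep(100, 9), rep(300, 6), 100)
  traj <- make_traj(x = xs, y = rep(300, length(xs)))
  rec <- reduce_trajectories(traj, rs)
  rec_b <- rec[rec$region == "B", ]
  expect_equal(rec_b$residence_h, 12)
  expect_equal(rec_b$first_entry_h, 5)
})

test_that("frozen (beached/exited) samples stop accruing residence", {
  rs <- two_region_set()
  st <- matrix(0L, 1, 21); st[1, 11:21] <- 1L
  traj <- make_traj(x = rep(60, 21), y = rep(60, 21), status = st)
  rec <- reduce_trajectories(traj, rs)
  expect_equal(rec$residence_h, 10)
})

test_that("non-hourly trajectories are rejected", {
  rs <- two_region_set()
  traj <- make_traj(x = rep(60, 5), y = rep(60, 5), hours = c(0, 2, 4, 6, 8))
  expect_error(reduce_trajectories(traj, rs), "hourly")
})

test_that("trajectory reduction matches a brute-force per-sample scan", {
  set.seed(33)
  rs <- two_region_set()
  rs <- add_source_region(rs, "westsea",
                          rbind(c(200, 0), c(260, 0), c(260, 120),
                                c(200, 120)))
  n <- 60; len <- 48
  X <- matrix(0, n, len); Y <- matrix(0, n, len)
  for (i in seq_len(n)) {
    # random-walk tracks that wander across the domain
    X[i, ] <- cumsum(c(runif(1, 0, 400), rnorm(len - 1, 0, 15)))
    Y[i, ] <- cumsum(c(runif(1, 0, 400), rnorm(len - 1, 0, 15)))
  }
  traj <- make_traj(x = X, y = Y)
  mine <- reduce_trajectories(traj, rs)
  oracle <- oracle_reduce(traj, rs)
  key <- function(d) d[order(d$particle_id, d$region),
                       c("particle_id", "origin", "region",
                         "released_within", "first_entry_h",
                         "residence_h")]
  a <- key(as.data.frame(mine)); b <- key(oracle)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("connectivity matrices count distinct particles", {
  rec <- data.frame(
    particle_id = c(1, 2, 3, 4, 4),
    origin = c("A", "A", "A", "B", "B"),
    region = c("B", "B", "B", "B", "A"),
    released_within = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    first_entry_h = c(5, 6, 7, NA, 9),
    residence_h = c(1, 2, 3, 10, 1))
  m <- connectivity_matrix(rec)
  expect_equal(m["A", "B"], 3)
  expect_equal(m["B", "B"], 1)
  expect_equal(m["B", "A"], 1)
  expect_equal(sum(m), 5)
})

test_that("interannual averaging is a per-cell mean over seasons", {
  r1 <- data.frame(particle_id = 1:4, origin = "A", region = "B",
                   released_within = FALSE, first_entry_h = 1,
                   residence_h = 1)
  r2 <- r1[1:6 %% 7, ]  # 6 rows
  r2 <- data.frame(particle_id = 1:6, origin = "A", region = "B",
                   released_within = FALSE, first_entry_h = 1,
                   residence_h = 1)
  out <- connectivity_matrix(list(r1, r2))
  expect_equal(out$mean["A", "B"], 5)
  expect_equal(out$per_season[[1]]["A", "B"], 4)
})

test_that("behaviour contrast reports difference and percent", {
  m1 <- matrix(c(100, 0), 1, 2,
               dimnames = list(origin = "A", destination = c("B", "C")))
  m2 <- matrix(c(112, 5), 1, 2,
               dimnames = list(origin = "A", destination = c("B", "C")))
  ct <- dvm_contrast(m1, m2)
  expect_equal(ct$difference["A", "B"], 12)
  expect_equal(ct$percent["A", "B"], 12)
  expect_true(is.na(ct$percent["A", "C"]))
  expect_true(ct$undefined["A", "C"])
  expect_equal(ct$difference["A", "C"], 5)
  same <- dvm_contrast(m1, m1)
  expect_true(all(same$difference == 0))
  m3 <- m2; colnames(m3) <- c("B", "D")
  expect_error(dvm_contrast(m1, m3), "axes")
})

test_that("rose bearings follow the compass convention", {
  g <- make_grid(c(100, 100), 10)
  base <- list(time_hours = c(0, 24 * 150), grid = g, season_id = "t",
               season_start = as.Date("2008-11-01"), pycnocline_m = 80,
               deep_factor = 1, daily_modulation = NULL)
  dims <- c(11, 11, 6, 2)
  east <- structure(c(base, list(u = array(0.1, dims),
                                 v = array(0, dims), w = NULL)),
                    class = "kf_field")
  rh <- rose_statistics(east, window = as.Date(c("2008-12-01",
                                                 "2009-03-31")))
  expect_equal(sum(rh$freq), 1, tolerance = 1e-12)
  expect_equal(rh$freq[3], 1)  # eastward water movement: 60-90 deg bin
  north <- structure(c(base, list(u = array(0, dims),
                                  v = array(0.1, dims), w = NULL)),
                     class = "kf_field")
  rn <- rose_statistics(north, window = as.Date(c("2008-12-01",
                                                  "2009-03-31")))
  expect_equal(rn$freq[12], 1)  # due north closes the 330-360 deg bin
  expect_equal(rn$mean_speed, 0.1)
})

test_that("opposed half-domains split the rose evenly", {
  g <- make_grid(c(100, 100), 10)
  dims <- c(11, 11, 6, 2)
  v <- array(0.1, dims)
  v[, 7:11, , ] <- -0.1
  f <- structure(list(u = array(0, dims), v = v, w = NULL,
                      time_hours = c(0, 24 * 150), grid = g,
                      season_id = "t",
                      season_start = as.Date("2008-11-01"),
                      pycnocline_m = 80, deep_factor = 1,
                      daily_modulation = NULL), class = "kf_field")
  rh <- rose_statistics(f, window = as.Date(c("2008-12-01",
                                              "2009-03-31")))
  expect_equal(rh$freq[12], 6 / 11, tolerance = 1e-12)  # northward half
  expect_equal(rh$freq[6], 5 / 11, tolerance = 1e-12)   # southward half
  expect_error(rose_statistics(f, window = as.Date(c("2010-01-01",
                                                     "2010-02-01"))),
               "empty")
})
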