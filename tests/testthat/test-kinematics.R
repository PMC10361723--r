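test_that("rigid rotation yields constant angular velocity and the wrap convention holds", {
  geom <- default_geom()
  s <- to_polar(rigid_track(0.3, n = 8), geom)
  expect_equal(s$aav, rep(0.3, 7), tolerance = 1e-9)
  expect_equal(s$dtheta, rep(0.06, 7), tolerance = 1e-9)

  # crossing the 2*pi seam: 2*pi - 0.1 -> 0.1 must give dtheta = +0.2
  tr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:1,
                   x_um = 20 * cos(c(2 * pi - 0.1, 0.1)),
                   y_um = 20 * sin(c(2 * pi - 0.1, 0.1)))
  s <- to_polar(tr, geom)
  expect_equal(s$dtheta, 0.2, tolerance = 1e-9)
  expect_equal(s$aav, 1.0, tolerance = 1e-9)

  # clockwise motion gives negative angular velocity
  s <- to_polar(rigid_track(-0.25), geom)
  expect_true(all(s$aav < 0))
  expect_equal(angular_velocity(s, 0.2), s$aav)
  expect_error(angular_velocity(s, 0), "positive")
})

test_that("tracks with fewer than 2 points or unordered frames are rejected", {
  geom <- default_geom()
  one <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0,
                    x_um = 5, y_um = 5)
  expect_error(to_polar(one, geom), "fewer than 2")
  bad <- rigid_track(0.2)
  bad$frame <- rev(bad$frame) * 0 + c(3, 3, 2, 1, 0, 4)
  expect_error(to_polar(bad, geom), "strictly increasing")
})

test_that("velocity components decompose the step and behave geometrically", {
  geom <- default_geom()
  # pure rotation: radial component ~ 0, tangential ~ r * omega (the chord
  # approximation is second-order in the per-step angle)
  s <- to_polar(rigid_track(0.3, r = 20, n = 10), geom)
  expect_true(all(abs(s$v_rad) < 0.05 * 20 * 0.3))
  expect_equal(s$v_tan, rep(20 * 0.3, 9), tolerance = 1e-3)

  # pure outward radial step of 3 um
  tr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:1,
                   x_um = c(10, 13), y_um = c(0, 0))
  s <- to_polar(tr, geom)
  expect_equal(s$v_tan, 0, tolerance = 1e-9)
  expect_equal(s$v_rad, 15, tolerance = 1e-9)

  # Pythagorean identity on random steps
  set.seed(4)
  tr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:30,
                   x_um = cumsum(rnorm(31, 0, 2)) + 15,
                   y_um = cumsum(rnorm(31, 0, 2)) + 15)
  s <- to_polar(tr, geom)
  speed2 <- (diff(tr$x_um)^2 + diff(tr$y_um)^2) / 0.2^2
  expect_equal(s$v_tan^2 + s$v_rad^2, speed2, tolerance = 1e-9)
  vc <- velocity_components(s, 0.2)
  expect_equal(vc$v_tan, s$v_tan)
})

test_that("kinematics are equivariant under joint rotation of image and axis", {
  set.seed(9)
  tr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:20,
                   x_um = cumsum(rnorm(21)) + 18, y_um = cumsum(rnorm(21)) - 6)
  g0 <- lro_geometry(c(0, 0), 30, anterior_axis_angle = pi / 2)
  s0 <- to_polar(tr, g0)
  for (rot in c(0.7, -1.9, 3.0)) {
    tr2 <- tr
    tr2$x_um <- tr$x_um * cos(rot) - tr$y_um * sin(rot)
    tr2$y_um <- tr$x_um * sin(rot) + tr$y_um * cos(rot)
    g2 <- lro_geometry(c(0, 0), 30, anterior_axis_angle = pi / 2 + rot)
    s2 <- to_polar(tr2, g2)
    for (col in c("aav", "v_tan", "v_rad", "lr", "pa")) {
      expect_equal(s2[[col]], s0[[col]], tolerance = 1e-9)
    }
  }
})

test_that("core exclusion keeps the half-radius boundary and drops inner steps", {
  geom <- default_geom(radius = 30)
  mk <- function(r) rigid_track(0.2, r = r, n = 3)
  inner <- to_polar(mk(0.49 * 30), geom)
  # boundary track built from axis-aligned points so radii are exactly R/2
  btr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:2,
                    x_um = c(15, 0, -15), y_um = c(0, 15, 0))
  boundary <- to_polar(btr, geom)
  outer <- to_polar(mk(0.8 * 30), geom)
  expect_equal(nrow(exclude_core(inner, geom)), 0)
  expect_equal(nrow(exclude_core(boundary, geom)), nrow(boundary))
  out <- exclude_core(outer, geom)
  expect_equal(nrow(out), nrow(outer))
  expect_equal(attr(out, "n_dropped"), 0L)

  # crafted mix: removal is exactly by min endpoint radius < R/2
  mix <- rbind(inner, outer)
  kept <- exclude_core(mix, geom)
  expect_equal(nrow(kept), nrow(outer))
  expect_equal(attr(kept, "n_dropped"), nrow(inner))
})

test_that("sector summaries reflect the generating field", {
  geom <- default_geom()
  tracks <- do.call(rbind, lapply(1:40, function(i) {
    rigid_track(0.3, r = 15 + i %% 14, theta0 = i * 0.157, n = 4,
                track = sprintf("T%02d", i))
  }))
  s <- to_polar(tracks, geom)
  ss <- sector_summary(s, n_sectors = 8)
  expect_equal(ss$pooled$value, rep(0.3, 8), tolerance = 1e-9)
  expect_equal(nrow(ss$per_embryo), 8)

  # a single sample in one sector: median equals the sample; empty sector NA
  single <- to_polar(rigid_track(0.42, theta0 = pi / 2 + 0.1, n = 2), geom)
  ss1 <- sector_summary(single, n_sectors = 8)
  expect_equal(ss1$pooled$value[1], 0.42, tolerance = 1e-9)
  expect_true(all(is.na(ss1$pooled$value[-1])))

  # anterior-graded synthetic field: anterior sector medians exceed posterior
  cfg <- flow_config(omega0 = 0.2, grad_pa = 0.16, grad_lr = 0, grad_time = 0,
                     embryo_sd = 0, jitter_sd = 0, n_tracks = 120,
                     n_frames = 3, stages = 6, seed = 3)
  sim <- generate_tracks(cfg, n_embryos = 1)
  sam <- to_polar(sim$tracks, default_geom())
  sg <- sector_summary(sam, n_sectors = 8)$pooled
  anterior <- sg$value[sg$sector %in% c(0, 7)]   # sectors flanking anterior
  posterior <- sg$value[sg$sector %in% c(3, 4)]
  expect_true(min(anterior) > max(posterior))
})

test_that("directionality uses the local radial frame and KS comparison works", {
  geom <- default_geom()
  # pure counterclockwise tangential step at angle 0 -> direction pi/2
  tr <- data.frame(embryo_id = "E1", track_id = "T1", frame = 0:1,
                   x_um = c(20, 20), y_um = c(0, 0.5))
  d <- directionality(to_polar(tr, geom))
  expect_equal(d$direction, pi / 2, tolerance = 1e-9)
  # pure outward step -> direction 0
  tr$y_um <- c(0, 0)
  tr$x_um <- c(20, 21)
  d <- directionality(to_polar(tr, geom))
  expect_equal(d$direction, 0, tolerance = 1e-9)
  # zero displacement is skipped
  tr$x_um <- c(20, 20)
  expect_equal(nrow(directionality(to_polar(tr, geom))), 0)

  # rigid rotation concentrates directions near pi/2 in all sectors
  tracks <- do.call(rbind, lapply(1:36, function(i) {
    rigid_track(0.3, theta0 = i * pi / 18, n = 3, track = paste0("T", i))
  }))
  d <- directionality(to_polar(tracks, geom))
  expect_true(all(abs(d$direction - pi / 2) < 0.1))
  expect_true(all(d$sector %in% 0:11))

  expect_error(compare_directionality(numeric(0), 1:3), "non-empty")
  same <- compare_directionality(d$direction, d$direction)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- compare_directionality(runif(50, 0, pi), runif(50, pi, 2 * pi))
  expect_equal(disjoint$statistic, 1)
})

test_that("track summaries give one observation per surviving track", {
  cfg <- flow_config(omega0 = 0.25, grad_pa = 0, grad_lr = 0, grad_time = 0,
                     embryo_sd = 0, jitter_sd = 0, n_tracks = 6, n_frames = 4,
                     stages = 6:7, seed = 5)
  sim <- generate_tracks(cfg, n_embryos = 3)
  obs <- track_summaries(sim$tracks, sim$meta)
  expect_equal(nrow(obs), 3 * 2 * 6)
  expect_equal(obs$aav, rep(0.25, nrow(obs)), tolerance = 1e-9)
  expect_equal(attr(obs, "n_dropped_tracks"), 0L)

  # a single-step track reduces to that step's values
  tr <- rigid_track(0.3, n = 2)
  tr$stage <- 6
  meta <- data.frame(embryo_id = "E1", stage = 6, group = "Sham",
                     center_x = 0, center_y = 0, radius = 30,
                     anterior_axis_deg = 90, dt_s = 0.2)
  obs1 <- track_summaries(tr, meta)
  s1 <- to_polar(tr, default_geom())
  expect_equal(obs1$aav, s1$aav)
  expect_equal(obs1$lr, s1$lr)
  expect_equal(obs1$n_steps, 1L)

  # a track fully inside the core is dropped and counted
  inner <- rigid_track(0.3, r = 5, n = 3, track = "Tin")
  inner$stage <- 6
  both <- rbind(tr, inner)
  obs2 <- track_summaries(both, meta)
  expect_equal(nrow(obs2), 1)
  expect_equal(attr(obs2, "n_dropped_tracks"), 1L)
})

test_that("track CSV round-trips through the reader", {
  cfg <- flow_config(n_tracks = 2, n_frames = 3, stages = 6, seed = 8)
  sim <- generate_tracks(cfg, n_embryos = 2)
  dir <- withr::local_tempdir()
  write_track_simulation(sim, dir)
  tracks <- read_tracks(file.path(dir, "tracks.csv"))
  meta <- read_track_metadata(file.path(dir, "meta.csv"))
  expect_equal(tracks$x_um, sim$tracks$x_um, tolerance = 1e-12)
  expect_equal(meta$radius, sim$meta$radius)
  obs_a <- track_summaries(sim$tracks, sim$meta)
  obs_b <- track_summaries(tracks, meta)
  expect_equal(obs_a$aav, obs_b$aav, tolerance = 1e-9)
})
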