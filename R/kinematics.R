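# Polar kinematics of LRO particle tracks.
#
# Axis convention: the image frame is rotated so that, in the analysis frame,
# +pa points anterior and +lr points to the embryo's right. Rotation is
# counterclockwise-positive as in dorsal-view imaging. `anterior_axis_angle`
# is the direction of the anterior axis in image coordinates (radians), so a
# value of pi/2 (anterior = image +y) leaves coordinates unchanged.

#' LRO frame geometry
#'
#' Describes the polar reference frame of one imaged LRO: center, radius,
#' orientation of the anterior axis in image coordinates, somite stage and
#' frame interval.
#'
#' @param center Numeric length-2, LRO center in image coordinates (um).
#' @param radius LRO radius (um), must be positive.
#' @param anterior_axis_angle Direction of the anterior axis in image
#'   coordinates (radians). Default `pi/2` (anterior along image +y).
#' @param stage Somite stage (integer, 3--12) or `NA`.
#' @param dt Frame interval in seconds (default 0.2).
#' @return An object of class `lro_geometry`.
#' @export
lro_geometry <- function(center = c(0, 0), radius, anterior_axis_angle = pi / 2,
                         stage = NA_integer_, dt = 0.2) {
  stopifnot(length(center) == 2, is.finite(radius))
  if (radius <= 0) stop("LRO radius must be positive")
  if (dt <= 0) stop("frame interval dt must be positive")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 anterior_axis_angle = as.numeric(anterior_axis_angle),
                 stage = stage, dt = as.numeric(dt)),
            class = "lro_geometry")
}

# Rotate image coordinates into the (lr, pa) analysis frame.
# Returns a two-column matrix: lr (embryo right), pa (anterior).
.rotate_to_axes <- function(x, y, geom) {
  vx <- x - geom$center[1]
  vy <- y - geom$center[2]
  a <- geom$anterior_axis_angle
  # anterior unit vector (cos a, sin a); right = anterior rotated by -90 deg
  cbind(lr = vx * sin(a) - vy * cos(a),
        pa = vx * cos(a) + vy * sin(a))
}

# Wrap an angle difference into (-pi, pi]; ties at pi go positive.
.wrap_angle <- function(d) {
  pi - ((pi - d) %% (2 * pi))
}

#' Convert particle tracks to polar kinematic samples
#'
#' Each consecutive frame pair of each track yields one kinematic sample:
#' polar coordinates at the step's first point, the wrapped angle change,
#' instantaneous angular velocity (`aav = dtheta / dt`, counterclockwise
#' positive), and tangential/radial velocity components obtained by projecting
#' the displacement onto the local tangential (counterclockwise-positive) and
#' radial (outward-positive) unit vectors at the first point.
#'
#' @param tracks Data frame with columns `embryo_id`, `track_id`, `frame`,
#'   `x_um`, `y_um` (one or more tracks).
#' @param geom An [lro_geometry()].
#' @return Data frame with one row per consecutive-frame step: `embryo_id`,
#'   `track_id`, `step`, `r`, `r_end` (radii of the two endpoints, um),
#'   `theta` (angle in `[0, 2*pi)` of the first point), `dtheta` (wrapped to
#'   `(-pi, pi]`), `aav` (rad/s), `v_tan`, `v_rad` (um/s), `disp_tan`,
#'   `disp_rad` (um), `lr`, `pa` (normalized coordinates of the first point,
#'   clipped to `[-1, 1]`).
#' @export
to_polar <- function(tracks, geom) {
  stopifnot(inherits(geom, "lro_geometry"))
  req <- c("embryo_id", "track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(tracks))) {
    stop("tracks must have columns: ", paste(req, collapse = ", "))
  }
  key <- interaction(tracks$embryo_id, tracks$track_id, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(tracks)), key), function(idx) {
    tr <- tracks[idx, ]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) stop("track with fewer than 2 points: ",
                           tr$embryo_id[1], "/", tr$track_id[1])
    if (any(diff(tr$frame) <= 0)) stop("frame indices must be strictly increasing")
    xy <- .rotate_to_axes(tr$x_um, tr$y_um, geom)
    n <- nrow(xy)
    i1 <- seq_len(n - 1)
    i2 <- i1 + 1
    r1 <- sqrt(rowSums(xy[i1, , drop = FALSE]^2))
    r2 <- sqrt(rowSums(xy[i2, , drop = FALSE]^2))
    th1 <- atan2(xy[i1, "pa"], xy[i1, "lr"]) %% (2 * pi)
    th2 <- atan2(xy[i2, "pa"], xy[i2, "lr"]) %% (2 * pi)
    dth <- .wrap_angle(th2 - th1)
    dlr <- xy[i2, "lr"] - xy[i1, "lr"]
    dpa <- xy[i2, "pa"] - xy[i1, "pa"]
    # outward radial and counterclockwise tangential units at the first point
    ur_lr <- xy[i1, "lr"] / r1
    ur_pa <- xy[i1, "pa"] / r1
    disp_rad <- dlr * ur_lr + dpa * ur_pa
    disp_tan <- dlr * (-ur_pa) + dpa * ur_lr
    dt_frames <- diff(tr$frame) * geom$dt
    data.frame(embryo_id = tr$embryo_id[i1], track_id = tr$track_id[i1],
               step = i1, r = r1, r_end = r2, theta = th1, dtheta = dth,
               aav = dth / dt_frames,
               v_tan = disp_tan / dt_frames, v_rad = disp_rad / dt_frames,
               disp_tan = disp_tan, disp_rad = disp_rad,
               lr = pmin(1, pmax(-1, xy[i1, "lr"] / geom$radius)),
               pa = pmin(1, pmax(-1, xy[i1, "pa"] / geom$radius)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Remove samples near the LRO core
#'
#' Tracked points near the center (within half the LRO radius) are excluded
#' from all kinematic summaries; a step is retained only if both endpoints lie
#' at radius `>= radius / 2` (boundary inclusive).
#'
#' @param samples Output of [to_polar()].
#' @param geom The matching [lro_geometry()].
#' @return The filtered samples; the number of removed rows is attached as
#'   attribute `n_dropped`.
#' @export
exclude_core <- function(samples, geom) {
  keep <- samples$r >= geom$radius / 2 & samples$r_end >= geom$radius / 2
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Instantaneous angular velocity
#'
#' Angular velocity is the wrapped particle angle change divided by the time
#' between consecutive frames; positive values are counterclockwise.
#'
#' @param samples Output of [to_polar()] (uses the `dtheta` column).
#' @param dt Frame interval in seconds.
#' @return Numeric vector of angular velocities (rad/s).
#' @export
angular_velocity <- function(samples, dt) {
  if (dt <= 0) stop("dt must be positive")
  samples$dtheta / dt
}

#' Tangential and radial velocity components
#'
#' @param samples Output of [to_polar()] (uses the stored step displacements).
#' @param dt Frame interval in seconds.
#' @return Data frame with `v_tan` (counterclockwise-positive) and `v_rad`
#'   (outward-positive), in um/s.
#' @export
velocity_components <- function(samples, dt) {
  if (dt <= 0) stop("dt must be positive")
  data.frame(v_tan = samples$disp_tan / dt, v_rad = samples$disp_rad / dt)
}

# Sector index of an angle for n equal sectors starting at `origin`,
# proceeding counterclockwise. Zero-based.
.sector_index <- function(theta, n_sectors, origin = pi / 2) {
  floor(((theta - origin) %% (2 * pi)) / (2 * pi / n_sectors))
}

#' Per-sector summaries of angular velocity
#'
#' Divides the LRO into `n_sectors` equal angular sectors (sector 0 starts at
#' the anterior direction and proceeds counterclockwise, configurable via
#' `origin`) and summarizes a kinematic quantity per sector, both pooled over
#' all samples and per embryo. Empty sectors are reported as `NA`, not zero.
#'
#' @param samples Output of [to_polar()] (optionally core-excluded).
#' @param n_sectors Number of sectors (default 8).
#' @param statistic Summary function (default [median()]).
#' @param value Column to summarize (default `"aav"`).
#' @param origin Angular origin of sector 0 in the analysis frame (radians,
#'   default `pi/2` = anterior).
#' @return List with `pooled` (data frame: `sector`, `n`, `value`) and
#'   `per_embryo` (data frame: `embryo_id`, `sector`, `n`, `value`).
#' @export
sector_summary <- function(samples, n_sectors = 8, statistic = stats::median,
                           value = "aav", origin = pi / 2) {
  stopifnot(n_sectors >= 1)
  sec <- .sector_index(samples$theta, n_sectors, origin)
  v <- samples[[value]]
  all_sec <- 0:(n_sectors - 1)
  pooled <- data.frame(
    sector = all_sec,
    n = vapply(all_sec, function(s) sum(sec == s), integer(1)),
    value = vapply(all_sec, function(s) {
      if (any(sec == s)) statistic(v[sec == s]) else NA_real_
    }, numeric(1)))
  embryos <- unique(samples$embryo_id)
  per_embryo <- do.call(rbind, lapply(embryos, function(e) {
    in_e <- samples$embryo_id == e
    data.frame(embryo_id = e, sector = all_sec,
               n = vapply(all_sec, function(s) sum(in_e & sec == s), integer(1)),
               value = vapply(all_sec, function(s) {
                 sel <- in_e & sec == s
                 if (any(sel)) statistic(v[sel]) else NA_real_
               }, numeric(1)))
  }))
  rownames(per_embryo) <- NULL
  list(pooled = pooled, per_embryo = per_embryo)
}

#' Particle directionality distribution
#'
#' The direction of each between-frame displacement is expressed in the local
#' frame whose zero is the outward radial direction at the step's first point
#' (so a pure counterclockwise tangential step has direction `pi/2`), mapped
#' to `[0, 2*pi)`. Each sample is also assigned to one of twelve 30-degree
#' positional sectors by the first point's angle. Steps with zero displacement
#' are skipped (direction undefined).
#'
#' @param samples Output of [to_polar()].
#' @param origin Angular origin of positional sector 0 (default anterior).
#' @return Data frame with `embryo_id`, `track_id`, `sector` (0--11) and
#'   `direction` (radians in `[0, 2*pi)`).
#' @export
directionality <- function(samples, origin = pi / 2) {
  moved <- samples$disp_tan != 0 | samples$disp_rad != 0
  s <- samples[moved, , drop = FALSE]
  data.frame(embryo_id = s$embryo_id, track_id = s$track_id,
             sector = .sector_index(s$theta, 12, origin),
             direction = atan2(s$disp_tan, s$disp_rad) %% (2 * pi),
             row.names = NULL)
}

#' Compare two directionality distributions
#'
#' Two-sample Kolmogorov-Smirnov test on directionality angles (values in
#' `[0, 2*pi)`), as used to compare trajectory distributions between
#' experimental groups.
#'
#' @param directions_a,directions_b Numeric vectors of directions.
#' @return List with `statistic` and `p_value`.
#' @export
compare_directionality <- function(directions_a, directions_b) {
  if (length(directions_a) == 0 || length(directions_b) == 0) {
    stop("both groups must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(directions_a, directions_b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Per-track flow observations
#'
#' Reduces tracks to the unit of observation used by the flow regression: one
#' row per track per stage with the track's median angular velocity and mean
#' normalized coordinates, after core exclusion. Tracks that lie entirely
#' inside the core are dropped; the count is attached as attribute
#' `n_dropped_tracks`.
#'
#' @param tracks Track table (`embryo_id`, `track_id`, `frame`, `x_um`,
#'   `y_um`, and `stage` if embryos were imaged at several stages).
#' @param meta Per-embryo metadata: `embryo_id`, `stage`, `group`, `center_x`,
#'   `center_y`, `radius`, `anterior_axis_deg`, `dt_s`. When `center_x` /
#'   `center_y` are missing or `NA` the centroid of that embryo's track points
#'   is used.
#' @return Data frame with `embryo_id`, `stage`, `group`, `track_id`,
#'   `aav` (median, rad/s), `lr`, `pa` (means of normalized coordinates) and
#'   `n_steps`.
#' @export
track_summaries <- function(tracks, meta) {
  if (!"stage" %in% names(tracks)) tracks$stage <- NA_integer_
  if (!"stage" %in% names(meta)) meta$stage <- NA_integer_
  key_t <- paste(tracks$embryo_id, tracks$stage, sep = "\r")
  key_m <- paste(meta$embryo_id, meta$stage, sep = "\r")
  n_dropped <- 0L
  rows <- lapply(unique(key_t), function(k) {
    tr <- tracks[key_t == k, , drop = FALSE]
    m <- meta[key_m == k, , drop = FALSE]
    if (nrow(m) != 1) stop("no unique metadata row for embryo/stage ", k)
    center <- c(m$center_x, m$center_y)
    if (any(is.na(center))) center <- c(mean(tr$x_um), mean(tr$y_um))
    geom <- lro_geometry(center = center, radius = m$radius,
                         anterior_axis_angle = m$anterior_axis_deg * pi / 180,
                         stage = m$stage, dt = m$dt_s)
    samples <- exclude_core(to_polar(tr, geom), geom)
    n_before <- length(unique(tr$track_id))
    if (nrow(samples) == 0) {
      n_dropped <<- n_dropped + n_before
      return(NULL)
    }
    by_track <- split(samples, samples$track_id, drop = TRUE)
    n_dropped <<- n_dropped + (n_before - length(by_track))
    do.call(rbind, lapply(by_track, function(s) {
      data.frame(embryo_id = m$embryo_id, stage = m$stage, group = m$group,
                 track_id = s$track_id[1], aav = median(s$aav),
                 lr = mean(s$lr), pa = mean(s$pa), n_steps = nrow(s),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_dropped_tracks") <- n_dropped
  out
}

#' Read a track table from CSV
#'
#' @param path CSV with columns `embryo_id`, `track_id`, `frame`, `x_um`,
#'   `y_um` and optionally `stage`.
#' @return Data frame.
#' @export
read_tracks <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read per-embryo metadata from CSV
#'
#' @param path CSV with columns `embryo_id`, `stage`, `group`, `center_x`,
#'   `center_y`, `radius`, `anterior_axis_deg`, `dt_s`.
#' @return Data frame.
#' @export
read_track_metadata <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
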