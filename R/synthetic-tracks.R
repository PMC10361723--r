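# Synthetic LRO particle tracks: rigid rotation about the organizer center at
# a position-dependent angular velocity, plus i.i.d. Gaussian positional
# jitter. This is the minimal generative process for which angular velocity
# is well defined and recoverable by the kinematics stage.

#' Configuration for the synthetic flow-track generator
#'
#' Defaults emulate a sham-like LRO flow field: a counterclockwise baseline
#' of 0.25 rad/s, an anterior-dominant gradient of 0.16 rad/s per unit
#' normalized posterior-anterior coordinate, a small left-right gradient, an
#' increase of 0.021 rad/s per somite stage, between-embryo variability, and
#' sub-micron positional jitter at a 0.2 s frame interval.
#'
#' @param omega0 Baseline angular velocity (rad/s).
#' @param grad_pa Anterior-posterior angular-velocity gradient (rad/s per unit
#'   normalized PA coordinate).
#' @param grad_lr Left-right gradient (rad/s per unit normalized LR).
#' @param grad_time Increase in angular velocity per somite stage
#'   (rad/s/stage, applied as `stage - min(stages)`).
#' @param embryo_sd Between-embryo SD of the baseline (rad/s).
#' @param jitter_sd Positional noise SD (um).
#' @param radius LRO radius (um).
#' @param n_tracks Tracks per embryo per stage.
#' @param n_frames Frames per track (>= 2).
#' @param dt Frame interval (s).
#' @param stages Somite stages at which each embryo is imaged.
#' @param include_core If `TRUE`, track radii are drawn from `[0, radius]`
#'   so that inner points exercise the core-exclusion filter; by default radii
#'   are drawn from `[radius/2, radius]` so every synthetic point survives it.
#' @param seed Root seed; all embryo- and track-level draws derive from it.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(omega0 = 0.25, grad_pa = 0.16, grad_lr = 0.004,
                        grad_time = 0.021, embryo_sd = 0.05, jitter_sd = 0.2,
                        radius = 30, n_tracks = 30, n_frames = 10, dt = 0.2,
                        stages = 6:8, include_core = FALSE, seed = 1L) {
  if (radius <= 0) stop("radius must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (n_frames < 2) stop("n_frames must be at least 2")
  if (embryo_sd < 0 || jitter_sd < 0) stop("SDs must be non-negative")
  structure(as.list(environment()), class = "flow_config")
}

#' Generate synthetic particle tracks
#'
#' Each track is a rigid rotation about the LRO center: a center angle and a
#' radius are drawn, the local angular velocity is evaluated at that position
#' from the configured field
#' `omega(lr, pa) = omega0 + embryo effect + group offsets + grad_pa * pa +
#' grad_lr * lr + grad_time * (stage - min(stages))`,
#' and frames are laid out symmetrically about the center angle at that
#' constant rate, with i.i.d. Gaussian jitter added to every coordinate.
#' Tracks are generated in a frame whose center is the origin and whose
#' anterior axis is image +y (`anterior_axis_deg = 90`).
#'
#' @param config A [flow_config()].
#' @param group_spec Named list mapping group label to a list of offsets (any
#'   of `omega`, `grad_pa`, `grad_lr`, `grad_time`, each in rad/s on the same
#'   scale as the corresponding field parameter; missing entries are 0).
#'   Embryos are assigned to groups round-robin.
#' @param n_embryos Number of embryos.
#' @return List with `tracks` (data frame: `embryo_id`, `track_id`, `frame`,
#'   `x_um`, `y_um`, `stage`), `meta` (per embryo-stage geometry and group,
#'   in the layout [track_summaries()] expects) and `truth` (drawn embryo
#'   effects and the configuration).
#' @export
generate_tracks <- function(config, group_spec = list(Sham = list()),
                            n_embryos = 10) {
  stopifnot(inherits(config, "flow_config"))
  groups <- names(group_spec)
  if (is.null(groups) || any(groups == "")) stop("group_spec must be named")
  off <- function(g, what) {
    v <- group_spec[[g]][[what]]
    if (is.null(v)) 0 else v
  }
  set.seed(config$seed)
  embryo_ids <- sprintf("E%03d", seq_len(n_embryos))
  embryo_group <- groups[((seq_len(n_embryos) - 1) %% length(groups)) + 1]
  b <- rnorm(n_embryos, 0, config$embryo_sd)
  t0 <- min(config$stages)
  r_lo <- if (config$include_core) 0 else config$radius / 2
  tracks <- vector("list", n_embryos * length(config$stages))
  meta <- vector("list", n_embryos * length(config$stages))
  k <- 0L
  for (i in seq_len(n_embryos)) {
    g <- embryo_group[i]
    for (stage in config$stages) {
      k <- k + 1L
      r0 <- runif(config$n_tracks, r_lo, config$radius)
      thc <- runif(config$n_tracks, 0, 2 * pi)
      lr <- r0 * cos(thc) / config$radius
      pa <- r0 * sin(thc) / config$radius
      omega <- config$omega0 + b[i] + off(g, "omega") +
        (config$grad_pa + off(g, "grad_pa")) * pa +
        (config$grad_lr + off(g, "grad_lr")) * lr +
        (config$grad_time + off(g, "grad_time")) * (stage - t0)
      j <- seq_len(config$n_frames) - 1
      rows <- lapply(seq_len(config$n_tracks), function(tk) {
        th <- thc[tk] + omega[tk] * config$dt * (j - (config$n_frames - 1) / 2)
        data.frame(embryo_id = embryo_ids[i],
                   track_id = sprintf("T%04d", tk),
                   frame = j,
                   x_um = r0[tk] * cos(th) +
                     rnorm(config$n_frames, 0, config$jitter_sd),
                   y_um = r0[tk] * sin(th) +
                     rnorm(config$n_frames, 0, config$jitter_sd),
                   stage = stage, stringsAsFactors = FALSE)
      })
      tracks[[k]] <- do.call(rbind, rows)
      meta[[k]] <- data.frame(embryo_id = embryo_ids[i], stage = stage,
                              group = g, center_x = 0, center_y = 0,
                              radius = config$radius, anterior_axis_deg = 90,
                              dt_s = config$dt, stringsAsFactors = FALSE)
    }
  }
  list(tracks = do.call(rbind, tracks),
       meta = do.call(rbind, meta),
       truth = list(embryos = data.frame(embryo_id = embryo_ids,
                                         group = embryo_group,
                                         effect = b,
                                         stringsAsFactors = FALSE),
                    config = config))
}

#' Write synthetic tracks and metadata to CSV
#'
#' Writes `tracks.csv`, `meta.csv` and `truth.json` under `dir` in the dialect
#' [read_tracks()] and [read_track_metadata()] read.
#'
#' @param sim Output of [generate_tracks()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_track_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$tracks, file.path(dir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(sim$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
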