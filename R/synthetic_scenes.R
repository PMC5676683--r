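# Synthetic scenes: textured elliptical animals moving in a bright arena,
# with scripted crossings and exact per-frame ground truth.
#
# Each animal is an ellipse carrying a rigid striped texture (the pattern is
# defined in body coordinates, so it rotates with the heading, mimicking
# real animal markings). Motion is a bounce-off-walls random walk with soft
# collision avoidance; scheduled crossings override the walk and steer a
# pair onto a straight-line collision so that their masks first overlap at
# the scheduled frame. Frames are rendered lazily and deterministically:
# frame k depends only on the seed and k, so streaming and batch access are
# bit-identical.

#' Scene configuration
#'
#' @param n_animals number of animals.
#' @param frame_size `c(width, height)` in pixels.
#' @param n_frames number of frames.
#' @param fps frames per second.
#' @param axes ellipse semi-axes `c(major, minor)` in pixels.
#' @param texture_distinctness 0 = identical textures, 1 = maximally
#'   distinct striped patterns.
#' @param speed nominal speed in px/frame.
#' @param turn_sd heading noise (radians/frame).
#' @param crossing_schedule list of `list(frame =, pair = c(i, j))` events;
#'   the pair's masks first overlap at (approximately) the scheduled frame.
#' @param background_intensity bright arena intensity.
#' @param noise_sd Gaussian pixel noise added after compositing.
#' @param seed RNG seed; everything about the scene is a pure function of
#'   the config.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_animals = 2L, frame_size = c(300L, 300L),
                         n_frames = 400L, fps = 25,
                         axes = c(14, 8), texture_distinctness = 1,
                         speed = 3, turn_sd = 0.15,
                         crossing_schedule = list(),
                         background_intensity = 240, noise_sd = 2,
                         seed = 1L) {
  stopifnot(n_animals >= 1, length(frame_size) == 2, n_frames >= 1,
            fps > 0, length(axes) == 2, axes[1] >= axes[2], axes[2] > 0,
            texture_distinctness >= 0, texture_distinctness <= 1,
            speed > 0, turn_sd >= 0,
            background_intensity > 0, background_intensity <= 255,
            noise_sd >= 0)
  if (2 * (axes[1] + 4) >= min(frame_size))
    stop("animals do not fit in the frame")
  for (ev in crossing_schedule)
    stopifnot(ev$frame > 0, ev$frame < n_frames, length(ev$pair) == 2,
              all(ev$pair >= 1), all(ev$pair <= n_animals),
              ev$pair[1] != ev$pair[2])
  structure(list(n_animals = as.integer(n_animals),
                 frame_size = as.integer(frame_size),
                 n_frames = as.integer(n_frames), fps = fps, axes = axes,
                 texture_distinctness = texture_distinctness,
                 speed = speed, turn_sd = turn_sd,
                 crossing_schedule = crossing_schedule,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# run code under a private seeded RNG stream, leaving the global stream
# untouched
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  force(code)
}

# per-animal texture parameters. Shared dark/bright anchor levels; the two
# interior stripe levels sit at animal-specific fractions of the range, and
# stripe widths differ, so after contrast normalization the histograms of
# distinct animals occupy different bins. distinctness d interpolates every
# parameter towards a common value.
.texture_params <- function(k, d) {
  pq <- list(c(0.12, 0.28), c(0.36, 0.52), c(0.60, 0.76),
             c(0.20, 0.88), c(0.44, 0.68))
  ww <- list(c(3, 5), c(4, 6), c(5, 4), c(6, 3), c(3, 7))
  i <- ((k - 1L) %% 5L) + 1L
  p <- (1 - d) * c(1 / 3, 2 / 3) + d * pq[[i]]
  w <- (1 - d) * c(4.5, 4.5) + d * ww[[i]]
  lo <- 40; hi <- 180
  list(levels = c(lo, lo + p[1] * (hi - lo), lo + p[2] * (hi - lo), hi),
       widths = w)
}

# texture intensity at body coordinates (u along major axis, v along minor)
.texture_value <- function(u, v, tp) {
  m <- (floor((u + 400) / tp$widths[1]) +
        floor((v + 400) / tp$widths[2])) %% 8
  # thin anchor stripes at the extremes, bulk mass on the two interior levels
  lev <- ifelse(m == 0, 1L, ifelse(m <= 3, 2L, ifelse(m <= 6, 3L, 4L)))
  tp$levels[lev]
}

# simulate all trajectories; returns per-frame positions and headings plus
# the crossing log
.simulate_paths <- function(cfg) {
  n <- cfg$n_animals; nf <- cfg$n_frames
  W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
  a <- cfg$axes[1]
  margin <- a + 4
  avoid <- 2.2 * 2 * a
  x <- matrix(0, nf, n); y <- matrix(0, nf, n); th <- matrix(0, nf, n)
  # scripted segments: per animal, frames with forced x, y, heading
  script <- vector("list", n)
  sched <- cfg$crossing_schedule
  if (length(sched) > 0)
    sched <- sched[order(vapply(sched, `[[`, 0, "frame"))]
  log <- data.frame(scheduled_frame = integer(0), animal_a = integer(0),
                    animal_b = integer(0), first_overlap_frame = integer(0))
  .with_seed(cfg$seed, {
    # initial positions on a jittered ring around the arena center
    ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)] +
      runif(1, 0, 2 * pi)
    r0 <- 0.30 * min(W, H)
    px <- W / 2 + r0 * cos(ang) + runif(n, -5, 5)
    py <- H / 2 + r0 * sin(ang) + runif(n, -5, 5)
    ph <- runif(n, 0, 2 * pi)
    next_ev <- 1L
    busy_until <- rep(-1L, n)
    for (t in seq_len(nf) - 1L) {
      # launch scripted crossings whose approach must start now
      while (next_ev <= length(sched)) {
        ev <- sched[[next_ev]]
        i <- ev$pair[1]; j <- ev$pair[2]; f <- ev$frame
        D <- sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
        need <- ceiling(max(D / 2 - (a - 1), 1) / cfg$speed)
        ws <- f - min(150L, max(20L, need))
        if (ws > t) break
        if (busy_until[i] >= t || busy_until[j] >= t)
          stop("impossible schedule: animals ", i, " and ", j,
               " still busy at frame ", t)
        mx <- (px[i] + px[j]) / 2; my <- (py[i] + py[j]) / 2
        Tp <- ceiling(2 * a / cfg$speed) + 2L
        for (kk in c(i, j)) {
          dx <- mx - px[kk]; dy <- my - py[kk]
          Dk <- sqrt(dx^2 + dy^2)
          if (Dk < 1e-9) { dx <- 1; dy <- 0; Dk <- 1 }
          ux <- dx / Dk; uy <- dy / Dk
          stopx <- mx - ux * (a - 1); stopy <- my - uy * (a - 1)
          v <- sqrt((stopx - px[kk])^2 + (stopy - py[kk])^2) / (f - t)
          if (v > 3 * cfg$speed)
            stop("impossible schedule: required speed ", round(v, 1),
                 " px/frame for animal ", kk, " at frame ", f)
          fr <- (t + 1L):(f + Tp)
          along <- ifelse(fr <= f,
                          v * (fr - t),
                          v * (f - t) + cfg$speed * (fr - f))
          sx <- pmin(pmax(px[kk] + ux * along, margin), W - 1 - margin)
          sy <- pmin(pmax(py[kk] + uy * along, margin), H - 1 - margin)
          script[[kk]] <- list(frames = fr, x = sx, y = sy,
                               th = atan2(uy, ux))
          busy_until[kk] <- f + Tp
        }
        log <- rbind(log, data.frame(scheduled_frame = f, animal_a = i,
                                     animal_b = j,
                                     first_overlap_frame = f))
        next_ev <- next_ev + 1L
      }
      noise <- rnorm(n, 0, cfg$turn_sd)   # one draw per animal per frame
      scripted <- vapply(seq_len(n), function(k)
        !is.null(script[[k]]) && t %in% script[[k]]$frames, TRUE)
      # soft collision avoidance between non-scripted pairs
      for (i in seq_len(n)) {
        if (scripted[i]) next
        for (j in seq_len(n)) {
          if (j == i) next
          d <- sqrt((px[i] - px[j])^2 + (py[i] - py[j])^2)
          if (d < avoid && d > 1e-9)
            ph[i] <- atan2(py[i] - py[j], px[i] - px[j])
        }
      }
      for (k in seq_len(n)) {
        if (scripted[k]) {
          s <- script[[k]]
          w <- match(t, s$frames)
          px[k] <- s$x[w]; py[k] <- s$y[w]; ph[k] <- s$th
          if (t == max(s$frames)) script[k] <- list(NULL)
        } else {
          ph[k] <- ph[k] + noise[k]
          px[k] <- px[k] + cfg$speed * cos(ph[k])
          py[k] <- py[k] + cfg$speed * sin(ph[k])
          if (px[k] < margin) { px[k] <- 2 * margin - px[k]; ph[k] <- pi - ph[k] }
          if (px[k] > W - 1 - margin) { px[k] <- 2 * (W - 1 - margin) - px[k]; ph[k] <- pi - ph[k] }
          if (py[k] < margin) { py[k] <- 2 * margin - py[k]; ph[k] <- -ph[k] }
          if (py[k] > H - 1 - margin) { py[k] <- 2 * (H - 1 - margin) - py[k]; ph[k] <- -ph[k] }
        }
        x[t + 1L, k] <- px[k]; y[t + 1L, k] <- py[k]; th[t + 1L, k] <- ph[k]
      }
    }
  })
  list(x = x, y = y, th = th, log = log)
}

# pixel rows/cols (0-based) and intensities of one animal at one frame
.animal_pixels <- function(cfg, tp, cx, cy, heading) {
  a <- cfg$axes[1]; b <- cfg$axes[2]
  W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
  c0 <- max(0L, floor(cx - a - 1)); c1 <- min(W - 1L, ceiling(cx + a + 1))
  r0 <- max(0L, floor(cy - a - 1)); r1 <- min(H - 1L, ceiling(cy + a + 1))
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  dx <- cc - cx; dy <- rr - cy
  u <- dx * cos(heading) + dy * sin(heading)
  v <- -dx * sin(heading) + dy * cos(heading)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(row = rr[inside], col = cc[inside],
       val = .texture_value(u[inside], v[inside], tp))
}

#' Generate a synthetic scene
#'
#' @param cfg a [scene_config()].
#' @return A `toxid_scene`: list with `frames` (a lazy `frame_source` with
#'   `$n_frames` and `$get_frame(i)`, 1-based), `truth` (a
#'   [ground_truth()]), `crossing_log` (data frame), `trajectory` (per-frame
#'   animal positions and headings) and `cfg`.
#' @export
generate_scene <- function(cfg = scene_config()) {
  sim <- .simulate_paths(cfg)
  n <- cfg$n_animals
  tps <- lapply(seq_len(n), .texture_params, d = cfg$texture_distinctness)
  truth_df <- data.frame(
    frame = rep(seq_len(cfg$n_frames) - 1L, times = n),
    x = as.numeric(sim$x), y = as.numeric(sim$y),
    animal_id = rep(seq_len(n), each = cfg$n_frames))
  render <- function(t) {   # t is 0-based
    W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
    img <- .with_seed(cfg$seed * 7919 + t, {
      m <- matrix(cfg$background_intensity, H, W)
      for (k in seq_len(n)) {
        ap <- .animal_pixels(cfg, tps[[k]], sim$x[t + 1L, k],
                             sim$y[t + 1L, k], sim$th[t + 1L, k])
        ix <- cbind(ap$row + 1L, ap$col + 1L)
        m[ix] <- pmin(m[ix], ap$val)   # darker body wins where bodies overlap
      }
      if (cfg$noise_sd > 0) m <- m + rnorm(length(m), 0, cfg$noise_sd)
      m
    })
    gray_frame(matrix(as.integer(round(pmin(pmax(img, 0), 255))),
                      nrow(img), ncol(img)), index = t)
  }
  frames <- structure(list(n_frames = cfg$n_frames,
                           get_frame = function(i) render(i - 1L)),
                      class = "frame_source")
  structure(list(
    frames = frames,
    truth = ground_truth(truth_df, n, cfg$fps,
                         cfg$n_frames / cfg$fps / 60),
    crossing_log = sim$log,
    trajectory = list(x = sim$x, y = sim$y, heading = sim$th),
    cfg = cfg), class = "toxid_scene")
}

#' Pixel mask of one animal in one frame
#'
#' Utility for inspecting rendered scenes (e.g. verifying that scheduled
#' crossings really overlap).
#'
#' @param scene a [generate_scene()] result.
#' @param frame 0-based frame index.
#' @param animal animal id.
#' @return Two-column matrix of 0-based `(row, col)` pixel coordinates.
#' @export
animal_mask <- function(scene, frame, animal) {
  cfg <- scene$cfg
  tp <- .texture_params(animal, cfg$texture_distinctness)
  ap <- .animal_pixels(cfg, tp, scene$trajectory$x[frame + 1L, animal],
                       scene$trajectory$y[frame + 1L, animal],
                       scene$trajectory$heading[frame + 1L, animal])
  cbind(row = ap$row, col = ap$col)
}

#' Recommended detection/tracking settings for a scene
#'
#' The generator places animal texture below 200 and the background at 240,
#' so a threshold of 220 separates them; size limits admit single animals
#' and merged (occluding) pairs.
#'
#' @param cfg a [scene_config()].
#' @return A list with `det_cfg` and `trk_cfg`.
#' @export
scene_tracking_defaults <- function(cfg) {
  area <- pi * cfg$axes[1] * cfg$axes[2]
  list(det_cfg = detection_config(threshold = 220,
                                  min_size = ceiling(area * 0.3),
                                  max_size = ceiling(area * 4),
                                  fps = cfg$fps),
       trk_cfg = tracking_config())
}

#' Canonical scene presets
#'
#' Four seeded scenes used throughout the test suite: a single-animal null
#' scene, a two-animal single-crossing scene, a five-animal ten-crossing
#' scene with distinct textures, and a five-animal identical-texture stress
#' scene.
#'
#' @param name one of `"null1"`, `"cross2"`, `"distinct5"`,
#'   `"identical5"`.
#' @param seed scene seed.
#' @param n_frames optional override of the preset length.
#' @return A [scene_config()].
#' @export
scene_preset <- function(name = c("null1", "cross2", "distinct5",
                                  "identical5"),
                         seed = 1L, n_frames = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    null1 = scene_config(n_animals = 1L, frame_size = c(200L, 200L),
                         n_frames = 300L, seed = seed),
    cross2 = scene_config(n_animals = 2L, frame_size = c(300L, 300L),
                          n_frames = 400L,
                          crossing_schedule = list(
                            list(frame = 200L, pair = c(1L, 2L))),
                          seed = seed),
    distinct5 = scene_config(n_animals = 5L, frame_size = c(400L, 400L),
                             n_frames = 2000L, texture_distinctness = 1,
                             crossing_schedule = .ten_crossings(),
                             seed = seed),
    identical5 = scene_config(n_animals = 5L, frame_size = c(400L, 400L),
                              n_frames = 600L, texture_distinctness = 0,
                              crossing_schedule = .ten_crossings()[1:3],
                              seed = seed))
  if (!is.null(n_frames)) {
    cfg$n_frames <- as.integer(n_frames)
    cfg$crossing_schedule <- Filter(function(ev) ev$frame < cfg$n_frames - 20,
                                    cfg$crossing_schedule)
  }
  cfg
}

.ten_crossings <- function() {
  pairs <- list(c(1L, 2L), c(3L, 4L), c(5L, 1L), c(2L, 3L), c(4L, 5L),
                c(1L, 3L), c(2L, 4L), c(3L, 5L), c(4L, 1L), c(5L, 2L))
  frames <- seq(150L, 1950L, by = 200L)
  Map(function(f, p) list(frame = f, pair = p), frames, pairs)
}

#' Render the canonical fixture suite to disk
#'
#' Writes each preset scene as a PNG frame sequence (`frame_%06d.png`), a
#' ground-truth CSV (`truth.csv`: frame,x,y,animal_id) and a scene config
#' JSON, plus a top-level manifest with the seeds.
#'
#' @param out_dir output directory (created if needed).
#' @param presets preset names to render.
#' @param seed scene seed.
#' @param n_frames optional per-scene frame-count override (for quick
#'   fixtures).
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
render_fixture_suite <- function(out_dir,
                                 presets = c("null1", "cross2", "distinct5",
                                             "identical5"),
                                 seed = 1L, n_frames = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, scenes = list())
  for (p in presets) {
    cfg <- scene_preset(p, seed = seed, n_frames = n_frames)
    scene <- generate_scene(cfg)
    sdir <- file.path(out_dir, p)
    dir.create(sdir, showWarnings = FALSE)
    for (i in seq_len(cfg$n_frames)) {
      fr <- scene$frames$get_frame(i)
      png::writePNG(fr$pixels / 255,
                    file.path(sdir, sprintf("frame_%06d.png", fr$index)))
    }
    write.csv(scene$truth$positions, file.path(sdir, "truth.csv"),
              row.names = FALSE)
    manifest$scenes[[p]] <- list(name = p, seed = seed,
                                 n_frames = cfg$n_frames,
                                 n_animals = cfg$n_animals,
                                 frame_size = cfg$frame_size,
                                 threshold = 220)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
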