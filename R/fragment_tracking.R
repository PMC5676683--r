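# Online trajectory-fragment creation.
#
# Detections are assigned to open fragments frame by frame: a constant-
# velocity Kalman filter predicts each fragment's next position, a Hungarian
# assignment minimizes the total Euclidean cost, and gating rules cut
# fragments at occlusions. Inactivation reasons: cost_gate (matched pair too
# far), size_gate (relative size change too large), lost (unmatched for too
# many frames), proximity (two predictions converge on one detection — the
# occlusion cut), end_of_video.

#' Detection configuration
#'
#' @param threshold intensity threshold; pixels below it are foreground.
#' @param min_size,max_size blob size filter (pixels).
#' @param fps frames per second of the video.
#' @param kn histogram bin count.
#' @param invert segment bright-on-dark video.
#' @param hu_binary compute Hu invariants on the binary silhouette instead of
#'   masked intensities.
#' @return A `detection_config` list.
#' @export
detection_config <- function(threshold = 128, min_size = 20L,
                             max_size = 1e6, fps = 25, kn = 32L,
                             invert = FALSE, hu_binary = FALSE) {
  stopifnot(threshold >= 0, threshold <= 255, min_size > 0,
            min_size <= max_size, fps > 0, kn >= 2)
  structure(list(threshold = threshold, min_size = as.integer(min_size),
                 max_size = max_size, fps = fps, kn = as.integer(kn),
                 invert = invert, hu_binary = hu_binary),
            class = "detection_config")
}

#' Tracking configuration
#'
#' `cost_limit` and `proximity_limit` default to `NULL`, meaning they are
#' estimated online from the first frame with detections as 4x and 1.5x the
#' median blob diameter (`2 * sqrt(size / pi)`).
#'
#' @param cost_limit maximum accepted assignment cost (pixels).
#' @param size_change_limit maximum accepted symmetric relative size change.
#' @param max_missed_frames frames a fragment may stay unmatched before it is
#'   marked lost.
#' @param proximity_limit distance (pixels) under which two fragment
#'   predictions converging on one detection trigger the occlusion cut.
#' @param process_noise,measurement_noise Kalman tuning scalars.
#' @return A `tracking_config` list.
#' @export
tracking_config <- function(cost_limit = NULL, size_change_limit = 1.0,
                            max_missed_frames = 10L, proximity_limit = NULL,
                            process_noise = 1e-2, measurement_noise = 1.0) {
  stopifnot(is.null(cost_limit) || cost_limit > 0, size_change_limit > 0,
            max_missed_frames > 0, is.null(proximity_limit) ||
            proximity_limit > 0, process_noise > 0, measurement_noise > 0)
  structure(list(cost_limit = cost_limit,
                 size_change_limit = size_change_limit,
                 max_missed_frames = as.integer(max_missed_frames),
                 proximity_limit = proximity_limit,
                 process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "tracking_config")
}

#' Construct a trajectory fragment from detection columns
#'
#' @param id fragment id.
#' @param frames integer vector of frame indices (strictly increasing).
#' @param x,y center-of-mass coordinates per detection.
#' @param size blob pixel counts.
#' @param t detection times in seconds (defaults to `frames / fps`).
#' @param hist `kn x n` matrix of ROI histograms (one column per detection).
#' @param hu `7 x n` matrix of Hu invariants.
#' @param fps time base used when `t` is missing.
#' @param active,inactive_reason activity flag and the rule that closed the
#'   fragment.
#' @return A `fragment` object.
#' @export
new_fragment <- function(id, frames, x, y, size = NULL, t = NULL,
                         hist = NULL, hu = NULL, fps = 25,
                         active = FALSE, inactive_reason = "end_of_video") {
  frames <- as.integer(frames)
  n <- length(frames)
  if (n == 0L) stop("fragment must contain at least one detection")
  if (any(diff(frames) <= 0L)) stop("frame numbers must strictly increase")
  stopifnot(length(x) == n, length(y) == n)
  if (is.null(size)) size <- rep(1, n)
  if (is.null(t)) t <- frames / fps
  if (active) inactive_reason <- "none"
  structure(list(id = id, frames = frames, x = as.numeric(x),
                 y = as.numeric(y), size = as.numeric(size),
                 t = as.numeric(t), hist = hist, hu = hu,
                 n = n, start_frame = frames[1], end_frame = frames[n],
                 active = active, inactive_reason = inactive_reason),
            class = "fragment")
}

#' @export
format.fragment <- function(x, ...) {
  sprintf("<fragment %s: %d detections, frames %d-%d, %s>",
          x$id, x$n, x$start_frame, x$end_frame,
          if (x$active) "active" else x$inactive_reason)
}

#' @export
print.fragment <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Predict a fragment's next position
#'
#' One-step-ahead position under the constant-velocity Kalman model, i.e.
#' the expected center of mass one frame after the fragment's last
#' detection. A single-detection fragment predicts its own position.
#'
#' @param fragment a [new_fragment()] object.
#' @param process_noise,measurement_noise Kalman tuning scalars.
#' @return Numeric `c(x, y)`.
#' @export
predict_position <- function(fragment, process_noise = 1e-2,
                             measurement_noise = 1.0) {
  if (fragment$n < 1L) stop("empty fragment")
  st <- .kf_run(fragment$frames, fragment$x, fragment$y,
                process_noise, measurement_noise)
  st <- .kf_predict(st, 1, process_noise)
  c(x = st$m[1], y = st$m[2])
}

#' Symmetric relative size change between two blob sizes
#'
#' `(s_i - s_jn) / s_jn` when the new blob is larger, `(s_jn - s_i) / s_i`
#' otherwise, so the measure is symmetric, non-negative and zero only at
#' equality.
#'
#' @param s_i,s_jn blob pixel counts (> 0).
#' @return Non-negative scalar.
#' @export
size_change <- function(s_i, s_jn) {
  if (any(s_i <= 0) || any(s_jn <= 0)) stop("sizes must be positive")
  ifelse(s_jn < s_i, (s_i - s_jn) / s_jn, (s_jn - s_i) / s_i)
}

#' Assignment cost between a fragment and a detection
#'
#' Euclidean distance between the fragment's predicted next position and the
#' detection's center of mass.
#'
#' @param fragment a fragment.
#' @param detection a detection from [extract_detection()].
#' @param ... passed to [predict_position()].
#' @return Distance in pixels.
#' @export
assignment_cost <- function(fragment, detection, ...) {
  p <- predict_position(fragment, ...)
  sqrt(sum((p - detection$cm)^2))
}

# --- online tracker state ---------------------------------------------------

#' Create an online tracker
#'
#' The tracker is a mutable state to which frames are fed one at a time with
#' [tracker_step()]; it never reads ahead. [track_sequence()] is the batch
#' convenience wrapper and produces bit-identical results.
#'
#' @param det_cfg a [detection_config()].
#' @param trk_cfg a [tracking_config()].
#' @return A `tracker` environment.
#' @export
tracker_new <- function(det_cfg = detection_config(),
                        trk_cfg = tracking_config()) {
  tr <- new.env(parent = emptyenv())
  tr$det_cfg <- det_cfg
  tr$trk_cfg <- trk_cfg
  tr$open <- list()        # active fragment builders
  tr$closed <- list()      # finished fragment builders
  tr$next_id <- 1L
  tr$events <- list()      # deactivation log: frame, fragment_id, reason
  class(tr) <- "tracker"
  tr
}

.builder_new <- function(id, det, r) {
  list(id = id, frames = det$frame, x = det$cm[[1]], y = det$cm[[2]],
       size = det$size, t = det$t,
       hist = matrix(det$hist, ncol = 1),
       hu = matrix(det$hu, ncol = 1),
       kf = .kf_init(det$cm, r), last_frame = det$frame,
       last_size = det$size, missed = 0L)
}

.builder_add <- function(b, det, q, r) {
  gap <- det$frame - b$last_frame
  st <- b$kf
  for (g in seq_len(gap)) st <- .kf_predict(st, 1, q)
  b$kf <- .kf_update(st, det$cm, r)
  b$frames <- c(b$frames, det$frame)
  b$x <- c(b$x, det$cm[[1]]); b$y <- c(b$y, det$cm[[2]])
  b$size <- c(b$size, det$size); b$t <- c(b$t, det$t)
  b$hist <- cbind(b$hist, det$hist)
  b$hu <- cbind(b$hu, det$hu)
  b$last_frame <- det$frame
  b$last_size <- det$size
  b$missed <- 0L
  b
}

.builder_predict <- function(b, frame, q) {
  st <- b$kf
  for (g in seq_len(frame - b$last_frame)) st <- .kf_predict(st, 1, q)
  c(st$m[1], st$m[2])
}

.builder_finalize <- function(b, active, reason) {
  new_fragment(b$id, b$frames, b$x, b$y, size = b$size, t = b$t,
               hist = b$hist, hu = b$hu, active = active,
               inactive_reason = reason)
}

#' Decide the detection-to-fragment assignment for one frame
#'
#' Pure decision function implementing the per-frame rules: (1) the occlusion
#' cut — if two or more fragment predictions lie within `proximity_limit` of
#' the same detection, all of them are deactivated and the detection starts a
#' new fragment; (2) Hungarian assignment minimizing total Euclidean cost over
#' the remaining fragments and detections; (3) gating — a matched pair whose
#' cost exceeds `cost_limit` or whose size change exceeds `size_change_limit`
#' is rejected and the fragment deactivated; (4) fragments unmatched for more
#' than `max_missed_frames` consecutive frames are marked lost; (5) every
#' unmatched detection starts a new fragment.
#'
#' @param predictions n x 2 matrix of fragment predicted positions.
#' @param last_sizes last blob size of each fragment.
#' @param missed current consecutive missed-frame count of each fragment.
#' @param det_cm m x 2 matrix of detection centers.
#' @param det_size detection blob sizes.
#' @param cfg a [tracking_config()] with resolved (non-`NULL`) limits.
#' @return List with `matches` (fragment index -> detection index, `NA` if
#'   unmatched), `deactivated` (integer indices), `reasons` (character, same
#'   order), `new_detections` (detection indices starting fragments), and
#'   `missed` (updated per-fragment missed counts).
#' @export
assign_detections <- function(predictions, last_sizes, missed, det_cm,
                              det_size, cfg) {
  nf <- if (is.null(predictions)) 0L else nrow(predictions)
  nd <- if (is.null(det_cm)) 0L else nrow(det_cm)
  matches <- rep(NA_integer_, nf)
  deact <- integer(0); reasons <- character(0)
  det_new <- logical(nd)
  frag_alive <- rep(TRUE, nf)

  if (nf > 0L && nd > 0L) {
    d2 <- outer(seq_len(nf), seq_len(nd), function(i, j)
      sqrt((predictions[i, 1] - det_cm[j, 1])^2 +
           (predictions[i, 2] - det_cm[j, 2])^2))
    # occlusion cut: >= 2 predictions within proximity_limit of one detection
    for (j in seq_len(nd)) {
      near <- which(frag_alive & d2[, j] < cfg$proximity_limit)
      if (length(near) >= 2L) {
        frag_alive[near] <- FALSE
        deact <- c(deact, near)
        reasons <- c(reasons, rep("proximity", length(near)))
        det_new[j] <- TRUE
      }
    }
    fi <- which(frag_alive); dj <- which(!det_new)
    if (length(fi) > 0L && length(dj) > 0L) {
      sol <- solve_assignment(d2[fi, dj, drop = FALSE])
      for (k in seq_along(fi)) {
        if (is.na(sol[k])) next
        i <- fi[k]; j <- dj[sol[k]]
        cost <- d2[i, j]
        dsz <- size_change(det_size[j], last_sizes[i])
        if (cost > cfg$cost_limit) {
          deact <- c(deact, i); reasons <- c(reasons, "cost_gate")
          frag_alive[i] <- FALSE
        } else if (dsz > cfg$size_change_limit) {
          deact <- c(deact, i); reasons <- c(reasons, "size_gate")
          frag_alive[i] <- FALSE
        } else {
          matches[i] <- j
        }
      }
    }
  }
  # lost rule and missed-frame bookkeeping
  if (nf > 0L) {
    unmatched <- which(frag_alive & is.na(matches))
    missed[unmatched] <- missed[unmatched] + 1L
    missed[!is.na(matches)] <- 0L
    lost <- unmatched[missed[unmatched] > cfg$max_missed_frames]
    if (length(lost) > 0L) {
      deact <- c(deact, lost); reasons <- c(reasons, rep("lost", length(lost)))
    }
  }
  new_det <- which(det_new | !(seq_len(nd) %in% matches))
  list(matches = matches, deactivated = deact, reasons = reasons,
       new_detections = new_det, missed = missed)
}

# resolve NULL cost/proximity limits from the median blob diameter of the
# first frame that has detections
.resolve_limits <- function(cfg, det_size) {
  if (!is.null(cfg$cost_limit) && !is.null(cfg$proximity_limit)) return(cfg)
  d <- 2 * sqrt(median(det_size) / pi)
  if (is.null(cfg$cost_limit)) cfg$cost_limit <- 4 * d
  if (is.null(cfg$proximity_limit)) cfg$proximity_limit <- 1.5 * d
  cfg
}

#' Feed one frame to the tracker
#'
#' @param tr a [tracker_new()] state.
#' @param frame a [gray_frame()]; frame indices must strictly increase across
#'   calls.
#' @return The tracker, invisibly.
#' @export
tracker_step <- function(tr, frame) {
  dc <- tr$det_cfg; tc <- tr$trk_cfg
  blobs <- segment_frame(frame, dc$threshold, dc$min_size, dc$max_size,
                         invert = dc$invert)
  dets <- lapply(blobs, function(b)
    extract_detection(frame, b, fps = dc$fps, kn = dc$kn,
                      hu_binary = dc$hu_binary))
  nf <- length(tr$open); nd <- length(dets)
  if (is.null(tc$cost_limit) || is.null(tc$proximity_limit)) {
    if (nd > 0L)
      tr$trk_cfg <- tc <- .resolve_limits(tc, vapply(dets, `[[`, 0, "size"))
    else if (nf == 0L) return(invisible(tr))
  }
  preds <- if (nf > 0L)
    t(vapply(tr$open, .builder_predict, numeric(2),
             frame = frame$index, q = tc$process_noise)) else NULL
  det_cm <- if (nd > 0L)
    t(vapply(dets, function(d) as.numeric(d$cm), numeric(2))) else NULL
  res <- assign_detections(
    predictions = preds,
    last_sizes = vapply(tr$open, `[[`, 0, "last_size"),
    missed = vapply(tr$open, `[[`, 0L, "missed"),
    det_cm = det_cm,
    det_size = vapply(dets, `[[`, 0, "size"),
    cfg = tc)
  # apply decisions
  for (i in seq_len(nf)) {
    if (!is.na(res$matches[i]))
      tr$open[[i]] <- .builder_add(tr$open[[i]], dets[[res$matches[i]]],
                                   tc$process_noise, tc$measurement_noise)
    else tr$open[[i]]$missed <- res$missed[i]
  }
  if (length(res$deactivated) > 0L) {
    for (k in seq_along(res$deactivated)) {
      i <- res$deactivated[k]
      b <- tr$open[[i]]
      tr$closed[[length(tr$closed) + 1L]] <-
        .builder_finalize(b, FALSE, res$reasons[k])
      tr$events[[length(tr$events) + 1L]] <-
        list(frame = frame$index, fragment_id = b$id, reason = res$reasons[k])
    }
    tr$open <- tr$open[-res$deactivated]
  }
  for (j in res$new_detections) {
    tr$open[[length(tr$open) + 1L]] <-
      .builder_new(tr$next_id, dets[[j]], tc$measurement_noise)
    tr$next_id <- tr$next_id + 1L
  }
  invisible(tr)
}

#' Collect all fragments from a tracker
#'
#' @param tr a tracker; open fragments are reported with reason
#'   `end_of_video` unless `keep_active = TRUE`.
#' @param keep_active report still-open fragments as active.
#' @return List of `fragment` objects sorted by fragment id.
#' @export
tracker_fragments <- function(tr, keep_active = FALSE) {
  frs <- c(tr$closed,
           lapply(tr$open, .builder_finalize, active = keep_active,
                  reason = "end_of_video"))
  frs[order(vapply(frs, `[[`, 0, "id"))]
}

#' Deactivation events recorded by a tracker
#'
#' @param tr a tracker.
#' @return Data frame with columns `frame`, `fragment_id`, `reason`.
#' @export
tracker_events <- function(tr) {
  if (length(tr$events) == 0L)
    return(data.frame(frame = integer(0), fragment_id = integer(0),
                      reason = character(0)))
  do.call(rbind, lapply(tr$events, as.data.frame))
}

#' Track a frame sequence into trajectory fragments
#'
#' Processes frames strictly in order (online: frame `k` uses only frames
#' `<= k`) and returns all fragments, active and inactive.
#'
#' @param frames a list of [gray_frame()] objects or a frame source as
#'   returned by [generate_scene()] / [read_frames()].
#' @param det_cfg a [detection_config()].
#' @param trk_cfg a [tracking_config()].
#' @param tracker optionally a pre-built tracker (for resuming).
#' @return List of `fragment` objects; the tracker used is attached as
#'   attribute `"tracker"`.
#' @export
track_sequence <- function(frames, det_cfg = detection_config(),
                           trk_cfg = tracking_config(), tracker = NULL) {
  tr <- if (is.null(tracker)) tracker_new(det_cfg, trk_cfg) else tracker
  if (inherits(frames, "frame_source")) {
    for (i in seq_len(frames$n_frames))
      tracker_step(tr, frames$get_frame(i))
  } else {
    for (f in frames) tracker_step(tr, f)
  }
  out <- tracker_fragments(tr)
  attr(out, "tracker") <- tr
  out
}
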