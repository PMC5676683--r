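# Pipeline plumbing: frame/CSV readers and writers, key=value config files,
# and the end-to-end run. All trajectory artifacts are plain CSV
# (inspectable and diff-able); reports are JSON.

#' Read a frame sequence from a directory of PNG files
#'
#' Files are taken in lexicographic order; zero-padded names
#' (`frame_000000.png`) therefore stream in frame order. Color images are
#' converted to grayscale with the ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B). Frames are read lazily.
#'
#' @param path directory containing `.png` frames.
#' @return A `frame_source` with `$n_frames` and `$get_frame(i)` (1-based;
#'   frame indices are `i - 1`).
#' @export
read_frames <- function(path) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no frames found in ", path)
  get_frame <- function(i) {
    arr <- tryCatch(png::readPNG(files[i]),
                    error = function(e) stop("unreadable frame ", i - 1L,
                                             " (", files[i], "): ",
                                             conditionMessage(e)))
    px <- if (length(dim(arr)) == 3L)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr
    gray_frame(round(px * 255), index = i - 1L)
  }
  structure(list(n_frames = length(files), get_frame = get_frame),
            class = "frame_source")
}

#' Write fragments to CSV
#'
#' One row per detection: `fragment_id,frame,t,x,y,size,hu1..hu7,
#' hist0..hist{kn-1}`, plus the fragment's closing reason. The file
#' round-trips losslessly through [read_fragments_csv()].
#'
#' @param fragments list of fragments (with `hist`/`hu` feature matrices).
#' @param path output file.
#' @export
write_fragments_csv <- function(fragments, path) {
  rows <- lapply(fragments, function(fr) {
    kn <- if (is.null(fr$hist)) 0L else nrow(fr$hist)
    df <- data.frame(fragment_id = fr$id, frame = fr$frames, t = fr$t,
                     x = fr$x, y = fr$y, size = fr$size,
                     inactive_reason = fr$inactive_reason)
    if (!is.null(fr$hu)) {
      hu <- as.data.frame(t(fr$hu))
      names(hu) <- paste0("hu", 1:7)
      df <- cbind(df, hu)
    }
    if (kn > 0L) {
      hs <- as.data.frame(t(fr$hist))
      names(hs) <- paste0("hist", seq_len(kn) - 1L)
      df <- cbind(df, hs)
    }
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read fragments back from CSV
#'
#' @param path a file written by [write_fragments_csv()].
#' @param fps time base (used only if the file lacks a `t` column).
#' @return List of `fragment` objects.
#' @export
read_fragments_csv <- function(path, fps = 25) {
  df <- read.csv(path)
  need <- c("fragment_id", "frame", "x", "y", "size")
  if (!all(need %in% names(df)))
    stop("malformed fragments CSV: missing ",
         paste(setdiff(need, names(df)), collapse = ", "))
  hu_cols <- grep("^hu[1-7]$", names(df), value = TRUE)
  hist_cols <- grep("^hist[0-9]+$", names(df), value = TRUE)
  hist_cols <- hist_cols[order(as.integer(sub("hist", "", hist_cols)))]
  lapply(split(df, df$fragment_id), function(d) {
    d <- d[order(d$frame), ]
    new_fragment(d$fragment_id[1], d$frame, d$x, d$y, size = d$size,
                 t = if ("t" %in% names(df)) d$t else d$frame / fps,
                 hist = if (length(hist_cols)) t(as.matrix(d[hist_cols])),
                 hu = if (length(hu_cols)) t(as.matrix(d[hu_cols])),
                 inactive_reason = if ("inactive_reason" %in% names(d))
                   d$inactive_reason[1] else "end_of_video")
  })
}

#' Read ground truth from CSV
#'
#' @param path CSV with columns `frame,x,y,animal_id`.
#' @param fps frames per second of the video.
#' @return A [ground_truth()].
#' @export
read_truth <- function(path, fps = 25) {
  df <- read.csv(path)
  need <- c("frame", "x", "y", "animal_id")
  bad <- which(!stats::complete.cases(df[intersect(need, names(df))]))
  if (!all(need %in% names(df)))
    stop("malformed truth CSV: missing ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (length(bad) > 0L)
    stop("malformed truth CSV row(s): line ",
         paste(bad + 1L, collapse = ", "))
  n_frames <- max(df$frame) + 1L
  ground_truth(df, n_animals = max(df$animal_id), fps = fps,
               duration_minutes = n_frames / fps / 60)
}

#' Parse a key=value config file
#'
#' Lines of `key = value`; `#` starts a comment; values are parsed as
#' numbers when possible, `true`/`false` as logicals.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false"))
        as.logical(toupper(val))
      else val
  }
  out
}

#' Run the full pipeline
#'
#' Tracks a frame sequence into fragments, fuses them into identities, and
#' (when ground truth is given) evaluates the result. Writes the fragments
#' CSV, identities CSV, assignment JSON, metrics JSON and a run log of all
#' effective parameters to `out_dir`.
#'
#' @param frames a `frame_source`, a list of frames, or a directory path.
#' @param n_animals number of animals in the experiment.
#' @param out_dir output directory (created if needed); `NULL` for no files.
#' @param det_cfg,trk_cfg,sim_cfg,asg_cfg module configurations.
#' @param truth optional [ground_truth()] (or truth CSV path) for
#'   evaluation.
#' @param seed seed recorded in the run log and used for the similarity
#'   subsampling.
#' @return List with `fragments`, `assignment`, `classification` and
#'   `metrics` (the latter two `NULL` without truth), invisibly.
#' @export
run_pipeline <- function(frames, n_animals, out_dir = NULL,
                         det_cfg = detection_config(),
                         trk_cfg = tracking_config(),
                         sim_cfg = similarity_config(),
                         asg_cfg = assignment_config(),
                         truth = NULL, seed = 1L) {
  if (is.character(frames)) frames <- read_frames(frames)
  if (is.character(truth)) truth <- read_truth(truth, fps = det_cfg$fps)
  sim_cfg$seed <- as.integer(seed)
  fragments <- track_sequence(frames, det_cfg, trk_cfg)
  assignment <- solve_identities(fragments, n_animals, sim_cfg, asg_cfg)
  classification <- metrics <- NULL
  if (!is.null(truth)) {
    classification <- classify_fragments(assignment, fragments, truth,
                                         min_samples =
                                           asg_cfg$min_fragment_samples)
    metrics <- compute_metrics(classification, truth$duration_minutes,
                               n_animals)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fragments_csv(fragments, file.path(out_dir, "fragments.csv"))
    write_identities_csv(fragments, assignment,
                         file.path(out_dir, "identities.csv"))
    jsonlite::write_json(
      list(labels = as.list(assignment$labels),
           unassigned = assignment$unassigned,
           stopped_at = as.list(assignment$stopped_at),
           n_animals = n_animals),
      file.path(out_dir, "assignment.json"), auto_unbox = TRUE,
      pretty = TRUE, na = "null")
    if (!is.null(metrics))
      jsonlite::write_json(
        list(CSR = metrics$CSR, CFR = metrics$CFR, IER = metrics$IER,
             fragments = as.list(metrics$fragments),
             samples = as.list(metrics$samples)),
        file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
        pretty = TRUE)
    log <- list(seed = seed, n_animals = n_animals,
                detection = unclass(det_cfg), tracking = unclass(trk_cfg),
                similarity = unclass(sim_cfg), assignment = unclass(asg_cfg))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  invisible(list(fragments = fragments, assignment = assignment,
                 classification = classification, metrics = metrics))
}

#' Write per-identity trajectories to CSV
#'
#' One row per detection of every assigned fragment:
#' `identity,fragment_id,frame,t,x,y,size`.
#'
#' @param fragments fragment list.
#' @param assignment an `identity_assignment`.
#' @param path output file.
#' @export
write_identities_csv <- function(fragments, assignment, path) {
  labels <- assignment$labels
  rows <- lapply(fragments, function(fr) {
    k <- labels[as.character(fr$id)]
    if (length(k) == 0L || is.na(k)) return(NULL)
    data.frame(identity = as.integer(k), fragment_id = fr$id,
               frame = fr$frames, t = fr$t, x = fr$x, y = fr$y,
               size = fr$size)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows)
    else data.frame(identity = integer(0), fragment_id = integer(0),
                    frame = integer(0), t = numeric(0), x = numeric(0),
                    y = numeric(0), size = numeric(0))
  df <- df[order(df$identity, df$frame), ]
  write.csv(df, path, row.names = FALSE)
}
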