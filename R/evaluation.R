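# Ground-truth validation.
#
# Fragments are compared with per-frame ground-truth labels, with error
# propagation: the first fragment given each identity defines that
# identity's reference animal, and every later fragment with that identity
# is correct only if it belongs to the same reference animal — so a single
# swap makes all subsequent fragments of both identities incorrect.
# Metrics: CFR (correct fragment rate) and IER (identity errors per animal
# per minute) count fragments; CSR (correct sample rate) counts samples.

#' Ground truth container
#'
#' @param positions data frame with columns `frame`, `x`, `y`, `animal_id`
#'   (one row per animal per frame; 0-based frames, 0-based pixel
#'   coordinates with x = column).
#' @param n_animals number of animals.
#' @param fps frames per second.
#' @param duration_minutes total video duration in minutes.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(positions, n_animals, fps, duration_minutes) {
  stopifnot(all(c("frame", "x", "y", "animal_id") %in% names(positions)),
            n_animals >= 1, fps > 0, duration_minutes > 0)
  structure(list(positions = positions, n_animals = n_animals,
                 fps = fps, duration_minutes = duration_minutes),
            class = "ground_truth")
}

#' True animal of each fragment
#'
#' Each detection is matched to the nearest ground-truth center on its frame
#' (within `max_radius` pixels); a fragment's true animal is the majority
#' label of its detections.
#'
#' @param fragments list of fragments.
#' @param truth a [ground_truth()].
#' @param max_radius maximum center-to-detection distance for a match.
#' @return Integer vector of true animal ids (NA where a fragment has no
#'   labeled detection), named by fragment id.
#' @export
fragment_truth_labels <- function(fragments, truth, max_radius = 30) {
  pos <- truth$positions
  by_frame <- split(pos, pos$frame)
  out <- vapply(fragments, function(fr) {
    lab <- integer(0)
    for (k in seq_len(fr$n)) {
      p <- by_frame[[as.character(fr$frames[k])]]
      if (is.null(p)) next
      d <- sqrt((p$x - fr$x[k])^2 + (p$y - fr$y[k])^2)
      if (min(d) <= max_radius) lab <- c(lab, p$animal_id[which.min(d)])
    }
    if (length(lab) == 0L) return(NA_integer_)
    tab <- table(lab)
    as.integer(names(tab)[which.max(tab)])
  }, 0L)
  stats::setNames(out, as.character(vapply(fragments, `[[`, 0, "id")))
}

#' Classify fragments as correct, incorrect or not assigned
#'
#' Implements the validation protocol with error propagation. For each
#' identity label, the reference animal is the true animal of the
#' first-starting fragment given that label. An assigned fragment is correct
#' (CF) if its true animal equals the reference animal, otherwise incorrect
#' (IF); unassigned fragments are NF. Fragments with fewer than
#' `min_samples` detections are discarded from all sets; for the IER,
#' incorrect fragments shorter than `min_ier_seconds` of video are
#' additionally discounted.
#'
#' @param assignment an `identity_assignment` (or a named label vector).
#' @param fragments the fragment list the assignment refers to.
#' @param truth a [ground_truth()].
#' @param min_samples discard threshold (samples).
#' @param min_ier_seconds IER duration threshold (seconds).
#' @param max_radius ground-truth matching radius (pixels).
#' @return A `fragment_classification`: list of fragment-id vectors `CF`,
#'   `IF`, `NF`, sample counts `samples_CF`, `samples_IF`, `samples_NF`,
#'   the IER-eligible incorrect count `IF_ier`, and per-fragment detail.
#' @export
classify_fragments <- function(assignment, fragments, truth,
                               min_samples = 25L, min_ier_seconds = 1.0,
                               max_radius = 30) {
  labels <- if (inherits(assignment, "identity_assignment"))
    assignment$labels else assignment
  n <- vapply(fragments, `[[`, 0, "n")
  ids <- as.character(vapply(fragments, `[[`, 0, "id"))
  keep <- n >= min_samples
  fragments <- fragments[keep]; ids <- ids[keep]; n <- n[keep]
  tl <- fragment_truth_labels(fragments, truth, max_radius)
  if (any(is.na(tl)))
    stop("fragment(s) with no ground-truth label: ",
         paste(ids[is.na(tl)], collapse = ", "))
  lab <- labels[ids]
  starts <- vapply(fragments, `[[`, 0L, "start_frame")
  # reference animal per identity = truth of its first-starting fragment
  ref <- integer(0)
  for (k in sort(unique(lab[!is.na(lab)]))) {
    members <- which(!is.na(lab) & lab == k)
    first <- members[which.min(starts[members])]
    ref[as.character(k)] <- tl[first]
  }
  status <- ifelse(is.na(lab), "NF",
                   ifelse(tl == ref[as.character(lab)], "CF", "IF"))
  seconds <- n / truth$fps
  cf <- ids[status == "CF"]; if_ <- ids[status == "IF"]
  nf <- ids[status == "NF"]
  structure(list(
    CF = cf, IF = if_, NF = nf,
    samples_CF = sum(n[status == "CF"]),
    samples_IF = sum(n[status == "IF"]),
    samples_NF = sum(n[status == "NF"]),
    IF_ier = sum(status == "IF" & seconds >= min_ier_seconds),
    detail = data.frame(fragment_id = ids, n_samples = n,
                        identity = as.integer(lab), true_animal = tl,
                        status = status, row.names = NULL)),
    class = "fragment_classification")
}

#' Validation metrics: CSR, CFR, IER
#'
#' `CFR = CF / (CF + IF + NF)` over fragment counts, `CSR = |CF| / (|CF| +
#' |IF| + |NF|)` over sample counts, and `IER = IF / (minutes x animals)`
#' counting only IER-eligible incorrect fragments. `minutes` is the total
#' video duration.
#'
#' @param classification a [classify_fragments()] result (or a list with
#'   fields `CF`, `IF`, `NF`, `samples_CF`, `samples_IF`, `samples_NF`, and
#'   optionally `IF_ier`).
#' @param duration_minutes total video duration in minutes.
#' @param n_animals number of animals.
#' @return A `metrics_report`: list with `CSR`, `CFR`, `IER`, the fragment
#'   and sample counts, `duration_minutes` and `n_animals`.
#' @export
compute_metrics <- function(classification, duration_minutes, n_animals) {
  stopifnot(duration_minutes > 0, n_animals >= 1)
  cl <- classification
  nf_counts <- c(CF = length(cl$CF), IF = length(cl$IF), NF = length(cl$NF))
  tot_f <- sum(nf_counts)
  tot_s <- cl$samples_CF + cl$samples_IF + cl$samples_NF
  if (tot_f == 0 || tot_s == 0) stop("empty fragment classification")
  if_ier <- if (!is.null(cl$IF_ier)) cl$IF_ier else length(cl$IF)
  structure(list(
    CSR = cl$samples_CF / tot_s,
    CFR = nf_counts[["CF"]] / tot_f,
    IER = if_ier / (duration_minutes * n_animals),
    fragments = nf_counts,
    samples = c(CF = cl$samples_CF, IF = cl$samples_IF,
                NF = cl$samples_NF),
    duration_minutes = duration_minutes, n_animals = n_animals),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("CSR %.3f  CFR %.3f  IER %.3f  (CF/IF/NF fragments %d/%d/%d)\n",
              x$CSR, x$CFR, x$IER, x$fragments[["CF"]],
              x$fragments[["IF"]], x$fragments[["NF"]]))
  invisible(x)
}
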