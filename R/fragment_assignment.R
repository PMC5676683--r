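# Fusing trajectory fragments into per-animal identities.
#
# Fragments are split into long and short; groups of long fragments in which
# all animals are simultaneously observed are matched to each other by
# Hungarian maximization of IdMatrix scores (the first group anchors the
# identity labels); remaining fragments are assigned greedily from highest to
# lowest IdMatrix value, long pool before short pool, with constraint
# propagation after every assignment, until the best value drops below a
# user-selected minimum correlation.

#' Assignment configuration
#'
#' @param long_limit minimum sample count of a "long" fragment.
#' @param min_correlation stopping value for the greedy assignment.
#' @param min_fragment_samples fragments with fewer samples are discarded
#'   before assignment.
#' @return An `assignment_config` list.
#' @export
assignment_config <- function(long_limit = 50L, min_correlation = 0.5,
                              min_fragment_samples = 25L) {
  stopifnot(long_limit > min_fragment_samples, min_fragment_samples > 0,
            min_correlation >= 0, min_correlation <= 1)
  structure(list(long_limit = as.integer(long_limit),
                 min_correlation = min_correlation,
                 min_fragment_samples = as.integer(min_fragment_samples)),
            class = "assignment_config")
}

#' Split fragments into long and short pools
#'
#' Fragments with fewer than `min_fragment_samples` samples are discarded;
#' of the rest, those with at least `long_limit` samples are long.
#'
#' @param fragments list of fragments.
#' @param long_limit long-fragment sample threshold.
#' @param min_fragment_samples discard threshold.
#' @return List with `long`, `short` and `discarded` fragment lists.
#' @export
split_long_short <- function(fragments, long_limit = 50L,
                             min_fragment_samples = 25L) {
  n <- vapply(fragments, `[[`, 0, "n")
  list(long = fragments[n >= long_limit],
       short = fragments[n >= min_fragment_samples & n < long_limit],
       discarded = fragments[n < min_fragment_samples])
}

#' Find complete groups of long fragments
#'
#' A complete group is a set of exactly `n_animals` long fragments that are
#' all simultaneously alive at some frame, i.e. a moment where every animal
#' is observed. Groups are reported in order of the first frame at which
#' they are complete.
#'
#' @param long_fragments list of long fragments.
#' @param n_animals number of animals in the experiment.
#' @return List of integer vectors of fragment ids (possibly empty).
#' @export
find_complete_groups <- function(long_fragments, n_animals) {
  stopifnot(n_animals >= 1)
  if (length(long_fragments) < n_animals) return(list())
  st <- vapply(long_fragments, `[[`, 0L, "start_frame")
  en <- vapply(long_fragments, `[[`, 0L, "end_frame")
  ids <- vapply(long_fragments, `[[`, 0, "id")
  bounds <- sort(unique(c(st, en + 1L)))
  seen <- character(0)
  groups <- list()
  for (f in bounds) {
    alive <- which(st <= f & en >= f)
    if (length(alive) != n_animals) next
    key <- paste(sort(ids[alive]), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    groups[[length(groups) + 1L]] <- ids[alive][order(st[alive], ids[alive])]
  }
  groups
}

# IdMatrix lookup helpers: labels are a named integer vector keyed by
# fragment id (NA = unassigned)
.id_index <- function(id_matrix) {
  ids <- attr(id_matrix, "fragment_ids")
  stats::setNames(seq_along(ids), as.character(ids))
}

.empty_labels <- function(fragments) {
  ids <- vapply(fragments, `[[`, 0, "id")
  stats::setNames(rep(NA_integer_, length(ids)), as.character(ids))
}

#' Assign identities to complete groups of long fragments
#'
#' The first group's fragments receive identities `1..n_animals` in start-
#' frame order (the anchoring convention: the first detected fragments define
#' the identities). Each subsequent group is matched against the already
#' labeled fragments by Hungarian maximization of summed IdMatrix values;
#' a group member whose best achievable score is zero (or that would coexist
#' with a fragment of the candidate identity) is left unassigned.
#'
#' @param groups list of fragment-id vectors from [find_complete_groups()].
#' @param id_matrix an [build_id_matrix()] result.
#' @param n_animals number of animals.
#' @param fragments the full fragment list (for coexistence checks).
#' @return Named integer vector: fragment id -> identity (NA = unassigned).
#' @export
assign_groups <- function(groups, id_matrix, n_animals, fragments) {
  labels <- .empty_labels(fragments)
  if (length(groups) == 0L) return(labels)
  idx <- .id_index(id_matrix)
  frag_by_id <- stats::setNames(fragments,
                                as.character(vapply(fragments, `[[`, 0, "id")))
  labels[as.character(groups[[1L]])] <- seq_len(n_animals)
  for (g in groups[-1L]) {
    gid <- as.character(g)
    todo <- gid[is.na(labels[gid])]
    if (length(todo) == 0L) next
    score <- matrix(0, length(todo), n_animals)
    for (a in seq_along(todo)) {
      fa <- frag_by_id[[todo[a]]]
      for (k in seq_len(n_animals)) {
        members <- names(labels)[!is.na(labels) & labels == k]
        if (length(members) == 0L) next
        if (any(vapply(members, function(m)
              coexist(fa, frag_by_id[[m]]), TRUE))) {
          score[a, k] <- -1
        } else {
          score[a, k] <- max(id_matrix[idx[todo[a]], idx[members]])
        }
      }
    }
    sol <- solve_assignment(1 - score)   # maximize summed scores
    for (a in seq_along(todo)) {
      k <- sol[a]
      if (!is.na(k) && score[a, k] > 0) labels[todo[a]] <- k
    }
  }
  labels
}

# zero all IdMatrix working entries made impossible by labeling fragment
# `fid` with identity k: entries between identity-k members and fragments
# coexisting with any member, and entries from `fid` to other identities
.propagate <- function(W, idx, labels, fid, frag_by_id) {
  k <- labels[[fid]]
  members <- names(labels)[!is.na(labels) & labels == k]
  others <- names(labels)[!is.na(labels) & labels != k]
  all_ids <- names(labels)
  fa <- frag_by_id[[fid]]
  for (g in all_ids) {
    if (g %in% members) next
    if (coexist(frag_by_id[[g]], fa)) {
      W[idx[g], idx[members]] <- 0
      W[idx[members], idx[g]] <- 0
    }
  }
  coex_with_members <- vapply(all_ids, function(g)
    any(vapply(members, function(m)
      coexist(frag_by_id[[g]], frag_by_id[[m]]), TRUE)), TRUE)
  bad <- all_ids[coex_with_members & !(all_ids %in% members)]
  W[idx[fid], idx[bad]] <- 0
  W[idx[bad], idx[fid]] <- 0
  if (length(others) > 0L) {
    W[idx[fid], idx[others]] <- 0
    W[idx[others], idx[fid]] <- 0
  }
  W
}

#' Greedy best-correlation assignment with knowledge propagation
#'
#' Repeatedly links the unassigned fragment with the largest IdMatrix value
#' against any labeled fragment, exhausting the long pool before considering
#' the short pool, and stopping a pool when its best value falls below
#' `min_correlation`. After each assignment the working matrix is updated:
#' entries that would now violate temporal coexistence and entries to other
#' identities are zeroed, propagating each decision to the remaining
#' fragments. Ties are broken by earlier start frame, then lower fragment id.
#'
#' @param id_matrix an [build_id_matrix()] result.
#' @param partial named label vector (fragment id -> identity, NA =
#'   unassigned), e.g. from [assign_groups()].
#' @param long,short fragment lists (the two pools).
#' @param min_correlation stopping value.
#' @param fragments full fragment list.
#' @return Named integer label vector; attribute `"stopped_at"` records the
#'   best value at which each pool stopped.
#' @export
greedy_assign <- function(id_matrix, partial, long, short,
                          min_correlation = 0.5, fragments) {
  labels <- partial
  idx <- .id_index(id_matrix)
  frag_by_id <- stats::setNames(fragments,
                                as.character(vapply(fragments, `[[`, 0, "id")))
  W <- unclass(id_matrix)
  diag(W) <- 0
  for (fid in names(labels)[!is.na(labels)])
    W <- .propagate(W, idx, labels, fid, frag_by_id)
  stopped <- c(long = NA_real_, short = NA_real_)
  for (pool_name in c("long", "short")) {
    pool <- if (pool_name == "long") long else short
    pool_ids <- as.character(vapply(pool, `[[`, 0, "id"))
    repeat {
      un <- pool_ids[is.na(labels[pool_ids])]
      lab <- names(labels)[!is.na(labels)]
      if (length(un) == 0L || length(lab) == 0L) break
      sub <- W[idx[un], idx[lab], drop = FALSE]
      best <- max(sub)
      if (best < min_correlation) { stopped[pool_name] <- best; break }
      hit <- which(sub == best, arr.ind = TRUE)
      if (nrow(hit) > 1L) {
        su <- vapply(un[hit[, 1]], function(u)
          frag_by_id[[u]]$start_frame, 0L)
        sid <- vapply(un[hit[, 1]], function(u) frag_by_id[[u]]$id, 0)
        hit <- hit[order(su, sid), , drop = FALSE]
      }
      u <- un[hit[1, 1]]; l <- lab[hit[1, 2]]
      k <- labels[[l]]
      members <- names(labels)[!is.na(labels) & labels == k]
      if (any(vapply(members, function(m)
            coexist(frag_by_id[[u]], frag_by_id[[m]]), TRUE))) {
        # stale entry: zero and continue
        W[idx[u], idx[members]] <- 0
        W[idx[members], idx[u]] <- 0
        next
      }
      labels[u] <- k
      W <- .propagate(W, idx, labels, u, frag_by_id)
    }
  }
  attr(labels, "stopped_at") <- stopped
  labels
}

#' Fuse trajectory fragments into animal identities
#'
#' Full assignment pipeline: build the IdMatrix, split long/short, find
#' complete groups, anchor and match them by Hungarian optimization, then
#' greedily assign the remaining fragments. If no complete group exists, the
#' largest set of simultaneously coexisting long fragments anchors the
#' identities instead (coexisting fragments are necessarily distinct
#' animals); this fallback is reported with a message.
#'
#' @param fragments list of fragments from [track_sequence()].
#' @param n_animals number of animals in the experiment.
#' @param sim_cfg a [similarity_config()].
#' @param asg_cfg an [assignment_config()].
#' @param id_matrix optionally a precomputed [build_id_matrix()].
#' @return An `identity_assignment`: list with `labels` (named integer
#'   vector, NA = unassigned), `n_animals`, `unassigned` (fragment ids),
#'   `stopped_at`, and the `id_matrix` used.
#' @export
solve_identities <- function(fragments, n_animals,
                             sim_cfg = similarity_config(),
                             asg_cfg = assignment_config(),
                             id_matrix = NULL) {
  pools <- split_long_short(fragments, asg_cfg$long_limit,
                            asg_cfg$min_fragment_samples)
  usable <- c(pools$long, pools$short)
  if (length(usable) == 0L)
    stop("no fragments with enough samples to assign")
  if (length(usable) == 1L) {
    labels <- .empty_labels(usable)
    labels[1L] <- 1L
    return(structure(list(labels = labels, n_animals = n_animals,
                          unassigned = character(0),
                          stopped_at = c(long = NA_real_, short = NA_real_),
                          id_matrix = NULL),
                     class = "identity_assignment"))
  }
  if (is.null(id_matrix)) id_matrix <- build_id_matrix(usable, sim_cfg)
  groups <- find_complete_groups(pools$long, n_animals)
  if (length(groups) > 0L) {
    partial <- assign_groups(groups, id_matrix, n_animals, usable)
  } else {
    message("no complete group of long fragments found; ",
            "anchoring on the largest coexisting set")
    partial <- .empty_labels(usable)
    anchor <- .largest_coexisting(pools$long)
    if (length(anchor) > 0L)
      partial[as.character(anchor)] <- seq_along(anchor)
  }
  labels <- greedy_assign(id_matrix, partial, pools$long, pools$short,
                          asg_cfg$min_correlation, usable)
  structure(list(labels = labels, n_animals = n_animals,
                 unassigned = names(labels)[is.na(labels)],
                 stopped_at = attr(labels, "stopped_at"),
                 id_matrix = id_matrix),
            class = "identity_assignment")
}

# largest set of long fragments simultaneously alive at one frame, ordered
# by start frame (fallback anchor when no complete group exists)
.largest_coexisting <- function(long_fragments) {
  if (length(long_fragments) == 0L) return(integer(0))
  st <- vapply(long_fragments, `[[`, 0L, "start_frame")
  en <- vapply(long_fragments, `[[`, 0L, "end_frame")
  ids <- vapply(long_fragments, `[[`, 0, "id")
  best <- integer(0)
  for (f in sort(unique(st))) {
    alive <- which(st <= f & en >= f)
    if (length(alive) > length(best))
      best <- alive[order(st[alive], ids[alive])]
  }
  ids[best]
}

#' @export
print.identity_assignment <- function(x, ...) {
  cat(sprintf("<identity_assignment: %d fragments, %d animals, %d unassigned>\n",
              length(x$labels), x$n_animals, length(x$unassigned)))
  invisible(x)
}
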