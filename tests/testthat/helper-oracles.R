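# Independent oracles and fixture builders used across the suite.

# --- flood-fill connected-components oracle (pure R, queue-based) ----------
flood_fill_components <- function(mask, min_size = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    members <- integer(0)
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, (p[2] - 1L) * nr + p[1])
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        q <- p + c(dr, dc)
        if (q[1] < 1 || q[1] > nr || q[2] < 1 || q[2] > nc) next
        if (mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    if (length(members) >= min_size)
      comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# --- exhaustive assignment oracle ------------------------------------------
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (s in perms(v[-i])) out <- c(out, list(c(v[i], s)))
  out
}

brute_force_min_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost); k <- min(n, m)
  best <- Inf
  rows <- if (k == n) list(seq_len(n))
    else utils::combn(seq_len(n), k, simplify = FALSE)
  for (rr in rows)
    for (p in perms(seq_len(m)))
      best <- min(best, sum(cost[cbind(rr, p[seq_len(k)])]))
  best
}

brute_force_max_score <- function(score) {
  best <- -Inf
  for (p in perms(seq_len(ncol(score)))) {
    k <- min(nrow(score), ncol(score))
    best <- max(best, sum(score[cbind(seq_len(k), p[seq_len(k)])]))
  }
  best
}

# --- image helpers for moment tests ----------------------------------------
full_mask <- function(img) {
  structure(list(
    px = cbind(row = as.vector(row(img)) - 1L,
               col = as.vector(col(img)) - 1L),
    bbox = c(0L, 0L, nrow(img) - 1L, ncol(img) - 1L)),
    class = "blob_mask")
}

rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# random textured elliptical blob on a zero background
random_texture_blob <- function(i, n = 41L) {
  a <- runif(1, 8, 16); b <- runif(1, 5, a)
  th <- runif(1, 0, pi)
  xs <- seq_len(n) - (n + 1) / 2
  img <- matrix(0, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    u <- xs[c] * cos(th) + xs[r] * sin(th)
    v <- -xs[c] * sin(th) + xs[r] * cos(th)
    if ((u / a)^2 + (v / b)^2 <= 1)
      img[r, c] <- 100 + 80 * sin(u / 3 + i) * cos(v / 2.5)
  }
  img
}

# first Hu invariant via direct double-loop central moments (independent of
# the package's vectorized implementation)
oracle_hu1 <- function(img) {
  m00 <- 0; mx <- 0; my <- 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    w <- img[r, c]
    m00 <- m00 + w; mx <- mx + w * (c - 1); my <- my + w * (r - 1)
  }
  cx <- mx / m00; cy <- my / m00
  mu20 <- 0; mu02 <- 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    w <- img[r, c]
    mu20 <- mu20 + w * (c - 1 - cx)^2
    mu02 <- mu02 + w * (r - 1 - cy)^2
  }
  (mu20 + mu02) / m00^2
}

# --- synthetic fragment builders -------------------------------------------
# fragment whose detections all carry the given histogram columns
make_hist_fragment <- function(id, start, hist, hu = NULL, size = NULL,
                               x = NULL, y = NULL) {
  n <- ncol(hist)
  if (is.null(hu)) hu <- matrix(rep(c(0.2, 0.01, 1e-4, 1e-5, 1e-9,
                                      1e-6, 1e-10), n), nrow = 7)
  if (is.null(size)) size <- rep(100, n)
  new_fragment(id, start:(start + n - 1L),
               x = if (is.null(x)) rep(10, n) else x,
               y = if (is.null(y)) rep(10, n) else y,
               size = size, hist = hist, hu = hu)
}

# histogram prototype with mass in an animal-specific band
hist_proto <- function(class, kn = 16L) {
  h <- rep(1, kn)
  band <- ((class - 1L) * 5L) %% (kn - 4L) + 1L
  h[band:(band + 3L)] <- c(30, 60, 60, 30)
  h
}

noisy_hist_cols <- function(proto, n, noise_sd = 2, seed = 1) {
  withr::with_seed(seed, {
    sapply(seq_len(n), function(i) pmax(0, proto + rnorm(length(proto),
                                                         0, noise_sd)))
  })
}

# --- independent per-sample confusion oracle -------------------------------
# recomputes the correct-sample rate by per-sample counting, with its own
# truth matching and majority-vote code path
oracle_sample_csr <- function(fragments, labels, truth, min_samples = 25L,
                              radius = 30) {
  pos <- truth$positions
  elig <- Filter(function(f) f$n >= min_samples, fragments)
  frag_animal <- numeric(0)
  for (f in elig) {
    votes <- c()
    for (k in seq_len(f$n)) {
      p <- pos[pos$frame == f$frames[k], ]
      if (nrow(p) == 0L) next
      d2 <- (p$x - f$x[k])^2 + (p$y - f$y[k])^2
      if (sqrt(min(d2)) <= radius)
        votes <- c(votes, p$animal_id[which.min(d2)])
    }
    tt <- sort(table(votes), decreasing = TRUE)
    frag_animal[as.character(f$id)] <- as.integer(names(tt)[1])
  }
  ids <- as.character(vapply(elig, `[[`, 0, "id"))
  lab <- labels[ids]
  starts <- vapply(elig, `[[`, 0L, "start_frame")
  refs <- numeric(0)
  for (k in unique(lab[!is.na(lab)])) {
    first <- ids[which(!is.na(lab) & lab == k)][
      which.min(starts[which(!is.na(lab) & lab == k)])]
    refs[as.character(k)] <- frag_animal[first]
  }
  correct <- 0; total <- 0
  for (f in elig) {
    total <- total + f$n
    k <- lab[as.character(f$id)]
    if (!is.na(k) &&
        frag_animal[as.character(f$id)] == refs[as.character(k)])
      correct <- correct + f$n
  }
  correct / total
}

# --- memoized scene fixtures (shared across test files) --------------------
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tracked_scene <- function(preset, seed = 1L, n_frames = NULL) {
  key <- paste(preset, seed, n_frames %||% "full", sep = "_")
  cached(key, {
    scene <- generate_scene(scene_preset(preset, seed = seed,
                                         n_frames = n_frames))
    cfgs <- scene_tracking_defaults(scene$cfg)
    fragments <- track_sequence(scene$frames, cfgs$det_cfg, cfgs$trk_cfg)
    list(scene = scene, fragments = fragments,
         events = tracker_events(attr(fragments, "tracker")),
         cfgs = cfgs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
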