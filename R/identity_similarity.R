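# Fragment-identity similarity.
#
# The likelihood that two trajectory fragments belong to the same animal is
# scored from the Pearson correlations of their detections' ROI intensity
# histograms: Sim(f_R, f_C) = A * sum_L w_L r_L, where A is the maximum
# histogram correlation over sampled detection pairs, r_L the fraction of
# correlations falling in level L of [0, 1), and w_L a Gaussian weight
# centered at perfect correlation (mu = 1, sigma = 0.05). Only detection
# pairs with similar shape (reciprocal-Hu distance) and size are correlated.
# The IdMatrix entry for two non-coexisting fragments is the correlation of
# their Sim profiles against all other fragments: two fragments of the same
# animal are not only similar to each other, they are similar to the same
# other fragments.

#' Similarity configuration
#'
#' @param Ln number of correlation levels on `[0, 1)`.
#' @param mu,sigma center and width of the Gaussian level weight (the
#'   defaults concentrate weight very near perfect correlation).
#' @param shape_diff_limit maximum reciprocal-Hu shape difference for a
#'   detection pair to be correlated.
#' @param size_change_limit_id maximum symmetric relative size change for a
#'   detection pair to be correlated.
#' @param max_pairs cap on the detection cross product per fragment pair;
#'   larger cross products are deterministically subsampled.
#' @param hu_epsilon magnitude floor applied before taking Hu reciprocals.
#' @param shape_log_hu if `TRUE` (default) the shape filter compares
#'   reciprocals of `sign(h) * log10(|h|)` instead of raw Hu reciprocals.
#'   Hu invariants span ten orders of magnitude, so raw reciprocal
#'   differences are dominated by the smallest components and no single
#'   threshold is meaningful; the log-magnitude convention (standard in
#'   contour matching) keeps the sum O(1) so `shape_diff_limit` behaves as
#'   a real shape gate.
#' @param seed seed for the deterministic pair subsampling.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(Ln = 10L, mu = 1, sigma = 0.05,
                              shape_diff_limit = 2.0,
                              size_change_limit_id = 0.5,
                              max_pairs = 10000L, hu_epsilon = 1e-8,
                              shape_log_hu = TRUE, seed = 1L) {
  stopifnot(Ln >= 2, sigma > 0, shape_diff_limit >= 0,
            size_change_limit_id >= 0, max_pairs >= 1, hu_epsilon > 0)
  structure(list(Ln = as.integer(Ln), mu = mu, sigma = sigma,
                 shape_diff_limit = shape_diff_limit,
                 size_change_limit_id = size_change_limit_id,
                 max_pairs = as.integer(max_pairs),
                 hu_epsilon = hu_epsilon, shape_log_hu = shape_log_hu,
                 seed = as.integer(seed)),
            class = "similarity_config")
}

#' Pearson correlation that never returns NaN
#'
#' Standard Pearson r; if either vector is constant the correlation is
#' undefined and 0 is returned instead of `NaN`.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  sa <- sum((a - mean(a))^2); sb <- sum((b - mean(b))^2)
  if (sa == 0 || sb == 0) return(0)
  sum((a - mean(a)) * (b - mean(b))) / sqrt(sa * sb)
}

# reciprocal Hu vector with a magnitude floor (sign preserved; zero treated
# as positive); log_hu switches to the sign * log10 magnitude convention
.hu_recip <- function(hu, eps, log_hu = FALSE) {
  s <- ifelse(hu >= 0, 1, -1)
  if (log_hu) {
    m <- s * log10(pmax(abs(hu), eps))
    s <- ifelse(m >= 0, 1, -1)
    1 / (s * pmax(abs(m), 1e-4))
  } else 1 / (s * pmax(abs(hu), eps))
}

#' Shape difference between two detections
#'
#' Sum over the seven Hu components of the absolute difference of their
#' reciprocals. Reciprocals are floored at `hu_epsilon` in magnitude so
#' near-zero invariants do not blow up. With `log_hu = TRUE` the reciprocals
#' are taken of `sign(h) * log10(|h|)` (the contour-matching convention used
#' by the pair filter; see [similarity_config()]).
#'
#' @param d1,d2 detections (or any list with a length-7 `hu` field).
#' @param hu_epsilon magnitude floor.
#' @param log_hu compare log-magnitude Hu values.
#' @return Non-negative scalar; zero for identical shapes.
#' @export
shape_diff <- function(d1, d2, hu_epsilon = 1e-8, log_hu = FALSE) {
  sum(abs(.hu_recip(d1$hu, hu_epsilon, log_hu) -
          .hu_recip(d2$hu, hu_epsilon, log_hu)))
}

# deterministic sample of k from n that neither reads nor disturbs the
# global RNG stream
.seeded_sample <- function(n, k, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  sample.int(n, k)
}

#' Histogram correlations between two fragments' detections
#'
#' Forms the cross product of the two fragments' detections (capped at
#' `max_pairs` by deterministic seeded subsampling), drops pairs whose shape
#' difference or size change exceeds the configured limits, and returns the
#' Pearson correlation of the remaining pairs' ROI histograms. Pairs removed
#' by the filters still count towards the denominator `n_pairs`.
#'
#' @param fR,fC fragments with `hist`, `hu` and `size` columns.
#' @param cfg a [similarity_config()].
#' @return List with `correlations` (numeric vector, possibly empty) and
#'   `n_pairs` (the denominator: sampled cross-product size).
#' @export
pair_correlations <- function(fR, fC, cfg = similarity_config()) {
  if (fR$n < 1L || fC$n < 1L) stop("fragments must be non-empty")
  # canonical argument order makes the subsample (and so Sim) symmetric
  if (is.numeric(fR$id) && is.numeric(fC$id) && fR$id > fC$id) {
    tmp <- fR; fR <- fC; fC <- tmp
  }
  total <- fR$n * fC$n
  if (total > cfg$max_pairs) {
    seed <- (cfg$seed * 2654435761 + fR$id * 40503 + fC$id) %% 2147483647
    idx <- .seeded_sample(total, cfg$max_pairs, seed)
  } else idx <- seq_len(total)
  ri <- ((idx - 1L) %% fR$n) + 1L
  ci <- ((idx - 1L) %/% fR$n) + 1L
  n_pairs <- length(idx)
  rhuR <- apply(fR$hu, 2, .hu_recip, eps = cfg$hu_epsilon,
                log_hu = isTRUE(cfg$shape_log_hu))
  rhuC <- apply(fC$hu, 2, .hu_recip, eps = cfg$hu_epsilon,
                log_hu = isTRUE(cfg$shape_log_hu))
  sd_ <- colSums(abs(rhuR[, ri, drop = FALSE] - rhuC[, ci, drop = FALSE]))
  dz <- size_change(fR$size[ri], fC$size[ci])
  keep <- sd_ <= cfg$shape_diff_limit & dz <= cfg$size_change_limit_id
  if (!any(keep))
    return(list(correlations = numeric(0), n_pairs = n_pairs))
  X <- fR$hist[, ri[keep], drop = FALSE]
  Y <- fC$hist[, ci[keep], drop = FALSE]
  kn <- nrow(X)
  Xc <- X - rep(colMeans(X), each = kn)
  Yc <- Y - rep(colMeans(Y), each = kn)
  den <- sqrt(colSums(Xc^2) * colSums(Yc^2))
  r <- ifelse(den == 0, 0, colSums(Xc * Yc) / den)
  list(correlations = as.numeric(r), n_pairs = n_pairs)
}

#' Similarity amplitude
#'
#' Maximum histogram correlation over the sampled detection pairs; 0 for an
#' empty correlation list.
#'
#' @param correlations numeric vector.
#' @return Scalar.
#' @export
similarity_amplitude <- function(correlations) {
  if (length(correlations) == 0L) return(0)
  max(correlations)
}

#' Gaussian-weighted correlation level distribution
#'
#' Bins correlations in `[0, 1)` into `Ln` half-open levels (1 exactly goes
#' to the top level; negative values are discarded but keep their place in
#' the denominator), and returns `sum_L w_L r_L` with `r_L = count_L /
#' n_pairs` and `w_L` the unnormalized Gaussian `exp(-(m_L - mu)^2 / (2
#' sigma^2))` at the level midpoint `m_L`.
#'
#' @param correlations numeric vector.
#' @param n_pairs denominator (>= `length(correlations)`).
#' @param cfg a [similarity_config()].
#' @return Non-negative scalar.
#' @export
weighted_distribution <- function(correlations, n_pairs,
                                  cfg = similarity_config()) {
  if (n_pairs == 0L) return(0)
  Ln <- cfg$Ln
  x <- correlations[correlations >= 0]
  if (length(x) == 0L) return(0)
  lev <- pmin(floor(x * Ln), Ln - 1L)          # 0-based level
  counts <- tabulate(lev + 1L, nbins = Ln)
  mids <- (seq_len(Ln) - 0.5) / Ln
  w <- exp(-(mids - cfg$mu)^2 / (2 * cfg$sigma^2))
  sum(w * counts / n_pairs)
}

#' Similarity between two fragments
#'
#' `Sim = A * sum_L w_L r_L`, with a negative amplitude clamped to 0 so the
#' similarity is non-negative; symmetric in its arguments.
#'
#' @param fR,fC fragments.
#' @param cfg a [similarity_config()].
#' @return Non-negative scalar.
#' @export
fragment_similarity <- function(fR, fC, cfg = similarity_config()) {
  pc <- pair_correlations(fR, fC, cfg)
  A <- similarity_amplitude(pc$correlations)
  if (A <= 0) return(0)
  A * weighted_distribution(pc$correlations, pc$n_pairs, cfg)
}

#' Do two fragments coexist in time?
#'
#' True iff the inclusive frame intervals `[first, last]` of the two
#' fragments overlap. Two coexisting fragments cannot be the same animal.
#' Abutting fragments (one ends the frame before the other starts) are
#' compatible.
#'
#' @param fR,fC fragments.
#' @return Logical.
#' @export
coexist <- function(fR, fC) {
  max(fR$start_frame, fC$start_frame) <= min(fR$end_frame, fC$end_frame)
}

#' Pairwise similarity matrix over a fragment set
#'
#' @param fragments list of fragments.
#' @param cfg a [similarity_config()].
#' @return A `sim_matrix`: symmetric N x N matrix with `fragment_ids`
#'   attribute.
#' @export
build_sim_matrix <- function(fragments, cfg = similarity_config()) {
  N <- length(fragments)
  S <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in i:N)
    S[i, j] <- S[j, i] <- fragment_similarity(fragments[[i]],
                                              fragments[[j]], cfg)
  structure(S, fragment_ids = vapply(fragments, `[[`, 0, "id"),
            class = c("sim_matrix", "matrix", "array"))
}

#' Fragment-identity likelihood matrix
#'
#' Entry (R, C) scores the likelihood that fragments R and C are the same
#' animal: 1 on the diagonal, exactly 0 for fragments that coexist in time,
#' and otherwise the Pearson correlation of the two fragments' similarity
#' profiles against all other fragments (self-entries excluded), clamped to
#' `[0, 1]`. When the correlation is undefined — fewer than two profile
#' entries, or a constant profile (a fragment similar to nothing else) —
#' the normalized pairwise similarity is used instead.
#'
#' @param fragments list of >= 2 fragments.
#' @param cfg a [similarity_config()].
#' @param sim optionally a precomputed [build_sim_matrix()] result.
#' @return An `id_matrix`: N x N matrix in `[0, 1]` with `fragment_ids`
#'   attribute.
#' @export
build_id_matrix <- function(fragments, cfg = similarity_config(),
                            sim = NULL) {
  N <- length(fragments)
  if (N < 2L) stop("need at least 2 fragments")
  if (is.null(sim)) sim <- build_sim_matrix(fragments, cfg)
  S <- unclass(sim)
  off <- S; diag(off) <- 0
  smax <- max(off)
  Id <- diag(N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (j <= i) next
    if (coexist(fragments[[i]], fragments[[j]])) { v <- 0 }
    else {
      keep <- setdiff(seq_len(N), c(i, j))
      u1 <- S[i, keep]; u2 <- S[j, keep]
      degenerate <- length(keep) < 2L ||
        stats::var(u1) == 0 || stats::var(u2) == 0
      v <- if (degenerate) { if (smax > 0) S[i, j] / smax else 0 }
        else pearson(u1, u2)
    }
    Id[i, j] <- Id[j, i] <- min(1, max(0, v))
  }
  structure(Id, fragment_ids = attr(sim, "fragment_ids"),
            class = c("id_matrix", "matrix", "array"))
}

#' Write a square fragment matrix as CSV
#'
#' @param m a `sim_matrix` or `id_matrix`.
#' @param path output file; fragment ids form the header row and first
#'   column.
#' @export
write_fragment_matrix <- function(m, path) {
  ids <- attr(m, "fragment_ids")
  df <- as.data.frame(unclass(m))
  names(df) <- ids
  df <- cbind(fragment_id = ids, df)
  write.csv(df, path, row.names = FALSE)
}
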