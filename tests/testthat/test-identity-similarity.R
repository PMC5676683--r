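test_that("pearson handles exact, anti- and degenerate correlation", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson(c(2, 2, 2), c(1, 5, 9)), 0)
})

test_that("shape difference sums reciprocal Hu distances", {
  d1 <- list(hu = c(0.2, 0.01, 1e-4, 1e-5, 1e-7, 1e-6, 1e-8))
  expect_equal(shape_diff(d1, d1), 0)
  d2 <- d1; d2$hu[1] <- 0.25
  expect_equal(shape_diff(d1, d2), abs(1 / 0.2 - 1 / 0.25))
  withr::with_seed(9, {
    for (i in 1:10) {
      a <- list(hu = rnorm(7) * 10^(-(0:6)))
      b <- list(hu = rnorm(7) * 10^(-(0:6)))
      expect_equal(shape_diff(a, b), shape_diff(b, a))
      expect_equal(shape_diff(a, b, log_hu = TRUE),
                   shape_diff(b, a, log_hu = TRUE))
    }
  })
})

test_that("pair correlations honour filters, caps and the denominator", {
  proto <- hist_proto(1)
  fA <- make_hist_fragment(1, 0, matrix(rep(proto, 3), ncol = 3))
  fB <- make_hist_fragment(2, 50, matrix(rep(proto, 4), ncol = 4))
  pc <- pair_correlations(fA, fB)
  expect_length(pc$correlations, 12L)
  expect_equal(pc$n_pairs, 12L)
  expect_true(all(abs(pc$correlations - 1) < 1e-12))

  # differing Hu values with a zero shape limit exclude everything
  fC <- make_hist_fragment(3, 100, matrix(rep(proto, 3), ncol = 3),
                           hu = matrix(rep(c(0.4, 0.02, 2e-4, 1e-5, 1e-9,
                                             1e-6, 1e-10), 3), nrow = 7))
  pc0 <- pair_correlations(fA, fC, similarity_config(shape_diff_limit = 0))
  expect_length(pc0$correlations, 0L)
  expect_equal(pc0$n_pairs, 9L)

  # cross products above max_pairs are deterministically subsampled
  big <- make_hist_fragment(4, 200, noisy_hist_cols(proto, 40, seed = 2))
  pcs1 <- pair_correlations(big, fB, similarity_config(max_pairs = 50))
  pcs2 <- pair_correlations(fB, big, similarity_config(max_pairs = 50))
  expect_equal(pcs1$n_pairs, 50L)
  expect_equal(pcs1, pcs2)   # symmetric despite subsampling
})

test_that("similarity amplitude is the correlation maximum", {
  expect_equal(similarity_amplitude(c(0.2, 0.9, -0.5)), 0.9)
  expect_equal(similarity_amplitude(numeric(0)), 0)
  expect_equal(similarity_amplitude(c(0.7, 0.7)), 0.7)
})

test_that("the Gaussian-weighted level distribution matches its closed form", {
  # all correlations at 1.0 land in the top level, midpoint 0.95
  expect_equal(weighted_distribution(rep(1, 5), 5), exp(-0.5),
               tolerance = 1e-9)
  expect_equal(weighted_distribution(c(-0.2, -1, 0 - 1e-9), 3), 0)
  half <- weighted_distribution(c(1, 1, -1, -1), 4)
  expect_equal(half, exp(-0.5) / 2, tolerance = 1e-9)
  expect_equal(weighted_distribution(numeric(0), 0), 0)
})

test_that("fragment similarity is symmetric, bounded and identity-peaked", {
  proto <- hist_proto(1)
  fA <- make_hist_fragment(1, 0, matrix(rep(proto, 4), ncol = 4))
  fA2 <- make_hist_fragment(2, 50, matrix(rep(proto, 4), ncol = 4))
  expect_equal(fragment_similarity(fA, fA2), exp(-0.5), tolerance = 1e-9)

  # disjoint support histograms anticorrelate; amplitude clamps to 0
  p1 <- c(rep(10, 8), rep(0, 8)); p2 <- c(rep(0, 8), rep(10, 8))
  f1 <- make_hist_fragment(3, 0, matrix(rep(p1, 3), ncol = 3))
  f2 <- make_hist_fragment(4, 50, matrix(rep(p2, 3), ncol = 3))
  expect_equal(fragment_similarity(f1, f2), 0)

  withr::with_seed(13, {
    for (i in 1:5) {
      g1 <- make_hist_fragment(5, 0, noisy_hist_cols(hist_proto(1), 5,
                                                     seed = i))
      g2 <- make_hist_fragment(6, 50, noisy_hist_cols(hist_proto(2), 6,
                                                      seed = i + 50))
      s12 <- fragment_similarity(g1, g2)
      expect_identical(s12, fragment_similarity(g2, g1))
      expect_gte(s12, 0)
    }
  })
})

test_that("coexistence is inclusive interval overlap", {
  a <- new_fragment(1, c(0L, 99L), x = c(0, 0), y = c(0, 0))
  b <- new_fragment(2, c(50L, 150L), x = c(0, 0), y = c(0, 0))
  c_ <- new_fragment(3, c(100L, 150L), x = c(0, 0), y = c(0, 0))
  expect_true(coexist(a, b))
  expect_false(coexist(a, c_))
  expect_true(coexist(a, a))
})

test_that("IdMatrix is symmetric, bounded, and zero exactly at coexistence", {
  protos <- lapply(1:3, hist_proto)
  frs <- list(
    make_hist_fragment(1, 0, noisy_hist_cols(protos[[1]], 5, seed = 1)),
    make_hist_fragment(2, 40, noisy_hist_cols(protos[[1]], 5, seed = 2)),
    make_hist_fragment(3, 38, noisy_hist_cols(protos[[2]], 5, seed = 3)),
    make_hist_fragment(4, 80, noisy_hist_cols(protos[[2]], 5, seed = 4)),
    make_hist_fragment(5, 120, noisy_hist_cols(protos[[3]], 5, seed = 5)))
  S <- build_sim_matrix(frs)
  expect_equal(unclass(S), t(unclass(S)), tolerance = 1e-9)
  Id <- build_id_matrix(frs, sim = S)
  M <- unclass(Id)
  expect_equal(M, t(M), tolerance = 1e-9)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(diag(M), rep(1, 5))
  for (i in 1:5) for (j in 1:5)
    if (i != j && coexist(frs[[i]], frs[[j]]))
      expect_identical(M[i, j], 0)
})

test_that("identical and anti-correlated similarity profiles map to 1 and 0", {
  proto <- hist_proto(1); other <- hist_proto(2)
  copyA <- matrix(rep(proto, 4), ncol = 4)
  frs <- list(
    make_hist_fragment(1, 0, copyA),
    make_hist_fragment(2, 50, copyA),                      # same animal
    make_hist_fragment(3, 100, noisy_hist_cols(proto, 4, noise_sd = 8,
                                               seed = 6)),
    make_hist_fragment(4, 150, matrix(rep(other, 4), ncol = 4)))
  Id <- build_id_matrix(frs)
  expect_equal(Id[1, 2], 1)

  # overlapping fragments are incompatible regardless of appearance
  frs_ov <- frs
  frs_ov[[2]] <- make_hist_fragment(2, 2, copyA)
  expect_identical(build_id_matrix(frs_ov)[1, 2], 0)

  # A similar to C only, B similar to D only: profiles anticorrelate
  p1 <- c(rep(10, 8), rep(1, 8)); p2 <- c(rep(1, 8), rep(10, 8))
  frs2 <- list(
    make_hist_fragment(1, 0, noisy_hist_cols(p1, 4, seed = 7)),
    make_hist_fragment(2, 50, noisy_hist_cols(p2, 4, seed = 8)),
    make_hist_fragment(3, 100, noisy_hist_cols(p1, 4, seed = 9)),
    make_hist_fragment(4, 150, noisy_hist_cols(p2, 4, seed = 10)))
  Id2 <- build_id_matrix(frs2)
  expect_identical(Id2[1, 2], 0)
})

test_that("added histogram noise never increases similarity to the partner", {
  proto <- hist_proto(1, kn = 32)
  base <- noisy_hist_cols(proto, 8, noise_sd = 1, seed = 20)
  partner <- make_hist_fragment(1, 0, base)
  noise_dir <- withr::with_seed(21, matrix(rnorm(length(base)), nrow(base)))
  sims <- sapply(c(0, 2, 4, 8, 16), function(s) {
    corrupted <- pmax(base + s * noise_dir, 0)
    fragment_similarity(partner,
                        make_hist_fragment(2, 100, corrupted))
  })
  expect_true(all(diff(sims) <= 1e-9))
})

test_that("within-texture-class similarity exceeds between-class similarity", {
  frs <- list(); cls <- integer(0); id <- 0L
  for (k in 1:3) for (r in 1:3) {
    id <- id + 1L
    frs[[id]] <- make_hist_fragment(id, id * 40,
                                    noisy_hist_cols(hist_proto(k), 6,
                                                    seed = id))
    cls[id] <- k
  }
  S <- unclass(build_sim_matrix(frs))
  same <- outer(cls, cls, `==`) & upper.tri(S)
  diff_ <- outer(cls, cls, `!=`) & upper.tri(S)
  expect_gt(mean(S[same]), mean(S[diff_]))
})
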