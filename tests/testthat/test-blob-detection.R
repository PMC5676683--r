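test_that("segmentation finds dark components and filters by size", {
  blank <- gray_frame(matrix(255L, 50, 50))
  expect_length(segment_frame(blank, 100), 0L)

  px <- matrix(255L, 100, 100)
  px[21:30, 21:30] <- 0L
  b <- segment_frame(gray_frame(px), 100, min_size = 10, max_size = 10000)
  expect_length(b, 1L)
  expect_equal(nrow(b[[1]]$px), 100L)
  expect_equal(b[[1]]$bbox, c(20, 20, 29, 29))

  # two 3x3 blocks plus an isolated dark pixel; min_size 5 keeps the blocks
  px <- matrix(255L, 40, 40)
  px[5:7, 5:7] <- 0L
  px[20:22, 30:32] <- 0L
  px[35, 10] <- 0L
  b <- segment_frame(gray_frame(px), 100, min_size = 5)
  expect_length(b, 2L)

  expect_error(segment_frame(gray_frame(px), 300), "threshold")
  expect_error(segment_frame(gray_frame(px), 100, min_size = 0), "min_size")
  expect_error(gray_frame(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("segmentation agrees with a flood-fill oracle on random frames", {
  withr::with_seed(11, {
    for (i in 1:50) {
      mask <- matrix(runif(64 * 64) < 0.18, 64, 64)
      px <- matrix(255L, 64, 64)
      px[mask] <- 0L
      min_size <- sample(1:4, 1)
      got <- segment_frame(gray_frame(px), 128, min_size = min_size)
      want <- flood_fill_components(mask, min_size)
      expect_length(got, length(want))
      got_sets <- lapply(got, function(b)
        as.integer(sort(unname(b$px[, 2]) * 64L + unname(b$px[, 1]) + 1L)))
      want_sets <- lapply(want, function(s) as.integer(sort(s)))
      expect_setequal(got_sets, want_sets)
    }
  })
})

test_that("ROI normalization stretches min to 0 and max to 255", {
  px <- matrix(255L, 10, 10)
  px[1:2, 1:2] <- c(10L, 10L, 110L, 210L)
  f <- gray_frame(px)
  roi <- normalize_roi(f, c(0, 0, 1, 1))
  expect_equal(min(roi), 0)
  expect_equal(max(roi), 255)
  expect_equal(sort(as.vector(roi)), c(0, 0, 127.5, 255))

  px[1:2, 1:2] <- 37L
  expect_equal(normalize_roi(gray_frame(px), c(0, 0, 1, 1)),
               matrix(0, 2, 2))

  ramp <- matrix(as.integer(seq(0, 255, length.out = 16)), 4, 4)
  expect_equal(normalize_roi(gray_frame(ramp), c(0, 0, 3, 3)),
               matrix(as.numeric(ramp), 4, 4))

  expect_error(normalize_roi(f, c(5, 5, 4, 6)), "bbox")
  expect_error(normalize_roi(f, c(0, 0, 99, 1)), "bbox")
})

test_that("ROI histogram bins per the half-open rule and conserves mass", {
  expect_equal(roi_histogram(matrix(0, 4, 4), 8),
               c(16, rep(0, 7)))
  expect_equal(roi_histogram(matrix(255, 1, 1), 8),
               c(rep(0, 7), 1))
  ramp <- matrix(0:255, 16, 16)
  expect_equal(roi_histogram(ramp, 4), rep(64, 4))
  expect_error(roi_histogram(ramp, 1), "kn")

  withr::with_seed(4, {
    for (i in 1:20) {
      roi <- matrix(runif(60, 0, 255), 6, 10)
      kn <- sample(2:64, 1)
      expect_equal(sum(roi_histogram(roi, kn)), 60L)
    }
  })
})

test_that("Hu invariants respect rotation, translation, mirror and scale", {
  withr::with_seed(7, {
    for (i in 1:20) {
      img <- random_texture_blob(i)
      h0 <- hu_moments(img, full_mask(img))
      expect_length(h0, 7L)

      hr <- hu_moments(rot90(img), full_mask(rot90(img)))
      expect_equal(hr, h0, tolerance = 1e-6)

      big <- matrix(0, nrow(img) + 12, ncol(img) + 12)
      big[5 + seq_len(nrow(img)), 7 + seq_len(ncol(img))] <- img
      ht <- hu_moments(big, full_mask(big))
      expect_equal(ht, h0, tolerance = 1e-9)

      mi <- img[, ncol(img):1]
      hm <- hu_moments(mi, full_mask(mi))
      expect_equal(hm[1:6], h0[1:6], tolerance = 1e-6)
      expect_equal(abs(hm[7]), abs(h0[7]), tolerance = 1e-6)
      expect_equal(sign(hm[7]), -sign(h0[7]))

      sc <- kronecker(img, matrix(1, 2, 2))
      hs <- hu_moments(sc, full_mask(sc))
      expect_equal(hs, h0, tolerance = 5e-2)
    }
  })
})

test_that("a disc and an equal-area 3:1 ellipse differ in the first invariant", {
  disc <- matrix(0, 61, 61)
  for (r in 1:61) for (c in 1:61)
    if ((r - 31)^2 + (c - 31)^2 <= 15^2) disc[r, c] <- 1
  ell <- matrix(0, 81, 81)
  a <- 15 * sqrt(3); b <- 15 / sqrt(3)
  for (r in 1:81) for (c in 1:81)
    if (((c - 41) / a)^2 + ((r - 41) / b)^2 <= 1) ell[r, c] <- 1
  h_disc <- hu_moments(disc, full_mask(disc))
  h_ell <- hu_moments(ell, full_mask(ell))
  expect_gt(abs(h_ell[1] - h_disc[1]) / h_disc[1], 0.10)
  # same conclusion from the independent double-loop moment oracle
  expect_equal(h_disc[1], oracle_hu1(disc), tolerance = 1e-9)
  expect_equal(h_ell[1], oracle_hu1(ell), tolerance = 1e-9)
  expect_error(hu_moments(matrix(0, 5, 5), full_mask(matrix(0, 5, 5))),
               "degenerate")
})

test_that("extract_detection assembles the feature bundle", {
  px <- matrix(255L, 100, 100)
  px[21:30, 21:30] <- 0L
  f <- gray_frame(px, index = 0L)
  b <- segment_frame(f, 100, min_size = 10)
  d <- extract_detection(f, b[[1]], fps = 30)
  expect_equal(unname(d$cm), c(24.5, 24.5))
  expect_equal(d$size, 100L)
  expect_equal(sum(d$hist), 100)

  px <- matrix(255L, 20, 20)
  px[6, 10] <- 0L   # row 5, col 9 (0-based)
  f <- gray_frame(px, index = 60L)
  b <- segment_frame(f, 100, min_size = 1)
  d <- extract_detection(f, b[[1]], fps = 30)
  expect_equal(unname(d$cm), c(9, 5))
  expect_equal(d$size, 1L)
  expect_equal(d$t, 2.0)

  # center of mass always lies inside the bounding box
  withr::with_seed(21, {
    for (i in 1:10) {
      px <- matrix(255L, 64, 64)
      r0 <- sample(5:40, 1); c0 <- sample(5:40, 1)
      px[r0:(r0 + sample(3:12, 1)), c0:(c0 + sample(3:12, 1))] <-
        sample(0:80, 1)
      f <- gray_frame(px)
      for (b in segment_frame(f, 128, min_size = 4)) {
        d <- extract_detection(f, b, fps = 25)
        expect_true(d$cm[["x"]] >= b$bbox[2] && d$cm[["x"]] <= b$bbox[4])
        expect_true(d$cm[["y"]] >= b$bbox[1] && d$cm[["y"]] <= b$bbox[3])
      }
    }
  })
})
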