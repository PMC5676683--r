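# Per-frame segmentation and feature extraction.
#
# Each frame is thresholded (dark animals, bright background), 8-connected
# components are filtered by size, and every surviving blob is summarised as a
# detection bundle: sub-pixel center of mass, pixel count, contrast-normalized
# ROI intensity histogram, the seven Hu moment invariants and the detection
# time. Coordinates are 0-based with x = column, y = row throughout.

#' Construct a grayscale frame
#'
#' @param pixels numeric or integer matrix of intensities in `[0, 255]`
#'   (rows = image rows, columns = image columns).
#' @param index 0-based frame number.
#' @return An object of class `gray_frame`.
#' @export
gray_frame <- function(pixels, index = 0L) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("frame must be a non-empty matrix")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, index = as.integer(index)),
            class = "gray_frame")
}

#' Segment one frame into blobs
#'
#' Thresholds dark pixels and returns the 8-connected components whose pixel
#' count falls within `[min_size, max_size]`, ordered by the row-major
#' position of each component's first pixel.
#'
#' @param frame a [gray_frame()].
#' @param intensity_threshold pixels strictly below this value are foreground.
#' @param min_size,max_size inclusive pixel-count bounds for a valid blob.
#' @param invert if `TRUE`, segment bright-on-dark video instead (pixels
#'   strictly above the threshold are foreground).
#' @return A list of blob masks; each has `px` (n x 2 matrix of 0-based
#'   `(row, col)` coordinates) and `bbox` `(row_min, col_min, row_max,
#'   col_max)`, inclusive and 0-based.
#' @export
segment_frame <- function(frame, intensity_threshold, min_size = 1L,
                          max_size = .Machine$integer.max, invert = FALSE) {
  stopifnot(inherits(frame, "gray_frame"))
  if (intensity_threshold < 0 || intensity_threshold > 255)
    stop("intensity_threshold must lie in [0, 255]")
  if (min_size <= 0 || min_size > max_size)
    stop("need 0 < min_size <= max_size")
  mask <- if (invert) frame$pixels > intensity_threshold
          else frame$pixels < intensity_threshold
  lab <- .cc_label(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nr <- nrow(lab)
  rows <- (idx - 1L) %% nr        # 0-based row
  cols <- (idx - 1L) %/% nr       # 0-based col
  out <- vector("list", nlab)
  keep <- logical(nlab)
  ord <- order(labs)
  labs <- labs[ord]; rows <- rows[ord]; cols <- cols[ord]
  bounds <- c(0L, cumsum(tabulate(labs, nlab)))
  for (l in seq_len(nlab)) {
    sel <- (bounds[l] + 1L):bounds[l + 1L]
    n <- length(sel)
    if (n < min_size || n > max_size) next
    r <- rows[sel]; c <- cols[sel]
    out[[l]] <- structure(
      list(px = cbind(row = r, col = c),
           bbox = c(min(r), min(c), max(r), max(c))),
      class = "blob_mask")
    keep[l] <- TRUE
  }
  out[keep]
}

#' Contrast-normalize the ROI enclosing a blob
#'
#' Min-max stretches the rectangular region so its minimum maps to 0 and its
#' maximum to 255. A constant region maps to all zeros.
#'
#' @param frame a [gray_frame()].
#' @param bbox inclusive 0-based `(row_min, col_min, row_max, col_max)`.
#' @return Numeric matrix of the normalized ROI.
#' @export
normalize_roi <- function(frame, bbox) {
  stopifnot(inherits(frame, "gray_frame"), length(bbox) == 4L)
  px <- frame$pixels
  if (bbox[1] < 0 || bbox[2] < 0 ||
      bbox[3] >= nrow(px) || bbox[4] >= ncol(px) ||
      bbox[3] < bbox[1] || bbox[4] < bbox[2])
    stop("degenerate or out-of-bounds bbox")
  roi <- px[(bbox[1]:bbox[3]) + 1L, (bbox[2]:bbox[4]) + 1L, drop = FALSE]
  roi <- matrix(as.numeric(roi), nrow(roi), ncol(roi))
  lo <- min(roi); hi <- max(roi)
  if (hi == lo) return(roi * 0)
  (roi - lo) * (255 / (hi - lo))
}

#' Histogram of a normalized ROI
#'
#' Bin `k` (0-based) counts values in `[255 k / kn, 255 (k + 1) / kn)`; the
#' value 255 exactly is counted in the last bin so every pixel is binned.
#'
#' @param norm_roi numeric matrix with values in `[0, 255]`.
#' @param kn number of bins (>= 2).
#' @return Integer vector of length `kn` summing to the ROI pixel count.
#' @export
roi_histogram <- function(norm_roi, kn) {
  if (kn < 2L) stop("kn must be >= 2")
  x <- as.numeric(norm_roi)
  bin <- pmin(floor(x * kn / 255), kn - 1L)
  tabulate(bin + 1L, nbins = kn)
}

#' Hu moment invariants of a masked blob image
#'
#' Computes the seven Hu invariants of the blob's intensity pattern. By
#' default the normalized ROI is masked so pixels outside the blob are zero
#' before moments are taken; with `binary = TRUE` the blob silhouette
#' (mask as 0/1 image) is used instead.
#'
#' @param norm_roi normalized ROI matrix (from [normalize_roi()]).
#' @param mask blob mask from [segment_frame()] (its `bbox` must be the ROI's).
#' @param binary use the binary silhouette instead of masked intensities.
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(norm_roi, mask, binary = FALSE) {
  stopifnot(inherits(mask, "blob_mask"))
  img <- matrix(0, nrow(norm_roi), ncol(norm_roi))
  r <- mask$px[, 1] - mask$bbox[1] + 1L
  c <- mask$px[, 2] - mask$bbox[2] + 1L
  img[cbind(r, c)] <- if (binary) 1 else norm_roi[cbind(r, c)]
  if (all(img == 0)) stop("degenerate blob: all-zero masked intensity")
  .hu_from_image(img)
}

# Hu invariants from an intensity image (weights = intensities, coordinates =
# pixel centers). Standard central-moment formulation.
.hu_from_image <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- seq_len(nc) - 1   # x = column
  ys <- seq_len(nr) - 1   # y = row
  m00 <- sum(img)
  cx <- sum(img %*% xs) / m00
  cy <- sum(ys %*% img) / m00
  dx <- xs - cx; dy <- ys - cy
  mu <- function(p, q) sum((dy^q %*% img) * dx^p)
  n <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- n(2, 0); n02 <- n(0, 2); n11 <- n(1, 1)
  n30 <- n(3, 0); n03 <- n(0, 3); n21 <- n(2, 1); n12 <- n(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  hu <- c(h1, h2, h3, h4, h5, h6, h7)
  if (any(!is.finite(hu))) stop("non-finite Hu invariants")
  hu
}

#' Extract the feature bundle for one blob
#'
#' @param frame a [gray_frame()].
#' @param blob a blob mask from [segment_frame()] on this frame.
#' @param fps frames per second (time base for `t`).
#' @param kn histogram bin count.
#' @param hu_binary compute Hu invariants on the binary silhouette.
#' @return A `detection`: list with `cm = c(x, y)` (sub-pixel center of mass),
#'   `size`, `hist`, `hu`, `t`, `frame`, `bbox`. A blob whose masked
#'   intensities are all zero (perfectly uniform body) falls back to
#'   silhouette Hu invariants.
#' @export
extract_detection <- function(frame, blob, fps, kn = 32L, hu_binary = FALSE) {
  stopifnot(inherits(blob, "blob_mask"))
  roi <- normalize_roi(frame, blob$bbox)
  hu <- if (hu_binary) hu_moments(roi, blob, binary = TRUE)
    else tryCatch(hu_moments(roi, blob),
                  error = function(e) hu_moments(roi, blob, binary = TRUE))
  structure(list(
    cm = c(x = mean(blob$px[, 2]), y = mean(blob$px[, 1])),
    size = nrow(blob$px),
    hist = roi_histogram(roi, kn),
    hu = hu,
    t = frame$index / fps,
    frame = frame$index,
    bbox = blob$bbox), class = "detection")
}
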