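#' Triangle autothreshold
#'
#' Geometric automatic threshold for skewed intensity histograms: on a
#' 256-bin histogram, a chord is drawn from the histogram peak to the far end
#' of its longer tail and the threshold is placed at the bin maximising the
#' perpendicular distance between chord and histogram. Designed for images
#' where foreground (bright objects on dark background) is a small fraction
#' of pixels, so the histogram peak is the background mode.
#'
#' @param x Numeric vector or matrix of intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold on the intensity scale of `x`; pixels strictly
#'   above it are foreground. Returns `Inf` for a constant input (no
#'   foreground).
#' @export
triangle_threshold <- function(x, n_bins = 256) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(Inf)
  b <- pmin(floor((v - lo) / (hi - lo) * n_bins), n_bins - 1) + 1L
  h <- tabulate(b, nbins = n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  first <- nz[1]; last <- nz[length(nz)]
  flipped <- (peak - first) > (last - peak)  # long tail on the left: mirror
  if (flipped) {
    h <- rev(h)
    peak <- n_bins + 1L - peak
    last <- n_bins + 1L - first
  }
  if (last <= peak) {
    thr_bin <- peak
  } else {
    idx <- peak:last
    # distance from (idx, h_idx) to the chord (peak, h_peak) -> (last, h_last)
    dx <- last - peak
    dy <- h[last] - h[peak]
    d <- abs(dy * (idx - peak) - dx * (h[idx] - h[peak]))
    thr_bin <- idx[which.max(d)]
  }
  if (flipped) thr_bin <- n_bins + 1L - thr_bin
  # threshold at the upper edge of the selected bin
  lo + thr_bin / n_bins * (hi - lo)
}

#' Segment marker-positive cells from a seed channel
#'
#' Reproduces a standard particle-analysis workflow: a median filter
#' (radius 2 px) applied to the seed channel, Triangle autothresholding
#' (bright objects on dark background), 8-connected component labelling,
#' per-object hole filling (ROIs include holes), and a particle filter
#' discarding components below a minimum area in um^2 (default 20).
#' Segmentation defines the ROIs only; dot counting and intensity
#' measurement read the raw channels.
#'
#' @param img An `arc_image`.
#' @param seed_channel Channel used to outline cells (e.g. `"Pomc"`).
#' @param min_size_um2 Minimum retained particle area in um^2.
#' @param median_radius Median filter radius in pixels (0 disables).
#' @param n_bins Histogram bins for the Triangle threshold.
#' @return A list: `rois`, a tibble (`roi_id`, `n_pixels`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`), and `labels`, an integer matrix of
#'   the same shape as the image (0 = background; ROI masks are mutually
#'   disjoint). A blank image yields zero ROIs, not an error.
#' @export
segment_cells <- function(img, seed_channel, min_size_um2 = 20,
                          median_radius = 2, n_bins = 256) {
  stopifnot(inherits(img, "arc_image"))
  ch <- get_channel(img, seed_channel)
  px2 <- img$pixel_size_um^2
  empty <- list(
    rois = tibble(roi_id = integer(), n_pixels = integer(),
                  area_um2 = numeric(), centroid_x_um = numeric(),
                  centroid_y_um = numeric()),
    labels = matrix(0L, nrow(ch), ncol(ch))
  )
  mx <- max(ch)
  if (mx <= min(ch)) return(empty)
  filt <- if (median_radius > 0) {
    EBImage::medianFilter(ch / mx, median_radius)
  } else {
    ch / mx
  }
  thr <- triangle_threshold(filt, n_bins = n_bins)
  mask <- filt > thr
  if (!any(mask)) return(empty)
  labels <- label_components8(mask)
  labels <- EBImage::fillHull(labels)
  labels <- matrix(as.integer(round(labels)), nrow(ch), ncol(ch))

  np <- tabulate(labels[labels > 0])
  keep <- which(np * px2 >= min_size_um2)
  if (!length(keep)) return(empty)
  relab <- integer(length(np))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]

  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  # pixel-centred physical coordinates: x along columns, y along rows
  cx <- tapply((idx[, 2] - 0.5) * img$pixel_size_um, lab, mean)
  cy <- tapply((idx[, 1] - 0.5) * img$pixel_size_um, lab, mean)
  npx <- tabulate(lab)
  list(
    rois = tibble(
      roi_id = seq_along(npx), n_pixels = npx, area_um2 = npx * px2,
      centroid_x_um = as.numeric(cx), centroid_y_um = as.numeric(cy)
    ),
    labels = labels
  )
}

# 8-connected component labelling: 4-connected pass (EBImage::bwlabel) plus a
# union-find merge of labels that touch diagonally
label_components8 <- function(mask) {
  lbl <- EBImage::bwlabel(mask)
  lbl <- matrix(as.integer(round(lbl)), nrow(mask), ncol(mask))
  n <- max(lbl)
  if (n < 2) return(lbl)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nr <- nrow(lbl); nc <- ncol(lbl)
  merge_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    if (!any(keep)) return(invisible(NULL))
    for (p in unique(paste(a[keep], b[keep]))) {
      ij <- as.integer(strsplit(p, " ")[[1]])
      ra <- find(ij[1]); rb <- find(ij[2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  # down-right and down-left diagonal neighbours
  merge_pairs(lbl[-nr, -nc], lbl[-1, -1])
  merge_pairs(lbl[-nr, -1], lbl[-1, -nc])
  roots <- vapply(seq_len(n), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- lbl
  out[out > 0] <- dense[out[out > 0]]
  out
}
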