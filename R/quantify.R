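#' Count fluorescent puncta inside segmented cells
#'
#' Detects transcript dots as local intensity maxima of the raw channel: a
#' pixel counts as a dot candidate when it is maximal in its 3x3
#' neighbourhood and exceeds an absolute intensity threshold; candidates
#' closer than `min_sep_px` (Euclidean) are collapsed onto the brighter one.
#' Detection is deterministic for a fixed input (ties broken by intensity,
#' then row, then column).
#'
#' @param img An `arc_image`.
#' @param labels ROI label matrix from [segment_cells()].
#' @param channel Channel to count dots in.
#' @param dot_threshold Intensity threshold; interpreted as a fraction of the
#'   channel maximum when `relative = TRUE` (making the count invariant to a
#'   global intensity rescaling), else as an absolute value.
#' @param min_sep_px Minimum separation between accepted dots, in pixels.
#' @param relative Whether `dot_threshold` is relative to the channel max.
#' @return A tibble `roi_id`, `dots` covering every ROI in `labels`.
#' @export
count_dots <- function(img, labels, channel, dot_threshold = 0.25,
                       min_sep_px = 3, relative = TRUE) {
  ch <- get_channel(img, channel)
  n_roi <- max(labels)
  out <- tibble(roi_id = seq_len(n_roi), dots = 0L)
  if (n_roi == 0) return(out)
  thr <- if (relative) dot_threshold * max(ch) else dot_threshold
  if (max(ch) <= 0) return(out)

  nr <- nrow(ch); nc <- ncol(ch)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- ch
  nb_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_max <- pmax(nb_max, pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  cand <- which(ch >= nb_max & ch > thr & labels > 0, arr.ind = TRUE)
  if (!nrow(cand)) return(out)
  v <- ch[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  lab <- labels[cand]

  counts <- integer(n_roi)
  for (roi in unique(lab)) {
    pts <- cand[lab == roi, , drop = FALSE]
    kept <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      if (!nrow(kept) ||
          min((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2) >= min_sep_px^2) {
        kept <- rbind(kept, p)
      }
    }
    counts[roi] <- nrow(kept)
  }
  out$dots <- counts
  out
}

#' Dot-count positivity call
#'
#' A cell is positive for a probe when it contains `threshold` (default 3)
#' or more signal dots; fewer dots make it negative.
#'
#' @param dots Integer vector of per-cell dot counts (>= 0).
#' @param threshold Minimum dot count for positivity.
#' @return Logical vector.
#' @export
call_positive <- function(dots, threshold = 3) {
  if (any(dots < 0)) abort("dot counts must be nonnegative")
  dots >= threshold
}

#' Per-cell signal intensity
#'
#' Intensity (a.u.) = raw integrated density / area: the sum of raw
#' (unfiltered) pixel values inside the ROI mask divided by the mask area in
#' pixels, i.e. the mean raw pixel value. Using pixel area keeps a uniform
#' field of value v at intensity v regardless of pixel size.
#'
#' @param img An `arc_image`.
#' @param labels ROI label matrix from [segment_cells()].
#' @param channel Channel to measure (raw values).
#' @param roi_id ROIs to measure; default all in `labels`.
#' @return A tibble `roi_id`, `intensity`.
#' @export
measure_intensity <- function(img, labels, channel, roi_id = NULL) {
  ch <- get_channel(img, channel)
  ids <- roi_id %||% seq_len(max(labels))
  if (!length(ids)) abort("no ROIs to measure (empty mask)")
  npx <- tabulate(labels[labels > 0], nbins = max(c(labels, ids)))
  if (any(npx[ids] == 0)) {
    abort(paste0("empty mask for roi_id: ",
                 paste(ids[npx[ids] == 0], collapse = ", ")))
  }
  sums <- tapply(ch[labels > 0], labels[labels > 0], sum)
  all_sum <- numeric(length(npx))
  all_sum[as.integer(names(sums))] <- as.numeric(sums)
  tibble(roi_id = ids, intensity = all_sum[ids] / npx[ids])
}

#' Segment and quantify a multi-channel image in one call
#'
#' Runs [segment_cells()] on the seed channel and then, for every retained
#' ROI and every queried channel, counts dots ([count_dots()]), calls
#' positivity ([call_positive()]) and measures raw intensity
#' ([measure_intensity()]).
#'
#' @inheritParams segment_cells
#' @inheritParams count_dots
#' @param channels Channels to quantify; default all but the seed channel.
#' @param positive_min_dots Dot-count positivity threshold.
#' @param exclude_rois Optional integer vector (or path to a text file, one
#'   `roi_id` per line) of ROIs to drop, e.g. manually rejected outlines.
#' @return A list: `cells`, a long tibble (`roi_id`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um`, `channel`, `dots`, `positive`,
#'   `intensity`); `rois` and `labels` as in [segment_cells()].
#' @export
quantify_image <- function(img, seed_channel,
                           channels = setdiff(names(img$channels),
                                              seed_channel),
                           min_size_um2 = 20, median_radius = 2,
                           dot_threshold = 0.25, min_sep_px = 3,
                           relative = TRUE, positive_min_dots = 3,
                           exclude_rois = NULL) {
  seg <- segment_cells(img, seed_channel, min_size_um2 = min_size_um2,
                       median_radius = median_radius)
  if (is.character(exclude_rois)) {
    exclude_rois <- as.integer(readLines(exclude_rois, warn = FALSE))
  }
  if (length(exclude_rois)) {
    seg$labels[seg$labels %in% exclude_rois] <- 0L
    seg$rois <- seg$rois[!seg$rois$roi_id %in% exclude_rois, , drop = FALSE]
  }
  if (!nrow(seg$rois)) {
    return(list(cells = tibble(
      roi_id = integer(), area_um2 = numeric(), centroid_x_um = numeric(),
      centroid_y_um = numeric(), channel = character(), dots = integer(),
      positive = logical(), intensity = numeric()
    ), rois = seg$rois, labels = seg$labels))
  }
  per_ch <- purrr::map_dfr(channels, function(chn) {
    d <- count_dots(img, seg$labels, chn, dot_threshold = dot_threshold,
                    min_sep_px = min_sep_px, relative = relative)
    i <- measure_intensity(img, seg$labels, chn, roi_id = seg$rois$roi_id)
    dplyr::inner_join(d, i, by = "roi_id") %>%
      dplyr::mutate(channel = chn,
                    positive = call_positive(.data$dots, positive_min_dots))
  })
  cells <- dplyr::inner_join(seg$rois, per_ch, by = "roi_id") %>%
    dplyr::select("roi_id", "area_um2", "centroid_x_um", "centroid_y_um",
                  "channel", "dots", "positive", "intensity")
  list(cells = cells, rois = seg$rois, labels = seg$labels)
}

#' Coexpression percentages within a reference population
#'
#' Restricts to cells positive for the reference marker and reports, for
#' each query (a single marker or a combination that must be jointly
#' positive), the percentage of reference-positive cells that are
#' query-positive.
#'
#' @param cells Long positivity tibble with columns `roi_id`, `channel`,
#'   `positive` (e.g. `quantify_image()$cells`).
#' @param reference_marker Channel defining the reference population.
#' @param query_markers List of queries; each element a character vector of
#'   one or more channels (a vector of length > 1 = joint positivity).
#' @return A tibble of class `arc_coexpression`: `reference`, `n_reference`,
#'   `query`, `n_positive`, `pct`. Zero reference-positive cells yield an
#'   empty table with a warning.
#' @export
coexpression_table <- function(cells, reference_marker, query_markers) {
  ref_ids <- cells$roi_id[cells$channel == reference_marker & cells$positive]
  ref_ids <- unique(ref_ids)
  if (!is.list(query_markers)) query_markers <- as.list(query_markers)
  empty <- tibble(reference = character(), n_reference = integer(),
                  query = character(), n_positive = integer(),
                  pct = numeric())
  class(empty) <- c("arc_coexpression", class(tibble()))
  if (!length(ref_ids)) {
    warn(paste0("no cells positive for reference marker '",
                reference_marker, "'"))
    return(empty)
  }
  out <- purrr::map_dfr(query_markers, function(q) {
    pos <- ref_ids
    for (m in q) {
      pos <- intersect(pos,
                       cells$roi_id[cells$channel == m & cells$positive])
    }
    tibble(reference = reference_marker, n_reference = length(ref_ids),
           query = paste(q, collapse = "&"), n_positive = length(pos),
           pct = 100 * length(pos) / length(ref_ids))
  })
  class(out) <- c("arc_coexpression", class(tibble()))
  out
}

#' Ratio of two coexpression percentages
#'
#' E.g. the Drd1:Drd2 positivity ratio within a reference population.
#'
#' @param tbl An `arc_coexpression` table.
#' @param x,y Query names whose percentages form the ratio `pct_x / pct_y`.
#' @return The ratio (numeric); errors when `pct_y` is 0.
#' @export
positivity_ratio <- function(tbl, x, y) {
  px <- tbl$pct[tbl$query == x]
  py <- tbl$pct[tbl$query == y]
  if (length(px) != 1 || length(py) != 1) {
    abort("x and y must each match exactly one query in the table")
  }
  if (py == 0) abort(paste0("percentage for '", y, "' is 0; ratio undefined"))
  px / py
}

#' Split cells into marker-positive and -negative subpopulations
#'
#' Disjoint, exhaustive partition of the segmented cells by positivity for
#' one marker (e.g. Drd2+ vs Drd2- POMC cells).
#'
#' @param cells Long positivity tibble (`roi_id`, `channel`, `positive`).
#' @param marker Channel to split on.
#' @return A list of two tibbles, `positive` and `negative`, each the
#'   rows of `cells` for the corresponding `roi_id`s.
#' @export
split_by_positivity <- function(cells, marker) {
  ids <- unique(cells$roi_id)
  pos <- unique(cells$roi_id[cells$channel == marker & cells$positive])
  list(
    positive = cells[cells$roi_id %in% pos, , drop = FALSE],
    negative = cells[!cells$roi_id %in% pos, , drop = FALSE]
  )
}
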