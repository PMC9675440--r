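#' Simulate a multi-channel image of disk-like cells with countable puncta
#'
#' Renders cells as uniform disks (the cell-body marker, e.g. a Pomc
#' channel) and, per query channel, a programmed number of well-separated
#' Gaussian puncta inside each disk, on a constant background with optional
#' Gaussian noise. Cell centres are placed by rejection sampling so that
#' disks never overlap (an error is raised when placement fails after
#' `max_tries` attempts). Ground truth (centre, radius, analytic area, true
#' dot count, body intensity per channel) is returned alongside, so
#' segmentation, dot counting and intensity measurement can be scored
#' exactly.
#'
#' @param cells Tibble with one row per cell: `radius_um` and, per channel,
#'   columns `body_<channel>` (disk intensity) and `dots_<channel>` (true
#'   punctum count). Built conveniently with [image_cell_specs()].
#' @param channels Channel names, first one is the seed (cell-body) channel.
#' @param shape Image dimensions in pixels, `c(rows, cols)`.
#' @param pixel_size_um Pixel size in um.
#' @param background Background intensity added to all channels.
#' @param noise_sd Gaussian noise SD (0 = noise-free; negative values are
#'   clipped at 0 to keep intensities nonnegative).
#' @param dot_amplitude Peak punctum intensity above the local signal.
#' @param dot_sigma_px Punctum Gaussian sigma in pixels.
#' @param dot_min_sep_px Minimum distance between puncta of one cell (px).
#' @param margin_um Minimum gap between disk rims and image border.
#' @param max_tries Placement attempts per cell before erroring.
#' @param seed Integer seed.
#' @return A list: `image` (an `arc_image`), `truth` (tibble `cell_id`,
#'   `x_um`, `y_um`, `radius_um`, `area_um2_true`, plus the `body_*` /
#'   `dots_*` columns), and `masks` (true-disk label matrix).
#' @export
simulate_image <- function(cells, channels = c("Pomc", "Drd2"),
                           shape = c(256, 256), pixel_size_um = 0.5,
                           background = 0, noise_sd = 0,
                           dot_amplitude = 200, dot_sigma_px = 1.2,
                           dot_min_sep_px = 5, margin_um = 2,
                           max_tries = 2000, seed = 1) {
  nr <- shape[1]; nc <- shape[2]
  w_um <- nc * pixel_size_um; h_um <- nr * pixel_size_um
  n_cells <- nrow(cells)
  withr::with_seed(seed, {
    # non-overlapping placement by rejection sampling
    xs <- ys <- numeric(0)
    for (i in seq_len(n_cells)) {
      r <- cells$radius_um[i]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        x <- runif(1, r + margin_um, w_um - r - margin_um)
        y <- runif(1, r + margin_um, h_um - r - margin_um)
        if (!length(xs) ||
            all((xs - x)^2 + (ys - y)^2 >
                (cells$radius_um[seq_along(xs)] + r + margin_um)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place cell %d without overlap after %d tries", i,
          max_tries))
      }
      xs <- c(xs, x); ys <- c(ys, y)
    }

    px_x <- (col(matrix(0, nr, nc)) - 0.5) * pixel_size_um
    px_y <- (row(matrix(0, nr, nc)) - 0.5) * pixel_size_um
    masks <- matrix(0L, nr, nc)
    imgs <- setNames(rep(list(matrix(background, nr, nc)), length(channels)),
                     channels)
    dot_xy <- vector("list", n_cells)

    for (i in seq_len(n_cells)) {
      disk <- (px_x - xs[i])^2 + (px_y - ys[i])^2 <= cells$radius_um[i]^2
      masks[disk] <- i
      for (chn in channels) {
        bcol <- paste0("body_", chn)
        if (bcol %in% names(cells) && cells[[bcol]][i] > 0) {
          imgs[[chn]][disk] <- imgs[[chn]][disk] + cells[[bcol]][i]
        }
      }
      # place puncta inside the disk, pairwise separated
      n_dots <- max(vapply(channels, function(chn) {
        dcol <- paste0("dots_", chn)
        if (dcol %in% names(cells)) cells[[dcol]][i] else 0L
      }, numeric(1)))
      pts <- matrix(numeric(0), 0, 2)
      while (nrow(pts) < n_dots) {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * max(cells$radius_um[i] -
                                      2 * dot_sigma_px * pixel_size_um, 0.1)
        p <- c(xs[i] + rad * cos(ang), ys[i] + rad * sin(ang))
        if (!nrow(pts) ||
            min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >=
            (dot_min_sep_px * pixel_size_um)^2) {
          pts <- rbind(pts, p)
        }
      }
      dot_xy[[i]] <- pts
      for (chn in channels) {
        dcol <- paste0("dots_", chn)
        k <- if (dcol %in% names(cells)) cells[[dcol]][i] else 0L
        if (k > 0) {
          for (j in seq_len(k)) {
            d2 <- (px_x - pts[j, 1])^2 + (px_y - pts[j, 2])^2
            imgs[[chn]] <- imgs[[chn]] + dot_amplitude *
              exp(-d2 / (2 * (dot_sigma_px * pixel_size_um)^2))
          }
        }
      }
    }
    if (noise_sd > 0) {
      imgs <- lapply(imgs, function(m) {
        pmax(m + rnorm(length(m), 0, noise_sd), 0)
      })
    }
    truth <- dplyr::bind_cols(
      tibble(cell_id = seq_len(n_cells), x_um = xs, y_um = ys,
             radius_um = cells$radius_um,
             area_um2_true = pi * cells$radius_um^2),
      cells[grep("^(body|dots)_", names(cells))]
    )
    list(image = channel_image(imgs, pixel_size_um), truth = truth,
         masks = masks)
  })
}

#' Convenience builder for image-simulation cell tables
#'
#' @param n Number of cells.
#' @param radius_um Disk radii (recycled).
#' @param body Named numeric vector of per-channel body intensities.
#' @param dots Named integer vector/list of per-channel true dot counts
#'   (recycled per cell; pass a list of vectors for per-cell counts).
#' @return A tibble suitable for [simulate_image()]'s `cells` argument.
#' @export
image_cell_specs <- function(n, radius_um = 5, body = c(Pomc = 100),
                             dots = c(Drd2 = 5)) {
  out <- tibble(cell_id = seq_len(n),
                radius_um = rep_len(radius_um, n))
  for (chn in names(body)) {
    out[[paste0("body_", chn)]] <- rep_len(body[[chn]], n)
  }
  for (chn in names(dots)) {
    out[[paste0("dots_", chn)]] <- as.integer(rep_len(dots[[chn]], n))
  }
  out
}
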