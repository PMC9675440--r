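test_that("dot counting recovers programmed puncta and is scale-invariant", {
  cells <- image_cell_specs(3, radius_um = 6, body = c(Pomc = 100),
                            dots = c(Drd2 = 5))
  sim <- simulate_image(cells, channels = c("Pomc", "Drd2"), seed = 12)
  seg <- segment_cells(sim$image, "Pomc")
  d <- count_dots(sim$image, seg$labels, "Drd2")
  expect_equal(d$dots, rep(5L, 3))

  # a channel with no signal: zero dots
  z <- count_dots(sim$image, seg$labels, "Pomc", relative = FALSE,
                  dot_threshold = 150)
  expect_equal(z$dots, rep(0L, 3))

  # doubling all intensities leaves relative-threshold counts unchanged
  doubled <- channel_image(lapply(sim$image$channels, function(m) 2 * m),
                           sim$image$pixel_size_um)
  d2 <- count_dots(doubled, seg$labels, "Drd2")
  expect_equal(d2$dots, d$dots)
})

test_that("positivity needs three or more dots", {
  expect_false(call_positive(2))
  expect_true(call_positive(3))
  expect_false(call_positive(0))
  expect_equal(call_positive(c(0, 2, 3, 7)), c(FALSE, FALSE, TRUE, TRUE))
  # monotone in the dot count
  expect_true(all(diff(call_positive(0:10)) >= 0))
  expect_error(call_positive(-1), "nonnegative")
})

test_that("intensity is raw integrated density over area", {
  labels <- matrix(0L, 10, 10)
  labels[3:6, 3:6] <- 1L
  # uniform 100 -> 100
  img <- channel_image(list(g = matrix(100, 10, 10)), 0.5)
  expect_equal(measure_intensity(img, labels, "g", 1)$intensity, 100)
  # half 50 / half 150 -> 100
  half <- matrix(50, 10, 10); half[, 3:4] <- 150  # 8 px each inside mask
  img2 <- channel_image(list(g = half), 0.5)
  expect_equal(measure_intensity(img2, labels, "g", 1)$intensity, 100)
  # zero channel -> 0
  img3 <- channel_image(list(g = matrix(0, 10, 10)), 0.5)
  expect_equal(measure_intensity(img3, labels, "g", 1)$intensity, 0)
  # empty mask -> error
  expect_error(measure_intensity(img, labels, "g", 2), "empty mask")

  # brute-force pixel-loop oracle on an irregular mask
  withr::local_seed(31)
  ch <- matrix(runif(400, 0, 4095), 20, 20)
  lab <- matrix(0L, 20, 20)
  lab[cbind(sample(20, 60, TRUE), sample(20, 60, TRUE))] <- 1L
  got <- measure_intensity(channel_image(list(g = ch), 1), lab, "g", 1)
  expect_equal(got$intensity, oracle_intensity(ch, lab, 1),
               tolerance = 1e-9)
})

test_that("coexpression tables reproduce the printed receptor ratios", {
  # AgRP population: Drd1 14.4%, Drd2 3.5% of 1000 reference cells
  mk_cells <- function(ref, n, n_d1, n_d2) {
    tibble::tibble(
      roi_id = rep(seq_len(n), 3),
      channel = rep(c(ref, "Drd1", "Drd2"), each = n),
      positive = c(rep(TRUE, n),
                   seq_len(n) <= n_d1,
                   seq_len(n) <= n_d2)
    )
  }
  agrp <- coexpression_table(mk_cells("Agrp", 1000, 144, 35), "Agrp",
                             list("Drd1", "Drd2", c("Drd1", "Drd2")))
  expect_equal(agrp$pct[agrp$query == "Drd1"], 14.4)
  expect_equal(agrp$pct[agrp$query == "Drd2"], 3.5)
  expect_equal(round(positivity_ratio(agrp, "Drd1", "Drd2"), 1), 4.1)

  pomc <- coexpression_table(mk_cells("Pomc", 500, 46, 167), "Pomc",
                             list("Drd1", "Drd2"))
  expect_equal(pomc$pct[pomc$query == "Drd1"], 9.2)
  expect_equal(pomc$pct[pomc$query == "Drd2"], 33.4)
  expect_equal(round(positivity_ratio(pomc, "Drd1", "Drd2"), 1), 0.3)

  # everything positive: 100% everywhere, ratio 1
  all_pos <- mk_cells("Pomc", 10, 10, 10)
  t3 <- coexpression_table(all_pos, "Pomc",
                           list("Drd1", "Drd2", c("Drd1", "Drd2")))
  expect_true(all(t3$pct == 100))
  expect_equal(positivity_ratio(t3, "Drd1", "Drd2"), 1)

  # no reference-positive cells: empty table with warning
  none <- dplyr::mutate(all_pos, positive = FALSE)
  expect_warning(t4 <- coexpression_table(none, "Pomc", list("Drd1")),
                 "no cells positive")
  expect_equal(nrow(t4), 0L)
})

test_that("positivity splits partition the cells exhaustively", {
  mk <- function(n, npos) {
    tibble::tibble(roi_id = seq_len(n), channel = "Drd2",
                   positive = seq_len(n) <= npos)
  }
  sp <- split_by_positivity(mk(10, 4), "Drd2")
  expect_equal(dplyr::n_distinct(sp$positive$roi_id), 4L)
  expect_equal(dplyr::n_distinct(sp$negative$roi_id), 6L)

  sp0 <- split_by_positivity(mk(5, 0), "Drd2")
  expect_equal(nrow(sp0$positive), 0L)

  withr::local_seed(77)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    cells <- tibble::tibble(roi_id = seq_len(n), channel = "Drd2",
                            positive = runif(n) < 0.4)
    sp_i <- split_by_positivity(cells, "Drd2")
    expect_equal(dplyr::n_distinct(sp_i$positive$roi_id) +
                   dplyr::n_distinct(sp_i$negative$roi_id), n)
    expect_length(intersect(sp_i$positive$roi_id, sp_i$negative$roi_id), 0)
  }
})

test_that("excluded ROIs are dropped from quantification", {
  cells <- image_cell_specs(3, radius_um = 5, body = c(Pomc = 100),
                            dots = c(Drd2 = 5))
  sim <- simulate_image(cells, channels = c("Pomc", "Drd2"), seed = 20)
  q <- quantify_image(sim$image, "Pomc", exclude_rois = 2L)
  expect_equal(sort(unique(q$cells$roi_id)), c(1L, 3L))
  expect_false(any(q$labels == 2L))
})
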