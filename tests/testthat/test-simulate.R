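test_that("Hill modulation obeys its limiting identities", {
  expect_equal(hill_modulation(0, emax = 0.8, ec50_uM = 3), 0)
  expect_equal(hill_modulation(3, emax = 0.8, ec50_uM = 3, hill = 1), 0.4)
  # saturation: within 0.1% of emax at 1000 x EC50
  v <- hill_modulation(3000, emax = 0.8, ec50_uM = 3, hill = 1)
  expect_lt(abs(v - 0.8) / 0.8, 1e-3)
  expect_error(hill_modulation(-1, 0.5, 3), "nonnegative")
  expect_error(hill_modulation(1, -1.5, 3), ">= -1")
})

test_that("spike-train generation is seed-deterministic with fixed truth", {
  p <- short_protocol()
  specs <- neuron_sim_specs(5, seed = 10)
  a <- simulate_spike_trains(specs, p, seed = 99)
  b <- simulate_spike_trains(specs, p, seed = 99)
  expect_identical(a$spikes, b$spikes)
  c <- simulate_spike_trains(specs, p, seed = 100)
  expect_false(identical(a$spikes, c$spikes))
  expect_identical(a$truth, c$truth)  # truth depends on specs, not draws

  # zero baseline rate: empty train
  s0 <- specs; s0$r0_hz <- 0; s0$emax <- 0
  expect_equal(nrow(simulate_spike_trains(s0, p, seed = 1)$spikes), 0L)
})

test_that("saturating inhibition suppresses the drug-window rate", {
  p <- short_protocol()
  spec <- tibble::tibble(neuron_id = "i", r0_hz = 8, response = "inhibited",
                         emax = -1, ec50_uM = 0.01, hill = 1,
                         rebound_amp = 0, rebound_tau_s = 60,
                         model = "poisson", shape = 1)
  sim <- simulate_spike_trains(spec, p, seed = 4)
  drug_rate <- sum(sim$spikes$spike_time_s >= 900) / 300
  expect_lt(drug_rate, 0.1 * 8)
})

test_that("no-effect neurons stay within Monte-Carlo error of baseline", {
  p <- short_protocol()
  specs <- neuron_sim_specs(30, p_excited = 0, p_inhibited = 0,
                            r0_range = c(5, 5), seed = 2)
  sim <- simulate_spike_trains(specs, p, seed = 3)
  drug <- sum(sim$spikes$spike_time_s >= 600) / (600 * 30)
  se <- sqrt(5 / (600 * 30))  # Poisson SE of the pooled rate estimate
  expect_lt(abs(drug - 5), 3 * se)
})

test_that("washout rebound adds a decaying rate bump after drug offset", {
  p <- dopamine_protocol()
  spec <- tibble::tibble(neuron_id = "r", r0_hz = 6, response = "inhibited",
                         emax = -1, ec50_uM = 0.01, hill = 1,
                         rebound_amp = 1.5, rebound_tau_s = 120,
                         model = "poisson", shape = 1)
  sim <- simulate_spike_trains(spec, p, seed = 6)
  wash <- sim$spikes$spike_time_s[sim$spikes$spike_time_s >= 3000]
  early <- sum(wash < 3150) / 150
  late <- sum(wash >= 3450) / 150
  expect_gt(early, 6)   # above baseline right after offset
  expect_gt(early, late + 1)
})

test_that("gamma-renewal trains are more regular than Poisson", {
  p <- short_protocol()
  mk <- function(model, shape) {
    tibble::tibble(neuron_id = "g", r0_hz = 6, response = "none", emax = 0,
                   ec50_uM = 3, hill = 1, rebound_amp = 0,
                   rebound_tau_s = 60, model = model, shape = shape)
  }
  sg <- simulate_spike_trains(mk("gamma", 8), p, seed = 7)
  sp <- simulate_spike_trains(mk("poisson", 1), p, seed = 7)
  sd_of <- function(s) {
    baseline_stats(bin_rates(s$spikes, c(300, 600)))$sd_hz
  }
  expect_lt(sd_of(sg), sd_of(sp))
})

test_that("simulated images carry exact ground truth", {
  cells <- image_cell_specs(2, radius_um = 5, body = c(Pomc = 100),
                            dots = c(Pomc = 0, Drd2 = 0))
  sim <- simulate_image(cells, channels = c("Pomc", "Drd2"), noise_sd = 0,
                        seed = 15)
  # body intensity on the true mask: exactly the programmed value
  for (i in 1:2) {
    vals <- sim$image$channels$Pomc[sim$masks == i]
    expect_lt(abs(mean(vals) - 100) / 100, 0.01)
  }
  # rendered disk area within one pixel-perimeter band of pi r^2
  px2 <- sim$image$pixel_size_um^2
  for (i in 1:2) {
    a <- sum(sim$masks == i) * px2
    band <- 2 * pi * 5 * sim$image$pixel_size_um
    expect_lt(abs(a - pi * 25), band)
  }
  expect_equal(sim$truth$area_um2_true, rep(pi * 25, 2))

  # zero true dots stay negative through the pipeline
  q <- quantify_image(sim$image, "Pomc")
  expect_true(all(!q$cells$positive))

  # non-overlap guarantee errors out when the field is too crowded
  crowded <- image_cell_specs(200, radius_um = 10, body = c(Pomc = 50))
  expect_error(simulate_image(crowded, channels = "Pomc",
                              shape = c(64, 64), max_tries = 50, seed = 1),
               "without overlap")
})

test_that("count-matrix generator hits programmed coexpression fractions", {
  fr <- tibble::tibble(cluster = "c1", gene = c("a", "b", "z"),
                       fraction = c(1, 0, 0.766))
  sim <- simulate_count_matrix(c(c1 = 2000), fr, seed = 9)
  expect_equal(percent_expressing(sim$counts, "a"), 100)
  expect_equal(percent_expressing(sim$counts, "b"), 0)
  pct <- percent_expressing(sim$counts, "z")
  ci <- 100 * 1.96 * sqrt(0.766 * 0.234 / 2000)
  expect_lt(abs(pct - 76.6), ci)
  expect_equal(sim$truth$fraction_realized[sim$truth$gene == "z"] * 100,
               pct)
})
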