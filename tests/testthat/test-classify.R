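test_that("the 3-sigma rule classifies window-mean changes strictly", {
  p <- short_protocol()
  # drug-window rate exactly 2.0 Hz (one spike every 0.5 s)
  drug <- regular_train("n1", 2, 600, 1200)
  base4 <- tibble::tibble(neuron_id = "n1", mean_hz = 4, sd_hz = 0.5,
                          n_bins = 30L)
  call <- classify_epoch(drug, p, "drug_30uM", base4)
  expect_equal(call$delta, -2)
  expect_equal(call$z, -4)                 # |delta| = 2 > 3 * 0.5
  expect_equal(call$class, "inhibited")

  # delta 2.5 vs 3 * SD 1.0: below threshold, not responsive
  drug65 <- regular_train("n2", 6.5, 600, 1200)
  base41 <- tibble::tibble(neuron_id = "n2", mean_hz = 4, sd_hz = 1,
                           n_bins = 30L)
  call2 <- classify_epoch(drug65, p, "drug_30uM", base41)
  expect_equal(call2$delta, 2.5)
  expect_equal(call2$class, "not_responsive")

  # ties (delta exactly 3 * SD) and delta = 0 are not responsive
  drug7 <- regular_train("n3", 7, 600, 1200)
  base_n3 <- tibble::tibble(neuron_id = "n3", mean_hz = 4, sd_hz = 1,
                            n_bins = 30L)
  call3 <- classify_epoch(drug7, p, "drug_30uM", base_n3)
  expect_equal(call3$delta, 3)
  expect_equal(call3$class, "not_responsive")
  drug4 <- regular_train("n4", 4, 600, 1200)
  base44 <- tibble::tibble(neuron_id = "n4", mean_hz = 4, sd_hz = 0.5,
                           n_bins = 30L)
  call4 <- classify_epoch(drug4, p, "drug_30uM", base44)
  expect_equal(call4$delta, 0)
  expect_equal(call4$z, 0)
  expect_equal(call4$class, "not_responsive")
  expect_equal(sign(call$z), sign(call$delta))
})

test_that("classification equals a direct-count oracle on random trains", {
  p <- dopamine_protocol()
  specs <- neuron_sim_specs(40, p_excited = 0.3, p_inhibited = 0.3,
                            effect_sd_mult = 5, seed = 21)
  sim <- simulate_spike_trains(specs, p, seed = 22)
  calls <- classify_responses(sim$spikes, p)
  by_neuron <- split(sim$spikes$spike_time_s, sim$spikes$neuron_id)
  for (ep in c("dopamine_0.3uM", "dopamine_30uM")) {
    got <- calls[calls$epoch == ep, ]
    for (id in names(by_neuron)) {
      o <- oracle_classify_one(by_neuron[[id]], p, ep)
      row <- got[got$neuron_id == id, ]
      expect_equal(row$delta, o$delta, tolerance = 1e-12)
      expect_identical(row$class, o$class)
    }
  }
  rm(sim, calls, by_neuron); gc(verbose = FALSE)
})

test_that("classification is invariant to uniform time translation", {
  p <- short_protocol()
  specs <- neuron_sim_specs(10, seed = 5)
  sim <- simulate_spike_trains(specs, p, seed = 6)
  c1 <- classify_responses(sim$spikes, p)
  shift <- 137.5
  p2 <- validate_protocol(dplyr::mutate(p, t_start_s = t_start_s + shift,
                                        t_end_s = t_end_s + shift))
  s2 <- dplyr::mutate(sim$spikes, spike_time_s = spike_time_s + shift)
  c2 <- classify_responses(s2, p2)
  expect_equal(c1$delta, c2$delta)
  expect_identical(c1$class, c2$class)
})

test_that("raising the drug-window rate never moves a call toward inhibited", {
  p <- short_protocol()
  base <- tibble::tibble(neuron_id = "n", mean_hz = 4, sd_hz = 0.6,
                         n_bins = 30L)
  rank_of <- c(inhibited = 1, not_responsive = 2, excited = 3)
  classes <- vapply(c(1, 2.5, 4, 5.5, 7, 9), function(r) {
    classify_epoch(regular_train("n", r, 600, 1200), p, "drug_30uM",
                   base)$class
  }, character(1))
  expect_true(all(diff(rank_of[classes]) >= 0))
})

test_that("silent neurons fall back to membrane potential or indeterminate", {
  p <- sst_protocol()
  t <- seq(0, 1199.9, by = 0.1)
  epoch <- t >= 600 & t < 900
  firing <- regular_train("firing", 2, 0, 1200)

  # hyperpolarisation: -55 -> -60 mV, |delta| = 5 > 3 * max(SD, floor)
  vm <- tibble::tibble(neuron_id = "silent", time_s = t,
                       vm_mV = ifelse(epoch, -60, -55))
  calls <- classify_responses(firing, p, vm = vm,
                              neurons = c("firing", "silent"))
  silent <- calls[calls$neuron_id == "silent", ]
  expect_equal(silent$modality, "membrane_potential")
  expect_equal(silent$delta, -5)
  expect_equal(silent$class, "inhibited")

  # flat Vm throughout: not responsive
  vm_flat <- tibble::tibble(neuron_id = "silent", time_s = t, vm_mV = -55)
  flat <- classify_responses(firing, p, vm = vm_flat,
                             neurons = c("firing", "silent"))
  expect_equal(flat$class[flat$neuron_id == "silent"], "not_responsive")

  # no Vm at all: indeterminate
  none <- classify_responses(firing, p, neurons = c("firing", "silent"))
  expect_equal(none$class[none$neuron_id == "silent"], "indeterminate")
  expect_true(is.na(none$z[none$neuron_id == "silent"]))

  # depolarising Vm on classify_vm directly
  vm_up <- tibble::tibble(neuron_id = "s2", time_s = t,
                          vm_mV = ifelse(epoch, -48, -55))
  up <- classify_vm(vm_up, p, "somatostatin_0.3uM")
  expect_equal(up$class, "excited")
})

test_that("population summaries report class percentages over classifiable n", {
  mk <- function(cls, conc = 30) {
    tibble::tibble(neuron_id = paste0("n", seq_along(cls)),
                   epoch = "e", agent = "dopamine", concentration_uM = conc,
                   baseline_mean = 1, baseline_sd = 1, drug_mean = 1,
                   delta = 0, z = 0, class = cls, modality = "firing_rate")
  }
  # 11 of 11 inhibited -> 100%
  s1 <- summarize_population(mk(rep("inhibited", 11)))
  expect_equal(s1$pct_inhibited, 100)
  expect_equal(s1$n, 11L)

  # 9 not responsive + 4 inhibited of 13 -> 69.2% / 30.8%
  s2 <- summarize_population(mk(c(rep("not_responsive", 9),
                                  rep("inhibited", 4))))
  expect_equal(round(s2$pct_not_responsive, 1), 69.2)
  expect_equal(round(s2$pct_inhibited, 1), 30.8)

  # all not responsive -> 100%; indeterminate excluded from the denominator
  s3 <- summarize_population(mk(c(rep("not_responsive", 5),
                                  "indeterminate")))
  expect_equal(s3$pct_not_responsive, 100)
  expect_equal(s3$n, 5L)
  expect_equal(s3$n_indeterminate, 1L)
  expect_equal(s3$pct_excited + s3$pct_not_responsive + s3$pct_inhibited,
               100)

  # a group with only indeterminate calls is omitted with a warning
  expect_warning(s4 <- summarize_population(
    dplyr::bind_rows(mk(rep("indeterminate", 3), conc = 0.3),
                     mk(rep("excited", 2), conc = 30))
  ), "omitted")
  expect_equal(nrow(s4), 1L)
})

test_that("heatmap tables align with zscore_trace and order rows stably", {
  p <- short_protocol()
  # constant-rate neuron: all-zero delta row
  s <- regular_train("flat", 3, 0, 1200)
  hm <- response_heatmap_table(s, p)
  expect_true(all(abs(hm$delta_hz) < 1e-12))

  specs <- neuron_sim_specs(8, seed = 13)
  sim <- simulate_spike_trains(specs, p, seed = 14)
  hm2 <- response_heatmap_table(sim$spikes, p)
  # compositional check against zscore_trace on the same baseline window
  base <- baseline_stats(bin_rates(sim$spikes, c(300, 600),
                                   neurons = specs$neuron_id))
  z <- zscore_trace(bin_rates(sim$spikes, c(0, 1200),
                              neurons = specs$neuron_id),
                    base, sd_floor = rate_sd_floor())
  key <- paste(z$neuron_id, z$bin)
  m <- match(paste(as.character(hm2$neuron_id), hm2$bin), key)
  expect_equal(hm2$z, z$z[m])

  # row order invariant under permutation of the input rows
  withr::local_seed(3)
  perm <- sim$spikes[sample(nrow(sim$spikes)), ]
  hm3 <- response_heatmap_table(perm, p)
  expect_identical(levels(hm2$neuron_id), levels(hm3$neuron_id))

  mats <- heatmap_matrices(hm2)
  expect_equal(dim(mats$delta), dim(mats$z))
  expect_equal(nrow(mats$z), 8L)
  expect_equal(ncol(mats$z), 120L)
})
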