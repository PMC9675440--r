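#' Classify drug responses of recorded neurons (3-sigma criterion)
#'
#' For every neuron and every drug epoch of the protocol, compares the mean
#' binned firing rate in the epoch's analysis window against the baseline
#' mean, in units of the baseline SD. A neuron is called a responder when the
#' change exceeds three baseline SDs: `excited` if
#' `delta > k * SD_effective`, `inhibited` if `delta < -k * SD_effective`,
#' otherwise `not_responsive` (ties are not responsive). `SD_effective =
#' max(baseline_sd, sd_floor)` guards near-silent baselines.
#'
#' Baseline statistics come from the last `baseline_window_s` seconds of the
#' single baseline epoch (default 5 min = 30 bins of 10 s); every drug epoch
#' is compared against this one pre-application baseline since concentrations
#' are applied sequentially without intervening washout. The drug analysis
#' window is the last `drug_window_s` seconds of each epoch, clipped to the
#' epoch length (a 5-min epoch analysed with the 5-min default uses the whole
#' epoch). Washout epochs are never classified.
#'
#' Neurons that fired no action potentials during baseline carry no usable
#' rate signal; when a membrane-potential table is supplied they are
#' classified on per-bin mean Vm instead (depolarisation = excited,
#' hyperpolarisation = inhibited, `modality = "membrane_potential"`);
#' otherwise they are returned as `indeterminate`.
#'
#' @param spikes Spike table (`neuron_id`, `spike_time_s`).
#' @param protocol An `arc_protocol`.
#' @param vm Optional membrane-potential table (`neuron_id`, `time_s`,
#'   `vm_mV`) used as fallback for silent neurons.
#' @param bin_width_s Bin width in seconds.
#' @param baseline_window_s Baseline statistics window (s).
#' @param drug_window_s Drug analysis window (s), taken from the epoch end.
#' @param k Responder multiplier (3 = the 3-sigma criterion).
#' @param sd_floor Rate SD floor in Hz; default [rate_sd_floor()] for the
#'   realised baseline bin count.
#' @param vm_sd_floor Vm SD floor in mV for the fallback modality.
#' @param neurons Optional character vector fixing the neuron set.
#' @return A tibble with one row per neuron x drug epoch: `neuron_id`,
#'   `epoch`, `agent`, `concentration_uM`, `baseline_mean`, `baseline_sd`,
#'   `drug_mean`, `delta`, `z`, `class`, `modality`. Rate-modality rows are
#'   in Hz, Vm-modality rows in mV.
#' @export
classify_responses <- function(spikes, protocol, vm = NULL,
                               bin_width_s = 10, baseline_window_s = 300,
                               drug_window_s = 300, k = 3,
                               sd_floor = NULL, vm_sd_floor = 0.01,
                               neurons = NULL) {
  protocol <- validate_protocol(protocol)
  s <- validate_spikes(spikes, protocol)
  if (!is.null(vm)) vm <- validate_vm(vm, protocol)
  ids <- neurons %||% unique(c(s$neuron_id, vm$neuron_id))
  if (!length(ids)) abort("no neurons to classify")
  f <- factor(s$neuron_id, levels = ids)

  base <- epoch_window(protocol[protocol$kind == "baseline", ],
                       baseline_window_s, bin_width_s)
  bc <- bin_count_matrix(s$spike_time_s, f, base$t0, base$n_bins, bin_width_s)
  br <- bc / bin_width_s
  base_mean <- colMeans(br)
  base_sd <- col_sds(br)
  floor_hz <- sd_floor %||% rate_sd_floor(bin_width_s, base$n_bins)

  epochs <- drug_epochs(protocol)
  calls <- purrr::pmap_dfr(epochs, function(label, kind, agent,
                                            concentration_uM, t_start_s,
                                            t_end_s) {
    w <- epoch_window(tibble(t_start_s = t_start_s, t_end_s = t_end_s),
                      drug_window_s, bin_width_s, label = label)
    dc <- bin_count_matrix(s$spike_time_s, f, w$t0, w$n_bins, bin_width_s)
    drug_mean <- colMeans(dc / bin_width_s)
    sd_eff <- pmax(base_sd, floor_hz)
    delta <- drug_mean - base_mean
    tibble(
      neuron_id = ids, epoch = label, agent = agent,
      concentration_uM = concentration_uM,
      baseline_mean = base_mean, baseline_sd = base_sd,
      drug_mean = drug_mean, delta = delta, z = delta / sd_eff,
      class = three_sigma_class(delta, sd_eff, k),
      modality = "firing_rate"
    )
  })

  silent <- ids[base_mean == 0 & base_sd == 0]
  if (length(silent)) {
    with_vm <- intersect(silent, unique(vm$neuron_id))
    no_vm <- setdiff(silent, with_vm)
    if (length(no_vm)) {
      idx <- calls$neuron_id %in% no_vm
      calls$class[idx] <- "indeterminate"
      calls$z[idx] <- NA_real_
      calls$modality[idx] <- "firing_rate"
    }
    for (ep in epochs$label) {
      if (length(with_vm)) {
        vcalls <- classify_vm(vm[vm$neuron_id %in% with_vm, ], protocol, ep,
                              bin_width_s = bin_width_s,
                              baseline_window_s = baseline_window_s,
                              drug_window_s = drug_window_s, k = k,
                              sd_floor = vm_sd_floor)
        m <- match(paste(vcalls$neuron_id, ep),
                   paste(calls$neuron_id, calls$epoch))
        for (col in c("baseline_mean", "baseline_sd", "drug_mean", "delta",
                      "z", "class", "modality")) {
          calls[[col]][m] <- vcalls[[col]]
        }
      }
    }
  }
  calls
}

#' Classify one drug epoch against precomputed baseline statistics
#'
#' The single-epoch core of [classify_responses()]: mean binned rate in the
#' epoch's analysis window minus the baseline mean, classed by the strict
#' `k`-sigma comparison. Exposed for composition and for cross-checking
#' against direct-count implementations.
#'
#' @inheritParams classify_responses
#' @param epoch_label Label of the drug epoch to classify.
#' @param baseline Output of [baseline_stats()] for the same neurons.
#' @return Same shape as [classify_responses()], one drug epoch only.
#' @export
classify_epoch <- function(spikes, protocol, epoch_label, baseline,
                           bin_width_s = 10, drug_window_s = 300, k = 3,
                           sd_floor = rate_sd_floor(bin_width_s, 30)) {
  protocol <- validate_protocol(protocol)
  ep <- protocol[protocol$label == epoch_label, ]
  if (nrow(ep) != 1 || ep$kind != "drug") {
    abort(paste0("'", epoch_label, "' is not a drug epoch of the protocol"))
  }
  s <- validate_spikes(spikes)
  ids <- baseline$neuron_id
  f <- factor(s$neuron_id, levels = ids)
  if (anyNA(f)) {
    abort(paste0("spikes contain neuron(s) without baseline statistics: ",
                 paste(unique(s$neuron_id[is.na(f)]), collapse = ", ")))
  }
  w <- epoch_window(ep, drug_window_s, bin_width_s, label = epoch_label)
  dc <- bin_count_matrix(s$spike_time_s, f, w$t0, w$n_bins, bin_width_s)
  drug_mean <- colMeans(dc / bin_width_s)
  sd_eff <- pmax(baseline$sd_hz, sd_floor)
  delta <- drug_mean - baseline$mean_hz
  tibble(
    neuron_id = ids, epoch = epoch_label, agent = ep$agent,
    concentration_uM = ep$concentration_uM,
    baseline_mean = baseline$mean_hz, baseline_sd = baseline$sd_hz,
    drug_mean = drug_mean, delta = delta, z = delta / sd_eff,
    class = three_sigma_class(delta, sd_eff, k),
    modality = "firing_rate"
  )
}

#' Classify a drug epoch from membrane potential
#'
#' Identical logic to [classify_epoch()] with per-bin mean membrane potential
#' (mV) in place of the firing rate: a depolarising shift beyond
#' `k * SD_effective` is `excited`, a hyperpolarising one `inhibited`. Used
#' as the response indicator for neurons that fire no action potentials.
#'
#' @inheritParams classify_responses
#' @param epoch_label Label of the drug epoch to classify.
#' @return Same shape as [classify_responses()]; values in mV,
#'   `modality = "membrane_potential"`. Neurons without Vm samples are
#'   returned `indeterminate`.
#' @export
classify_vm <- function(vm, protocol, epoch_label, bin_width_s = 10,
                        baseline_window_s = 300, drug_window_s = 300, k = 3,
                        sd_floor = 0.01, neurons = NULL) {
  protocol <- validate_protocol(protocol)
  ep <- protocol[protocol$label == epoch_label, ]
  if (nrow(ep) != 1 || ep$kind != "drug") {
    abort(paste0("'", epoch_label, "' is not a drug epoch of the protocol"))
  }
  ids <- neurons %||% unique(vm$neuron_id)
  base <- epoch_window(protocol[protocol$kind == "baseline", ],
                       baseline_window_s, bin_width_s)
  w <- epoch_window(ep, drug_window_s, bin_width_s, label = epoch_label)
  one <- function(id) {
    d <- vm[vm$neuron_id == id, ]
    if (!nrow(d)) {
      return(tibble(
        neuron_id = id, epoch = epoch_label, agent = ep$agent,
        concentration_uM = ep$concentration_uM,
        baseline_mean = NA_real_, baseline_sd = NA_real_,
        drug_mean = NA_real_, delta = NA_real_, z = NA_real_,
        class = "indeterminate", modality = "membrane_potential"
      ))
    }
    bb <- vm_bin_means(d, base$t0, base$n_bins, bin_width_s)
    db <- vm_bin_means(d, w$t0, w$n_bins, bin_width_s)
    m <- mean(bb); s <- sd(bb)
    sd_eff <- max(s, sd_floor)
    delta <- mean(db) - m
    tibble(
      neuron_id = id, epoch = epoch_label, agent = ep$agent,
      concentration_uM = ep$concentration_uM,
      baseline_mean = m, baseline_sd = s, drug_mean = mean(db),
      delta = delta, z = delta / sd_eff,
      class = three_sigma_class(delta, sd_eff, k),
      modality = "membrane_potential"
    )
  }
  purrr::map_dfr(ids, one)
}

#' Summarise response calls per agent and concentration
#'
#' Counts and percentages of `excited` / `not_responsive` / `inhibited`
#' calls per (agent, concentration). Indeterminate calls are excluded from
#' the percentage denominator and reported separately, so the three class
#' percentages sum to 100.
#'
#' @param calls Output of [classify_responses()].
#' @return A tibble of class `arc_popsummary`: `agent`, `concentration_uM`,
#'   `n` (classifiable), `n_excited`, `n_not_responsive`, `n_inhibited`,
#'   `n_indeterminate`, `pct_excited`, `pct_not_responsive`,
#'   `pct_inhibited`.
#' @export
summarize_population <- function(calls) {
  out <- calls %>%
    dplyr::group_by(.data$agent, .data$concentration_uM) %>%
    dplyr::summarise(
      n = sum(.data$class != "indeterminate"),
      n_excited = sum(.data$class == "excited"),
      n_not_responsive = sum(.data$class == "not_responsive"),
      n_inhibited = sum(.data$class == "inhibited"),
      n_indeterminate = sum(.data$class == "indeterminate"),
      .groups = "drop"
    )
  empty <- out$n == 0
  if (any(empty)) {
    warn(paste0("group(s) with no classifiable neurons omitted: ",
                paste(paste0(out$agent[empty], " ",
                             out$concentration_uM[empty], " uM"),
                      collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  out <- dplyr::mutate(
    out,
    pct_excited = 100 * .data$n_excited / .data$n,
    pct_not_responsive = 100 * .data$n_not_responsive / .data$n,
    pct_inhibited = 100 * .data$n_inhibited / .data$n
  )
  class(out) <- c("arc_popsummary", class(tibble()))
  out
}

#' Per-bin response table for population heatmaps
#'
#' Bins every neuron over the full protocol span (baseline through washout)
#' and reports, per bin, the rate change from baseline (`delta_hz`) and the
#' z-score. Washout bins are displayed but are never used for classification.
#' Rows (neurons) are ordered by mean z in the top-concentration drug epoch,
#' descending, so the ordering is stable under permutation of the input.
#'
#' @inheritParams classify_responses
#' @return A long tibble of class `arc_heatmap` (`neuron_id` as an ordered
#'   factor, `bin`, `t_mid_s`, `epoch`, `rate_hz`, `delta_hz`, `z`); pivot to
#'   matrices with [heatmap_matrices()].
#' @export
response_heatmap_table <- function(spikes, protocol, bin_width_s = 10,
                                   baseline_window_s = 300, sd_floor = NULL,
                                   neurons = NULL) {
  protocol <- validate_protocol(protocol)
  s <- validate_spikes(spikes, protocol)
  ids <- neurons %||% unique(s$neuron_id)
  span <- protocol_span(protocol)
  rates <- bin_rates(s, span, bin_width_s, neurons = ids)

  base <- epoch_window(protocol[protocol$kind == "baseline", ],
                       baseline_window_s, bin_width_s)
  bstats <- bin_rates(s, c(base$t0, base$t0 + base$n_bins * bin_width_s),
                      bin_width_s, neurons = ids) %>% baseline_stats()
  floor_hz <- sd_floor %||% rate_sd_floor(bin_width_s, base$n_bins)
  out <- zscore_trace(rates, bstats, sd_floor = floor_hz)
  out$t_mid_s <- (out$t_start_s + out$t_end_s) / 2
  out$epoch <- epoch_at(protocol, out$t_mid_s)

  top <- drug_epochs(protocol)
  top <- top[which.max(top$concentration_uM), ]
  key <- out %>%
    dplyr::filter(.data$t_mid_s >= top$t_start_s,
                  .data$t_mid_s < top$t_end_s) %>%
    dplyr::group_by(.data$neuron_id) %>%
    dplyr::summarise(sort_z = mean(.data$z), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$sort_z), .data$neuron_id)
  out$neuron_id <- factor(out$neuron_id, levels = key$neuron_id)
  out <- dplyr::arrange(out, .data$neuron_id, .data$bin)
  out <- dplyr::select(out, "neuron_id", "bin", "t_mid_s", "epoch",
                       "rate_hz", "delta_hz", "z")
  class(out) <- c("arc_heatmap", class(tibble()))
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "protocol") <- protocol
  out
}

#' Pivot a heatmap table to aligned matrices
#'
#' @param x An `arc_heatmap` tibble from [response_heatmap_table()].
#' @return A list of two aligned numeric matrices, `delta` and `z`, one row
#'   per neuron (display order) and one column per bin.
#' @export
heatmap_matrices <- function(x) {
  wide <- function(col) {
    m <- tidyr::pivot_wider(x[c("neuron_id", "bin", col)],
                            names_from = "bin", values_from = dplyr::all_of(col))
    out <- as.matrix(m[-1])
    rownames(out) <- as.character(m$neuron_id)
    out
  }
  list(delta = wide("delta_hz"), z = wide("z"))
}

# --- internal helpers -------------------------------------------------------

# strict k-sigma classing on a window-mean change
three_sigma_class <- function(delta, sd_eff, k) {
  dplyr::case_when(
    delta > k * sd_eff ~ "excited",
    delta < -k * sd_eff ~ "inhibited",
    TRUE ~ "not_responsive"
  )
}

# analysis window: last `window_s` of the epoch (clipped to epoch length),
# truncated backwards from the epoch end to whole bins
epoch_window <- function(ep, window_s, bin_width_s, label = "baseline") {
  len <- min(window_s, ep$t_end_s - ep$t_start_s)
  n_bins <- floor(len / bin_width_s + 1e-9)
  if (n_bins < 1) {
    abort(paste0("epoch '", label, "' is shorter than one bin (",
                 bin_width_s, " s)"))
  }
  list(t0 = ep$t_end_s - n_bins * bin_width_s, n_bins = n_bins)
}

# column sample SDs of a counts/rates matrix without apply() overhead
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

# per-bin mean Vm for one neuron's uniformly sampled trace
vm_bin_means <- function(d, t0, n_bins, w) {
  keep <- d$time_s >= t0 & d$time_s < t0 + n_bins * w
  b <- pmin(floor((d$time_s[keep] - t0) / w), n_bins - 1) + 1
  if (length(unique(b)) < n_bins) {
    abort(paste0("vm trace has empty bins in the analysis window for neuron ",
                 d$neuron_id[1]))
  }
  as.numeric(tapply(d$vm_mV[keep], b, mean))
}

# epoch label at given times (half-open membership; NA outside all epochs)
epoch_at <- function(protocol, t) {
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(protocol))) {
    inside <- t >= protocol$t_start_s[i] & t < protocol$t_end_s[i]
    out[inside] <- protocol$label[i]
  }
  out
}
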