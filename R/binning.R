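#' Bin spike counts into firing rates
#'
#' Divides a half-open analysis window `[t0, t1)` into uniform bins (default
#' 10 s, the width used for the 5-minute / 30-bin baseline statistic) and
#' converts per-bin spike counts to rates in Hz. When the window length is
#' not an integer multiple of the bin width it is truncated to the largest
#' multiple, counting backwards from the window end, so that the bins always
#' abut the end of the window ("at the end of the drug application").
#'
#' @param spikes Spike table (`neuron_id`, `spike_time_s`).
#' @param window Numeric length-2, `c(t0, t1)` in seconds, half-open.
#' @param bin_width_s Bin width in seconds (> 0).
#' @param neurons Optional character vector fixing the neuron set (neurons
#'   with no spikes still get all-zero rows); defaults to the neurons present
#'   in `spikes`.
#' @return A tibble with one row per neuron and bin: `neuron_id`, `bin`
#'   (1-based), `t_start_s`, `t_end_s`, `n_spikes`, `rate_hz`.
#' @export
bin_rates <- function(spikes, window, bin_width_s = 10, neurons = NULL) {
  s <- validate_spikes(spikes)
  if (length(window) != 2 || !all(is.finite(window))) {
    abort("window must be c(t0, t1) with finite values")
  }
  if (bin_width_s <= 0) abort("bin_width_s must be > 0")
  n_bins <- floor((window[2] - window[1]) / bin_width_s + 1e-9)
  if (window[2] <= window[1] || n_bins < 1) {
    abort("empty analysis window: it must contain at least one full bin")
  }
  t0 <- window[2] - n_bins * bin_width_s
  ids <- neurons %||% unique(s$neuron_id)
  f <- factor(s$neuron_id, levels = ids)
  if (anyNA(f)) {
    abort("spikes contain neuron(s) not listed in `neurons`")
  }
  counts <- bin_count_matrix(s$spike_time_s, f, t0, n_bins, bin_width_s)
  tibble(
    neuron_id = rep(ids, each = n_bins),
    bin = rep(seq_len(n_bins), length(ids)),
    t_start_s = t0 + (rep(seq_len(n_bins), length(ids)) - 1) * bin_width_s,
    t_end_s = t0 + rep(seq_len(n_bins), length(ids)) * bin_width_s,
    n_spikes = as.integer(counts),
    rate_hz = as.numeric(counts) / bin_width_s
  )
}

# counts matrix (n_bins x n_neurons) over [t0, t0 + n_bins*w); vectorised so
# that population-scale simulations (10^4 neurons, 10^7 spikes) stay fast
bin_count_matrix <- function(times, id_f, t0, n_bins, w) {
  keep <- times >= t0 & times < t0 + n_bins * w
  b <- pmin(floor((times[keep] - t0) / w), n_bins - 1)
  code <- (as.integer(id_f[keep]) - 1L) * n_bins + as.integer(b) + 1L
  matrix(tabulate(code, nbins = n_bins * nlevels(id_f)), nrow = n_bins)
}

#' Baseline mean and standard deviation of binned firing rates
#'
#' Per neuron: arithmetic mean of the per-bin rates and their sample standard
#' deviation (n - 1 denominator). With the defaults this is the 5-minute /
#' 30 x 10 s baseline statistic that anchors the 3-sigma responder criterion.
#' An all-zero baseline (mean 0, SD 0) is legal here and flagged downstream
#' (silent neurons fall back to the membrane-potential modality).
#'
#' @param rates Output of [bin_rates()].
#' @return A tibble: `neuron_id`, `mean_hz`, `sd_hz`, `n_bins`.
#' @export
baseline_stats <- function(rates) {
  if (!all(c("neuron_id", "rate_hz") %in% names(rates))) {
    abort("rates must come from bin_rates() (columns neuron_id, rate_hz)")
  }
  out <- rates %>%
    dplyr::group_by(.data$neuron_id) %>%
    dplyr::summarise(
      mean_hz = mean(.data$rate_hz),
      sd_hz = sd(.data$rate_hz),
      n_bins = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_bins < 2)) {
    abort(paste0("baseline needs >= 2 bins; offending neuron(s): ",
                 paste(out$neuron_id[out$n_bins < 2], collapse = ", ")))
  }
  out
}

#' Per-bin z-score trace
#'
#' `z_i = (rate_i - baseline_mean) / SD_effective`, with `SD_effective =
#' max(baseline_sd, sd_floor)`. Used for response visualisation; the
#' classifier applies the same standardisation to window means.
#'
#' @param rates Output of [bin_rates()].
#' @param baseline Output of [baseline_stats()] for the same neurons.
#' @param sd_floor Lower bound for the baseline SD (Hz). The default 0
#'   errors on a zero-SD baseline; pass [rate_sd_floor()] to use the
#'   classifier's floor.
#' @return `rates` with columns `delta_hz` and `z` appended.
#' @export
zscore_trace <- function(rates, baseline, sd_floor = 0) {
  x <- dplyr::left_join(rates, baseline, by = "neuron_id")
  if (anyNA(x$mean_hz)) {
    abort(paste0("no baseline statistics for neuron(s): ",
                 paste(unique(x$neuron_id[is.na(x$mean_hz)]), collapse = ", ")))
  }
  sd_eff <- pmax(x$sd_hz, sd_floor)
  if (any(sd_eff <= 0)) {
    abort(paste0("zero effective baseline SD for neuron(s): ",
                 paste(unique(x$neuron_id[sd_eff <= 0]), collapse = ", "),
                 "; supply a positive sd_floor"))
  }
  x$delta_hz <- x$rate_hz - x$mean_hz
  x$z <- x$delta_hz / sd_eff
  dplyr::select(x, -"mean_hz", -"sd_hz", -"n_bins")
}

#' Rate resolution floor for the effective baseline SD
#'
#' One spike in one bin is the smallest nonzero rate the binning can resolve
#' (`1 / bin_width` Hz); dividing by `sqrt(n_bins)` converts it to the scale
#' of a window-mean difference. With the defaults (10 s bins, 30 bins) the
#' floor is ~0.018 Hz. It only bites for near-silent baselines, where the
#' empirical SD collapses and would otherwise make the 3-sigma test
#' infinitely sensitive.
#'
#' @param bin_width_s Bin width in seconds.
#' @param n_bins Number of baseline bins.
#' @return The floor in Hz.
#' @export
rate_sd_floor <- function(bin_width_s = 10, n_bins = 30) {
  (1 / bin_width_s) / sqrt(n_bins)
}
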