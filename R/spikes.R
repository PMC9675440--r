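#' Validate a spike table
#'
#' A spike table holds one row per action potential: `neuron_id` and
#' `spike_time_s`. Within each neuron spike times must be strictly
#' increasing; duplicates are rejected (two action potentials cannot share a
#' timestamp at any realistic sampling rate). When a protocol is supplied,
#' all spikes must fall inside its half-open recording window
#' `[t_start, t_end)`.
#'
#' @param spikes Data frame with columns `neuron_id`, `spike_time_s`.
#' @param protocol Optional `arc_protocol`; if given, spikes are checked
#'   against the recording window it spans.
#' @return The spike table as a tibble, sorted by time within neuron (the
#'   original neuron order of first appearance is preserved).
#' @export
validate_spikes <- function(spikes, protocol = NULL) {
  req <- c("neuron_id", "spike_time_s")
  miss <- setdiff(req, names(spikes))
  if (length(miss)) {
    abort(paste0("spike table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  s <- as_tibble(spikes)
  s$neuron_id <- as.character(s$neuron_id)
  s$spike_time_s <- as.numeric(s$spike_time_s)
  if (any(!is.finite(s$spike_time_s))) {
    bad <- unique(s$neuron_id[!is.finite(s$spike_time_s)])
    abort(paste0("non-finite spike times for neuron(s): ",
                 paste(bad, collapse = ", ")))
  }
  # stable sort: keep first-appearance neuron order, times ascending within
  ord <- factor(s$neuron_id, levels = unique(s$neuron_id))
  s <- s[order(ord, s$spike_time_s), , drop = FALSE]
  dup <- duplicated(s[c("neuron_id", "spike_time_s")])
  if (any(dup)) {
    abort(paste0("duplicate spike time(s) for neuron(s): ",
                 paste(unique(s$neuron_id[dup]), collapse = ", ")))
  }
  if (!is.null(protocol)) {
    span <- protocol_span(validate_protocol(protocol))
    out <- s$spike_time_s < span[1] | s$spike_time_s >= span[2]
    if (any(out)) {
      abort(paste0("spike time(s) outside the recording window [",
                   span[1], ", ", span[2], ") for neuron(s): ",
                   paste(unique(s$neuron_id[out]), collapse = ", ")))
    }
  }
  s
}

#' Read spike times (and optional membrane potential) from delimited text
#'
#' The spike file is delimited text with columns `neuron_id, spike_time_s`
#' (seconds on the recording clock). An optional membrane-potential file has
#' columns `neuron_id, time_s, vm_mV`, uniformly sampled per neuron. When a
#' protocol file is given the returned objects are cross-validated against
#' its recording window.
#'
#' @param path Spike table path (CSV/TSV; delimiter auto-detected).
#' @param protocol_path Optional protocol YAML path (see [read_protocol()]).
#' @param vm_path Optional membrane-potential table path.
#' @return A list with elements `spikes` (tibble), `protocol`
#'   (`arc_protocol` or `NULL`) and `vm` (tibble or `NULL`).
#' @export
read_spike_table <- function(path, protocol_path = NULL, vm_path = NULL) {
  if (!file.exists(path)) abort(paste0("spike file not found: ", path))
  # parse times via strtod (correctly rounded) so write/read is the identity
  s <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           spike_time_s = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  if (is.character(s$spike_time_s)) {
    s$spike_time_s <- as.numeric(s$spike_time_s)
  }
  protocol <- if (!is.null(protocol_path)) read_protocol(protocol_path)
  spikes <- validate_spikes(s, protocol)
  vm <- NULL
  if (!is.null(vm_path)) {
    if (!file.exists(vm_path)) abort(paste0("vm file not found: ", vm_path))
    vm <- readr::read_delim(vm_path, show_col_types = FALSE, progress = FALSE)
    vm <- validate_vm(vm, protocol)
  }
  list(spikes = spikes, protocol = protocol, vm = vm)
}

#' @rdname read_spike_table
#' @param spikes A validated spike table.
#' @return `write_spike_table()` writes CSV at full double precision (times
#'   survive a write/read round trip bit-exactly) and returns `path`
#'   invisibly.
#' @export
write_spike_table <- function(spikes, path) {
  s <- validate_spikes(spikes)
  # 17 significant digits: lossless text representation of a double
  s$spike_time_s <- sprintf("%.17g", s$spike_time_s)
  readr::write_csv(s, path)
  invisible(path)
}

#' Validate a membrane-potential table
#'
#' Columns `neuron_id, time_s, vm_mV`; per neuron the samples must be at a
#' uniform interval (to 1e-6 s) and, when a protocol is given, cover its
#' recording window.
#'
#' @param vm Data frame with columns `neuron_id`, `time_s`, `vm_mV`.
#' @param protocol Optional `arc_protocol` whose span must be covered.
#' @return The table as a tibble sorted by time within neuron.
#' @export
validate_vm <- function(vm, protocol = NULL) {
  req <- c("neuron_id", "time_s", "vm_mV")
  miss <- setdiff(req, names(vm))
  if (length(miss)) {
    abort(paste0("vm table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  v <- as_tibble(vm)
  v$neuron_id <- as.character(v$neuron_id)
  ord <- factor(v$neuron_id, levels = unique(v$neuron_id))
  v <- v[order(ord, v$time_s), , drop = FALSE]
  check_one <- function(d, id) {
    if (nrow(d) < 2) abort(paste0("vm trace too short for neuron ", id))
    dt <- diff(d$time_s)
    if (max(dt) - min(dt) > 1e-6) {
      abort(paste0("vm trace not uniformly sampled for neuron ", id))
    }
    if (!is.null(protocol)) {
      span <- protocol_span(protocol)
      # coverage of [t_start, t_end): last sample may sit one interval short
      if (d$time_s[1] > span[1] + 1e-9 ||
          d$time_s[nrow(d)] + dt[1] < span[2] - 1e-9) {
        abort(paste0("vm trace does not cover the recording window for neuron ",
                     id))
      }
    }
    invisible(NULL)
  }
  split(v, ord) |> purrr::iwalk(check_one)
  v
}
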