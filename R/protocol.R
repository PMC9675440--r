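#' Build a bath-application protocol
#'
#' A protocol is a tibble of ordered, non-overlapping epochs on the recording
#' clock, each labelled `baseline`, `drug` or `washout`. Epoch intervals are
#' half-open `[t_start_s, t_end_s)`: an event exactly on a boundary belongs to
#' the later epoch. Concentrations are in micromolar throughout; baseline and
#' washout epochs carry concentration 0.
#'
#' @param label Character vector of unique epoch labels.
#' @param kind One of `"baseline"`, `"drug"`, `"washout"` per epoch.
#' @param agent Agent name per epoch (`"none"` for baseline/washout).
#' @param concentration_uM Bath concentration in uM (0 outside drug epochs).
#' @param t_start_s,t_end_s Epoch boundaries in seconds.
#' @return A validated protocol tibble with class `arc_protocol`.
#' @seealso [dopamine_protocol()], [sst_protocol()], [read_protocol()]
#' @export
application_protocol <- function(label, kind, agent, concentration_uM,
                                 t_start_s, t_end_s) {
  p <- tibble(
    label = as.character(label),
    kind = as.character(kind),
    agent = as.character(agent),
    concentration_uM = as.numeric(concentration_uM),
    t_start_s = as.numeric(t_start_s),
    t_end_s = as.numeric(t_end_s)
  )
  validate_protocol(p)
}

#' Standard sequential dopamine application protocol
#'
#' Four increasing dopamine concentrations (0.3, 3, 10, 30 uM) bath-applied
#' for 10 minutes each without intervening washout, preceded by a baseline
#' epoch and followed by a washout epoch.
#'
#' @param baseline_s Baseline epoch duration in seconds.
#' @param concentrations_uM Concentrations, applied in the given order.
#' @param epoch_s Duration of each drug epoch in seconds.
#' @param washout_s Washout duration in seconds (0 to omit).
#' @param agent Agent name.
#' @return An `arc_protocol` tibble.
#' @export
dopamine_protocol <- function(baseline_s = 600,
                              concentrations_uM = c(0.3, 3, 10, 30),
                              epoch_s = 600, washout_s = 600,
                              agent = "dopamine") {
  n <- length(concentrations_uM)
  starts <- baseline_s + (seq_len(n) - 1L) * epoch_s
  label <- c("baseline", paste0(agent, "_", concentrations_uM, "uM"))
  kind <- c("baseline", rep("drug", n))
  agents <- c("none", rep(agent, n))
  conc <- c(0, concentrations_uM)
  t0 <- c(0, starts)
  t1 <- c(baseline_s, starts + epoch_s)
  if (washout_s > 0) {
    label <- c(label, "washout")
    kind <- c(kind, "washout")
    agents <- c(agents, "none")
    conc <- c(conc, 0)
    t0 <- c(t0, baseline_s + n * epoch_s)
    t1 <- c(t1, baseline_s + n * epoch_s + washout_s)
  }
  application_protocol(label, kind, agents, conc, t0, t1)
}

#' Somatostatin application protocol
#'
#' Single 300 nM (0.3 uM) somatostatin epoch of 5 minutes, with baseline and
#' optional washout.
#'
#' @inheritParams dopamine_protocol
#' @param concentration_uM Somatostatin concentration in uM (300 nM = 0.3).
#' @return An `arc_protocol` tibble.
#' @export
sst_protocol <- function(baseline_s = 600, concentration_uM = 0.3,
                         epoch_s = 300, washout_s = 300) {
  dopamine_protocol(
    baseline_s = baseline_s, concentrations_uM = concentration_uM,
    epoch_s = epoch_s, washout_s = washout_s, agent = "somatostatin"
  )
}

#' Validate a protocol tibble
#'
#' Enforces the protocol invariants: required columns; epochs sorted and
#' non-overlapping; exactly one baseline epoch, preceding all drug epochs;
#' nonnegative concentrations that are zero outside drug epochs; positive
#' epoch durations; unique labels.
#'
#' @param protocol A data frame of epochs.
#' @return The protocol as an `arc_protocol` tibble, invisibly usable in
#'   pipelines.
#' @export
validate_protocol <- function(protocol) {
  req <- c("label", "kind", "agent", "concentration_uM", "t_start_s", "t_end_s")
  missing_cols <- setdiff(req, names(protocol))
  if (length(missing_cols)) {
    abort(paste0("protocol is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  p <- as_tibble(protocol)[req]
  bad_kind <- setdiff(unique(p$kind), c("baseline", "drug", "washout"))
  if (length(bad_kind)) {
    abort(paste0("unknown epoch kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  if (anyDuplicated(p$label)) {
    abort(paste0("duplicated epoch label(s): ",
                 paste(unique(p$label[duplicated(p$label)]), collapse = ", ")))
  }
  if (any(!is.finite(p$t_start_s)) || any(!is.finite(p$t_end_s))) {
    abort("epoch boundaries must be finite")
  }
  bad_dur <- p$label[p$t_end_s <= p$t_start_s]
  if (length(bad_dur)) {
    abort(paste0("epoch(s) with nonpositive duration: ",
                 paste(bad_dur, collapse = ", ")))
  }
  if (is.unsorted(p$t_start_s, strictly = TRUE)) {
    abort("epochs must be sorted by t_start_s (strictly increasing)")
  }
  n <- nrow(p)
  if (n > 1) {
    ov <- which(p$t_start_s[-1] < p$t_end_s[-n])
    if (length(ov)) {
      abort(paste0("overlapping epochs: '", p$label[ov[1]], "' and '",
                   p$label[ov[1] + 1], "'"))
    }
  }
  if (any(p$concentration_uM < 0)) abort("concentrations must be nonnegative")
  nonzero_off <- p$kind != "drug" & p$concentration_uM != 0
  if (any(nonzero_off)) {
    abort(paste0("baseline/washout epoch(s) must have concentration 0: ",
                 paste(p$label[nonzero_off], collapse = ", ")))
  }
  ib <- which(p$kind == "baseline")
  if (length(ib) != 1) {
    abort(sprintf("protocol must contain exactly one baseline epoch (found %d)",
                  length(ib)))
  }
  id <- which(p$kind == "drug")
  if (length(id) && any(id < ib)) {
    abort("the baseline epoch must precede all drug epochs")
  }
  class(p) <- c("arc_protocol", class(tibble()))
  p
}

#' Read / write a protocol file
#'
#' The on-disk format is a YAML key-value file with a top-level `epochs`
#' list; each entry carries `label`, `kind`, `agent`, `concentration_uM`,
#' `t_start_s` and `t_end_s`.
#'
#' @param path File path.
#' @return `read_protocol()` returns a validated `arc_protocol` tibble;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) abort(paste0("protocol file not found: ", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$epochs) || !length(y$epochs)) {
    abort(paste0("protocol file has no 'epochs' entries: ", path))
  }
  p <- purrr::map_dfr(y$epochs, function(e) {
    req <- c("label", "kind", "agent", "concentration_uM", "t_start_s", "t_end_s")
    miss <- setdiff(req, names(e))
    if (length(miss)) {
      abort(paste0("protocol epoch '", e$label %||% "?",
                   "' is missing field(s): ", paste(miss, collapse = ", ")))
    }
    tibble(
      label = as.character(e$label), kind = as.character(e$kind),
      agent = as.character(e$agent),
      concentration_uM = as.numeric(e$concentration_uM),
      t_start_s = as.numeric(e$t_start_s), t_end_s = as.numeric(e$t_end_s)
    )
  })
  validate_protocol(p)
}

#' @rdname read_protocol
#' @param protocol An `arc_protocol` tibble (or coercible data frame).
#' @export
write_protocol <- function(protocol, path) {
  p <- validate_protocol(protocol)
  epochs <- purrr::pmap(p, function(label, kind, agent, concentration_uM,
                                    t_start_s, t_end_s) {
    list(label = label, kind = kind, agent = agent,
         concentration_uM = concentration_uM,
         t_start_s = t_start_s, t_end_s = t_end_s)
  })
  yaml::write_yaml(list(epochs = epochs), path, precision = 15)
  invisible(path)
}

# window spanned by a protocol (recording clock)
protocol_span <- function(protocol) {
  c(min(protocol$t_start_s), max(protocol$t_end_s))
}

# drug epochs, in application order
drug_epochs <- function(protocol) {
  dplyr::filter(protocol, .data$kind == "drug")
}
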