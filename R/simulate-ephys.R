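#' Hill dose-response modulation
#'
#' Fractional rate change at bath concentration `c`:
#' `emax * c^h / (ec50^h + c^h)`. Inhibitory responses carry a negative
#' `emax` (>= -1 so that the modulated rate stays nonnegative); `c = 0`
#' gives 0 and `c = ec50` with `h = 1` gives `emax / 2`.
#'
#' @param conc_uM Concentration(s) in uM (>= 0).
#' @param emax Fractional change at saturation (>= -1; sign = direction).
#' @param ec50_uM Half-maximal concentration in uM (> 0).
#' @param hill Hill coefficient (> 0).
#' @return Fractional rate change, same length as `conc_uM`.
#' @export
hill_modulation <- function(conc_uM, emax, ec50_uM, hill = 1) {
  if (any(conc_uM < 0)) abort("concentrations must be nonnegative")
  if (any(ec50_uM <= 0)) abort("ec50_uM must be positive")
  if (any(hill <= 0)) abort("hill must be positive")
  if (any(emax < -1)) abort("emax must be >= -1 (rate cannot go negative)")
  ifelse(conc_uM == 0, 0,
         emax * conc_uM^hill / (ec50_uM^hill + conc_uM^hill))
}

#' Build a table of simulated-neuron specifications
#'
#' One row per neuron: baseline rate, response direction, dose-response
#' parameters, washout rebound, and spiking model (`"poisson"` or
#' `"gamma"` renewal with the given shape; shape > 1 gives more regular
#' trains with a smaller baseline SD). The `effect_sd_mult` interface sets
#' the saturating rate change as a multiple of the *expected* baseline SD of
#' binned rates (`sqrt(r0 / (shape * bin_width))` for a renewal train), which
#' is the natural scale of the 3-sigma criterion; `emax` is derived from it.
#'
#' @param n Number of neurons.
#' @param p_excited,p_inhibited Class mixture probabilities (rest = none).
#' @param r0_range Baseline rate range in Hz (uniform draw).
#' @param effect_sd_mult Magnitude of the saturating rate change, in units of
#'   the expected baseline SD (used for excited/inhibited neurons).
#' @param ec50_uM,hill Dose-response parameters.
#' @param rebound_amp Fractional washout rebound amplitude for inhibited
#'   neurons (0 disables).
#' @param rebound_tau_s Rebound decay constant in seconds.
#' @param model `"poisson"` or `"gamma"`.
#' @param shape Gamma-renewal shape (ignored for Poisson).
#' @param bin_width_s Bin width the effect scale refers to.
#' @param seed Integer seed (draws are reproducible).
#' @return A tibble with one row per neuron; columns `neuron_id`, `r0_hz`,
#'   `response`, `emax`, `ec50_uM`, `hill`, `rebound_amp`, `rebound_tau_s`,
#'   `model`, `shape`.
#' @export
neuron_sim_specs <- function(n, p_excited = 0.3, p_inhibited = 0.3,
                             r0_range = c(1, 10), effect_sd_mult = 8,
                             ec50_uM = 3, hill = 1.5,
                             rebound_amp = 0.5, rebound_tau_s = 60,
                             model = "poisson", shape = 1,
                             bin_width_s = 10, seed = 1) {
  stopifnot(p_excited + p_inhibited <= 1)
  withr::with_seed(seed, {
    r0 <- runif(n, r0_range[1], r0_range[2])
    cls <- sample(c("excited", "inhibited", "none"), n, replace = TRUE,
                  prob = c(p_excited, p_inhibited, 1 - p_excited - p_inhibited))
    shape_eff <- if (model == "gamma") shape else 1
    sd_exp <- sqrt(r0 / (shape_eff * bin_width_s))
    emax <- dplyr::case_when(
      cls == "excited" ~ pmax(effect_sd_mult * sd_exp / r0, 0),
      cls == "inhibited" ~ -pmin(effect_sd_mult * sd_exp / r0, 1),
      TRUE ~ 0
    )
    tibble(
      neuron_id = sprintf("n%04d", seq_len(n)), r0_hz = r0, response = cls,
      emax = emax, ec50_uM = ec50_uM, hill = hill,
      rebound_amp = ifelse(cls == "inhibited", rebound_amp, 0),
      rebound_tau_s = rebound_tau_s, model = model, shape = shape_eff
    )
  })
}

#' Simulate spike trains under a bath-application protocol
#'
#' Generates, per neuron, a point process with piecewise rate
#' `r(t) = r0 * (1 + hill_modulation(c(t)))` where `c(t)` is the protocol's
#' concentration profile (instantaneous bath exchange at epoch boundaries).
#' Inhibited neurons with `rebound_amp > 0` additionally receive an
#' exponentially decaying rate bump `r0 * rebound_amp * exp(-t'/tau)` from
#' the offset of the final drug epoch, emulating post-washout rebound
#' firing. Spiking is homogeneous Poisson within an epoch, or a
#' gamma-renewal process (restarted at epoch boundaries) when
#' `model = "gamma"`.
#'
#' Ground truth per drug concentration: the programmed rate change
#' `delta = r0 * hill_modulation(c)` and the class it implies under the
#' 3-sigma criterion at the *expected* baseline SD
#' (`sqrt(r0 / (shape * bin_width))`): `excited`/`inhibited` when
#' `|delta| > 3 * expected SD`, else `none`.
#'
#' @param specs Tibble from [neuron_sim_specs()] (or built by hand with the
#'   same columns).
#' @param protocol An `arc_protocol`.
#' @param seed Integer seed; fixed seed = identical realisation.
#' @param bin_width_s Bin width used for the ground-truth class scale.
#' @return A list: `spikes` (tibble `neuron_id`, `spike_time_s`), `truth`
#'   (tibble `neuron_id`, `concentration_uM`, `delta_hz_true`,
#'   `class_true`), and `specs` (echo).
#' @export
simulate_spike_trains <- function(specs, protocol, seed = 1,
                                  bin_width_s = 10) {
  protocol <- validate_protocol(protocol)
  req <- c("neuron_id", "r0_hz", "response", "emax", "ec50_uM", "hill",
           "rebound_amp", "rebound_tau_s", "model", "shape")
  miss <- setdiff(req, names(specs))
  if (length(miss)) {
    abort(paste0("specs is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(specs$r0_hz < 0)) abort("baseline rates must be nonnegative")
  if (any(specs$emax < -1)) abort("emax must be >= -1")

  epochs <- protocol
  last_drug <- dplyr::slice_tail(drug_epochs(protocol), n = 1)
  t_off <- if (nrow(last_drug)) last_drug$t_end_s else NA_real_

  spikes <- withr::with_seed(seed, {
    purrr::pmap(specs, function(neuron_id, r0_hz, response, emax, ec50_uM,
                                hill, rebound_amp, rebound_tau_s, model,
                                shape, ...) {
      times <- purrr::pmap(epochs, function(label, kind, agent,
                                            concentration_uM, t_start_s,
                                            t_end_s) {
        r <- r0_hz * (1 + hill_modulation(concentration_uM, emax, ec50_uM,
                                          hill))
        dur <- t_end_s - t_start_s
        reb <- rebound_amp > 0 && kind == "washout" && !is.na(t_off) &&
          t_start_s >= t_off
        if (reb) {
          # thinning against the rebound envelope
          rmax <- r + r0_hz * rebound_amp
          n <- rpois(1, rmax * dur)
          tt <- sort(runif(n, 0, dur))
          lambda <- r + r0_hz * rebound_amp *
            exp(-(t_start_s + tt - t_off) / rebound_tau_s)
          tt <- tt[runif(n) < lambda / rmax]
          t_start_s + tt
        } else if (r <= 0) {
          numeric(0)
        } else if (model == "gamma" && shape != 1) {
          isi <- rgamma(ceiling(r * dur + 6 * sqrt(r * dur) + 20),
                        shape = shape, rate = shape * r)
          tt <- cumsum(isi)
          t_start_s + tt[tt < dur]
        } else {
          n <- rpois(1, r * dur)
          t_start_s + sort(runif(n, 0, dur))
        }
      })
      # a point process has a.s. distinct points; drop rare duplicates that
      # arise from the finite resolution of the uniform RNG
      unique(unlist(times))
    })
  })
  n_sp <- lengths(spikes)
  spikes_tbl <- tibble(
    neuron_id = rep(specs$neuron_id, n_sp),
    spike_time_s = unlist(spikes)
  )

  conc <- drug_epochs(protocol)$concentration_uM
  truth <- tidyr::crossing(
    dplyr::select(specs, "neuron_id", "r0_hz", "emax", "ec50_uM", "hill",
                  "shape"),
    concentration_uM = conc
  ) %>%
    dplyr::mutate(
      delta_hz_true = .data$r0_hz *
        hill_modulation(.data$concentration_uM, .data$emax, .data$ec50_uM,
                        .data$hill),
      sd_expected = sqrt(.data$r0_hz / (.data$shape * bin_width_s)),
      class_true = dplyr::case_when(
        .data$delta_hz_true > 3 * .data$sd_expected ~ "excited",
        .data$delta_hz_true < -3 * .data$sd_expected ~ "inhibited",
        TRUE ~ "none"
      )
    ) %>%
    dplyr::select("neuron_id", "concentration_uM", "delta_hz_true",
                  "sd_expected", "class_true")
  list(spikes = spikes_tbl, truth = truth, specs = specs)
}
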