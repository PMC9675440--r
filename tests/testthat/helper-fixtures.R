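# Fixture builders and independent oracles used across the suite.
# Oracles deliberately use different primitives (hist(), pixel loops,
# pairwise comparisons) than the implementation they check.

# perfectly regular spike train: one spike every 1/rate seconds
regular_train <- function(id, rate_hz, t0, t1, phase = 0.25) {
  tibble::tibble(
    neuron_id = id,
    spike_time_s = seq(t0 + phase / rate_hz, t1 - 1e-9, by = 1 / rate_hz)
  )
}

# direct-count oracle for one neuron's response call: counts spikes bin by
# bin with hist(), takes mean/SD with the textbook formulas, applies the
# strict 3-sigma rule
oracle_classify_one <- function(times, protocol, epoch_label,
                                bin_width_s = 10, baseline_window_s = 300,
                                drug_window_s = 300, k = 3,
                                sd_floor = NULL) {
  win <- function(t0, t1, wmax) {
    len <- min(wmax, t1 - t0)
    nb <- floor(len / bin_width_s + 1e-9)
    seq(t1 - nb * bin_width_s, t1, by = bin_width_s)
  }
  bl <- protocol[protocol$kind == "baseline", ]
  ep <- protocol[protocol$label == epoch_label, ]
  be <- win(bl$t_start_s, bl$t_end_s, baseline_window_s)
  de <- win(ep$t_start_s, ep$t_end_s, drug_window_s)
  counts_in <- function(edges) {
    inside <- times >= edges[1] & times < edges[length(edges)]
    if (!any(inside)) return(rep(0, length(edges) - 1))
    hist(times[inside], breaks = edges, plot = FALSE, right = FALSE)$counts
  }
  br <- counts_in(be) / bin_width_s
  dr <- counts_in(de) / bin_width_s
  m <- mean(br); s <- sd(br)
  floor_hz <- if (is.null(sd_floor)) {
    (1 / bin_width_s) / sqrt(length(br))
  } else {
    sd_floor
  }
  sd_eff <- max(s, floor_hz)
  delta <- mean(dr) - m
  cls <- if (delta > k * sd_eff) {
    "excited"
  } else if (delta < -k * sd_eff) {
    "inhibited"
  } else {
    "not_responsive"
  }
  list(delta = delta, class = cls, baseline_mean = m, baseline_sd = s)
}

# exact two-sided Mann-Whitney p by enumerating group assignments, with U
# computed by pairwise comparison counting (not ranks)
oracle_mwu <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x); n <- length(v)
  G <- outer(v, v, function(a, b) (a > b) + 0.5 * (a == b))
  u_of <- function(S) sum(G[S, setdiff(seq_len(n), S), drop = FALSE])
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, u_of)
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# brute-force pixel-loop intensity: sum of raw values / pixel count
oracle_intensity <- function(ch, labels, roi) {
  tot <- 0; npx <- 0
  for (i in seq_len(nrow(ch))) {
    for (j in seq_len(ncol(ch))) {
      if (labels[i, j] == roi) {
        tot <- tot + ch[i, j]
        npx <- npx + 1
      }
    }
  }
  tot / npx
}

# a compact two-epoch protocol used where the full 4-concentration ramp
# would only add runtime: 600 s baseline, one 600 s drug epoch at 30 uM
short_protocol <- function() {
  application_protocol(
    label = c("baseline", "drug_30uM"),
    kind = c("baseline", "drug"),
    agent = c("none", "dopamine"),
    concentration_uM = c(0, 30),
    t_start_s = c(0, 600), t_end_s = c(600, 1200)
  )
}
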