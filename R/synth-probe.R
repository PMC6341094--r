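#' Simulate a multichannel extracellular probe recording
#'
#' Phenomenological generator for paired MUA/LFP recordings: white
#' background noise, a delta-band oscillation whose amplitude is multiplied
#' by a suppression factor during (lag-shifted) stimulation epochs, a small
#' unmodulated gamma oscillation, inhomogeneous-Poisson network bursts with
#' reduced rate in the same epochs, and tonic template spikes from a set of
#' ground-truth units. Ground-truth spike times, burst times and templates
#' are returned alongside the traces.
#'
#' Units are assigned one of three waveform families (narrow, broad,
#' triphasic); units on adjacent channel pairs appear on both channels
#' (stereotrode-like) with a fixed amplitude ratio.
#'
#' @param protocol Stimulation protocol.
#' @param truth [synth_truth()] object (delta/burst/unit fields are used).
#' @param seed Integer seed.
#' @param fs_raw Sampling rate, Hz (25 kHz in the acquisition emulated).
#' @param n_channels Number of probe channels.
#' @param duration_s Portion of the protocol to synthesise (default: whole
#'   scan). Blocks outside the window simply do not occur.
#' @return Object of class `probe_recording`: `traces` (channels x samples,
#'   microvolts), `fs`, `site`, `units` (list with `times`, `channels`,
#'   `template`, `family`), `burst_times`, `protocol`, `truth`.
#' @export
simulate_probe <- function(protocol, truth, seed, fs_raw = 25000,
                           n_channels = 4, duration_s = NULL) {
  validate_protocol(protocol)
  if (truth$delta_suppression <= 0 || truth$delta_suppression > 1)
    stop_config("delta_suppression must lie in (0, 1]")
  nyq_need <- 2 * max(truth$delta_freq_hz, truth$gamma_freq_hz)
  if (fs_raw <= nyq_need)
    stop_config("fs_raw must exceed twice the highest synthesised frequency")
  dur <- duration_s %||% protocol_span(protocol)
  n <- round(dur * fs_raw)
  t <- (seq_len(n) - 1) / fs_raw

  with_seed(seed, {
    # lag-shifted stimulation indicator on the sample grid
    stim <- rep(FALSE, n)
    for (on in protocol$block_onsets) {
      lo <- on + truth$lfp_lag_s
      hi <- on + protocol$block_duration + truth$lfp_lag_s
      stim[t >= lo & t < hi] <- TRUE
    }

    traces <- matrix(stats::rnorm(n * n_channels, 0, truth$probe_noise_sd_uv),
                     n_channels, n, byrow = TRUE)

    # delta oscillation with suppressed envelope during lagged stim epochs
    env <- truth$delta_amp_uv *
      ifelse(stim, truth$delta_suppression, 1)
    phase <- 2 * pi * truth$delta_freq_hz * t + stats::runif(1, 0, 2 * pi)
    delta <- env * sin(phase)
    gamma <- truth$gamma_amp_uv *
      sin(2 * pi * truth$gamma_freq_hz * t + stats::runif(1, 0, 2 * pi))
    field <- delta + gamma
    for (ch in seq_len(n_channels)) traces[ch, ] <- traces[ch, ] + field

    # waveform templates: 40 samples (1.6 ms at 25 kHz), trough-aligned
    tmpl_len <- max(20L, round(0.0016 * fs_raw))
    families <- c("narrow", "broad", "triphasic")
    units <- vector("list", truth$n_units)
    for (u in seq_len(truth$n_units)) {
      fam <- families[(u - 1) %% 3 + 1]
      amp <- 120 + 40 * ((u - 1) %/% 3)
      tmpl <- spike_template(fam, tmpl_len, fs_raw, amp)
      ch <- (u - 1) %% n_channels + 1
      chans <- if (n_channels > 1 && u %% 2 == 0)
        c(ch, ch %% n_channels + 1) else ch
      # tonic Poisson spikes with an enforced 2 ms refractory
      times <- poisson_train(truth$tonic_rate_hz, dur, refractory_s = 0.002)
      units[[u]] <- list(times = times, channels = chans,
                         template = tmpl, family = fam, amp = amp)
    }

    # network bursts: inhomogeneous Poisson via thinning
    burst_rate <- function(tt) {
      r <- rep(truth$burst_rate_hz, length(tt))
      for (on in protocol$block_onsets) {
        lo <- on + truth$lfp_lag_s
        hi <- on + protocol$block_duration + truth$lfp_lag_s
        r[tt >= lo & tt < hi] <- truth$burst_rate_hz * truth$burst_suppression
      }
      r
    }
    cand <- poisson_train(truth$burst_rate_hz, dur)
    keep <- stats::runif(length(cand)) < burst_rate(cand) / truth$burst_rate_hz
    burst_times <- cand[keep]
    for (bt in burst_times) {
      for (u in seq_len(truth$n_units)) {
        nk <- stats::rpois(1, truth$burst_spikes_per_unit)
        if (nk > 0) {
          extra <- sort(bt + stats::runif(nk, 0, 0.1))
          units[[u]]$times <- sort(c(units[[u]]$times, extra))
        }
      }
    }

    # stamp templates into the traces (secondary stereo channel at 60%)
    for (u in seq_len(truth$n_units)) {
      ui <- units[[u]]
      idx <- round(ui$times * fs_raw) + 1L
      idx <- idx[idx + tmpl_len - 1L <= n & idx >= 1L]
      units[[u]]$times <- (idx - 1L) / fs_raw
      for (j in seq_along(ui$channels)) {
        gain <- if (j == 1) 1 else 0.6
        for (i0 in idx) {
          rng <- i0:(i0 + tmpl_len - 1L)
          traces[ui$channels[j], rng] <- traces[ui$channels[j], rng] +
            gain * ui$template
        }
      }
    }

    structure(list(traces = traces, fs = fs_raw, site = "synthetic-site",
                   units = units, burst_times = burst_times,
                   protocol = protocol, truth = truth,
                   duration_s = dur, template_len = tmpl_len, seed = seed),
              class = "probe_recording")
  })
}

# homogeneous Poisson event train on [0, dur), optional dead time
poisson_train <- function(rate_hz, dur, refractory_s = 0) {
  n <- stats::rpois(1, rate_hz * dur)
  tt <- sort(stats::runif(n, 0, dur))
  if (refractory_s > 0 && length(tt) > 1)
    tt <- tt[c(TRUE, diff(tt) > refractory_s)]
  tt
}

# canonical extracellular waveform shapes, trough-normalised to `amp` uV
spike_template <- function(family, len, fs, amp) {
  tt <- (seq_len(len) - 1) / fs * 1000  # ms
  tc <- tt[round(len * 0.3)]            # trough position
  w <- switch(family,
    narrow    = -exp(-0.5 * ((tt - tc) / 0.08)^2) +
                 0.35 * exp(-0.5 * ((tt - tc - 0.25) / 0.15)^2),
    broad     = -exp(-0.5 * ((tt - tc) / 0.16)^2) +
                 0.45 * exp(-0.5 * ((tt - tc - 0.55) / 0.30)^2),
    triphasic =  0.3 * exp(-0.5 * ((tt - tc + 0.20) / 0.10)^2) -
                 exp(-0.5 * ((tt - tc) / 0.10)^2) +
                 0.5 * exp(-0.5 * ((tt - tc - 0.35) / 0.20)^2),
    stop_config("unknown template family: ", family))
  w / abs(min(w)) * amp   # trough depth = -amp microvolts
}

#' @export
print.probe_recording <- function(x, ...) {
  cat(sprintf("<probe_recording> %d ch x %.0f s at %g Hz, %d units, %d bursts\n",
              nrow(x$traces), x$duration_s, x$fs, length(x$units),
              length(x$burst_times)))
  invisible(x)
}

#' Ground-truth spike times pooled across units
#' @param rec A `probe_recording`.
#' @return Sorted numeric vector of seconds.
#' @export
ground_truth_spikes <- function(rec) {
  sort(unlist(lapply(rec$units, `[[`, "times"), use.names = FALSE))
}
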