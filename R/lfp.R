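#' Split a raw trace into MUA and LFP bands
#'
#' Zero-phase (forward-backward Butterworth) filtering of the raw
#' extracellular signal: the MUA trace is band-passed 0.3-3 kHz at the raw
#' rate; the LFP trace is low-pass filtered at 1.9 kHz and decimated by
#' exactly 8 (so a 25 kHz acquisition yields a 3125 Hz LFP).
#'
#' @param raw Numeric vector (one channel) or channels x samples matrix.
#' @param fs_raw Sampling rate, Hz; must support the 0.3-3 kHz MUA band.
#' @param mua_band MUA band edges, Hz.
#' @param lfp_cutoff LFP low-pass cutoff, Hz.
#' @param decimate LFP down-sampling factor.
#' @return List with `mua` (same rate as input) and `lfp`, an `lfp_trace`
#'   object (`samples`, `fs`, `provenance`).
#' @export
preprocess_traces <- function(raw, fs_raw, mua_band = c(300, 3000),
                              lfp_cutoff = 1900, decimate = 8) {
  if (fs_raw <= 2 * mua_band[2])
    stop_config("fs_raw too low for the MUA band (need > ",
                2 * mua_band[2], " Hz)")
  one <- function(x) {
    bp <- signal::butter(3, mua_band / (fs_raw / 2), type = "pass")
    mua <- signal::filtfilt(bp, x)
    # a cutoff at/above Nyquist is a no-op filter; skip it
    lfp <- if (lfp_cutoff < 0.95 * fs_raw / 2) {
      lp <- signal::butter(4, lfp_cutoff / (fs_raw / 2), type = "low")
      signal::filtfilt(lp, x)
    } else x
    list(mua = mua, lfp = lfp[seq(1, length(x), by = decimate)])
  }
  if (is.matrix(raw)) {
    res <- apply(raw, 1, one, simplify = FALSE)
    mua <- do.call(rbind, lapply(res, `[[`, "mua"))
    lfp <- do.call(rbind, lapply(res, `[[`, "lfp"))
  } else {
    res <- one(raw)
    mua <- res$mua; lfp <- res$lfp
  }
  prov <- list(
    sprintf("butterworth band-pass %g-%g Hz order 3, zero-phase", mua_band[1], mua_band[2]),
    sprintf("butterworth low-pass %g Hz order 4, zero-phase", lfp_cutoff),
    sprintf("decimated by %d: fs %g -> %g Hz", decimate, fs_raw, fs_raw / decimate))
  list(mua = mua,
       lfp = structure(list(samples = lfp, fs = fs_raw / decimate,
                            provenance = prov), class = "lfp_trace"))
}

#' @export
print.lfp_trace <- function(x, ...) {
  n <- if (is.matrix(x$samples)) ncol(x$samples) else length(x$samples)
  cat(sprintf("<lfp_trace> %.1f s at %g Hz\n", n / x$fs, x$fs))
  invisible(x)
}

#' Complex Morlet wavelet amplitude spectrum
#'
#' Continuous wavelet transform with a complex Morlet wavelet of
#' `n_cycles` cycles (FFT-based convolution per frequency). Amplitudes are
#' normalised so that a pure sinusoid of amplitude A produces a ridge of
#' amplitude ~A at its frequency. Traces above `max_analysis_fs` are
#' anti-alias decimated first (all analysis frequencies sit far below that
#' rate), keeping long recordings tractable.
#'
#' @param lfp `lfp_trace` object, or numeric vector with `fs` given.
#' @param frequencies Analysis frequencies, Hz (default 40 log-spaced
#'   points, 0.5-100 Hz); all must lie in (0, fs/2).
#' @param fs Sampling rate when `lfp` is a bare vector.
#' @param n_cycles Morlet width in cycles.
#' @param max_analysis_fs Internal analysis rate cap, Hz.
#' @return Object of class `wavelet_spectrum`: `amplitude` (freq x time),
#'   `frequencies`, `times` (s), `fs`, `units = "raw"`.
#' @export
wavelet_amplitude <- function(lfp, frequencies = NULL, fs = NULL,
                              n_cycles = 6, max_analysis_fs = 500) {
  x <- if (inherits(lfp, "lfp_trace")) lfp$samples else lfp
  if (is.matrix(x)) x <- colMeans(x)   # average recording sites
  fs <- if (inherits(lfp, "lfp_trace")) lfp$fs else fs
  if (is.null(fs)) stop_config("fs required when lfp is a bare vector")
  frequencies <- frequencies %||% exp(seq(log(0.5), log(100), length.out = 40))
  if (any(frequencies <= 0 | frequencies >= fs / 2))
    stop_config("frequencies must lie in (0, fs/2)")
  x <- x - mean(x)   # a DC offset carries no band-limited amplitude
  dec <- max(1L, floor(fs / max_analysis_fs))
  if (dec > 1) {
    if (max(frequencies) >= fs / dec / 2)
      dec <- max(1L, floor(fs / (4 * max(frequencies))))
    if (dec > 1) {
      lpf <- signal::butter(4, 0.8 / dec, type = "low")
      x <- signal::filtfilt(lpf, x)[seq(1, length(x), by = dec)]
      fs <- fs / dec
    }
  }
  n <- length(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  amp <- matrix(0, length(frequencies), n)
  ke <- numeric(length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    sd_t <- n_cycles / (2 * pi * f)
    half <- min(ceiling(4 * sd_t * fs), floor((nfft - 1) / 2))
    tt <- (-half:half) / fs
    env <- exp(-tt^2 / (2 * sd_t^2))
    w <- env * exp(2i * pi * f * tt)
    w <- w * (2 / sum(env))             # sinusoid amplitude A -> ridge ~A
    ke[i] <- sum(Mod(w)^2)              # white-noise response variance / sigma^2
    wf <- c(w[(half + 1):(2 * half + 1)], complex(real = numeric(nfft - (2 * half + 1))),
            w[1:half])
    conv <- stats::fft(X * stats::fft(wf), inverse = TRUE) / nfft
    amp[i, ] <- Mod(conv[seq_len(n)])
  }
  structure(list(amplitude = amp, frequencies = frequencies,
                 times = (seq_len(n) - 1) / fs, fs = fs, units = "raw",
                 kernel_energy = ke),
            class = "wavelet_spectrum")
}

#' @export
print.wavelet_spectrum <- function(x, ...) {
  cat(sprintf("<wavelet_spectrum> %d freqs (%.3g-%.3g Hz) x %d times, units=%s\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times), x$units))
  invisible(x)
}

#' Trial-averaged, baseline-z-scored spectrum
#'
#' Epochs the amplitude spectrum around each block onset, averages across
#' trials, and z-scores each frequency row against the pre-onset baseline
#' window (per-frequency mean and sd).
#'
#' @param spectrum `wavelet_spectrum` (raw units).
#' @param protocol Stimulation protocol.
#' @param baseline_s Pre-onset baseline length, seconds; the window
#'   `[-baseline_s, 0)` must not overlap the previous block's stimulation.
#' @param post_s Epoch length after onset (default: one inter-onset period
#'   minus the baseline).
#' @return `wavelet_spectrum` with `units = "z"` and `times` relative to
#'   block onset.
#' @export
trial_average_z <- function(spectrum, protocol, baseline_s = 10,
                            post_s = NULL) {
  post_s <- post_s %||% (protocol$inter_onset - baseline_s)
  on_prev_end <- protocol$block_onsets - c(Inf, diff(protocol$block_onsets)) +
    protocol$block_duration
  if (any(protocol$block_onsets - baseline_s < on_prev_end))
    stop_config("baseline window overlaps the previous stimulation block")
  dt <- spectrum$times[2] - spectrum$times[1]
  rel <- seq(-baseline_s, post_s - dt, by = dt)
  acc <- NULL
  n_tr <- 0
  for (on in protocol$block_onsets) {
    idx <- round((on + rel - spectrum$times[1]) / dt) + 1L
    if (min(idx) < 1 || max(idx) > length(spectrum$times)) next
    seg <- spectrum$amplitude[, idx, drop = FALSE]
    acc <- if (is.null(acc)) seg else acc + seg
    n_tr <- n_tr + 1
  }
  if (n_tr == 0) stop_config("no trial window lies within the spectrum span")
  avg <- acc / n_tr
  base_cols <- which(rel < 0)
  mu <- rowMeans(avg[, base_cols, drop = FALSE])
  sdv <- apply(avg[, base_cols, drop = FALSE], 1, stats::sd)
  sdv[sdv == 0] <- NA_real_
  z <- sweep(sweep(avg, 1, mu), 1, sdv, `/`)
  structure(list(amplitude = z, frequencies = spectrum$frequencies,
                 times = rel, fs = spectrum$fs, units = "z",
                 n_trials = n_tr), class = "wavelet_spectrum")
}

# stimulation / baseline masks over a time axis, excluding `transition_s`
# after the start of each epoch (stim epochs and baseline epochs alike)
epoch_masks <- function(times, protocol, transition_s) {
  stim <- rep(FALSE, length(times))
  excl <- rep(FALSE, length(times))
  for (on in protocol$block_onsets) {
    off <- on + protocol$block_duration
    stim[times >= on & times < off] <- TRUE
    excl[times >= on & times < min(on + transition_s, off)] <- TRUE
    excl[times >= off & times < off + transition_s] <- TRUE
  }
  list(stim = stim & !excl, base = !stim & !excl)
}

#' Fractional band-power change under stimulation
#'
#' Mean band power (amplitude squared, or amplitude with
#' `measure = "amplitude"`) over stimulation epochs minus the baseline
#' mean, divided by the baseline mean. The first `transition_s` seconds of
#' every epoch (stimulation epochs and the post-offset baseline epochs)
#' are excluded, reflecting the ~5 s lag of LFP power changes.
#'
#' @param spectrum `wavelet_spectrum` in raw units.
#' @param protocol Stimulation protocol.
#' @param band Two-element band edges, Hz (e.g. delta `c(1, 4)`).
#' @param transition_s Transition exclusion, seconds.
#' @param measure `"power"` (default) or `"amplitude"`.
#' @return List: `fractional_change`, `stim_mean`, `base_mean`, `band`,
#'   `measure`.
#' @export
fractional_band_change <- function(spectrum, protocol, band,
                                   transition_s = 5,
                                   measure = c("power", "amplitude")) {
  measure <- match.arg(measure)
  if (spectrum$units != "raw")
    stop_config("fractional change is defined on the raw amplitude spectrum")
  rows <- which(spectrum$frequencies >= band[1] & spectrum$frequencies <= band[2])
  if (!length(rows)) stop_config("band lies outside the frequency grid")
  a <- spectrum$amplitude[rows, , drop = FALSE]
  pow <- colMeans(if (measure == "power") a^2 else a)
  m <- epoch_masks(spectrum$times, protocol, transition_s)
  if (!any(m$stim) || !any(m$base))
    stop_config("no stimulation or baseline samples remain after exclusion")
  sm <- mean(pow[m$stim]); bm <- mean(pow[m$base])
  list(fractional_change = (sm - bm) / bm, stim_mean = sm, base_mean = bm,
       band = band, measure = measure, transition_s = transition_s)
}

#' Network-burst detection and stimulus-locked burst statistics
#'
#' Population spike counts are binned at `bin_s`; a burst is a maximal run
#' of bins exceeding `thresh_mult` times the median baseline bin count,
#' with runs separated by less than `merge_gap_s` merged. Burst rates are
#' computed for stimulation and baseline epochs (with the same transition
#' exclusion as band power) and summarised as a fractional change.
#'
#' @param spike_times Pooled spike times, seconds (e.g. all events from
#'   [detect_spikes()] across channels, or generator ground truth).
#' @param protocol Stimulation protocol; must contain stimulation blocks.
#' @param bin_s Bin width, seconds.
#' @param thresh_mult Burst threshold as a multiple of the median baseline
#'   bin count.
#' @param merge_gap_s Maximum gap between merged burst runs, seconds.
#' @param transition_s Transition exclusion, seconds.
#' @param duration_s Recording span (default: protocol span).
#' @return List: `burst_times` (run centres, s), `stim_rate_hz`,
#'   `base_rate_hz`, `fractional_change`, `threshold_count`.
#' @export
burst_statistics <- function(spike_times, protocol, bin_s = 0.1,
                             thresh_mult = 3, merge_gap_s = 0.2,
                             transition_s = 5, duration_s = NULL) {
  if (!length(protocol$block_onsets))
    stop_config("protocol contains no stimulation blocks")
  dur <- duration_s %||% protocol_span(protocol)
  breaks <- seq(0, dur + bin_s, by = bin_s)
  counts <- tabulate(findInterval(spike_times, breaks,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  centers <- breaks[-length(breaks)] + bin_s / 2
  m <- epoch_masks(centers, protocol, transition_s)
  med_base <- stats::median(counts[m$base])
  thr <- thresh_mult * med_base
  above <- counts > thr
  # merge runs separated by < merge_gap_s
  gap_bins <- ceiling(merge_gap_s / bin_s)
  r <- rle(above)
  if (length(r$lengths) > 2) {
    for (i in seq_along(r$values)) {
      if (!r$values[i] && i > 1 && i < length(r$values) &&
          r$lengths[i] < gap_bins)
        r$values[i] <- TRUE
    }
  }
  above <- inverse.rle(r)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  bi <- which(runs$values)
  burst_times <- (centers[starts[bi]] + centers[ends[bi]]) / 2
  if (!length(burst_times) || !any(m$base))
    stop_config("no baseline bursts detected; burst fraction undefined - ",
                "lower thresh_mult or check the spike input")
  in_mask <- function(mask) {
    idx <- round((burst_times - centers[1]) / bin_s) + 1L
    ok <- idx >= 1 & idx <= length(mask)
    sum(mask[idx[ok]])
  }
  t_stim <- sum(m$stim) * bin_s
  t_base <- sum(m$base) * bin_s
  stim_rate <- in_mask(m$stim) / t_stim
  base_rate <- in_mask(m$base) / t_base
  if (base_rate == 0)
    stop_config("zero baseline burst rate; fractional change undefined - ",
                "record a longer baseline or lower thresh_mult")
  list(burst_times = burst_times, stim_rate_hz = stim_rate,
       base_rate_hz = base_rate,
       fractional_change = (stim_rate - base_rate) / base_rate,
       threshold_count = thr)
}
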