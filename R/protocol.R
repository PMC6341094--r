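#' Photostimulation block protocols
#'
#' Construct the stimulation/acquisition protocol shared by every pipeline
#' stage: the short-block paradigm (6 blocks of 20 s ON / 40 s OFF, 12 min
#' scan) or the long-block paradigm (20 s ON / 160 s OFF, 24 min scan).
#' Light trains are 20 Hz with 5 ms pulses; one fMRI volume every 2 s, so a
#' 20 s block spans exactly 10 volumes. A 60 s lead-in baseline precedes the
#' first block so that percent-change normalisation has at least 30 baseline
#' volumes.
#'
#' @param kind `"short"` or `"long"`.
#' @param lead_in_s Baseline before the first block onset, seconds.
#' @return An object of class `stim_protocol`: a list with fields
#'   `block_onsets` (s), `block_duration` (s), `inter_onset` (s),
#'   `pulse_rate` (Hz), `pulse_width_ms`, `volume_interval` (s),
#'   `n_volumes`, and `kind`.
#' @examples
#' p <- make_protocol("short")
#' p$block_duration / p$volume_interval   # 10 volumes per block
#' @export
make_protocol <- function(kind = c("short", "long"), lead_in_s = 60) {
  if (!is.character(kind) || !kind[1] %in% c("short", "long"))
    stop_config("unknown protocol kind: ", deparse(kind[1]),
                " (expected \"short\" or \"long\")")
  kind <- kind[1]
  inter <- if (kind == "short") 60 else 180
  n_vol <- if (kind == "short") 360L else 720L
  proto <- structure(list(
    kind            = kind,
    block_onsets    = lead_in_s + (0:5) * inter,
    block_duration  = 20,
    inter_onset     = inter,
    pulse_rate      = 20,
    pulse_width_ms  = 5,
    volume_interval = 2,
    n_volumes       = n_vol
  ), class = "stim_protocol")
  validate_protocol(proto)
  proto
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (any(diff(p$block_onsets) <= 0))
    stop_config("block onsets must be strictly increasing")
  span <- p$n_volumes * p$volume_interval
  if (any(p$block_onsets < 0) || any(p$block_onsets + p$block_duration > span))
    stop_config("stimulation blocks must lie inside the scan span")
  if (abs(p$block_duration / p$volume_interval -
          round(p$block_duration / p$volume_interval)) > 1e-9)
    stop_config("block duration must be an integer number of volumes")
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol '%s'> %d blocks of %g s ON / %g s OFF, %g Hz %g ms pulses\n",
    x$kind, length(x$block_onsets), x$block_duration,
    x$inter_onset - x$block_duration, x$pulse_rate, x$pulse_width_ms))
  cat(sprintf("  %d volumes every %g s (%.1f min); first onset %g s\n",
              x$n_volumes, x$volume_interval,
              x$n_volumes * x$volume_interval / 60, x$block_onsets[1]))
  invisible(x)
}

# seconds covered by the scan
protocol_span <- function(p) p$n_volumes * p$volume_interval

# boxcar indicator of stimulation sampled at dt, optionally lagged
protocol_boxcar <- function(p, dt, lag_s = 0) {
  t <- seq(0, protocol_span(p) - dt, by = dt)
  box <- numeric(length(t))
  for (on in p$block_onsets) {
    box[t >= on + lag_s & t < on + p$block_duration + lag_s] <- 1
  }
  list(time = t, box = box)
}

# volume indices (1-based) falling inside any stimulation block, with an
# optional tail to cover the hemodynamic return to baseline
stim_volumes <- function(p, tail_s = 0) {
  t <- (seq_len(p$n_volumes) - 1) * p$volume_interval
  idx <- rep(FALSE, p$n_volumes)
  for (on in p$block_onsets)
    idx <- idx | (t >= on & t < on + p$block_duration + tail_s)
  which(idx)
}
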