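#' Generator ground truth
#'
#' Assemble the ground-truth parameter set that drives every synthetic
#' generator: the per-ROI, per-block response amplitude schedule, response
#' signs, the HRF, contrast-agent clearance drift, noise level, LFP/burst
#' modulation, electro-vascular coupling targets and structure-function r^2
#' targets. Named presets encode the study conditions each synthetic
#' experiment emulates.
#'
#' Presets:
#' \describe{
#'   \item{`control`}{Flat 2% projection-area responses (negative-going),
#'     +1.5% DRN response; noise sd 0.3% per volume; between-subject
#'     amplitude variability 10%.}
#'   \item{`adaptation_short`}{Projection-area block amplitudes decline
#'     linearly from 2.6% (block 1) to 1.7% (block 6); DRN flat; noise sd
#'     0.3%; no between-subject variability (the adaptation recovery
#'     experiment is defined at the volume-noise level only).}
#'   \item{`restraint`}{As control with every amplitude scaled by 0.5 in all
#'     scans (globally blunted response, connectivity pattern preserved).}
#'   \item{`fluoxetine`}{As control; in post-drug scans (2 and 3) the
#'     response amplitude of prefrontal/cingulate/amygdala/striatal ROIs is
#'     scaled by 1.5.}
#' }
#'
#' @param preset Preset name (see Details).
#' @param atlas Atlas list from [default_atlas()].
#' @param hrf HRF from [gamma_hrf()]; shared with the fitting side.
#' @param ... Named overrides of any truth field.
#' @return Object of class `synth_truth`.
#' @export
synth_truth <- function(preset = c("control", "adaptation_short",
                                   "restraint", "fluoxetine"),
                        atlas = default_atlas(), hrf = gamma_hrf(), ...) {
  preset <- match.arg(preset)
  labels <- atlas$labels
  n_blocks <- 6L
  sign <- stats::setNames(rep(-1, length(labels)), labels)
  if ("DRN" %in% labels) sign["DRN"] <- 1

  # % amplitude magnitude per block (rows) per ROI (cols)
  amp <- matrix(2.0, n_blocks, length(labels), dimnames = list(NULL, labels))
  if ("DRN" %in% labels) amp[, "DRN"] <- 1.5

  tr <- list(
    preset            = preset,
    roi_labels        = labels,
    sign              = sign,
    amplitude_schedule = amp,          # % per block, magnitude
    scan_amp_scale    = rep(1, 3),     # per-scan multiplier (session of 3)
    scan_scale_rois   = labels,        # ROIs the per-scan multiplier targets
    hrf               = hrf,
    drift_pct_per_min = -0.1,          # iron-oxide clearance drift
    noise_sd_pct      = 0.3,
    subject_amp_sd    = 0.1,           # lognormal sd of subject amplitude
    baseline_au       = 1000,          # raw scanner units
    ar1               = 0,             # optional AR(1) noise coefficient
    # electrophysiology
    lfp_lag_s         = 5,
    delta_freq_hz     = 2.2,
    delta_amp_uv      = 60,
    delta_suppression = 0.5,           # amplitude multiplier during stim
    gamma_freq_hz     = 55,
    gamma_amp_uv      = 8,
    burst_rate_hz     = 0.4,
    burst_suppression = 0.5,           # rate multiplier during stim
    burst_spikes_per_unit = 6,
    tonic_rate_hz     = 10,            # per unit
    probe_noise_sd_uv = 8,
    n_units           = 6,
    # calibration targets
    coupling_targets  = c(delta = 0.75, gamma = 0.24, MUA = -0.1),
    regional_targets  = c(delta_power = 0.69, burst_frequency = 0.78),
    sf_r2_targets     = c(projection = 0, HTR1F = 0.526,
                          HTR2A = 0.212, HTR2C = 0.308)
  )

  if (preset == "adaptation_short") {
    decl <- seq(2.6, 1.7, length.out = n_blocks)
    for (l in labels) if (l != "DRN") tr$amplitude_schedule[, l] <- decl
    tr$subject_amp_sd <- 0
  } else if (preset == "restraint") {
    tr$amplitude_schedule <- tr$amplitude_schedule * 0.5
  } else if (preset == "fluoxetine") {
    tr$scan_amp_scale <- c(1, 1.5, 1.5)
    tr$scan_scale_rois <- intersect(c("mPFC", "ACA", "BLA", "CP"), labels)
  }

  dots <- list(...)
  unknown <- setdiff(names(dots), names(tr))
  if (length(unknown))
    stop_config("unknown truth field(s): ", paste(unknown, collapse = ", "))
  tr[names(dots)] <- dots
  validate_truth(tr, n_blocks)
  structure(tr, class = "synth_truth")
}

validate_truth <- function(tr, n_blocks) {
  if (nrow(tr$amplitude_schedule) != n_blocks)
    stop_config("amplitude schedule must have one row per block")
  if (any(abs(tr$coupling_targets) > 1))
    stop_config("coupling targets must have |r| <= 1")
  if (any(tr$sf_r2_targets < 0 | tr$sf_r2_targets > 1))
    stop_config("r^2 targets must lie in [0, 1]")
  if (tr$delta_suppression <= 0 || tr$delta_suppression > 1)
    stop_config("delta_suppression must lie in (0, 1]")
  if (tr$burst_suppression <= 0 || tr$burst_suppression > 1)
    stop_config("burst_suppression must lie in (0, 1]")
  invisible(tr)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth '%s'> %d ROIs, blocks x ROI schedule %.2g-%.2g%%\n",
              x$preset, length(x$roi_labels),
              min(x$amplitude_schedule), max(x$amplitude_schedule)))
  cat(sprintf("  noise %.2g%%, drift %.2g%%/min, subject amp sd %.2g\n",
              x$noise_sd_pct, x$drift_pct_per_min, x$subject_amp_sd))
  invisible(x)
}
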