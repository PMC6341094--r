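#' Simulate a CBV ofMRI cohort
#'
#' Generate raw ROI-by-time scanner signals for a cohort of synthetic
#' subjects under an intravascular iron-oxide contrast acquisition. The raw
#' per-ROI signal is
#' `baseline * (1 + drift*t) * (1 - signed_response(t)/100) + noise`,
#' where the signed response is the per-block boxcar convolved with the
#' shared gamma HRF and scaled by the ground-truth amplitude schedule. A CBV
#' increase therefore lowers the raw signal, so the preprocessing stage's
#' sign-inversion step is exercised, never bypassed.
#'
#' @param protocol A [make_protocol()] object.
#' @param truth A [synth_truth()] object consistent with the protocol.
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; identical `(arguments, seed)` give
#'   bit-identical cohorts.
#' @param n_scans Scans per session (3 in the study design).
#' @return Object of class `synth_cohort`: `subjects` data frame
#'   (`id`, `sex`, `condition`), `scans[[subject]][[scan]]` raw matrices
#'   (volumes x ROI), `scan_truth[[subject]][[scan]]` the injected amplitude
#'   matrices (% with sign), plus `protocol` and `truth`.
#' @export
simulate_cbv_cohort <- function(protocol, truth, n_subjects, seed, n_scans = 3) {
  validate_protocol(protocol)
  if (nrow(truth$amplitude_schedule) != length(protocol$block_onsets))
    stop_config("amplitude schedule length does not match protocol blocks")
  if (length(truth$scan_amp_scale) < n_scans)
    stop_config("truth$scan_amp_scale shorter than n_scans")
  with_seed(seed, {
    labels <- truth$roi_labels
    reg <- block_regressors(protocol, truth$hrf)   # volumes x blocks
    t_min <- (seq_len(protocol$n_volumes) - 1) * protocol$volume_interval / 60
    subjects <- data.frame(
      id = sprintf("sub-%02d", seq_len(n_subjects)),
      sex = rep(c("F", "M"), length.out = n_subjects),
      condition = truth$preset,
      stringsAsFactors = FALSE)
    scans <- vector("list", n_subjects)
    scan_truth <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      subj_scale <- if (truth$subject_amp_sd > 0)
        exp(stats::rnorm(1, 0, truth$subject_amp_sd)) else 1
      scans[[s]] <- vector("list", n_scans)
      scan_truth[[s]] <- vector("list", n_scans)
      for (k in seq_len(n_scans)) {
        amp <- truth$amplitude_schedule * subj_scale
        sc_rois <- intersect(truth$scan_scale_rois, labels)
        amp[, sc_rois] <- amp[, sc_rois] * truth$scan_amp_scale[k]
        signed <- sweep(amp, 2, truth$sign[labels], `*`)
        resp <- reg %*% signed                       # volumes x ROI, %
        drift <- 1 + truth$drift_pct_per_min / 100 * t_min
        raw <- truth$baseline_au * drift * (1 - resp / 100)
        if (truth$noise_sd_pct > 0) {
          e <- matrix(stats::rnorm(length(raw), 0,
                                   truth$noise_sd_pct / 100 * truth$baseline_au),
                      nrow(raw), ncol(raw))
          if (truth$ar1 > 0) e <- apply(e, 2, function(v)
            as.numeric(stats::filter(v, truth$ar1, method = "recursive")))
          raw <- raw + e
        }
        colnames(raw) <- labels
        scans[[s]][[k]] <- raw
        scan_truth[[s]][[k]] <- signed
      }
    }
    structure(list(subjects = subjects, scans = scans, scan_truth = scan_truth,
                   protocol = protocol, truth = truth, seed = seed),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort '%s'> %d subjects x %d scans, %d ROIs x %d volumes\n",
              x$truth$preset, nrow(x$subjects), length(x$scans[[1]]),
              length(x$truth$roi_labels), x$protocol$n_volumes))
  invisible(x)
}
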