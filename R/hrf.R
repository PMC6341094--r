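#' Gamma hemodynamic response function
#'
#' Single-gamma HRF kernel for CBV-weighted rodent fMRI. The default
#' (shape 6, scale 0.6 s, no onset delay) peaks at (shape-1)*scale = 3 s,
#' consistent with the fast cerebral-blood-volume response reported for
#' awake/sedated rodents. The kernel is peak-normalised to 1 so that a
#' regression coefficient against a peak-normalised regressor reads directly
#' in percent signal change.
#'
#' @param shape Gamma shape parameter (dimensionless, > 1).
#' @param scale Gamma scale parameter, seconds.
#' @param delay Pure onset delay, seconds.
#' @param duration_s Kernel support, seconds.
#' @return Object of class `hrf_model` with `$shape`, `$scale`, `$delay`,
#'   `$duration_s`, and `$kernel(dt)` — a function returning the sampled,
#'   peak-normalised kernel at sampling step `dt` seconds.
#' @examples
#' h <- gamma_hrf()
#' k <- h$kernel(0.1)
#' (which.max(k) - 1) * 0.1   # time-to-peak ~ 3 s
#' @export
gamma_hrf <- function(shape = 6, scale = 0.6, delay = 0, duration_s = 16) {
  if (shape <= 1 || scale <= 0) stop_config("hrf shape must be > 1 and scale > 0")
  structure(list(
    shape = shape, scale = scale, delay = delay, duration_s = duration_s,
    kernel = function(dt) {
      t <- seq(0, duration_s, by = dt)
      k <- stats::dgamma(pmax(t - delay, 0), shape = shape, scale = scale)
      k / max(k)
    }
  ), class = "hrf_model")
}

#' @export
print.hrf_model <- function(x, ...) {
  cat(sprintf("<hrf_model> gamma(shape=%g, scale=%g s), delay %g s, peak at %g s\n",
              x$shape, x$scale, x$delay, x$delay + (x$shape - 1) * x$scale))
  invisible(x)
}

# Convolve a finely sampled input with the HRF and bin-average onto the
# volume grid. Shared by the synthetic generator, the GLM design builder and
# the electro-vascular coupling regressor so that all three live on exactly
# the same kernel (recovery on matched data is then an OLS identity).
convolve_to_grid <- function(x, dt, hrf, volume_interval, n_volumes) {
  k <- hrf$kernel(dt)
  y <- stats::convolve(x, rev(k), type = "open")[seq_along(x)] * dt
  per_vol <- round(volume_interval / dt)
  if (abs(per_vol - volume_interval / dt) > 1e-8)
    stop_config("volume_interval must be a multiple of dt")
  n_need <- per_vol * n_volumes
  if (length(y) < n_need) y <- c(y, numeric(n_need - length(y)))
  colMeans(matrix(y[seq_len(n_need)], nrow = per_vol))
}

# Per-block peak-normalised response regressors on the volume grid.
# Column b is the HRF-convolved boxcar of block b alone; all columns share
# one normalisation constant (the peak of a single convolved block) so a
# coefficient of 1 corresponds to a 1% peak response in every block.
block_regressors <- function(protocol, hrf, dt = 0.1) {
  p <- protocol
  nb <- length(p$block_onsets)
  t <- seq(0, protocol_span(p) - dt, by = dt)
  cols <- vapply(seq_len(nb), function(b) {
    box <- as.numeric(t >= p$block_onsets[b] & t < p$block_onsets[b] + p$block_duration)
    convolve_to_grid(box, dt, hrf, p$volume_interval, p$n_volumes)
  }, numeric(p$n_volumes))
  peak <- max(cols)
  if (peak <= 0) stop_config("degenerate protocol: zero response regressor")
  cols / peak
}
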