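#' HRF-convolved regressor on the fMRI volume grid
#'
#' Convolves a finely sampled electrophysiological series (band-power
#' envelope or MUA rate) with the gamma HRF and bin-averages it onto the
#' fMRI volume grid, using exactly the same kernel machinery as the GLM
#' design builder — a boxcar input therefore reproduces the GLM activity
#' regressor.
#'
#' @param x Numeric series sampled at `fs_in` Hz.
#' @param fs_in Input sampling rate, Hz; must be finer than the volume grid
#'   and divide it evenly.
#' @param hrf HRF model.
#' @param volume_interval fMRI volume spacing, seconds.
#' @param n_volumes Expected length on the volume grid; the input duration
#'   must match within one volume.
#' @param normalize Peak-normalise the output (as GLM regressors are).
#' @return Numeric vector of length `n_volumes`.
#' @export
convolved_regressor <- function(x, fs_in, hrf, volume_interval, n_volumes,
                                normalize = TRUE) {
  dt <- 1 / fs_in
  if (dt >= volume_interval)
    stop_config("input sampling must be finer than the volume interval")
  dur_in <- length(x) * dt
  dur_out <- n_volumes * volume_interval
  if (abs(dur_in - dur_out) > volume_interval)
    stop_config("series duration differs from the fMRI run by more than one volume")
  if (length(x) < n_volumes * round(volume_interval / dt))
    x <- c(x, rep(x[length(x)], n_volumes * round(volume_interval / dt) - length(x)))
  y <- convolve_to_grid(x, dt, hrf, volume_interval, n_volumes)
  if (normalize && max(abs(y)) > 0) y <- y / max(abs(y))
  y
}

#' Site-level electro-vascular coupling
#'
#' Pearson correlation between an HRF-convolved electrophysiological
#' regressor and the (preprocessed) CBV series of the same site, excluding
#' the convolution burn-in volumes.
#'
#' @param regressor Regressor on the volume grid ([convolved_regressor()]).
#' @param cbv CBV series, same length.
#' @param kind Signal kind label (`"delta"`, `"gamma"`, `"MUA"`).
#' @param site,animal,roi Identifiers carried into the record.
#' @param burn_in_volumes Leading volumes excluded (HRF kernel length).
#' @return Object of class `coupling_record`: `site`, `animal`, `roi`,
#'   `kind`, `r`, `p`, `n`.
#' @export
site_coupling <- function(regressor, cbv, kind = "delta", site = NA,
                          animal = NA, roi = NA, burn_in_volumes = 8) {
  if (length(regressor) != length(cbv))
    stop_config("regressor and CBV series must have equal length")
  keep <- seq_along(cbv) > burn_in_volumes
  if (sum(keep) < 3) stop_config("need >= 3 volumes after burn-in")
  ct <- stats::cor.test(regressor[keep], cbv[keep])
  structure(list(site = site, animal = animal, roi = roi, kind = kind,
                 r = unname(ct$estimate), p = ct$p.value, n = sum(keep)),
            class = "coupling_record")
}

#' @export
print.coupling_record <- function(x, ...) {
  cat(sprintf("<coupling_record> %s %s/%s: r = %.3f (p = %.3g, n = %d)\n",
              x$kind, x$animal, x$roi, x$r, x$p, x$n))
  invisible(x)
}

#' Coupling across the sites of a `coupled_sites` generator object
#'
#' Convenience wrapper: builds the convolved band-power regressor for every
#' site and returns one [site_coupling()] record each.
#'
#' @param cs `coupled_sites` object.
#' @param hrf HRF model (the generator's by default).
#' @param kind Signal kind label.
#' @return Data frame: `site`, `animal`, `roi`, `kind`, `r`, `p`, `n`.
#' @export
couple_sites <- function(cs, hrf = cs$truth$hrf, kind = "delta") {
  rows <- lapply(cs$sites, function(s) {
    reg <- convolved_regressor(s$power, s$env_fs, hrf,
                               cs$protocol$volume_interval,
                               cs$protocol$n_volumes)
    rec <- site_coupling(reg, s$cbv, kind = kind, site = s$site,
                         animal = s$animal, roi = s$roi,
                         burn_in_volumes = cs$burn_in_volumes)
    data.frame(site = rec$site, animal = rec$animal, roi = rec$roi,
               kind = rec$kind, r = rec$r, p = rec$p, n = rec$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regional coupling: fractional ephys metric vs COPE across matched sites
#'
#' Pearson correlation across recording sites between a fractional
#' electrophysiological change (delta power or burst frequency) and the
#' hemodynamic COPE of the same `(animal, ROI)` pair. Pairing is strict;
#' unmatched sites are dropped with a warning.
#'
#' @param metrics Data frame `animal`, `roi`, `metric`.
#' @param copes Data frame `animal`, `roi`, `cope`.
#' @return Object of class `regional_coupling`: `r`, `p`, `n`, `pairs`
#'   (the matched data), `dropped`.
#' @export
regional_coupling <- function(metrics, copes) {
  need <- function(df, cols, nm)
    if (!all(cols %in% names(df)))
      stop_config(nm, " must have columns ", paste(cols, collapse = ", "))
  need(metrics, c("animal", "roi", "metric"), "metrics")
  need(copes, c("animal", "roi", "cope"), "copes")
  m <- merge(metrics, copes, by = c("animal", "roi"))
  dropped <- nrow(metrics) - nrow(m)
  if (dropped > 0)
    warning(dropped, " site(s) without a matched (animal, ROI) COPE dropped")
  if (nrow(m) < 3) stop_config("fewer than 3 matched (animal, ROI) pairs")
  ct <- stats::cor.test(m$metric, m$cope)
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
                 pairs = m, dropped = dropped),
            class = "regional_coupling")
}

#' @export
print.regional_coupling <- function(x, ...) {
  cat(sprintf("<regional_coupling> r = %.3f (p = %.3g) over %d matched sites\n",
              x$r, x$p, x$n))
  invisible(x)
}
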