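#' Simulate site-paired band-power / CBV recordings with a target coupling
#'
#' For each synthetic recording site, generate (i) a delta-band LFP power
#' envelope sampled at `env_fs` Hz — baseline power suppressed during
#' lag-shifted stimulation epochs, plus smooth envelope noise — and (ii) a
#' CBV time series on the fMRI volume grid constructed as a scaled copy of
#' the HRF-convolved envelope plus white noise whose variance is set
#' analytically so that the population correlation between the convolved
#' regressor and the CBV series (over the analysed volumes, excluding the
#' convolution burn-in) equals `target_r`.
#'
#' @param protocol Stimulation protocol.
#' @param truth [synth_truth()] object (lag, suppression, HRF are used).
#' @param n_sites Number of site-paired recordings.
#' @param target_r Population Pearson r between convolved power and CBV.
#' @param seed Integer seed.
#' @param env_fs Envelope sampling rate, Hz.
#' @param burn_in_volumes Volumes excluded from the coupling analysis
#'   (convolution burn-in); must match the coupling stage's setting.
#' @return Object of class `coupled_sites`: per-site list with `power`
#'   (envelope series), `env_fs`, `cbv` (volume series), `site`, `animal`,
#'   `roi`; plus `target_r` and `protocol`.
#' @export
simulate_coupled_sites <- function(protocol, truth, n_sites = 8,
                                   target_r = 0.75, seed = 7,
                                   env_fs = 10, burn_in_volumes = 8) {
  validate_protocol(protocol)
  if (abs(target_r) > 1) stop_config("|target_r| must be <= 1")
  with_seed(seed, {
    dt <- 1 / env_fs
    bx <- protocol_boxcar(protocol, dt, lag_s = truth$lfp_lag_s)
    base_pow <- truth$delta_amp_uv^2 / 2
    supp_pow <- base_pow * truth$delta_suppression^2
    sites <- vector("list", n_sites)
    rois <- c("mPFC", "ACA", "MOs", "SSp", "RSP", "VIS", "PTLp", "AUD")
    for (s in seq_len(n_sites)) {
      env <- ifelse(bx$box > 0, supp_pow, base_pow)
      # smooth multiplicative envelope noise (moving-average smoothed)
      e <- stats::rnorm(length(env), 0, 0.15)
      e <- stats::filter(e, rep(1 / 21, 21), sides = 2)
      e[is.na(e)] <- 0
      power <- env * (1 + as.numeric(e))
      x <- convolved_regressor(power, env_fs, truth$hrf,
                               protocol$volume_interval, protocol$n_volumes)
      keep <- seq_len(protocol$n_volumes) > burn_in_volumes
      xs <- x - mean(x[keep])
      amp <- 2                                  # % CBV scale
      alpha <- amp / max(abs(xs))
      sd_x <- stats::sd(xs[keep])
      sd_e <- if (abs(target_r) < 1)
        abs(alpha) * sd_x * sqrt(1 / target_r^2 - 1) else 0
      cbv <- sign(target_r) * alpha * xs +
        stats::rnorm(protocol$n_volumes, 0, sd_e)
      sites[[s]] <- list(power = power, env_fs = env_fs, cbv = cbv,
                         site = sprintf("site-%02d", s),
                         animal = sprintf("m%02d", (s - 1) %/% 2 + 1),
                         roi = rois[(s - 1) %% length(rois) + 1])
    }
    structure(list(sites = sites, target_r = target_r, protocol = protocol,
                   truth = truth, burn_in_volumes = burn_in_volumes,
                   seed = seed),
              class = "coupled_sites")
  })
}

#' Simulate animal- and ROI-matched site pairs with a target correlation
#'
#' Draw `(fractional metric, COPE)` pairs for matched recording sites from a
#' bivariate normal model whose population correlation equals `target_r`.
#' Used for the regional electro-vascular comparisons (fractional delta
#' power or fractional burst-frequency change against the site's COPE).
#'
#' @param n_sites Number of matched sites.
#' @param target_r Population Pearson correlation.
#' @param seed Integer seed.
#' @param metric_mean,metric_sd Location/scale of the fractional metric
#'   (dimensionless; defaults emulate ~40% suppression).
#' @param cope_mean,cope_sd Location/scale of the COPEs (% CBV change;
#'   negative-going projection responses).
#' @param metric_name Label for the metric column.
#' @return Data frame with `animal`, `roi`, `metric`, `cope` and attribute
#'   `target_r`.
#' @export
simulate_matched_sites <- function(n_sites = 15, target_r, seed,
                                   metric_mean = -0.4, metric_sd = 0.15,
                                   cope_mean = -2, cope_sd = 0.6,
                                   metric_name = "delta_power") {
  if (abs(target_r) > 1) stop_config("|target_r| must be <= 1")
  with_seed(seed, {
    u <- stats::rnorm(n_sites)
    v <- stats::rnorm(n_sites)
    metric <- metric_mean + metric_sd * u
    cope <- cope_mean + cope_sd * (target_r * u + sqrt(1 - target_r^2) * v)
    rois <- c("mPFC", "ACA", "MOs", "MOp", "SSp", "RSP", "VIS", "AUD")
    out <- data.frame(
      animal = sprintf("m%02d", (seq_len(n_sites) - 1) %/% 3 + 1),
      roi = rois[(seq_len(n_sites) - 1) %% length(rois) + 1],
      metric = metric, cope = cope, stringsAsFactors = FALSE)
    names(out)[3] <- "metric"
    attr(out, "metric_name") <- metric_name
    attr(out, "target_r") <- target_r
    out
  })
}
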