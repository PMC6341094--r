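# shared fixtures, all generated in code

short_protocol <- function() make_protocol("short")

# a noiseless, drift-free adaptation truth for identity checks
exact_truth <- function(preset = "adaptation_short") {
  synth_truth(preset, noise_sd_pct = 0, drift_pct_per_min = 0,
              subject_amp_sd = 0)
}

# one preprocessed scan from a single-subject cohort
one_scan <- function(truth, protocol = short_protocol(), seed = 1) {
  co <- simulate_cbv_cohort(protocol, truth, 1, seed, n_scans = 1)
  list(raw = co$scans[[1]][[1]], truth = co$scan_truth[[1]][[1]],
       pp = preprocess_cbv(co$scans[[1]][[1]], protocol, "cbv"))
}

# trace with template spikes stamped at known sample indices
stamped_trace <- function(n, fs, spike_samples, template, noise_sd = 0,
                          seed = 1) {
  tr <- if (noise_sd > 0) withr::with_seed(seed, rnorm(n, 0, noise_sd))
        else numeric(n)
  L <- length(template)
  for (i in spike_samples) tr[i:(i + L - 1)] <- tr[i:(i + L - 1)] + template
  tr
}

narrow_template <- function(fs = 25000, amp = 250, len = 40)
  raphemap:::spike_template("narrow", len, fs, amp)

broad_template <- function(fs = 25000, amp = 350, len = 40)
  raphemap:::spike_template("broad", len, fs, amp)

# lfp_trace wrapper around a bare vector
as_lfp <- function(x, fs)
  structure(list(samples = x, fs = fs, provenance = list()),
            class = "lfp_trace")

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# two-unit ground-truth recording shared by sorting and acceptance tests
two_unit_recording <- function(seed = 42, dur_s = 120, fs = 25000,
                               rate = 5) {
  set.seed(seed)
  n <- fs * dur_s + 100
  tr <- rnorm(n, 0, 5)
  t1 <- raphemap:::poisson_train(rate, dur_s - 1, refractory_s = 0.003) + 0.5
  t2 <- raphemap:::poisson_train(rate, dur_s - 1, refractory_s = 0.003) + 0.5
  tm1 <- narrow_template(fs, amp = 200)
  tm2 <- broad_template(fs, amp = 350)
  for (i in round(t1 * fs)) tr[i:(i + 39)] <- tr[i:(i + 39)] + tm1
  for (i in round(t2 * fs)) tr[i:(i + 39)] <- tr[i:(i + 39)] + tm2
  ev <- detect_spikes(tr, fs)
  truth1 <- round(t1 * fs) + which.min(tm1) - 1
  truth2 <- round(t2 * fs) + which.min(tm2) - 1
  label <- vapply(ev$events$sample, function(s) {
    d1 <- min(abs(truth1 - s)); d2 <- min(abs(truth2 - s))
    if (min(d1, d2) > 3) NA_integer_ else if (d1 < d2) 1L else 2L
  }, integer(1))
  list(events = ev, label = label)
}
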