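test_that("z-scored metrics satisfy the normalisation contract", {
  rec <- two_unit_recording()
  m <- compute_spike_metrics(rec$events)
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-9)
  expect_equal(ncol(m), 5)
})

test_that("a constant metric column is dropped with a warning", {
  rec <- two_unit_recording(seed = 7, dur_s = 30)
  ev <- rec$events
  ev$snippets <- ev$snippets * 0
  ev$snippets[, 12] <- -1          # identical waveforms: everything constant
  expect_warning(m <- compute_spike_metrics(ev), "constant")
  expect_lt(ncol(m), 5)
})

test_that("two template populations separate in the metric space", {
  rec <- two_unit_recording()
  m <- compute_spike_metrics(rec$events)
  pc <- stats::prcomp(m)$x[, 1:2]
  lab <- rec$label
  ok <- !is.na(lab)
  # silhouette on the first two principal axes, true labels
  d <- as.matrix(dist(pc[ok, ]))
  l <- lab[ok]
  sil <- vapply(seq_along(l), function(i) {
    a <- mean(d[i, l == l[i]][-which(which(l == l[i]) == i)])
    b <- mean(d[i, l != l[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("well-separated units sort into two pure included clusters", {
  rec <- two_unit_recording()
  m <- compute_spike_metrics(rec$events)
  so <- sort_spikes(m, rec$events$time, seed = 1)
  inc <- which(vapply(so$clusters, `[[`, logical(1), "included"))
  expect_equal(length(inc), 2)
  # contamination of included clusters below 2%
  for (ci in inc) {
    gl <- rec$label[so$clusters[[ci]]$members]
    gl <- gl[!is.na(gl)]
    main <- max(table(gl))
    expect_lt(1 - main / length(gl), 0.02)
  }
  # and no returned cluster violates the ISI ceiling
  for (cl in so$clusters)
    expect_lte(cl$isi_violation, so$violation_ceiling)
})

test_that("over-clustered single unit merges back to one cluster", {
  set.seed(3)
  n <- 600
  m <- matrix(rnorm(n * 3, 0, 0.5), n, 3)        # one tight cloud
  times <- sort(runif(n, 0, 600))
  times <- times[c(TRUE, diff(times) > 0.003)]   # no refractory violations
  m <- m[seq_along(times), , drop = FALSE]
  so <- sort_spikes(m, times, seed = 2)
  expect_equal(length(so$clusters), 1)
})

test_that("merges that would breach the refractory ceiling are vetoed", {
  # two units with identical metrics but interleaved spikes 1 ms apart:
  # distance says merge, refractory says never
  set.seed(4)
  n <- 300
  t1 <- seq(0.1, by = 0.050, length.out = n)
  t2 <- t1 + 0.001                                # 1 ms < 2 ms refractory
  times <- as.numeric(rbind(t1, t2))
  m <- matrix(rnorm(2 * n * 2, 0, 0.2), 2 * n, 2)
  m[seq(1, 2 * n, by = 2), 1] <- m[seq(1, 2 * n, by = 2), 1] + 0.5  # d << 2.5
  so <- sort_spikes(m, times, min_spikes = 50, seed = 5)
  expect_gte(length(so$clusters), 2)
  # every union the merger produced was certified against the ceiling
  for (cl in so$clusters)
    if (cl$merged) expect_lte(cl$isi_violation, so$violation_ceiling)
})

test_that("inclusion threshold is strict and empty input returns empty", {
  m <- matrix(rnorm(100), 50, 2)
  so <- sort_spikes(m, sort(runif(50, 0, 100)), min_spikes = 50, seed = 1)
  expect_false(any(vapply(so$clusters, `[[`, logical(1), "included")))
  so0 <- sort_spikes(matrix(numeric(0), 0, 2), numeric(0))
  expect_length(so0$clusters, 0)
  expect_error(sort_spikes(m, sort(runif(50, 0, 100)), d_merge = -1),
               class = "raphemap_config_error")
})

test_that("waveform typing recovers the template families deterministically", {
  # three families of cluster centroids
  set.seed(6)
  fam_centers <- rbind(c(0, 0, 0), c(6, 0, 0), c(0, 6, 0))
  clusters <- list()
  truth <- integer(0)
  for (f in 1:3) for (k in 1:4) {
    clusters[[length(clusters) + 1]] <- list(
      members = 1:60, times = sort(runif(60, 0, 60)),
      centroid = fam_centers[f, ] + rnorm(3, 0, 0.2),
      n_spikes = 60, isi_violation = 0, stereo = FALSE, included = TRUE)
    truth <- c(truth, f)
  }
  sc <- structure(list(clusters = clusters, min_spikes = 50),
                  class = "spike_clusters")
  ty <- classify_waveform_types(sc, k_types = 3, seed = 2)
  # adjusted-Rand = 1 <=> perfect agreement up to label permutation
  tab <- table(ty$types$type, truth)
  expect_equal(sum(apply(tab, 1, max)), length(truth))
  ty2 <- classify_waveform_types(sc, k_types = 3, seed = 2)
  expect_identical(ty$types, ty2$types)
  ty1 <- classify_waveform_types(sc, k_types = 1)
  expect_true(all(ty1$types$type == 1))
  expect_error(classify_waveform_types(sc, k_types = 99),
               class = "raphemap_config_error")
})

test_that("stimulus-locked units fire above baseline end to end", {
  p <- short_protocol()
  fs <- 25000
  dur <- 130                       # lead-in + first block and off period
  set.seed(11)
  base_t <- raphemap:::poisson_train(3, dur, refractory_s = 0.003)
  stim_t <- 60 + sort(runif(200, 0, 20))   # 20 Hz-locked burst in block 1
  tm <- narrow_template(fs, amp = 250)
  all_t <- sort(c(base_t, stim_t))
  all_t <- all_t[c(TRUE, diff(all_t) > 0.002)]
  tr <- stamped_trace(dur * fs + 100, fs, round(all_t * fs) + 1, tm,
                      noise_sd = 5, seed = 12)
  ev <- detect_spikes(tr, fs)
  tt <- ev$events$time
  stim_rate <- sum(tt >= 60 & tt < 80) / 20
  base_rate <- sum(tt < 60) / 60
  expect_gt(stim_rate, base_rate)
})
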