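#' Detect extracellular spikes by threshold crossing
#'
#' Spikes are detected on a MUA-band trace as excursions beyond `k_sd`
#' standard deviations of the noise below zero (extracellular somatic
#' spikes are negative-going). The noise standard deviation is estimated
#' robustly as `median(|trace|)/0.6745`, which is not inflated by the
#' spikes themselves. After each detection a dead time of one snippet
#' window suppresses further crossings, so multiphasic waveforms are not
#' double-counted. Each event carries a trough-aligned waveform snippet.
#'
#' @param trace Numeric vector, MUA-band-filtered signal (microvolts).
#' @param fs Sampling rate, Hz.
#' @param k_sd Threshold multiplier (5 by default).
#' @param noise_sd Optional externally supplied noise sd; default robust
#'   estimate from the trace.
#' @param window Snippet length in samples (default 1.6 ms worth).
#' @param pre_frac Fraction of the window placed before the trough.
#' @param channel Channel index stored on the events.
#' @return Object of class `spike_events`: data frame `events`
#'   (`time`, `sample`, `channel`, `trough_uv`), `snippets` (events x
#'   window matrix), `fs`, `window`, `noise_sd`, `k_sd`.
#' @export
detect_spikes <- function(trace, fs, k_sd = 5, noise_sd = NULL,
                          window = max(20L, round(0.0016 * fs)),
                          pre_frac = 0.3, channel = 1L) {
  if (fs <= 0) stop_config("fs must be positive")
  if (length(trace) < window)
    stop_config("trace shorter than one snippet window")
  sd_n <- noise_sd %||% (stats::median(abs(trace)) / 0.6745)
  thr <- -k_sd * sd_n
  below <- trace < thr
  cross <- which(below & !c(FALSE, below[-length(below)]))
  pre <- round(window * pre_frac)
  post <- window - pre - 1L
  events <- integer(0)
  last_end <- -Inf
  for (i in cross) {
    if (i <= last_end) next
    # align to the trough within one window after the crossing
    seg_end <- min(i + window - 1L, length(trace))
    trough <- i - 1L + which.min(trace[i:seg_end])
    events <- c(events, trough)
    last_end <- trough + window   # dead time: one snippet window
  }
  keep <- events - pre >= 1L & events + post <= length(trace)
  events <- events[keep]
  snip <- if (length(events))
    t(vapply(events, function(i) trace[(i - pre):(i + post)],
             numeric(window))) else
    matrix(numeric(0), 0, window)
  structure(list(
    events = data.frame(time = (events - 1L) / fs, sample = events,
                        channel = rep(channel, length(events)),
                        trough_uv = trace[events]),
    snippets = snip, fs = fs, window = window, pre = pre,
    noise_sd = sd_n, k_sd = k_sd), class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf("<spike_events> %d events, %d-sample snippets at %g Hz (%.1f sd threshold)\n",
              nrow(x$events), x$window, x$fs, x$k_sd))
  invisible(x)
}

#' Combine events from multiple channels, flagging stereotrode pairs
#'
#' Events detected on adjacent channels within a coincidence window are
#' treated as a single two-channel (stereotrode-like) event; the deeper
#' trough's snippet is kept.
#'
#' @param event_list List of `spike_events`, one per channel.
#' @param coincidence_ms Pairing window, milliseconds.
#' @return `spike_events` with an extra logical `stereo` column.
#' @export
merge_channel_events <- function(event_list, coincidence_ms = 0.4) {
  stopifnot(length(event_list) >= 1)
  fs <- event_list[[1]]$fs
  ev <- do.call(rbind, lapply(event_list, function(e) e$events))
  sn <- do.call(rbind, lapply(event_list, function(e) e$snippets))
  o <- order(ev$time)
  ev <- ev[o, , drop = FALSE]; sn <- sn[o, , drop = FALSE]
  n <- nrow(ev)
  stereo <- rep(FALSE, n)
  drop <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (drop[i]) next
      j <- i + 1
      while (j <= n && (ev$time[j] - ev$time[i]) * 1000 <= coincidence_ms) {
        if (!drop[j] && abs(ev$channel[j] - ev$channel[i]) == 1) {
          stereo[i] <- TRUE; stereo[j] <- TRUE
          drop[if (ev$trough_uv[i] <= ev$trough_uv[j]) j else i] <- TRUE
          break
        }
        j <- j + 1
      }
    }
  }
  keep <- !drop
  out <- event_list[[1]]
  out$events <- cbind(ev[keep, , drop = FALSE],
                      stereo = stereo[keep] | FALSE)
  rownames(out$events) <- NULL
  out$snippets <- sn[keep, , drop = FALSE]
  out
}

#' Per-event spike metrics, z-scored
#'
#' Computes five waveform features per event — trough amplitude, peak
#' amplitude (after the trough), trough-to-peak width, half-width at half
#' trough depth, and peak/trough ratio — and standardises each metric to
#' mean 0, sd 1. Constant metric columns are undefined under z-scoring and
#' are dropped with a warning.
#'
#' @param events `spike_events` object (or a snippet matrix with attribute
#'   `fs`).
#' @param metrics Character subset of the five metric names.
#' @return Numeric matrix events x metrics (z units) with attribute `raw`
#'   (the unstandardised metrics).
#' @export
compute_spike_metrics <- function(events,
                                  metrics = c("trough_amp", "peak_amp",
                                              "trough_to_peak", "half_width",
                                              "peak_trough_ratio")) {
  snip <- events$snippets
  fs <- events$fs
  if (nrow(snip) < 2) stop_config("need at least 2 events for z-scoring")
  ms_per <- 1000 / fs
  raw <- t(apply(snip, 1, function(w) {
    it <- which.min(w)
    trough <- -w[it]
    post <- if (it < length(w)) w[(it + 1):length(w)] else 0
    ip <- it + which.max(post)
    peak <- max(post)
    half <- w <= -trough / 2
    c(trough_amp = trough,
      peak_amp = peak,
      trough_to_peak = (ip - it) * ms_per,
      half_width = sum(half) * ms_per,
      peak_trough_ratio = peak / trough)
  }))
  raw <- raw[, metrics, drop = FALSE]
  sds <- apply(raw, 2, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping constant spike metric column(s): ",
            paste(colnames(raw)[const], collapse = ", "))
    raw <- raw[, !const, drop = FALSE]
  }
  z <- scale(raw)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "raw") <- raw
  z
}

#' Sort spikes by refractory-constrained agglomeration of k-means clusters
#'
#' The sorter over-clusters the z-scored metric space with k-means
#' (`k = min(20, floor(n/50))`, at least 1) and then progressively merges
#' the closest centroid pair while (i) the Euclidean inter-centroid
#' distance is below `d_merge` and (ii) the merged cluster's fraction of
#' inter-spike intervals shorter than `refractory_ms` does not exceed
#' `violation_ceiling`. Events observable on two channels (stereotrode
#' events) are sorted first, then the residual single-channel events.
#' Clusters with strictly more than `min_spikes` events are flagged
#' `included`.
#'
#' @param metrics z-scored metric matrix from [compute_spike_metrics()].
#' @param times Event times, seconds (sorted).
#' @param stereo Logical vector: event observable on 2 channels. `NULL`
#'   treats all events as single-channel (one pass).
#' @param d_merge Merge distance threshold in z-space (2.5).
#' @param refractory_ms Refractory period, ms (2).
#' @param min_spikes Inclusion threshold, strict (50).
#' @param violation_ceiling Maximum tolerated ISI-violation fraction after a
#'   merge (0.005; exact zero is untestable under chance coincidence).
#' @param max_k Over-clustering cap (20).
#' @param seed Integer seed for the k-means initialisation.
#' @return Object of class `spike_clusters`: `clusters` list (each with
#'   `members`, `times`, `centroid`, `n_spikes`, `isi_violation`, `merged`
#'   — whether the cluster is a union certified by the refractory test —
#'   `stereo`, `included`), `assignment` integer vector over events, and
#'   the parameters used.
#' @export
sort_spikes <- function(metrics, times, stereo = NULL, d_merge = 2.5,
                        refractory_ms = 2, min_spikes = 50,
                        violation_ceiling = 0.005, max_k = 20, seed = 1) {
  if (d_merge <= 0) stop_config("d_merge must be positive")
  n <- nrow(metrics)
  if (is.null(n) || n == 0)
    return(structure(list(clusters = list(), assignment = integer(0),
                          d_merge = d_merge, refractory_ms = refractory_ms,
                          min_spikes = min_spikes,
                          violation_ceiling = violation_ceiling),
                     class = "spike_clusters"))
  if (is.unsorted(times)) stop_config("times must be sorted ascending")
  stereo <- stereo %||% rep(FALSE, n)
  passes <- if (any(stereo)) list(which(stereo), which(!stereo))
            else list(seq_len(n))
  passes <- Filter(length, passes)

  clusters <- list()
  assignment <- integer(n)
  with_seed(seed, {
    for (p in seq_along(passes)) {
      idx <- passes[[p]]
      sub <- metrics[idx, , drop = FALSE]
      k <- max(1L, min(max_k, floor(length(idx) / 50)))
      cl <- if (k == 1 || length(idx) <= k)
        list(cluster = rep(1L, length(idx)))
      else stats::kmeans(sub, centers = k, nstart = 5, iter.max = 50)
      groups <- split(idx, cl$cluster)
      groups <- merge_clusters(groups, metrics, times,
                               d_merge, refractory_ms, violation_ceiling)
      for (gi in seq_along(groups$groups)) {
        g <- groups$groups[[gi]]
        cid <- length(clusters) + 1L
        assignment[g] <- cid
        tt <- sort(times[g])
        isis <- diff(tt) * 1000
        clusters[[cid]] <- list(
          members = g, times = tt,
          centroid = colMeans(metrics[g, , drop = FALSE]),
          mean_waveform = NULL,
          n_spikes = length(g),
          isi_violation = if (length(isis)) mean(isis < refractory_ms) else 0,
          merged = groups$merged[gi],
          stereo = p == 1 && any(stereo),
          included = length(g) > min_spikes)
      }
    }
  })
  structure(list(clusters = clusters, assignment = assignment,
                 d_merge = d_merge, refractory_ms = refractory_ms,
                 min_spikes = min_spikes,
                 violation_ceiling = violation_ceiling),
            class = "spike_clusters")
}

# iterative closest-pair agglomeration under the distance and refractory
# constraints; groups is a list of event-index vectors. Returns the merged
# groups plus a flag marking clusters that are unions of initial clusters
# (only those were subject to, and certified by, the refractory test).
merge_clusters <- function(groups, metrics, times, d_merge, refractory_ms,
                           violation_ceiling) {
  viol_frac <- function(g) {
    tt <- sort(times[g])
    if (length(tt) < 2) return(0)
    mean(diff(tt) * 1000 < refractory_ms)
  }
  was_merged <- rep(FALSE, length(groups))
  repeat {
    if (length(groups) < 2) break
    cent <- t(vapply(groups, function(g)
      colMeans(metrics[g, , drop = FALSE]), numeric(ncol(metrics))))
    d <- as.matrix(stats::dist(cent))
    diag(d) <- Inf
    merged <- FALSE
    while (any(is.finite(d))) {
      ij <- arrayInd(which.min(d), dim(d))
      i <- ij[1]; j <- ij[2]
      if (d[i, j] >= d_merge) break
      cand <- c(groups[[i]], groups[[j]])
      if (viol_frac(cand) <= violation_ceiling) {
        groups[[i]] <- cand
        groups[[j]] <- NULL
        was_merged[i] <- TRUE
        was_merged <- was_merged[-j]
        merged <- TRUE
        break
      }
      d[i, j] <- Inf; d[j, i] <- Inf   # pair vetoed by refractory test
    }
    if (!merged) break
  }
  list(groups = groups, merged = was_merged)
}

#' @export
print.spike_clusters <- function(x, ...) {
  inc <- sum(vapply(x$clusters, `[[`, logical(1), "included"))
  cat(sprintf("<spike_clusters> %d clusters (%d included with > %d spikes)\n",
              length(x$clusters), inc, x$min_spikes))
  invisible(x)
}

#' Classify sorted clusters into waveform types
#'
#' k-means on the per-cluster mean (centroid) metrics of the included
#' clusters; deterministic given `seed`.
#'
#' @param clusters `spike_clusters` object.
#' @param k_types Number of waveform types.
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Object of class `waveform_types`: data frame `types`
#'   (`cluster`, `type`), `centroids` (type-mean metrics), `k_types`.
#' @export
classify_waveform_types <- function(clusters, k_types, seed = 1, nstart = 10) {
  inc <- which(vapply(clusters$clusters, `[[`, logical(1), "included"))
  if (k_types < 1) stop_config("k_types must be >= 1")
  if (length(inc) < k_types)
    stop_config("k_types exceeds the number of included clusters")
  cent <- t(vapply(clusters$clusters[inc], `[[`,
                   numeric(length(clusters$clusters[[inc[1]]]$centroid)),
                   "centroid"))
  lab <- if (k_types == 1) rep(1L, length(inc)) else with_seed(seed, {
    km <- stats::kmeans(cent, centers = k_types, nstart = nstart, iter.max = 100)
    # relabel types by first appearance for seed-stable, order-stable output
    first <- tapply(seq_along(km$cluster), km$cluster, min)
    match(km$cluster, as.integer(names(sort(first))))
  })
  cents <- do.call(rbind, lapply(sort(unique(lab)), function(l)
    colMeans(cent[lab == l, , drop = FALSE])))
  structure(list(types = data.frame(cluster = inc, type = lab),
                 centroids = cents, k_types = k_types),
            class = "waveform_types")
}

#' Kruskal-Wallis comparison of stimulus-locked spiking across types
#'
#' Computes per-cluster spiking probabilities (spikes per light pulse within
#' the response windows of the chosen mode), then compares waveform types
#' with a Kruskal-Wallis test (tie-corrected H) followed by Dunn's post-hoc
#' pairwise z tests, Holm-adjusted.
#'
#' @param prob Named list (or split vector) of per-cluster spiking
#'   probabilities, one numeric vector per type; or computed internally from
#'   `clusters`, `types`, `protocol` if those are given via
#'   [pulse_response_probability()].
#' @return List: `H`, `p`, `dunn` (data frame of pairwise comparisons with
#'   raw and Holm-adjusted p), `groups`.
#' @export
spike_response_stats <- function(prob) {
  if (!is.list(prob) || length(prob) < 2)
    stop_config("need >= 2 type groups")
  if (any(!vapply(prob, length, 1L)))
    stop_config("every type group must be non-empty")
  x <- unlist(prob, use.names = FALSE)
  g <- factor(rep(names(prob) %||% seq_along(prob),
                  vapply(prob, length, 1L)))
  kw <- stats::kruskal.test(x, g)
  dunn <- dunn_posthoc(x, g)
  list(H = unname(kw$statistic), p = kw$p.value, dunn = dunn,
       groups = levels(g))
}

# Dunn's z tests on mean ranks with tie correction, Holm-adjusted
dunn_posthoc <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[i]] + 1 / ni[[j]]))
    z <- (mr[[i]] - mr[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ])
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  rownames(out) <- NULL
  out
}

#' Per-cluster spiking probability per light pulse
#'
#' Spikes per pulse within the response windows: in `single_pulse` mode each
#' pulse opens its own window (`window_ms` after pulse onset); in `train`
#' mode the whole stimulation block is one window and the probability is
#' spikes per pulse delivered in the block.
#'
#' @param cluster_times List of per-cluster spike-time vectors (seconds).
#' @param protocol Stimulation protocol (pulse rate/width and block timing).
#' @param mode `"single_pulse"` or `"train"`.
#' @param window_ms Response window per pulse in `single_pulse` mode.
#' @return Numeric vector, one probability per cluster.
#' @export
pulse_response_probability <- function(cluster_times, protocol,
                                       mode = c("train", "single_pulse"),
                                       window_ms = 10) {
  mode <- match.arg(mode)
  per_block <- protocol$pulse_rate * protocol$block_duration
  vapply(cluster_times, function(tt) {
    if (mode == "train") {
      n_in <- 0
      for (on in protocol$block_onsets)
        n_in <- n_in + sum(tt >= on & tt < on + protocol$block_duration)
      n_in / (per_block * length(protocol$block_onsets))
    } else {
      pulses <- unlist(lapply(protocol$block_onsets, function(on)
        seq(on, on + protocol$block_duration - 1 / protocol$pulse_rate,
            by = 1 / protocol$pulse_rate)))
      hits <- vapply(pulses, function(p0)
        sum(tt >= p0 & tt < p0 + window_ms / 1000), numeric(1))
      mean(hits)
    }
  }, numeric(1))
}
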