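#' Write / read ROI time series as TSV + JSON sidecar
#'
#' The columnar table has one column per ROI (header row of labels) and one
#' row per volume; the sidecar records the protocol, units and any ground
#' truth so a series file is self-describing.
#'
#' @param series `roi_series` object or volumes x ROI matrix.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.json`.
#' @param protocol Protocol stored in the sidecar.
#' @param ground_truth Optional list stored verbatim in the sidecar.
#' @return Invisibly, the TSV path.
#' @export
write_roi_series <- function(series, path_prefix, protocol = NULL,
                             ground_truth = NULL) {
  dat <- if (inherits(series, "roi_series")) series$data else as.matrix(series)
  utils::write.table(format(as.data.frame(dat), digits = 10, trim = TRUE),
                     paste0(path_prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    units = if (inherits(series, "roi_series")) "percent_change" else "raw",
    volume_interval = if (inherits(series, "roi_series"))
      series$volume_interval else protocol$volume_interval,
    provenance = if (inherits(series, "roi_series")) series$provenance,
    protocol = if (!is.null(protocol)) unclass(protocol),
    ground_truth = ground_truth)
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(path_prefix, ".tsv"))
}

#' @rdname write_roi_series
#' @return `read_roi_series`: list with `data` (matrix) and `sidecar`.
#' @export
read_roi_series <- function(path_prefix) {
  dat <- as.matrix(utils::read.table(paste0(path_prefix, ".tsv"),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
  side <- if (file.exists(paste0(path_prefix, ".json")))
    jsonlite::read_json(paste0(path_prefix, ".json"), simplifyVector = TRUE)
  list(data = dat, sidecar = side)
}

#' Write / read a probe recording as int16 binary + JSON sidecar
#'
#' Traces are stored channel-interleaved as little-endian 16-bit integers
#' with a microvolt-per-bit scale factor recorded in the sidecar, together
#' with the sampling rate, channel count, and ground-truth spike/burst
#' times.
#'
#' @param rec `probe_recording` object.
#' @param path_prefix Output path without extension; writes `<prefix>.bin`
#'   and `<prefix>.json`.
#' @param uv_per_bit Quantisation step, microvolts per integer unit.
#' @return Invisibly, the binary path.
#' @export
write_probe_recording <- function(rec, path_prefix, uv_per_bit = 0.1) {
  q <- round(rec$traces / uv_per_bit)
  q <- pmin(pmax(q, -32768), 32767)
  con <- file(paste0(path_prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(q[seq_along(q)]), con, size = 2, endian = "little")
  side <- list(fs = rec$fs, n_channels = nrow(rec$traces),
               uv_per_bit = uv_per_bit, site = rec$site,
               interleave = "channel",
               ground_truth = list(
                 unit_times = lapply(rec$units, `[[`, "times"),
                 unit_channels = lapply(rec$units, `[[`, "channels"),
                 unit_family = vapply(rec$units, `[[`, character(1), "family"),
                 burst_times = rec$burst_times),
               protocol = unclass(rec$protocol))
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paste0(path_prefix, ".bin"))
}

#' @rdname write_probe_recording
#' @return `read_probe_recording`: list with `traces` (channels x samples,
#'   microvolts), `fs`, and `sidecar`.
#' @export
read_probe_recording <- function(path_prefix) {
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  sz <- file.info(paste0(path_prefix, ".bin"))$size
  con <- file(paste0(path_prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
  traces <- matrix(v * side$uv_per_bit, nrow = side$n_channels)
  list(traces = traces, fs = side$fs, sidecar = side)
}

#' Write / read a per-ROI atlas map as a two-column TSV
#'
#' @param map Named numeric vector.
#' @param path Output TSV path (`ROI`, `value` columns).
#' @return Invisibly, `path`.
#' @export
write_atlas_map <- function(map, path) {
  utils::write.table(data.frame(ROI = names(map), value = unname(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_map
#' @return `read_atlas_map`: named numeric vector.
#' @export
read_atlas_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  stats::setNames(df$value, df$ROI)
}

#' Export a volumetric map as NIfTI-1
#'
#' Thin wrapper over RNifti for optional volumetric phantom export; errors
#' if RNifti is not installed.
#'
#' @param vol 3D (or 4D) numeric array.
#' @param path Output `.nii` path.
#' @param voxel_mm Isotropic voxel size, mm.
#' @return Invisibly, `path`.
#' @export
export_nifti <- function(vol, path, voxel_mm = 0.15) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop_config("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(vol, pixdim = rep(voxel_mm, min(3, length(dim(vol)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
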