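#' Simulate atlas maps with controlled structure-function correlation
#'
#' Generate per-ROI anatomical maps (projection density, receptor
#' expression) whose squared Pearson correlation with a given COPE map
#' equals a target r^2. Each map is built by mixing the standardised COPE
#' map with a noise map orthogonalised against it in-sample, at the
#' analytically required ratio `m = r*u + sqrt(1-r^2)*z`, so the sample r^2
#' equals the target to machine precision for every seed. A `projection`
#' map with target 0 is always included (the study's projection-density
#' null).
#'
#' @param cope_truth Named numeric vector of per-ROI COPE values (>= 3 ROIs).
#' @param r2_targets Named numeric vector of r^2 targets in `[0, 1]`, one
#'   per map. A `projection` entry with target 0 is added if absent.
#' @param seed Integer seed.
#' @param location,scale Affine placement of the returned maps (arbitrary
#'   expression units; correlation is affine-invariant).
#' @return Object of class `atlas_maps`: named list of named numeric
#'   vectors over the same ROI labels, plus `r2_targets`.
#' @export
simulate_atlas_maps <- function(cope_truth, r2_targets, seed,
                                location = 5, scale = 2) {
  if (length(cope_truth) < 3)
    stop_config("need at least 3 ROIs for a defined correlation")
  if (is.null(names(cope_truth)))
    stop_config("cope_truth must be a named vector")
  if (any(r2_targets < 0 | r2_targets > 1))
    stop_config("r^2 targets must lie in [0, 1]")
  if (!"projection" %in% names(r2_targets))
    r2_targets <- c(projection = 0, r2_targets)
  with_seed(seed, {
    u <- as.numeric(scale(cope_truth))        # standardised cope map
    maps <- lapply(r2_targets, function(r2) {
      z <- stats::rnorm(length(u))
      z <- stats::resid(stats::lm(z ~ u))     # in-sample orthogonal noise
      z <- as.numeric(scale(z))
      r <- sqrt(r2)
      m <- r * u + sqrt(1 - r2) * z
      stats::setNames(location + scale * m, names(cope_truth))
    })
    structure(list(maps = maps, r2_targets = r2_targets,
                   roi_labels = names(cope_truth), seed = seed),
              class = "atlas_maps")
  })
}

#' @export
print.atlas_maps <- function(x, ...) {
  cat(sprintf("<atlas_maps> %d maps over %d ROIs: %s\n",
              length(x$maps), length(x$roi_labels),
              paste(sprintf("%s(r2=%.3g)", names(x$r2_targets), x$r2_targets),
                    collapse = ", ")))
  invisible(x)
}
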