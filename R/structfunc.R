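#' Remove white-matter structures from a map
#'
#' Drops white-matter-labelled entries from a per-ROI map so that
#' projection-density comparisons reflect terminal fields rather than fibre
#' tracts. Label matching is case-insensitive.
#'
#' @param map Named numeric vector (ROI -> value).
#' @param wm_labels Character vector of white-matter labels.
#' @return The masked map, with attribute `n_removed`.
#' @export
mask_white_matter <- function(map, wm_labels) {
  if (is.null(names(map))) stop_config("map must be a named vector")
  drop <- tolower(names(map)) %in% tolower(wm_labels)
  if (all(drop)) stop_config("masking removed every entry of the map")
  out <- map[!drop]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Structure-function correlation of a map against the COPE map
#'
#' Pearson correlation (and r^2, the variance in the hemodynamic response
#' explained by the map) over the ROIs shared by the COPE table and the
#' anatomical map. Label harmonisation is an inner join, case-insensitive.
#'
#' @param copes Cope table (`roi`, `cope`) or `ofmri_glm` fit, or a named
#'   numeric vector.
#' @param map Named numeric vector (ROI -> value).
#' @param map_id Identifier carried into the result.
#' @return Object of class `structfunc_result`: `map_id`, `r`, `r2`, `p`,
#'   `n`, `shared_rois`, `dropped_labels`.
#' @export
structure_function_corr <- function(copes, map, map_id = "map") {
  cv <- if (is.numeric(copes) && !is.null(names(copes))) copes else {
    tab <- cope_table(copes)
    stats::setNames(tab$cope, tab$roi)
  }
  if (is.null(names(map))) stop_config("map must be a named vector")
  key_c <- tolower(names(cv)); key_m <- tolower(names(map))
  shared <- intersect(key_c, key_m)
  if (length(shared) < 3)
    stop_config("fewer than 3 shared ROIs between COPE table and map")
  x <- cv[match(shared, key_c)]
  y <- map[match(shared, key_m)]
  ct <- stats::cor.test(x, y)
  structure(list(map_id = map_id, r = unname(ct$estimate),
                 r2 = unname(ct$estimate)^2, p = ct$p.value,
                 n = length(shared), shared_rois = names(cv)[match(shared, key_c)],
                 dropped_labels = setdiff(names(map), names(map)[match(shared, key_m)])),
            class = "structfunc_result")
}

#' @export
print.structfunc_result <- function(x, ...) {
  cat(sprintf("<structfunc_result> %s: r = %.3f, r2 = %.3f (p = %.3g, n = %d)\n",
              x$map_id, x$r, x$r2, x$p, x$n))
  invisible(x)
}

#' Screen a collection of receptor-expression maps
#'
#' Runs [structure_function_corr()] for every map, corrects the p-values
#' across the screened maps with Benjamini-Hochberg FDR, and ranks by r^2
#' (ties broken by map label for a stable order).
#'
#' @param copes Cope table / fit / named vector (see
#'   [structure_function_corr()]).
#' @param maps Named list of maps, or an `atlas_maps` object.
#' @return Data frame: `map`, `r`, `r2`, `p`, `q`, `n`, `significant`
#'   (q < 0.05), sorted by decreasing r^2.
#' @export
receptor_screen <- function(copes, maps) {
  if (inherits(maps, "atlas_maps")) maps <- maps$maps
  if (!length(maps)) stop_config("need at least one map to screen")
  res <- lapply(names(maps), function(nm)
    structure_function_corr(copes, maps[[nm]], map_id = nm))
  out <- data.frame(
    map = vapply(res, `[[`, character(1), "map_id"),
    r = vapply(res, `[[`, numeric(1), "r"),
    r2 = vapply(res, `[[`, numeric(1), "r2"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = vapply(res, `[[`, integer(1), "n"),
    stringsAsFactors = FALSE)
  out$q <- fdr_correct(out$p)
  out$significant <- out$q < 0.05
  out[order(-out$r2, out$map), c("map", "r", "r2", "p", "q", "n", "significant")]
}
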