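#' Default ROI atlas for the DRN serotonin projection system
#'
#' A 39-region atlas in the style of a harmonised Allen-atlas ROI reduction:
#' the dorsal raphe nucleus (`DRN`) plus 38 forebrain/midbrain projection
#' targets. `drop_drn = TRUE` returns the 38-ROI set used for
#' structure-function comparison, where the stimulated nucleus itself is
#' excluded. White-matter labels are carried separately so projection maps
#' that include fibre tracts can be masked.
#'
#' @param drop_drn Drop the DRN ROI (38-ROI atlas).
#' @return List with `labels`, `wm_labels`, and `adjacency` (symmetric
#'   logical matrix over `labels`; a coarse anterior-posterior neighbourhood
#'   graph used for cluster-extent correction).
#' @export
default_atlas <- function(drop_drn = FALSE) {
  labels <- c(
    "DRN",
    "mPFC", "ACA", "ORB", "AI", "PIR",
    "MOp", "MOs", "SSp", "SSs", "AUD", "VIS", "RSP", "PTLp", "TEa",
    "PERI", "ECT", "ENT", "CA1d", "CA1v", "CA3", "DG", "SUB",
    "CLA", "BLA", "CEA", "MEA",
    "LS", "NAc", "CP", "GPe", "BST",
    "MD", "VPM", "LGd", "LP", "LHA", "PVH", "PAG")
  stopifnot(length(labels) == 39L)
  if (drop_drn) labels <- setdiff(labels, "DRN")

  # coarse anatomical neighbour pairs (bilateral ROIs treated as one node)
  pairs <- list(
    c("mPFC", "ACA"), c("mPFC", "ORB"), c("ACA", "MOs"), c("ORB", "AI"),
    c("AI", "PIR"), c("MOp", "MOs"), c("MOp", "SSp"), c("SSp", "SSs"),
    c("SSs", "AUD"), c("AUD", "TEa"), c("VIS", "RSP"), c("VIS", "PTLp"),
    c("PTLp", "SSp"), c("RSP", "ACA"), c("TEa", "ECT"), c("ECT", "PERI"),
    c("PERI", "ENT"), c("ENT", "SUB"), c("SUB", "CA1d"), c("CA1d", "CA3"),
    c("CA1v", "CA3"), c("CA3", "DG"), c("CLA", "AI"), c("BLA", "CEA"),
    c("CEA", "MEA"), c("BLA", "ECT"), c("LS", "NAc"), c("NAc", "CP"),
    c("CP", "GPe"), c("BST", "LS"), c("MD", "VPM"), c("VPM", "LP"),
    c("LGd", "LP"), c("LP", "PAG"), c("LHA", "PVH"), c("PAG", "DRN"),
    c("MD", "PAG"), c("CP", "BLA"), c("LHA", "BST"))
  adj <- matrix(FALSE, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (pr in pairs) {
    if (all(pr %in% labels)) {
      adj[pr[1], pr[2]] <- TRUE
      adj[pr[2], pr[1]] <- TRUE
    }
  }
  list(labels = labels,
       wm_labels = c("cc", "ac", "ic", "fx", "cg", "opt"),
       adjacency = adj)
}
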