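#' Session-level contrast of three scans
#'
#' Fluoxetine sessions: the two post-drug scans are averaged and the
#' pre-drug scan subtracted. Restraint (and control) sessions: all three
#' scans are averaged.
#'
#' @param scans 3 x ROI matrix (or list of 3 named cope vectors).
#' @param mode `"fluoxetine"` or `"restraint"`.
#' @return Named numeric vector, one value per ROI.
#' @export
session_contrast <- function(scans, mode = c("fluoxetine", "restraint")) {
  mode <- match.arg(mode)
  if (is.list(scans)) scans <- do.call(rbind, scans)
  if (nrow(scans) != 3) stop_config("a session must contain exactly 3 scans")
  if (mode == "fluoxetine") colMeans(scans[2:3, , drop = FALSE]) - scans[1, ]
  else colMeans(scans)
}

# OLS t-statistic engine for one contrast over many response columns;
# factorises X once so the permutation loop only does matrix products
ols_t_engine <- function(X, cvec) {
  df <- nrow(X) - qr(X)$rank
  XtXinv <- chol2inv(chol(crossprod(X)))
  H <- XtXinv %*% t(X)                  # (X'X)^-1 X'
  var_c <- drop(crossprod(cvec, XtXinv %*% cvec))
  ct_H <- drop(crossprod(cvec, H))      # row vector: cope = ct_H %*% Y
  function(Y) {
    beta <- H %*% Y
    res <- Y - X %*% beta
    sigma2 <- colSums(res^2) / df
    list(t = drop(ct_H %*% Y) / sqrt(sigma2 * var_c), df = df)
  }
}

ols_t <- function(X, Y, cvec) ols_t_engine(X, cvec)(Y)

#' Permutation test of a group contrast over ROI COPE maps
#'
#' Observed per-ROI t statistics come from an OLS fit of
#' `cope ~ group + covariates`; the null distribution is built with a
#' Freedman-Lane scheme — covariates are regressed out, and the
#' covariate-residualised data rows are permuted — which keeps nuisance
#' structure (scan order, sex) intact while permuting group membership.
#' Family-wise corrected p-values use the max-|t| statistic; if an ROI
#' adjacency is supplied, cluster-extent corrected p-values are computed as
#' the fraction of permutation maximum extents at least as large as the
#' observed cluster's extent.
#'
#' @param copes Subjects x ROI matrix of COPE maps.
#' @param groups Two-level factor over subjects; the contrast is
#'   level2 - level1.
#' @param covariates Optional data frame of nuisance covariates.
#' @param n_perm Number of permutations (5000 in the full analysis).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param adjacency Optional symmetric logical ROI adjacency matrix for
#'   cluster-extent correction.
#' @param forming_p Cluster-forming threshold as an uncorrected two-sided
#'   p-value.
#' @return Object of class `perm_result`: `table` (per-ROI `roi`, `t`,
#'   `p_uncorrected`, `p_fwe`, `cluster`, `p_cluster`), `clusters` table,
#'   `n_perm`, `seed`, `df`, `null_max_t` summary.
#' @export
permutation_test <- function(copes, groups, covariates = NULL,
                             n_perm = 5000, seed = 1, adjacency = NULL,
                             forming_p = 0.01) {
  copes <- as.matrix(copes)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_config("groups must have exactly 2 levels")
  if (min(table(groups)) < 2) stop_config("need >= 2 subjects per group")
  if (n_perm < 100) stop_config("n_perm must be >= 100")
  n <- nrow(copes)
  g <- as.numeric(groups == levels(groups)[2])
  Z <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  X <- cbind(g = g, Z)
  if (qr(X)$rank < ncol(X))
    stop_config("group indicator is collinear with the covariates; ",
                "no exchangeable permutation scheme exists")
  cvec <- c(1, numeric(ncol(Z)))

  engine <- ols_t_engine(X, cvec)
  obs <- engine(copes)
  # Freedman-Lane: permute the covariate-residualised data
  Rz <- copes - Z %*% qr.coef(qr(Z), copes)

  thr_t <- if (!is.null(adjacency))
    stats::qt(1 - forming_p / 2, obs$df) else NULL
  obs_cl <- if (!is.null(adjacency))
    find_clusters(abs(obs$t) >= thr_t, adjacency) else NULL

  max_t <- numeric(n_perm)
  exceed <- numeric(length(obs$t))
  max_ext <- if (!is.null(adjacency)) numeric(n_perm) else NULL
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      tb <- engine(Rz[pm, , drop = FALSE])$t
      exceed <- exceed + (abs(tb) >= abs(obs$t))
      max_t[b] <- max(abs(tb))
      if (!is.null(adjacency))
        max_ext[b] <- max(0L, find_clusters(abs(tb) >= thr_t, adjacency)$extent)
    }
  })
  p_unc <- (1 + exceed) / (n_perm + 1)
  p_fwe <- vapply(abs(obs$t), function(ti)
    (1 + sum(max_t >= ti)) / (n_perm + 1), numeric(1))
  p_fwe <- pmax(p_fwe, p_unc)

  labels <- colnames(copes) %||% paste0("roi", seq_len(ncol(copes)))
  tab <- data.frame(roi = labels, t = unname(obs$t),
                    p_uncorrected = p_unc, p_fwe = p_fwe,
                    cluster = NA_integer_, p_cluster = NA_real_,
                    stringsAsFactors = FALSE)
  cl_tab <- NULL
  if (!is.null(adjacency) && nrow(obs_cl) > 0) {
    cl_tab <- obs_cl
    cl_tab$p_corrected <- vapply(cl_tab$extent, function(e)
      (1 + sum(max_ext >= e)) / (n_perm + 1), numeric(1))
    for (i in seq_len(nrow(cl_tab))) {
      tab$cluster[cl_tab$members[[i]]] <- i
      tab$p_cluster[cl_tab$members[[i]]] <- cl_tab$p_corrected[i]
    }
  }
  structure(list(table = tab, clusters = cl_tab, n_perm = n_perm,
                 seed = seed, df = obs$df, forming_p = forming_p,
                 null_max_t = stats::quantile(max_t, c(0.5, 0.95, 0.99))),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %d ROIs, %d permutations (seed %d), df = %d\n",
              nrow(x$table), x$n_perm, x$seed, x$df))
  sig <- x$table[x$table$p_fwe < 0.05, ]
  cat(sprintf("  %d ROI(s) with FWE p < 0.05\n", nrow(sig)))
  if (nrow(sig)) print(sig[, c("roi", "t", "p_uncorrected", "p_fwe")],
                       row.names = FALSE, digits = 3)
  invisible(x)
}

# connected components of the supra-threshold ROI set on an adjacency
# matrix (plain breadth-first search; called once per permutation, so kept
# allocation-light)
find_clusters <- function(above, adjacency) {
  idx <- which(above)
  if (!length(idx))
    return(data.frame(cluster = integer(0), extent = integer(0),
                      members = I(list())))
  sub <- adjacency[idx, idx, drop = FALSE]
  comp <- integer(length(idx))
  cid <- 0L
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(sub[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  members <- split(idx, comp)
  out <- data.frame(cluster = seq_along(members),
                    extent = lengths(members))
  out$members <- I(unname(members))
  out[order(-out$extent), , drop = FALSE]
}

#' Cluster-extent correction of a statistic map
#'
#' Clusters are connected components of the supra-threshold set on the ROI
#' adjacency graph; each observed cluster's corrected p-value is the
#' fraction of null maximum extents at least as large as its extent.
#'
#' @param stat Numeric statistic map (e.g. |t| per ROI).
#' @param adjacency Symmetric logical adjacency matrix.
#' @param forming_threshold Cluster-forming threshold on `stat`.
#' @param null_max_extents Numeric vector of maximum cluster extents under
#'   the null (one per permutation).
#' @return Data frame: `cluster`, `extent`, `members` (list column),
#'   `p_corrected`. Empty (zero rows) when nothing is supra-threshold.
#' @export
cluster_extent_correct <- function(stat, adjacency, forming_threshold,
                                   null_max_extents) {
  cl <- find_clusters(stat >= forming_threshold, adjacency)
  n_perm <- length(null_max_extents)
  cl$p_corrected <- vapply(cl$extent, function(e)
    (1 + sum(null_max_extents >= e)) / (n_perm + 1), numeric(1))
  cl
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate adjustment across ROIs (or maps); a thin,
#' named wrapper so pipeline outputs record which correction produced them.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
fdr_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_config("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Normalise projection-area COPEs to the DRN COPE
#'
#' Divides every ROI's COPE by the DRN COPE, expressing each projection
#' area's response relative to the stimulated nucleus (the study's
#' functional-connectivity measure, invariant to global amplitude scaling).
#' Requires a stable DRN response: `|t_DRN| >= t_floor`.
#'
#' @param copes Cope table (`roi`, `cope`, and `t` if available) or an
#'   `ofmri_glm` fit.
#' @param drn_label ROI label of the dorsal raphe nucleus.
#' @param t_floor Minimum |t| of the DRN COPE (ratio stability).
#' @return Data frame `roi`, `normalized` with the DRN row equal to 1.
#' @export
normalize_to_drn <- function(copes, drn_label = "DRN", t_floor = 2) {
  tab <- cope_table(copes)
  i <- match(drn_label, tab$roi)
  if (is.na(i)) stop_config("DRN ROI '", drn_label, "' not present")
  if (!is.null(tab$t) && is.finite(tab$t[i]) && abs(tab$t[i]) < t_floor)
    stop_config("|t_DRN| = ", signif(abs(tab$t[i]), 3), " below the ",
                t_floor, " floor; normalisation would be unstable")
  if (tab$cope[i] == 0) stop_config("zero DRN COPE; ratio undefined")
  data.frame(roi = tab$roi, normalized = tab$cope / tab$cope[i],
             stringsAsFactors = FALSE)
}
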