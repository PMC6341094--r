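#' Preprocess raw CBV/BOLD ROI time series
#'
#' In order: (1) linear detrend with the slope fitted on non-stimulation
#' volumes only (accounting for intravascular contrast-agent clearance
#' without biasing it by the evoked response), (2) percent-change
#' normalisation against the mean of the pre-first-block baseline volumes,
#' (3) sign inversion if `contrast = "cbv"` (iron-oxide contrast: a CBV
#' increase lowers the raw signal, so inversion makes activation
#' positive-going).
#'
#' @param raw Volumes x ROI matrix of strictly positive raw signals.
#' @param protocol Stimulation protocol.
#' @param contrast `"cbv"` (sign-inverted) or `"bold"`.
#' @param response_tail_s Post-block tail excluded (with the blocks) from
#'   the detrending fit, seconds.
#' @return Object of class `roi_series`: `data` (volumes x ROI, % change),
#'   `volume_interval`, `roi_labels`, `provenance`.
#' @export
preprocess_cbv <- function(raw, protocol, contrast = c("cbv", "bold"),
                           response_tail_s = 16) {
  contrast <- match.arg(contrast)
  raw <- as.matrix(raw)
  if (nrow(raw) != protocol$n_volumes)
    stop_config("raw series rows must equal protocol n_volumes")
  t_vol <- (seq_len(nrow(raw)) - 1) * protocol$volume_interval
  fit_idx <- setdiff(seq_len(nrow(raw)), stim_volumes(protocol, response_tail_s))
  base_idx <- which(t_vol < protocol$block_onsets[1])
  out <- raw
  for (j in seq_len(ncol(raw))) {
    co <- stats::lm.fit(cbind(1, t_vol[fit_idx]), raw[fit_idx, j])$coefficients
    detr <- raw[, j] - (co[1] + co[2] * t_vol) + co[1]  # remove slope, keep level
    b0 <- mean(detr[base_idx])
    if (!is.finite(b0) || b0 <= 0)
      stop_config("non-positive baseline mean in ROI ", j)
    out[, j] <- 100 * (detr - b0) / b0
  }
  if (contrast == "cbv") out <- -out
  structure(list(
    data = out, volume_interval = protocol$volume_interval,
    roi_labels = colnames(raw) %||% paste0("roi", seq_len(ncol(raw))),
    provenance = c("linear detrend (non-stimulation volumes)",
                   sprintf("percent change to baseline (%d volumes)", length(base_idx)),
                   if (contrast == "cbv") "sign inverted (CBV contrast)")),
    class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d volumes x %d ROIs (%% change, TR %g s)\n",
              nrow(x$data), ncol(x$data), x$volume_interval))
  invisible(x)
}

#' Build the first-level GLM design matrix
#'
#' Activity regressors are stimulation boxcars convolved with the gamma HRF
#' on a fine grid, bin-averaged to the volume grid and peak-normalised
#' (pooled: one regressor for all blocks; `per_block = TRUE`: one per
#' block). Each activity regressor is paired with its temporal derivative
#' (finite difference), and orthogonal polynomial drift regressors up to
#' `poly_order` plus a constant complete the design.
#'
#' @param protocol Stimulation protocol.
#' @param hrf HRF model from [gamma_hrf()].
#' @param poly_order Polynomial drift order (0 = constant only).
#' @param per_block One activity regressor per block.
#' @param derivatives Include temporal derivatives.
#' @return Object of class `design_matrix`: `X` (volumes x columns, named),
#'   `activity_cols`, `protocol`, `hrf`, `poly_order`.
#' @export
build_design <- function(protocol, hrf = gamma_hrf(), poly_order = 2,
                         per_block = FALSE, derivatives = TRUE) {
  reg <- block_regressors(protocol, hrf)
  act <- if (per_block) reg else matrix(rowSums(reg), ncol = 1)
  act <- act / max(act)
  colnames(act) <- if (per_block)
    paste0("block", seq_len(ncol(act))) else "activity"
  cols <- list(act)
  if (derivatives) {
    der <- apply(act, 2, function(v) c(0, diff(v)))
    colnames(der) <- paste0(colnames(act), "_deriv")
    cols <- c(cols, list(der))
  }
  n <- protocol$n_volumes
  drift <- matrix(1, n, 1, dimnames = list(NULL, "constant"))
  if (poly_order >= 1) {
    pm <- stats::poly(seq_len(n), degree = poly_order)
    colnames(pm) <- paste0("poly", seq_len(poly_order))
    drift <- cbind(drift, pm)
  }
  X <- do.call(cbind, c(cols, list(drift)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_config("design matrix is rank deficient; collinear column(s): ",
                paste(dep, collapse = ", "))
  }
  structure(list(X = X, activity_cols = colnames(act),
                 protocol = protocol, hrf = hrf, poly_order = poly_order,
                 per_block = per_block),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d columns: %s\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Fit the first-level GLM and extract COPEs
#'
#' Ordinary least squares fit of the design to every ROI time series; the
#' contrast of parameter estimates (COPE) is `c %*% beta` with its standard
#' error and t statistic. Residual diagnostics (lag-1 autocorrelation and
#' the fraction of residual variance at the stimulation frequency) are
#' returned so model adequacy can be inspected.
#'
#' @param series `roi_series` (or a volumes x ROI matrix).
#' @param design `design_matrix`.
#' @param contrast Numeric contrast vector over design columns, or the name
#'   of a single column (default: sum over the activity columns).
#' @return Object of class `ofmri_glm` with `copes` (data frame: `roi`,
#'   `cope`, `se`, `t`), `beta`, `residuals`, `fitted`, `diagnostics`,
#'   `design`, `contrast`, `df`.
#' @export
fit_glm <- function(series, design, contrast = NULL) {
  Y <- if (inherits(series, "roi_series")) series$data else as.matrix(series)
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop_config("design rows must equal series volumes")
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  if (is.null(contrast)) {
    cvec[design$activity_cols] <- 1
  } else if (is.character(contrast)) {
    if (!all(contrast %in% colnames(X)))
      stop_config("unknown contrast column(s)")
    cvec[contrast] <- 1
  } else {
    if (length(contrast) != ncol(X))
      stop_config("contrast length must equal the number of design columns")
    cvec[] <- contrast
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop_config("singular design matrix")
  beta <- qr.coef(qrX, Y)
  fitted <- X %*% beta
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv_c <- drop(chol2inv(qr.R(qrX)) %*% cvec)
  var_c <- sum(cvec * XtXinv_c)
  cope <- drop(crossprod(beta, cvec))
  se <- sqrt(sigma2 * var_c)
  labels <- colnames(Y) %||% paste0("roi", seq_len(ncol(Y)))
  # residual diagnostics: lag-1 autocorrelation, stimulus-locked power
  ac1 <- apply(res, 2, function(r) {
    if (stats::sd(r) < .Machine$double.eps^0.5) return(NA_real_)
    stats::cor(r[-1], r[-length(r)])
  })
  f_stim <- 1 / design$protocol$inter_onset
  tt <- (seq_len(nrow(Y)) - 1) * design$protocol$volume_interval
  sc <- cbind(sin(2 * pi * f_stim * tt), cos(2 * pi * f_stim * tt))
  stim_frac <- apply(res, 2, function(r) {
    fit <- stats::lm.fit(sc, r)
    1 - sum(fit$residuals^2) / sum(r^2)
  })
  structure(list(
    copes = data.frame(roi = labels, cope = unname(cope), se = unname(se),
                       t = unname(cope / se), stringsAsFactors = FALSE),
    beta = beta, residuals = res, fitted = fitted, df = df,
    diagnostics = data.frame(roi = labels, resid_ac1 = unname(ac1),
                             stim_locked_frac = unname(stim_frac)),
    design = design, contrast = cvec), class = "ofmri_glm")
}

#' @export
print.ofmri_glm <- function(x, ...) {
  cat(sprintf("<ofmri_glm> %d ROIs, %d-column design, df = %d\n",
              nrow(x$copes), ncol(x$design$X), x$df))
  cat("contrast:", paste(names(x$contrast)[x$contrast != 0], collapse = " + "), "\n")
  top <- utils::head(x$copes[order(-abs(x$copes$t)), ], 5)
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.ofmri_glm <- function(object, ...) {
  out <- merge(object$copes, object$diagnostics, by = "roi", sort = FALSE)
  class(out) <- c("summary.ofmri_glm", "data.frame")
  out
}

#' @export
coef.ofmri_glm <- function(object, ...) object$beta

#' @export
residuals.ofmri_glm <- function(object, ...) object$residuals

#' @export
fitted.ofmri_glm <- function(object, ...) object$fitted

#' @export
predict.ofmri_glm <- function(object, newdesign = NULL, ...) {
  X <- if (is.null(newdesign)) object$design$X else newdesign$X
  X %*% object$beta
}

#' COPE table accessor
#' @param object An `ofmri_glm` fit.
#' @return Data frame `roi`, `cope`, `se`, `t`.
#' @export
cope_table <- function(object) {
  if (inherits(object, "ofmri_glm")) object$copes
  else if (is.data.frame(object) && all(c("roi", "cope") %in% names(object)))
    object
  else stop_config("not a cope table or ofmri_glm fit")
}

#' Block-wise response amplitudes
#'
#' Fits the per-block design and returns the six per-block COPEs per ROI
#' (in block order), quantifying response adaptation across the train of
#' stimulation blocks.
#'
#' @param series `roi_series` or matrix.
#' @param protocol Stimulation protocol.
#' @param hrf HRF model.
#' @param poly_order Drift order.
#' @return Matrix blocks x ROI of amplitude estimates (%), with attribute
#'   `se` (matching matrix of standard errors).
#' @export
blockwise_amplitudes <- function(series, protocol, hrf = gamma_hrf(),
                                 poly_order = 2) {
  design <- build_design(protocol, hrf, poly_order = poly_order,
                         per_block = TRUE)
  nb <- length(design$activity_cols)
  est <- se <- NULL
  for (b in seq_len(nb)) {
    fit <- fit_glm(series, design, contrast = design$activity_cols[b])
    est <- rbind(est, fit$copes$cope)
    se <- rbind(se, fit$copes$se)
  }
  labels <- if (inherits(series, "roi_series")) series$roi_labels
            else colnames(series)
  dimnames(est) <- dimnames(se) <- list(paste0("block", seq_len(nb)), labels)
  attr(est, "se") <- se
  est
}

#' Frame-wise displacement from rigid-body motion parameters
#'
#' `FD_t = sum |d translations| + radius * sum |d rotations|`, the standard
#' scalar motion summary with rotations converted to arc length on a sphere
#' of `rotation_radius_mm` (5 mm, a mouse-brain radius).
#'
#' @param motion Volumes x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param rotation_radius_mm Rotation-to-arc-length radius, mm.
#' @return List: `fd` (length volumes - 1, mm), `mean`, `sd`.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 5) {
  motion <- as.matrix(motion)
  if (rotation_radius_mm <= 0) stop_config("rotation radius must be positive")
  if (nrow(motion) < 2) stop_config("need at least 2 volumes")
  if (ncol(motion) != 6) stop_config("motion must have 6 columns")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(fd = fd, mean = mean(fd), sd = stats::sd(fd))
}

#' Gaussian smoothing of a volumetric map
#'
#' Separable Gaussian smoothing to a target FWHM in mm. Interior mass is
#' preserved (kernel normalised to sum 1). If the FWHM is below the voxel
#' size the map is returned unchanged with a warning.
#'
#' @param vol 2D or 3D numeric array.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param fwhm_mm Target full width at half maximum, mm.
#' @return Smoothed array of the same dimension.
#' @export
smooth_map <- function(vol, voxel_mm, fwhm_mm = 0.45) {
  if (fwhm_mm < voxel_mm) {
    warning("FWHM below voxel size; returning the map unsmoothed")
    return(vol)
  }
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(-half:half)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    vp <- c(numeric(half), v, numeric(half))
    stats::convolve(vp, k, type = "filter")   # symmetric kernel
  }
  a <- as.array(vol)
  nd <- length(dim(a))
  for (d in seq_len(nd)) {
    res <- apply(a, setdiff(seq_len(nd), d), conv1)
    # apply() puts the convolved dimension first: rotate it back into place
    a <- if (d == 1) array(res, dim(a)) else
      aperm(array(res, dim(a)[c(d, setdiff(seq_len(nd), d))]),
            order(c(d, setdiff(seq_len(nd), d))))
  }
  a
}
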