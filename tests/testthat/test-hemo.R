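test_that("the default HRF peaks near 3 s and is peak-normalised", {
  h <- gamma_hrf()
  k <- h$kernel(0.05)
  expect_equal(max(k), 1)
  expect_equal((which.max(k) - 1) * 0.05, 3, tolerance = 0.1)
  expect_true(all(k >= 0))
})

test_that("design matrices have the documented shapes and properties", {
  p <- short_protocol()
  h <- gamma_hrf()
  d0 <- build_design(p, h, poly_order = 0, per_block = FALSE)
  expect_equal(colnames(d0$X), c("activity", "activity_deriv", "constant"))
  db <- build_design(p, h, poly_order = 2, per_block = TRUE)
  act <- db$X[, paste0("block", 1:6)]
  expect_lt(max(abs(stats::cor(act)[upper.tri(diag(6))])), 0.1)
  # derivative is the finite difference of its activity column
  expect_equal(db$X[, "block1_deriv"], c(0, diff(db$X[, "block1"])))
  # drift columns orthogonal to the constant
  polys <- db$X[, grepl("^poly", colnames(db$X)), drop = FALSE]
  expect_lt(max(abs(colSums(polys))), 1e-9)
  # duplicated column -> singular-design error in the fitter
  d0dup <- d0
  d0dup$X <- cbind(d0$X, activity2 = d0$X[, "activity"])
  y <- matrix(rnorm(p$n_volumes * 2), ncol = 2)
  expect_error(fit_glm(y, d0dup), class = "raphemap_config_error")
})

test_that("preprocessing removes drift, normalises and inverts sign", {
  p <- short_protocol()
  n <- p$n_volumes
  t_min <- (seq_len(n) - 1) * 2 / 60
  # pure linear drift, no response -> ~0 everywhere
  raw <- cbind(a = 1000 * (1 - 0.01 * t_min))
  pp <- preprocess_cbv(raw, p, "cbv")
  expect_lt(max(abs(pp$data)), 1e-9)
  # DRN activation (raw signal dip) comes out positive-going under cbv
  # mode; negative-going projection responses keep their sign
  tr <- exact_truth("control")
  sc <- one_scan(tr)
  expect_equal(max(sc$pp$data[, "DRN"]), 1.5, tolerance = 0.02)
  expect_equal(min(sc$pp$data[, "mPFC"]), -2, tolerance = 0.02)
  # bold mode flips the sign relative to cbv
  pb <- preprocess_cbv(sc$raw, p, "bold")
  expect_equal(pb$data, -sc$pp$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(preprocess_cbv(raw - 2000, p), class = "raphemap_config_error")
})

test_that("noiseless GLM recovery is exact and linear in the amplitude", {
  p <- short_protocol()
  tr <- exact_truth("control")
  sc <- one_scan(tr)
  d <- build_design(p, tr$hrf, poly_order = 2)
  fit <- fit_glm(sc$pp, d, contrast = "activity")
  expect_equal(fit$copes$cope, unname(sc$truth[1, ] * 1), tolerance = 1e-10)
  # scale injected response by alpha -> COPEs scale by alpha
  tr3 <- exact_truth("control")
  tr3$amplitude_schedule <- tr3$amplitude_schedule * 3
  sc3 <- one_scan(tr3)
  fit3 <- fit_glm(sc3$pp, d, contrast = "activity")
  expect_equal(fit3$copes$cope, 3 * fit$copes$cope, tolerance = 1e-9)
  # contrast summing two block regressors doubles a single-block COPE
  db <- build_design(p, tr$hrf, per_block = TRUE, poly_order = 0)
  f1 <- fit_glm(sc$pp, db, contrast = "block1")
  f12 <- fit_glm(sc$pp, db, contrast = c("block1", "block2"))
  expect_equal(f12$copes$cope, 2 * f1$copes$cope, tolerance = 1e-9)
})

test_that("amplitude estimates are unbiased under volume noise", {
  p <- short_protocol()
  tr <- synth_truth("adaptation_short")   # noise sd 0.3%, no subject effect
  co <- simulate_cbv_cohort(p, tr, 40, seed = 13, n_scans = 1)
  d <- build_design(p, tr$hrf, per_block = TRUE)
  err <- vapply(seq_len(40), function(s) {
    pp <- preprocess_cbv(co$scans[[s]][[1]], p, "cbv")
    fit_glm(pp, d, contrast = "block1")$copes$cope[2] -
      co$scan_truth[[s]][[1]][1, 2]
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.02)
})

test_that("model classes expose the standard modelling methods", {
  tr <- exact_truth("control")
  sc <- one_scan(tr)
  d <- build_design(short_protocol(), tr$hrf)
  fit <- fit_glm(sc$pp, d)
  expect_s3_class(fit, "ofmri_glm")
  expect_equal(dim(coef(fit)), c(ncol(d$X), 39))
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(sc$pp$data),
               tolerance = 1e-10)
  expect_equal(predict(fit), fitted(fit))
  sm <- summary(fit)
  expect_true(all(c("cope", "se", "t", "resid_ac1") %in% names(sm)))
  expect_output(print(fit), "ofmri_glm")
  # t = cope / se with positive se
  expect_true(all(fit$copes$se > 0))
  expect_equal(fit$copes$t, fit$copes$cope / fit$copes$se)
})

test_that("explicit detrending and polynomial drift columns agree", {
  p <- short_protocol()
  tr <- synth_truth("control", subject_amp_sd = 0)
  co <- simulate_cbv_cohort(p, tr, 1, seed = 17, n_scans = 1)
  raw <- co$scans[[1]][[1]]
  h <- tr$hrf
  # route 1: preprocess (includes linear detrend), drift order 0
  f1 <- fit_glm(preprocess_cbv(raw, p, "cbv"),
                build_design(p, h, poly_order = 0), contrast = "activity")
  # route 2: percent change + inversion only, linear drift in the design
  base_idx <- seq_len(30)
  pc <- -100 * sweep(sweep(raw, 2, colMeans(raw[base_idx, ]), `-`),
                     2, colMeans(raw[base_idx, ]), `/`)
  f2 <- fit_glm(pc, build_design(p, h, poly_order = 1), contrast = "activity")
  expect_equal(f1$copes$cope, f2$copes$cope, tolerance = 0.01 * 2)
})

test_that("block-wise amplitudes track constant and zero schedules", {
  p <- short_protocol()
  tr <- exact_truth("control")     # flat 2% projections
  sc <- one_scan(tr)
  amps <- blockwise_amplitudes(sc$pp, p, tr$hrf)
  expect_equal(unname(amps[, "mPFC"]), rep(-2, 6), tolerance = 1e-9)
  tr0 <- exact_truth("control")
  tr0$amplitude_schedule[] <- 0
  sc0 <- one_scan(tr0)
  expect_lt(max(abs(blockwise_amplitudes(sc0$pp, p, tr0$hrf))), 1e-9)
})

test_that("frame-wise displacement follows the arc-length formula", {
  expect_equal(framewise_displacement(matrix(0, 5, 6))$fd, rep(0, 4))
  mo <- matrix(0, 3, 6); mo[2, 1] <- 0.01
  expect_equal(framewise_displacement(mo)$fd, c(0.01, 0.01))
  mo2 <- matrix(0, 3, 6); mo2[2, 4] <- 0.002
  expect_equal(framewise_displacement(mo2, rotation_radius_mm = 5)$fd,
               c(0.01, 0.01))
  expect_error(framewise_displacement(mo, rotation_radius_mm = 0),
               class = "raphemap_config_error")
  expect_error(framewise_displacement(mo[1, , drop = FALSE]),
               class = "raphemap_config_error")
})

test_that("gaussian smoothing has the right width and superposes", {
  img <- array(0, c(21, 21, 21)); img[11, 11, 11] <- 1
  sm <- smooth_map(img, voxel_mm = 0.15, fwhm_mm = 0.45)
  expect_equal(sum(sm), 1, tolerance = 1e-6)          # mass preserved
  prof <- sm[, 11, 11]
  expect_equal(sum(prof >= max(prof) / 2) * 0.15, 0.45, tolerance = 0.15 / 2)
  # constant image unchanged in the fully interior region
  cst <- array(2, c(21, 21))
  smc <- smooth_map(cst, 0.15, 0.45)
  expect_equal(smc[10:12, 10:12], cst[10:12, 10:12], tolerance = 1e-6)
  # superposition of two point sources
  i2 <- array(0, c(21, 21, 21)); i2[5, 5, 5] <- 2; i2[15, 15, 15] <- 1
  ia <- array(0, c(21, 21, 21)); ia[5, 5, 5] <- 2
  ib <- array(0, c(21, 21, 21)); ib[15, 15, 15] <- 1
  expect_equal(smooth_map(i2, 0.15, 0.45),
               smooth_map(ia, 0.15, 0.45) + smooth_map(ib, 0.15, 0.45),
               tolerance = 1e-12)
  expect_warning(sm0 <- smooth_map(img, voxel_mm = 0.5, fwhm_mm = 0.45),
                 "unsmoothed")
  expect_identical(sm0, img)
})
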