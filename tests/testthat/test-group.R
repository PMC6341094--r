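test_that("session contrasts implement the scan arithmetic", {
  scans <- rbind(c(1, 10), c(3, 20), c(5, 30))
  expect_equal(session_contrast(scans, "fluoxetine"), c(3, 15))
  expect_equal(session_contrast(scans, "restraint"), c(3, 20))
  same <- rbind(c(2, 2), c(2, 2), c(2, 2))
  expect_equal(session_contrast(same, "fluoxetine"), c(0, 0))
  expect_error(session_contrast(scans[1:2, ], "fluoxetine"),
               class = "raphemap_config_error")
})

test_that("Benjamini-Hochberg step-up reproduces the hand example", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_correct(0.03), 0.03)
  expect_error(fdr_correct(c(0.5, 1.2)), class = "raphemap_config_error")
})

test_that("permutation p-values are deterministic and properly ordered", {
  set.seed(1)
  co <- matrix(rnorm(12 * 8), 12, 8)
  co[7:12, 2] <- co[7:12, 2] + 3
  g <- factor(rep(c("a", "b"), each = 6))
  r1 <- permutation_test(co, g, n_perm = 300, seed = 5)
  r2 <- permutation_test(co, g, n_perm = 300, seed = 5)
  expect_identical(r1$table, r2$table)
  expect_true(all(r1$table$p_fwe >= r1$table$p_uncorrected))
  expect_true(all(r1$table$p_uncorrected >= 0 & r1$table$p_fwe <= 1))
  expect_lt(r1$table$p_fwe[2], 0.05)
  expect_error(permutation_test(co, factor(rep("a", 12)), n_perm = 300),
               class = "raphemap_config_error")
  expect_error(permutation_test(co, g, n_perm = 10),
               class = "raphemap_config_error")
})

test_that("covariates are handled by the Freedman-Lane scheme", {
  set.seed(2)
  n <- 16
  sex <- rep(c("F", "M"), 8)
  g <- factor(rep(c("a", "b"), each = 8))
  co <- matrix(rnorm(n * 6), n, 6) + 2 * (sex == "M")  # sex effect only
  r <- permutation_test(co, g, covariates = data.frame(sex = sex),
                        n_perm = 400, seed = 3)
  expect_gt(min(r$table$p_uncorrected), 0.05)  # no spurious group effect
  # collinear design is rejected
  expect_error(permutation_test(co, g, covariates = data.frame(x = g),
                                n_perm = 400), class = "raphemap_config_error")
})

test_that("null permutation p-values are super-uniform", {
  g <- factor(rep(c("a", "b"), each = 6))
  ps <- unlist(lapply(1:150, function(k) {
    set.seed(k + 1000)
    y <- matrix(rnorm(12 * 4), 12, 4)
    permutation_test(y, g, n_perm = 199, seed = k)$table$p_uncorrected
  }))
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdfv <- vapply(grid, function(x) mean(ps <= x), numeric(1))
  expect_lt(max(ecdfv - grid), 0.04)   # never markedly anti-conservative
})

test_that("cluster extents match brute-force enumeration on a toy graph", {
  # 6-node path graph: components of a thresholded map are runs
  adj <- matrix(FALSE, 6, 6)
  for (i in 1:5) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  brute_max_extent <- function(above) {
    r <- rle(above)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }
  set.seed(4)
  for (k in 1:50) {
    stat <- rnorm(6)
    cl <- cluster_extent_correct(stat, adj, 0, null_max_extents = 1:10)
    expect_equal(if (nrow(cl)) max(cl$extent) else 0L,
                 brute_max_extent(stat >= 0))
  }
  # corrected p bounds
  cl1 <- cluster_extent_correct(c(5, 0, 0, 0, 0, 0), adj, 1,
                                null_max_extents = rep(2, 100))
  expect_equal(cl1$p_corrected, 1)                  # extent 1 never beats 2
  cl5 <- cluster_extent_correct(c(5, 5, 5, 5, 5, 0), adj, 1,
                                null_max_extents = rep(2, 100))
  expect_equal(cl5$p_corrected, 1 / 101)            # extent 5 never reached
  cl0 <- cluster_extent_correct(rep(0, 6), adj, 1, rep(2, 100))
  expect_equal(nrow(cl0), 0)
})

test_that("two-group effects are detected with the documented power", {
  hits <- mean(vapply(1:40, function(k) {
    set.seed(k)
    y <- matrix(rnorm(11 * 6), 11, 6)
    y[8:11, 1] <- y[8:11, 1] + 5          # 5x noise sd, n = 7 vs 4
    g <- factor(c(rep("a", 7), rep("b", 4)))
    permutation_test(y, g, n_perm = 300, seed = k)$table$p_fwe[1] < 0.05
  }, logical(1)))
  expect_gte(hits, 0.9)
})

test_that("DRN normalisation is exact, scale-invariant and guarded", {
  ct <- data.frame(roi = c("DRN", "mPFC"), cope = c(2, -1), t = c(6, -5))
  nm <- normalize_to_drn(ct)
  expect_equal(nm$normalized, c(1, -0.5))
  ct3 <- ct; ct3$cope <- ct3$cope * 3
  expect_equal(normalize_to_drn(ct3)$normalized, nm$normalized)
  weak <- data.frame(roi = c("DRN", "mPFC"), cope = c(0.1, -1), t = c(0.5, -5))
  expect_error(normalize_to_drn(weak), class = "raphemap_config_error")
  expect_error(normalize_to_drn(data.frame(roi = "mPFC", cope = 1)),
               class = "raphemap_config_error")
})

test_that("restraint blunting leaves normalised connectivity unchanged", {
  p <- short_protocol()
  d <- build_design(p, gamma_hrf())
  sc_c <- one_scan(exact_truth("control"))
  tr_s <- exact_truth("restraint")          # every amplitude x 0.5
  sc_s <- one_scan(tr_s)
  n_c <- normalize_to_drn(fit_glm(sc_c$pp, d))
  n_s <- normalize_to_drn(fit_glm(sc_s$pp, d))
  expect_equal(n_s$normalized, n_c$normalized, tolerance = 1e-9)
})
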