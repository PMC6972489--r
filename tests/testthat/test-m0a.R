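make_tissue <- function(pgm, pwm, pcsf, vent = NULL) {
  d <- dim(pgm)
  structure(list(pve_gm = pgm, pve_wm = pwm, pve_csf = pcsf,
                 ventricle_mask = if (is.null(vent)) array(FALSE, d) else vent,
                 brain_mask = (pgm + pwm + pcsf) >= 0.5,
                 voxel_size_mm = c(3.5, 3.5, 5)),
            class = "tissue_maps")
}

test_that("lambda variants: PVE-weighted, brain-average, tissue-specific", {
  d <- c(2, 2, 1)
  t <- make_tissue(array(c(1, 0, 0.5, 0.2), d), array(c(0, 0, 0.3, 0.5), d),
                   array(c(0, 1, 0.2, 0.3), d))
  pve <- lambda_map(t, "pve")
  expect_equal(pve[1, 1, 1], 0.98)                    # pure GM
  expect_equal(pve[2, 1, 1], 1.15)                    # pure CSF
  expect_equal(pve[1, 2, 1], 0.966, tolerance = 1e-12) # 0.5/0.3/0.2 mix
  avg <- lambda_map(t, "avg")
  expect_true(all(avg == 0.5 * 0.98 + 0.5 * 0.82))    # = 0.90
  tsp <- lambda_map(t, "tspec")
  expect_equal(tsp[1, 2, 1], 0.98)                    # GM majority
  expect_equal(tsp[2, 2, 1], 0.82)                    # WM majority
  # tie GM/WM resolved toward GM
  t2 <- make_tissue(array(0.5, c(1, 1, 1)), array(0.5, c(1, 1, 1)),
                    array(0, c(1, 1, 1)))
  expect_equal(lambda_map(t2, "tspec")[1, 1, 1], 0.98)
  # all-zero PVEs have no lambda
  t3 <- make_tissue(array(0, c(1, 1, 1)), array(0, c(1, 1, 1)),
                    array(0, c(1, 1, 1)))
  expect_true(is.na(lambda_map(t3, "pve")[1, 1, 1]))
})

test_that("PVE-weighted lambda stays within the per-tissue extremes", {
  t <- fx_pasl()$ph$tissue
  lam <- lambda_map(t, "pve")
  b <- t$brain_mask
  expect_true(all(lam[b] >= 0.82 - 1e-12 & lam[b] <= 1.15 + 1e-12))
})

test_that("reference-tissue masks follow thresholds and ventricle labels", {
  t <- fx_pasl()$ph$tissue
  restrictive <- build_rt_mask(t, "csf", 0.9, intersect_ventricles = FALSE)
  extensive <- build_rt_mask(t, "csf", 0.6, intersect_ventricles = FALSE)
  expect_lte(sum(restrictive), sum(extensive))
  expect_true(all(extensive[restrictive]))
  vent <- build_rt_mask(t, "csf", 0.9, intersect_ventricles = TRUE)
  expect_true(all(t$ventricle_mask[vent]))
  expect_gt(sum(vent), 0)
  # sharp phantom: a tissue with PVE identically 1 masks its whole region
  ts <- fx_sharp()$tissue
  expect_equal(sum(build_rt_mask(ts, "wm", 0.9)), sum(ts$pve_wm == 1))
  # empty mask errors with a hint
  tm <- make_tissue(array(0.8, c(2, 2, 1)), array(0.2, c(2, 2, 1)),
                    array(0, c(2, 2, 1)))
  expect_error(build_rt_mask(tm, "gm", 0.9), "extensive")
})

test_that("reference-tissue M0a implements the T2*/lambda normalization", {
  d <- c(2, 2, 1)
  t <- make_tissue(array(0, d), array(0, d), array(1, d))
  m0t <- new_m0_map(array(c(100, 110, 90, 100), d), "M0t", "test")
  mask <- array(TRUE, d)
  # TE = 13 ms, CSF: factor e^(13*(1/400 - 1/50)) = 0.79652, lambda 1.15
  opts <- calib_options(te_ms = 13, t2star_blood_ms = 50)
  m0a <- m0a_reference_tissue(m0t, mask, opts, "csf")
  expect_equal(m0a$values, 100 * exp(13 * (1 / 400 - 1 / 50)) / 1.15,
               tolerance = 1e-12)
  expect_equal(m0a$method, "RT-CSF")
  expect_equal(m0a$options$n_mask, 4)
  # TE = 0 removes the T2* factor entirely
  opts0 <- calib_options(te_ms = 0)
  expect_equal(m0a_reference_tissue(m0t, mask, opts0, "csf")$values,
               100 / 1.15, tolerance = 1e-12)
  # matched T2* (WM reference, blood T2* = 50) leaves only the lambda
  opts_wm <- calib_options(te_ms = 19, t2star_blood_ms = 50)
  expect_equal(m0a_reference_tissue(m0t, mask, opts_wm, "wm")$values,
               100 / 0.82, tolerance = 1e-12)
})

test_that("echo-time unit mix-ups are rejected", {
  expect_error(calib_options(te_ms = 0.019), "ms")
  expect_error(calib_options(alpha = 1.2), "alpha")
})

test_that("voxelwise M0a reduces to M0t / lambda at TE = 0 and no smoothing", {
  ph <- fx_sharp()
  t <- ph$tissue
  m0t_meas <- ph$truth$m0t
  m0t <- new_m0_map(m0t_meas, "M0t", "test")
  opts <- calib_options(te_ms = 0, smoothing = "none")
  m0a <- m0a_voxelwise(m0t, t, opts)
  b <- t$brain_mask
  lam <- lambda_map(t, "pve")
  expect_equal(m0a$values[b], (m0t_meas / lam)[b], tolerance = 1e-12)
})

test_that("3x3 median smoothing removes a single-voxel spike", {
  d <- c(9, 9, 1)
  t <- make_tissue(array(1, d), array(0, d), array(0, d))
  vals <- array(100, d)
  vals[5, 5, 1] <- 1000
  m0t <- new_m0_map(vals, "M0t", "test")
  opts <- calib_options(te_ms = 0, smoothing = "3x3", t2star_blood_ms = 60)
  m0a <- m0a_voxelwise(m0t, t, opts)
  expect_equal(m0a$values[5, 5, 1], 100 / 0.98, tolerance = 1e-12)
  expect_equal(m0a$values[2, 2, 1], 100 / 0.98, tolerance = 1e-12)
})

test_that("low-M0a voxels are floored to NA rather than exploding", {
  d <- c(9, 9, 1)
  t <- make_tissue(array(1, d), array(0, d), array(0, d))
  vals <- array(100, d)
  vals[3, 3, 1] <- 1e-4
  m0t <- new_m0_map(vals, "M0t", "test")
  opts <- calib_options(te_ms = 0, smoothing = "none")
  m0a <- m0a_voxelwise(m0t, t, opts)
  expect_true(is.na(m0a$values[3, 3, 1]))
})

test_that("bias estimator returns ~1 on unbiased data and recovers a known field", {
  ph_flat <- fx_sharp()
  m0t_flat <- new_m0_map(ph_flat$truth$m0t * exp(-19 / ph_flat$truth$t2star),
                         "M0t", "test")
  b1 <- estimate_bias_field(m0t_flat, ph_flat$tissue)
  expect_lt(max(abs(b1[ph_flat$tissue$brain_mask] - 1)), 0.02)
  # blurred phantom with a 1.3 peak-to-trough truth field
  ph <- make_phantom(test_spec(), bias_ptt = 1.3)
  m0t_b <- new_m0_map(ph$truth$bias_field * ph$truth$m0t *
                        exp(-19 / ph$truth$t2star), "M0t", "test")
  est <- estimate_bias_field(m0t_b, ph$tissue)
  b <- ph$tissue$brain_mask
  expect_gt(stats::cor(est[b], ph$truth$bias_field[b]), 0.95)
  expect_true(all(est > 0))
  expect_equal(mean(est[b]), 1, tolerance = 1e-9)
  expect_error(estimate_bias_field(array(0, dim(ph$truth$m0t)), ph$tissue),
               "degenerate")
})
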