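test_that("LongTR correction divides by the T1 recovery fraction", {
  ph <- fx_sharp()
  acq <- acq_params("pCASL")
  cal <- simulate_calibration_scan(ph$truth, acq)    # TR = 6 s
  m0t <- m0t_longtr(cal, ph$tissue, t1_correction = TRUE)
  csf <- ph$tissue$pve_csf == 1
  gm <- ph$tissue$pve_gm == 1
  # corrected / raw = 1 / (1 - e^(-6/T1)): CSF 1/0.7522, GM 1/0.9901
  expect_equal(unique(round(m0t$values[csf] / cal$values[csf], 6)),
               round(1 / (1 - exp(-6 / 4.3)), 6))
  expect_equal(unique(round(m0t$values[gm] / cal$values[gm], 6)),
               round(1 / (1 - exp(-6 / 1.3)), 6))
  # with a very long TR the correction is the identity
  acq_inf <- acq; acq_inf$calib_tr_s <- 1e5
  cal_inf <- simulate_calibration_scan(ph$truth, acq_inf)
  m0t_inf <- m0t_longtr(cal_inf, ph$tissue, t1_correction = TRUE)
  expect_equal(m0t_inf$values, cal_inf$values, tolerance = 1e-12)
  # passthrough records the option
  off <- m0t_longtr(cal, ph$tissue, t1_correction = FALSE)
  expect_equal(off$values, cal$values)
  expect_false(off$options$t1_correction)
})

test_that("LongTR refuses dangerously short TRs", {
  ph <- fx_sharp()
  acq <- acq_params("pCASL")
  cal <- simulate_calibration_scan(ph$truth, acq)
  expect_error(m0t_longtr(cal, ph$tissue, t1_correction = TRUE, tr_s = 0.1),
               "20x")
})

test_that("CtrAvg divides by 1 - A e^(-TI/T1) per tissue", {
  ph <- fx_sharp()
  acq <- acq_params("PASL_Q2TIPS", slice_time_ms = 0)
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 1)
  raw <- m0t_ctravg(ds, ph$tissue, ti_s = 2.4, t1_correction = FALSE)
  cor <- m0t_ctravg(ds, ph$tissue, ti_s = 2.4, t1_correction = TRUE, A = 0.9)
  csf <- ph$tissue$pve_csf == 1
  gm <- ph$tissue$pve_gm == 1
  # divisors: CSF 1 - 0.9 e^(-2400/4300) = 0.4849; GM 0.8578
  expect_equal(unique(round(raw$values[csf] / cor$values[csf], 6)),
               round(1 - 0.9 * exp(-2.4 / 4.3), 6))
  expect_equal(unique(round(raw$values[gm] / cor$values[gm], 6)),
               round(1 - 0.9 * exp(-2.4 / 1.3), 6))
  # A = 0 makes the correction the identity at any TI
  a0 <- m0t_ctravg(ds, ph$tissue, ti_s = 0.8, t1_correction = TRUE, A = 0)
  r0 <- m0t_ctravg(ds, ph$tissue, ti_s = 0.8, t1_correction = FALSE)
  expect_equal(a0$values, r0$values, tolerance = 1e-12)
})

test_that("CtrAvg rejects background-suppressed data and unknown TIs", {
  pc <- fx_pcasl()
  expect_error(m0t_ctravg(pc$ds, pc$ph$tissue), "background")
  ds <- fx_pasl()$ds
  expect_error(m0t_ctravg(ds, fx_pasl()$ph$tissue, ti_s = 0.5),
               "not acquired")
})

test_that("saturation-recovery fit recovers (M0t, T1, A) on noiseless curves", {
  tis <- seq(0.4, 2.4, by = 0.2)
  y <- 1000 * (1 - 0.90 * exp(-tis / 1.3))
  fit <- aslcalib:::.satrec_fit_voxel(y, tis, estimate_A = TRUE)
  expect_equal(fit$m0t, 1000, tolerance = 1e-3)
  expect_equal(fit$t1t, 1.3, tolerance = 1e-3)
  expect_equal(fit$A, 0.90, tolerance = 1e-3)
})

test_that("fixing A = 1 on A = 0.9 data biases M0t low", {
  tis <- seq(0.4, 2.4, by = 0.2)
  y <- 1000 * (1 - 0.90 * exp(-tis / 1.3))
  fit <- aslcalib:::.satrec_fit_voxel(y, tis, estimate_A = FALSE)
  expect_lt(fit$m0t, 1000)
  expect_equal(fit$A, 1.0)
})

test_that("a flat control series fits as full recovery (A -> 0)", {
  tis <- seq(0.4, 2.4, by = 0.2)
  fit <- aslcalib:::.satrec_fit_voxel(rep(800, 11), tis, estimate_A = TRUE)
  expect_lt(fit$A, 1e-3)
  expect_equal(fit$m0t, 800, tolerance = 1e-6)
})

test_that("SatRec on the phantom returns exact M0t, T1 and A maps", {
  fx <- fx_pasl()
  brain <- fx$ph$tissue$brain_mask
  m0t_meas <- fx$ph$truth$m0t * exp(-19 / fx$ph$truth$t2star)
  expect_equal(fx$m0t$values[brain], m0t_meas[brain], tolerance = 1e-3)
  expect_equal(fx$satfit$A[brain], rep(0.9, sum(brain)), tolerance = 1e-3)
  expect_equal(fx$satfit$t1t[brain], fx$ph$truth$t1[brain], tolerance = 1e-3)
  expect_equal(fx$m0t$options$A_mean, 0.9, tolerance = 1e-3)
})

test_that("SatRec requires >= 3 TIs and no background suppression", {
  fx <- fx_pasl()
  ds2 <- fx$ds
  keep <- ds2$meta$vol_ti_s %in% c(0.4, 2.4)
  ds2$control <- ds2$control[, , , keep, drop = FALSE]
  ds2$label <- ds2$label[, , , keep, drop = FALSE]
  ds2$meta$vol_ti_s <- ds2$meta$vol_ti_s[keep]
  ds2$meta$vol_repeat <- ds2$meta$vol_repeat[keep]
  expect_error(m0t_satrec(ds2, fx$ph$tissue), "3 distinct")
  expect_error(m0t_satrec(fx_pcasl()$ds), "background")
})

test_that("SatRec and T1-corrected CtrAvg agree in pure-tissue voxels", {
  ph <- fx_sharp()
  acq <- acq_params("PASL_Q2TIPS")
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 3)
  sr <- m0t_satrec(ds, ph$tissue)$m0t
  ca <- m0t_ctravg(ds, ph$tissue, ti_s = 2.4, t1_correction = TRUE, A = 0.9)
  pure <- ph$tissue$pve_gm == 1 | ph$tissue$pve_wm == 1 |
    ph$tissue$pve_csf == 1
  rel <- abs(sr$values[pure] / ca$values[pure] - 1)
  expect_lt(max(rel), 0.01)
})
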