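# Shared fixtures, built lazily and cached for the whole test run. Kinetic
# fitting is the expensive step, so phantoms here are smaller than the
# package default grid; all quantities under test are grid-independent.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

test_spec <- function(grid_shape = c(24L, 24L, 6L), ...)
  phantom_spec(grid_shape = grid_shape, ...)

# End-to-end fixtures use the package-default phantom grid (32 x 32 x 8):
# the 2% round-trip bands are properties of that stated world, and shrinking
# the grid thickens tissue boundaries relative to structure size.

# unbiased noiseless PASL phantom + fitted perfusion maps + SatRec M0t
fx_pasl <- function() fx_get("pasl", function() {
  ph <- make_phantom(phantom_spec(), bias_ptt = 1)
  acq <- acq_params("PASL_Q2TIPS")
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 7L)
  perf <- fit_volume(average_differences(ds), tissue = ph$tissue)
  sat <- m0t_satrec(ds, ph$tissue)
  list(ph = ph, acq = acq, ds = ds, perf = perf, m0t = sat$m0t,
       satfit = sat$fit)
})

# same phantom with a 1.3 peak-to-trough coil bias applied
fx_pasl_biased <- function() fx_get("pasl_biased", function() {
  ph <- make_phantom(phantom_spec(), bias_ptt = 1.3)
  acq <- acq_params("PASL_Q2TIPS")
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 7L)
  perf <- fit_volume(average_differences(ds), tissue = ph$tissue)
  sat <- m0t_satrec(ds, ph$tissue)
  list(ph = ph, acq = acq, ds = ds, perf = perf, m0t = sat$m0t,
       satfit = sat$fit)
})

# zero-slice-time PASL phantom for nominal-TI analytic checks
fx_pasl_st0 <- function() fx_get("pasl_st0", function() {
  ph <- make_phantom(phantom_spec(), bias_ptt = 1)
  acq <- acq_params("PASL_Q2TIPS", slice_time_ms = 0)
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 7L)
  perf <- fit_volume(average_differences(ds), tissue = ph$tissue)
  list(ph = ph, acq = acq, ds = ds, perf = perf)
})

# sharp-boundary (no blur) phantom: every voxel is pure tissue
fx_sharp <- function() fx_get("sharp", function() {
  make_phantom(test_spec(pve_blur_fwhm_mm = 0), bias_ptt = 1)
})

# noiseless pCASL phantom + calibration scan + fit
fx_pcasl <- function() fx_get("pcasl", function() {
  ph <- make_phantom(phantom_spec(), bias_ptt = 1)
  acq <- acq_params("pCASL")
  ds <- simulate_asl_series(ph$truth, ph$tissue, acq, noise_sd = 0, seed = 7L)
  calib <- simulate_calibration_scan(ph$truth, acq)
  perf <- fit_volume(average_differences(ds), tissue = ph$tissue)
  list(ph = ph, acq = acq, ds = ds, calib = calib, perf = perf)
})

# quadrature oracle for the tissue compartment: numerical convolution of the
# labeled-blood delivery with exponential tissue decay (independent of the
# closed forms in the package)
oracle_tissue_signal <- function(t, p, sequence) {
  if (t <= p$att) return(0)
  upper <- min(t, p$att + p$tau)
  c_fun <- if (sequence == "PASL_Q2TIPS") {
    function(s) exp(-s / p$t1_blood)
  } else {
    function(s) rep(exp(-p$att / p$t1_blood), length(s))
  }
  integrand <- function(s) c_fun(s) * exp(-(t - s) / p$t1_tissue)
  2 * p$f_rel * stats::integrate(integrand, p$att, upper,
                                 rel.tol = 1e-10)$value
}

# build a 1-voxel "averaged differences" object for single-curve fitting
one_voxel_diffs <- function(y, t_s, tau_s, sequence = "PASL_Q2TIPS") {
  list(dm = array(y, c(1, 1, 1, length(y))), t_nominal_s = t_s,
       tau_s = tau_s, slice_time_s = 0, sequence = sequence,
       te_ms = 19, alpha = 0.98)
}
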