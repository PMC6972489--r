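test_that("tissue signal vanishes before arrival and without perfusion", {
  p <- kinetic_params(f_rel = 0.01, att = 0.8, tau = 0.75)
  expect_equal(tissue_signal(0.4, p, "PASL_Q2TIPS"), 0)
  expect_equal(tissue_signal(0.5 * p$att, p, "pCASL"), 0)
  p0 <- kinetic_params(f_rel = 0, att = 0.8)
  tt <- seq(0, 4, by = 0.1)
  expect_true(all(tissue_signal(tt, p0, "PASL_Q2TIPS") == 0))
  # decays to zero at long times
  expect_lt(tissue_signal(30, p, "PASL_Q2TIPS"), 1e-8)
  expect_lt(tissue_signal(30, p, "pCASL"), 1e-8)
})

test_that("closed-form tissue signal matches the quadrature oracle", {
  # the worked example first
  p <- kinetic_params(f_rel = 0.01, att = 0.7, tau = 0.75,
                      t1_blood = 1.65, t1_tissue = 1.3)
  expect_equal(tissue_signal(1.5, p, "PASL_Q2TIPS"),
               oracle_tissue_signal(1.5, p, "PASL_Q2TIPS"),
               tolerance = 1e-6)
  # 100 random parameter draws per sequence, fixed seed
  set.seed(42)
  for (sq in c("PASL_Q2TIPS", "pCASL")) {
    for (i in 1:100) {
      p <- kinetic_params(f_rel = runif(1, 0.001, 0.03),
                          att = runif(1, 0.2, 2),
                          tau = runif(1, 0.3, 1.8),
                          t1_blood = runif(1, 1.3, 2),
                          t1_tissue = runif(1, 0.8, 4))
      t <- runif(1, 0, 4)
      expect_equal(tissue_signal(t, p, sq), oracle_tissue_signal(t, p, sq),
                   tolerance = 1e-6)
    }
  }
})

test_that("closed form is stable when tissue and blood T1 coincide", {
  p <- kinetic_params(f_rel = 0.01, att = 0.5, tau = 0.7,
                      t1_blood = 1.65, t1_tissue = 1.65)
  expect_equal(tissue_signal(1.2, p, "PASL_Q2TIPS"),
               oracle_tissue_signal(1.2, p, "PASL_Q2TIPS"),
               tolerance = 1e-8)
})

test_that("arterial compartment is a decaying box-car", {
  p <- kinetic_params(f_rel = 0.01, att = 0.9, abv = 0.01, tau = 0.75,
                      att_art = 0.5)
  expect_equal(arterial_signal(0.45, p, "PASL_Q2TIPS"), 0)
  expect_equal(arterial_signal(1.3, p, "PASL_Q2TIPS"), 0)
  expect_gt(arterial_signal(0.8, p, "PASL_Q2TIPS"), 0)
  p0 <- kinetic_params(f_rel = 0.01, att = 0.9, abv = 0, att_art = 0.5)
  expect_true(all(arterial_signal(seq(0, 3, 0.05), p0, "PASL_Q2TIPS") == 0))
  # undecayed integral = 2 * abv * tau
  pinf <- kinetic_params(f_rel = 0, att = 0.9, abv = 0.01, tau = 0.75,
                         t1_blood = 1e9, att_art = 0.5)
  int <- stats::integrate(function(t) arterial_signal(t, pinf, "PASL_Q2TIPS"),
                          0, 3, rel.tol = 1e-10,
                          subdivisions = 1000, stop.on.error = FALSE)$value
  expect_equal(int, 2 * 0.01 * 0.75, tolerance = 1e-4)
})

test_that("forward signal is the superposition and is linear in amplitudes", {
  p <- kinetic_params(f_rel = 0.012, att = 0.8, abv = 0.008, tau = 0.75,
                      att_art = 0.45)
  tt <- seq(0, 3.5, by = 0.07)
  expect_equal(forward_signal(tt, p, "PASL_Q2TIPS"),
               tissue_signal(tt, p, "PASL_Q2TIPS") +
                 arterial_signal(tt, p, "PASL_Q2TIPS"))
  p2 <- p; p2$f_rel <- 2 * p$f_rel; p2$abv <- 2 * p$abv
  expect_equal(forward_signal(tt, p2, "pCASL"),
               2 * forward_signal(tt, p, "pCASL"), tolerance = 1e-12)
})

test_that("pCASL tail decays at the apparent tissue rate", {
  p <- kinetic_params(f_rel = 0.01, att = 0.7, tau = 1.4, t1_tissue = 1.3)
  tt <- seq(2.3, 3.3, by = 0.25)   # all beyond att + tau = 2.1
  y <- tissue_signal(tt, p, "pCASL")
  slopes <- diff(log(y)) / diff(tt)
  expect_equal(slopes, rep(-1 / 1.3, length(slopes)), tolerance = 1e-10)
})

test_that("signal at early times never increases with arterial transit time", {
  set.seed(1)
  for (i in 1:25) {
    t0 <- runif(1, 0.3, 1.5)
    atts <- sort(runif(2, 0.2, 2.5))
    y <- vapply(atts, function(a) {
      p <- kinetic_params(f_rel = 0.01, att = a, tau = 0.75)
      tissue_signal(t0, p, "PASL_Q2TIPS")
    }, 0)
    expect_lte(y[2], y[1] + 1e-12)
  }
})

test_that("noiseless single-curve refit recovers the generating parameters", {
  tis <- seq(0.4, 2.4, by = 0.2)
  tau <- pasl_bolus_duration(tis)
  p <- kinetic_params(f_rel = 4.2, att = 0.73, abv = 0.05, tau = NA,
                      att_art = 0.41)
  y <- vapply(seq_along(tis), function(m) {
    pm <- p; pm$tau <- tau[m]
    forward_signal(tis[m], pm, "PASL_Q2TIPS")
  }, 0)
  perf <- fit_volume(one_voxel_diffs(y, tis, tau), t1_tissue = 1.3)
  expect_equal(perf$cbf_rel[1, 1, 1], 4.2, tolerance = 1e-4)
  expect_equal(perf$att[1, 1, 1], 0.73, tolerance = 1e-3)
  expect_equal(perf$abv[1, 1, 1], 0.05, tolerance = 1e-3)
  expect_true(perf$converged[1, 1, 1])
})

test_that("all-zero voxels are flagged, with perfusion at the lower bound", {
  tis <- seq(0.4, 2.4, by = 0.2)
  perf <- fit_volume(one_voxel_diffs(rep(0, 11), tis,
                                     pasl_bolus_duration(tis)))
  expect_equal(perf$cbf_rel[1, 1, 1], 0)
  expect_false(perf$converged[1, 1, 1])
})

test_that("fewer than 4 time points is rejected", {
  expect_error(fit_volume(one_voxel_diffs(c(1, 2, 3), c(0.5, 1, 1.5),
                                          rep(0.75, 3))),
               "4 distinct")
})

test_that("median perfusion bias stays below 5% at SNR ~ 10", {
  tis <- seq(0.4, 2.4, by = 0.2)
  tau <- pasl_bolus_duration(tis)
  p <- kinetic_params(f_rel = 4.2, att = 0.7, abv = 0, tau = NA)
  y0 <- vapply(seq_along(tis), function(m) {
    pm <- p; pm$tau <- tau[m]
    forward_signal(tis[m], pm, "PASL_Q2TIPS")
  }, 0)
  noise_sd <- max(y0) / 10
  set.seed(99)
  fits <- replicate(50, {
    y <- y0 + rnorm(length(y0), 0, noise_sd)
    fit_volume(one_voxel_diffs(y, tis, tau), t1_tissue = 1.3)$cbf_rel[1, 1, 1]
  })
  expect_lt(abs(median(fits) / 4.2 - 1), 0.05)
})
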