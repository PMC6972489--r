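# Forward simulation of ASL control/label series and calibration scans from
# the digital phantom's ground truth.

# Parameter-vectorised tissue kernel: t scalar (or vector recycled against the
# voxel vectors), att / t1t voxel vectors. Same closed forms as
# .tissue_kernel, needed because simulation varies parameters across voxels
# at a fixed acquisition time.
.kernel_vox <- function(t, att, tau, t1b, t1t, sequence) {
  u <- pmin(t, att + tau)
  on <- t > att
  out <- numeric(length(att))
  if (sequence == "PASL_Q2TIPS") {
    k <- 1 / t1t - 1 / t1b
    small <- abs(k) < 1e-8
    v <- exp(-t / t1t) * (exp(k * u) - exp(k * att)) /
      ifelse(small, 1, k)
    v[small] <- (exp(-t / t1t) * (u - att))[small]
    out <- ifelse(on, v, 0)
  } else {
    v <- exp(-att / t1b) * t1t *
      (exp(-(t - u) / t1t) - exp(-(t - att) / t1t))
    out <- ifelse(on, v, 0)
  }
  out
}

.arterial_vox <- function(t, atta, tau, t1b, sequence) {
  inside <- t >= atta & t < atta + tau
  dec <- if (sequence == "PASL_Q2TIPS") exp(-t / t1b) else exp(-atta / t1b)
  ifelse(inside, dec, 0)
}

#' Simulate a multi-TI/PLD ASL control-label series
#'
#' Forward-simulates the acquired 4D control and label series from phantom
#' ground truth under the extended kinetic model (tissue + arterial
#' compartments).
#'
#' The control image at effective time `t_eff = nominal + (slice-1) *
#' slice_time` is `bias * M0t * exp(-TE/T2*_t) * (1 - A * exp(-t_eff/T1))`
#' for the presaturation (PASL) flavour, or the steady-state magnitude
#' `bias * M0t * exp(-TE/T2*_t) * (1 - exp(-TR/T1))` scaled by the static
#' background-suppression factor for the pCASL flavour. The label image is
#' the control minus `bias * M0a * alpha * forward-model` difference signal,
#' where `M0a = m0_blood * exp(-TE/T2*_a)`; attenuation of the labeled bolus
#' by background suppression is conventionally folded into `alpha`.
#' Independent Gaussian noise is added per volume.
#'
#' @param truth,tissue Ground truth and tissue maps from [make_phantom()].
#' @param acq An [acq_params()] object.
#' @param noise_sd Gaussian noise standard deviation in signal units (>= 0).
#' @param seed Integer seed for the noise stream.
#' @param t2star_blood_ms T2* of arterial blood, ms.
#' @return Object of class `asl_dataset`: 4D `control` and `label` arrays
#'   (x, y, z, volume) plus a `meta` list recording sequence, per-volume
#'   nominal times `vol_ti_s`, repeats, bolus durations, slice time, TE, TR,
#'   alpha, presaturation efficiency A and background-suppression settings.
#' @export
simulate_asl_series <- function(truth, tissue, acq, noise_sd = 0, seed = 1L,
                                t2star_blood_ms = 50) {
  stopifnot(inherits(truth, "ground_truth"), inherits(tissue, "tissue_maps"))
  .check_same_grid(truth$m0t, tissue$pve_gm, "truth and tissue")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  d <- dim(truth$m0t)
  nti <- length(acq$ti_or_pld_s)
  nvol <- nti * acq$n_repeats
  st_s <- acq$slice_time_ms / 1000
  te_fac_t <- exp(-acq$te_ms / truth$t2star)
  m0a_sig <- truth$m0_blood * exp(-acq$te_ms / t2star_blood_ms)
  f_map <- truth$cbf / 6000              # mL/100g/min -> 1/s

  control <- array(0, c(d, nvol))
  label <- array(0, c(d, nvol))
  vol_ti <- rep(acq$ti_or_pld_s, each = acq$n_repeats)
  bolus <- if (acq$sequence == "PASL_Q2TIPS")
    pasl_bolus_duration(vol_ti) else rep(acq$label_duration_s, nvol)

  set.seed(as.integer(seed))
  t1b <- 1.65
  for (v in seq_len(nvol)) {
    ti <- vol_ti[v]
    tau_v <- bolus[v]
    for (z in seq_len(d[3])) {
      teff <- ti + (z - 1) * st_s
      m0t_sl <- truth$m0t[, , z] * te_fac_t[, , z] * truth$bias_field[, , z]
      if (acq$sequence == "PASL_Q2TIPS") {
        rec <- 1 - truth$presat_A * exp(-teff / truth$t1[, , z])
        stat <- m0t_sl * rec
        tmod <- teff
      } else {
        rec <- 1 - exp(-acq$tr_s / truth$t1[, , z])
        stat <- m0t_sl * rec *
          (if (acq$background_suppression) acq$bs_factor else 1)
        tmod <- acq$label_duration_s + teff
      }
      att <- as.vector(truth$att[, , z])
      t1t <- as.vector(truth$t1[, , z])
      atta <- as.vector(truth$att_art[, , z])
      dm <- 2 * as.vector(f_map[, , z]) *
        .kernel_vox(tmod, att, tau_v, t1b, t1t, acq$sequence) +
        2 * as.vector(truth$abv[, , z]) *
        .arterial_vox(tmod, atta, tau_v, t1b, acq$sequence)
      dm <- matrix(dm, d[1], d[2]) * m0a_sig * acq$alpha *
        truth$bias_field[, , z]
      control[, , z, v] <- stat
      label[, , z, v] <- stat - dm
    }
  }
  if (noise_sd > 0) {
    control <- control + array(stats::rnorm(length(control), 0, noise_sd),
                               dim(control))
    label <- label + array(stats::rnorm(length(label), 0, noise_sd),
                           dim(label))
  }
  meta <- list(sequence = acq$sequence, vol_ti_s = vol_ti,
               vol_repeat = rep(seq_len(acq$n_repeats), times = nti),
               bolus_s = bolus, slice_time_ms = acq$slice_time_ms,
               te_ms = acq$te_ms, tr_s = acq$tr_s, alpha = acq$alpha,
               A = truth$presat_A,
               label_duration_s = acq$label_duration_s,
               background_suppression = acq$background_suppression,
               bs_factor = if (acq$background_suppression) acq$bs_factor else 1,
               t2star_blood_ms = t2star_blood_ms,
               noise_sd = noise_sd, seed = as.integer(seed))
  structure(list(control = control, label = label, meta = meta),
            class = "asl_dataset")
}

#' @export
print.asl_dataset <- function(x, ...) {
  cat("<asl_dataset> ", x$meta$sequence, ", grid ",
      paste(dim(x$control)[1:3], collapse = "x"), ", ",
      dim(x$control)[4], " volumes (",
      length(unique(x$meta$vol_ti_s)), " times x ",
      max(x$meta$vol_repeat), " repeats)\n", sep = "")
  invisible(x)
}

#' Simulate the separate long-TR calibration scan
#'
#' A proton-density-weighted reference image with no labeling and no
#' background suppression: voxelwise
#' `bias * M0t * exp(-TE/T2*_t) * (1 - exp(-TR/T1))` plus Gaussian noise.
#'
#' @inheritParams simulate_asl_series
#' @return An `m0_map` of kind `"M0t_raw"` whose options record `calib_tr_s`.
#' @export
simulate_calibration_scan <- function(truth, acq, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(acq$calib_tr_s) || acq$calib_tr_s <= 0)
    stop("acq$calib_tr_s must be a positive calibration TR in seconds")
  te_fac <- exp(-acq$te_ms / truth$t2star)
  vals <- truth$bias_field * truth$m0t * te_fac *
    (1 - exp(-acq$calib_tr_s / truth$t1))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim(vals))
  }
  new_m0_map(vals, kind = "M0t_raw", method = "LongTR_raw",
             options = list(calib_tr_s = acq$calib_tr_s, te_ms = acq$te_ms,
                            noise_sd = noise_sd, seed = as.integer(seed)))
}
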