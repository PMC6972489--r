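#' Construct an M0 map container
#'
#' Container for tissue (M0t) or arterial (M0a) equilibrium-magnetization
#' maps; `values` is a 3D array, or a scalar for reference-tissue M0a. Full
#' method/option provenance travels with the object.
#'
#' @param values 3D array or scalar, signal units.
#' @param kind `"M0t"`, `"M0a"` or `"M0t_raw"` (uncorrected scan).
#' @param method Label of the generating method, e.g. `"SatRec"`,
#'   `"CtrAvg"`, `"LongTR"`, `"RT-CSF"`, `"Voxel"`.
#' @param options List of options used (recorded verbatim).
#' @return Object of class `m0_map`.
#' @export
new_m0_map <- function(values, kind, method, options = list()) {
  structure(list(values = values, kind = kind, method = method,
                 options = options),
            class = "m0_map")
}

#' @export
print.m0_map <- function(x, ...) {
  dd <- if (length(x$values) == 1) "scalar"
        else paste(dim(x$values), collapse = "x")
  cat("<m0_map> kind=", x$kind, " method=", x$method, " (", dd, ")\n",
      sep = "")
  invisible(x)
}

#' M0t from a separate long-TR calibration scan (LongTR)
#'
#' Corrects the long-TR proton-density scan for incomplete T1 relaxation at
#' its TR: `M0t(i) = S(i) / (1 - exp(-TR / T1_t(i)))`, with the tissue T1 of
#' each voxel taken as the PVE-weighted combination of the per-tissue
#' constants. With `t1_correction = FALSE` the scan is passed through
#' unchanged (the option under comparison).
#'
#' @param calib `m0_map` holding the raw calibration scan (see
#'   [simulate_calibration_scan()]).
#' @param tissue `tissue_maps` supplying PVE maps.
#' @param t1_correction Logical, default `TRUE`.
#' @param tr_s Calibration TR in seconds (defaults to the scan's recorded
#'   `calib_tr_s`).
#' @param constants Tissue constants.
#' @return `m0_map` of kind `"M0t"`, method `"LongTR"`.
#' @export
m0t_longtr <- function(calib, tissue, t1_correction = TRUE, tr_s = NULL,
                       constants = asl_tissue_constants()) {
  stopifnot(inherits(calib, "m0_map"), inherits(tissue, "tissue_maps"))
  if (is.null(tr_s)) tr_s <- calib$options$calib_tr_s
  if (is.null(tr_s) || tr_s <= 0) stop("tr_s must be a positive TR in seconds")
  vals <- calib$values
  if (t1_correction) {
    t1 <- pve_weighted_map(tissue, constants$t1, fill = NA_real_)
    fac <- 1 - exp(-tr_s / t1)
    brain <- tissue$brain_mask
    if (any(fac[brain] < 0.05, na.rm = TRUE))
      stop("TR = ", tr_s, " s is too short: T1 correction would amplify ",
           "signal by more than 20x in some voxels")
    vals <- ifelse(brain, vals / fac, vals)
  }
  new_m0_map(vals, kind = "M0t", method = "LongTR",
             options = list(t1_correction = t1_correction, tr_s = tr_s))
}

#' M0t from averaged control images at a fixed TI (CtrAvg)
#'
#' Averages the control images at the chosen TI across repeats and, when
#' requested, corrects for incomplete saturation recovery during TI:
#' `M0t(i) = M_ctrl(i) / (1 - A * exp(-t_eff / T1_t(i)))`, using the
#' slice-time-corrected effective time of each slice and the PVE-weighted
#' tissue T1. The presaturation efficiency defaults to A = 0.90, the
#' approximate average recovered by the saturation-recovery fit on this kind
#' of sequence.
#'
#' @param ds `asl_dataset` (must not be background-suppressed).
#' @param tissue `tissue_maps`.
#' @param ti_s TI whose controls are averaged, s; must match an acquired TI
#'   (default: the longest acquired TI, approximately 2.4 s on the reference
#'   schedule; the short-TI comparison option is approximately 0.8 s).
#' @param t1_correction Logical, default `TRUE`.
#' @param A Presaturation efficiency used in the correction, default 0.90
#'   (the `A = 1` option corresponds to assuming perfect saturation).
#' @param constants Tissue constants.
#' @return `m0_map` of kind `"M0t"`, method `"CtrAvg"`.
#' @export
m0t_ctravg <- function(ds, tissue, ti_s = NULL, t1_correction = TRUE,
                       A = 0.90, constants = asl_tissue_constants()) {
  stopifnot(inherits(ds, "asl_dataset"), inherits(tissue, "tissue_maps"))
  if (isTRUE(ds$meta$background_suppression))
    stop("control averaging requires a sequence without background ",
         "suppression: the static tissue signal in these controls is ",
         "attenuated and cannot serve as M0t")
  tis <- unique(ds$meta$vol_ti_s)
  if (is.null(ti_s)) ti_s <- max(tis)
  sel_ti <- tis[which.min(abs(tis - ti_s))]
  if (abs(sel_ti - ti_s) > 1e-6)
    stop("ti_s = ", ti_s, " s was not acquired; available: ",
         paste(signif(tis, 4), collapse = ", "))
  vols <- which(ds$meta$vol_ti_s == sel_ti)
  d <- dim(ds$control)[1:3]
  avg <- array(0, d)
  for (v in vols) avg <- avg + ds$control[, , , v]
  avg <- avg / length(vols)
  if (t1_correction) {
    t1 <- pve_weighted_map(tissue, constants$t1, fill = NA_real_)
    st_s <- ds$meta$slice_time_ms / 1000
    for (z in seq_len(d[3])) {
      teff <- sel_ti + (z - 1) * st_s
      fac <- 1 - A * exp(-teff / t1[, , z])
      sl <- avg[, , z]
      brain <- tissue$brain_mask[, , z]
      sl[brain] <- sl[brain] / fac[brain]
      avg[, , z] <- sl
    }
  }
  new_m0_map(avg, kind = "M0t", method = "CtrAvg",
             options = list(ti_s = sel_ti, t1_correction = t1_correction,
                            A = A))
}

#' M0t from voxelwise saturation-recovery fitting (SatRec)
#'
#' Fits `M_ctrl(t_eff) = M0t * (1 - A * exp(-t_eff / T1t))` to the repeat-
#' averaged control images across TIs at each voxel (slice-time-corrected
#' effective times), estimating M0t, the tissue T1 and, optionally, the
#' presaturation efficiency A. With `estimate_A = FALSE`, A is fixed at 1
#' (the "perfect saturation" comparison option). The fitted T1t map is also
#' useful downstream (tissue contrast, lambda weighting checks).
#'
#' Bounded quasi-Newton least squares per voxel, initialised at
#' (max signal, 1.3 s, 0.9); T1 is constrained to (0.2, 6) s and A to
#' [0, 1.2]. Non-converged voxels are flagged, not dropped.
#'
#' @param ds `asl_dataset` from a presaturation sequence with >= 3 TIs.
#' @param tissue Optional `tissue_maps`; restricts fitting to the brain mask.
#' @param estimate_A Logical, default `TRUE`.
#' @return List with `m0t` (an `m0_map`, method `"SatRec"`) and `fit`
#'   (class `satrec_fit`: arrays `m0t`, `t1t`, `A`, `rss`, `converged`).
#' @export
m0t_satrec <- function(ds, tissue = NULL, estimate_A = TRUE) {
  stopifnot(inherits(ds, "asl_dataset"))
  if (isTRUE(ds$meta$background_suppression))
    stop("saturation-recovery M0t requires a presaturation sequence ",
         "without background suppression")
  tis <- unique(ds$meta$vol_ti_s)
  if (length(tis) < 3)
    stop("saturation-recovery fitting needs at least 3 distinct TIs")
  d <- dim(ds$control)[1:3]
  # repeat-averaged control per TI
  ctrl <- array(0, c(d, length(tis)))
  for (i in seq_along(tis)) {
    vols <- which(ds$meta$vol_ti_s == tis[i])
    acc <- array(0, d)
    for (v in vols) acc <- acc + ds$control[, , , v]
    ctrl[, , , i] <- acc / length(vols)
  }
  mask <- if (!is.null(tissue)) tissue$brain_mask else array(TRUE, d)
  st_s <- ds$meta$slice_time_ms / 1000

  m0 <- array(NA_real_, d); t1 <- array(NA_real_, d)
  Am <- array(NA_real_, d); rss <- array(NA_real_, d)
  conv <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    teff <- tis + (z - 1) * st_s
    idx <- which(matrix(mask[, , z], d[1], d[2]), arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      y <- ctrl[i, j, z, ]
      fit <- .satrec_fit_voxel(y, teff, estimate_A)
      m0[i, j, z] <- fit$m0t; t1[i, j, z] <- fit$t1t
      Am[i, j, z] <- fit$A; rss[i, j, z] <- fit$rss
      conv[i, j, z] <- fit$converged
    }
  }
  sat <- structure(list(m0t = m0, t1t = t1, A = Am, rss = rss,
                        converged = conv),
                   class = "satrec_fit")
  m0map <- new_m0_map(m0, kind = "M0t", method = "SatRec",
                      options = list(estimate_A = estimate_A,
                                     A_mean = mean(Am[mask], na.rm = TRUE)))
  list(m0t = m0map, fit = sat)
}

# One-voxel saturation-recovery fit; y = signal at effective times t.
.satrec_fit_voxel <- function(y, t, estimate_A) {
  if (all(abs(y) < 1e-12))
    return(list(m0t = 0, t1t = NA_real_, A = NA_real_, rss = 0,
                converged = FALSE))
  model <- function(p) p[1] * (1 - p[3] * exp(-t / p[2]))
  if (estimate_A) {
    obj <- function(p) sum((y - model(p))^2)
    init <- c(max(y), 1.3, 0.9)
    lo <- c(0, 0.2, 0); hi <- c(Inf, 6, 1.2)
  } else {
    obj <- function(p) sum((y - p[1] * (1 - exp(-t / p[2])))^2)
    init <- c(max(y), 1.3)
    lo <- c(0, 0.2); hi <- c(Inf, 6)
  }
  op <- stats::optim(init, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                     control = list(factr = 1e4, maxit = 500))
  p <- op$par
  if (!estimate_A) p <- c(p, 1.0)
  list(m0t = p[1], t1t = p[2], A = p[3], rss = op$value,
       converged = op$convergence == 0)
}
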