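#' Partition-coefficient map
#'
#' Builds the per-voxel brain--blood water partition coefficient lambda used
#' by the voxelwise M0a derivation, in one of three variants:
#' \describe{
#'   \item{pve}{PVE-weighted average:
#'     `lambda_GM*PVE_GM + lambda_WM*PVE_WM + lambda_CSF*PVE_CSF` (default).}
#'   \item{avg}{single brain-average constant
#'     `0.5*lambda_GM + 0.5*lambda_WM = 0.90` everywhere.}
#'   \item{tspec}{tissue-specific: the lambda of the majority tissue in each
#'     voxel (ties resolved GM > WM > CSF).}
#' }
#' Voxels with all-zero PVEs have no defined lambda and are returned as `NA`
#' (they are outside the usable brain mask).
#'
#' @param tissue `tissue_maps`.
#' @param variant `"pve"`, `"avg"` or `"tspec"`.
#' @param constants Tissue constants.
#' @return 3D array of lambda values (mL/g), `NA` outside the brain.
#' @export
lambda_map <- function(tissue, variant = c("pve", "avg", "tspec"),
                       constants = asl_tissue_constants()) {
  variant <- match.arg(variant)
  lam <- constants$lambda
  d <- dim(tissue$pve_gm)
  s <- tissue$pve_gm + tissue$pve_wm + tissue$pve_csf
  defined <- s > 0
  out <- array(NA_real_, d)
  if (variant == "pve") {
    v <- tissue$pve_gm * lam[["gm"]] + tissue$pve_wm * lam[["wm"]] +
      tissue$pve_csf * lam[["csf"]]
    out[defined] <- v[defined]
  } else if (variant == "avg") {
    out[defined] <- 0.5 * lam[["gm"]] + 0.5 * lam[["wm"]]
  } else {
    # majority tissue; which.max returns the first maximum, and the stacking
    # order GM, WM, CSF implements the tie-break priority
    stack <- cbind(as.vector(tissue$pve_gm), as.vector(tissue$pve_wm),
                   as.vector(tissue$pve_csf))
    maj <- max.col(stack, ties.method = "first")
    v <- c(lam[["gm"]], lam[["wm"]], lam[["csf"]])[maj]
    out[defined] <- v[defined]
  }
  out
}

#' Reference-tissue mask
#'
#' Thresholds a tissue PVE map at the restrictive (0.9) or extensive (0.6)
#' level; for CSF the mask may additionally be intersected with the phantom's
#' ventricle labels (the stand-in for an atlas-derived lateral-ventricle
#' mask), giving the restrictive/intermediate CSF variants.
#'
#' @param tissue `tissue_maps`.
#' @param tissue_kind `"csf"`, `"wm"` or `"gm"`.
#' @param pve_threshold 0.9 (restrictive) or 0.6 (extensive); other values
#'   are allowed but off-grid.
#' @param intersect_ventricles Logical; CSF only.
#' @return Logical 3D array; its attribute `n_voxels` records the count.
#' @export
build_rt_mask <- function(tissue, tissue_kind = c("csf", "wm", "gm"),
                          pve_threshold = 0.9,
                          intersect_ventricles = (tissue_kind == "csf")) {
  tissue_kind <- match.arg(tissue_kind)
  pve <- switch(tissue_kind, csf = tissue$pve_csf, wm = tissue$pve_wm,
                gm = tissue$pve_gm)
  mask <- pve >= pve_threshold
  if (tissue_kind == "csf" && isTRUE(intersect_ventricles))
    mask <- mask & tissue$ventricle_mask
  if (!any(mask))
    stop("empty ", toupper(tissue_kind), " reference mask at threshold ",
         pve_threshold, "; consider the extensive option (threshold 0.6",
         if (tissue_kind == "csf") ", no ventricle intersection", ")")
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

#' Estimate the coil-sensitivity bias field from an M0t map
#'
#' Approximates the smooth multiplicative receive-coil profile directly from
#' the data, in the spirit of segmentation-based bias estimators: each
#' voxel's expected intensity is predicted (up to one global scale) from its
#' tissue composition, `lambda_pve * exp(-TE / T2*_pve)`, and the log-ratio
#' of observed to predicted intensity is fit with a third-order polynomial
#' surface over the brain. The result is strictly positive, smooth, and
#' normalised to mean 1 over the brain. On perfectly uniform (unbiased)
#' input the field is 1 everywhere.
#'
#' The prediction assumes the M0t map is free of residual saturation
#' effects; M0t maps produced without T1 correction degrade the estimate
#' (as they do for segmentation-based estimators on real data).
#'
#' @param m0t `m0_map` (or bare 3D array) of tissue magnetization.
#' @param tissue `tissue_maps` providing PVEs and the brain mask.
#' @param opts [calib_options()] supplying TE and the tissue constants.
#' @return 3D array: multiplicative bias field, 1 outside the brain.
#' @export
estimate_bias_field <- function(m0t, tissue, opts = calib_options()) {
  vals <- if (inherits(m0t, "m0_map")) m0t$values else m0t
  .check_same_grid(vals, tissue$pve_gm, "m0t and tissue")
  brain <- tissue$brain_mask & is.finite(vals) & vals > 0
  if (sum(brain) < 20)
    stop("degenerate M0t input: no usable positive voxels")
  d <- dim(vals)
  k <- opts$constants
  lam <- pve_weighted_map(tissue, k$lambda, fill = NA_real_)
  t2s <- pve_weighted_map(tissue, k$t2star, fill = NA_real_)
  pred <- lam * exp(-opts$te_ms / t2s)
  ok <- brain & is.finite(pred) & pred > 0
  co <- .norm_coords(d)
  X <- cbind(1, stats::poly(cbind(as.vector(co$x)[ok], as.vector(co$y)[ok],
                                  as.vector(co$z)[ok]),
                            degree = 3, raw = TRUE))
  ratio <- log(vals[ok] / pred[ok])
  fit <- stats::lm.fit(X, ratio)
  bias <- array(1, d)
  bias[ok] <- exp(drop(X %*% fit$coefficients))
  bias[brain & !ok] <- 1
  bias[brain] <- bias[brain] / mean(bias[brain])
  bias
}

#' Apply coil-sensitivity correction to a map
#'
#' Divides a volume (or `m0_map`) by a multiplicative bias field inside the
#' brain mask.
#'
#' @param x `m0_map` or 3D array.
#' @param bias Bias field from [estimate_bias_field()] (or ground truth).
#' @param tissue `tissue_maps` for the brain mask.
#' @return Same type as `x`.
#' @export
correct_bias <- function(x, bias, tissue) {
  fix <- function(v) {
    v[tissue$brain_mask] <- v[tissue$brain_mask] / bias[tissue$brain_mask]
    v
  }
  if (inherits(x, "m0_map")) {
    x$values <- fix(x$values)
    x$options$bias_corrected <- TRUE
    x
  } else fix(x)
}

#' Physical width of a median-smoothing kernel
#'
#' In-plane physical extent of the named kernel option: kernel voxels times
#' the in-plane voxel size (e.g. 3 x 3.5 mm = 10.5 mm for the default
#' `"3x3"` kernel).
#'
#' @param smoothing `"3x3"`, `"5x5"` or `"none"`.
#' @param voxel_size_mm Voxel size 3-vector, mm.
#' @return Width in mm (0 for `"none"`).
#' @export
smoothing_fwhm_mm <- function(smoothing = c("3x3", "5x5", "none"),
                              voxel_size_mm = c(3.5, 3.5, 5.0)) {
  smoothing <- match.arg(smoothing)
  k <- switch(smoothing, "3x3" = 3, "5x5" = 5, none = 0)
  k * voxel_size_mm[1]
}

#' Reference-tissue M0a (scalar)
#'
#' Computes the single arterial-blood equilibrium magnetization value from
#' the mean M0t over a homogeneous reference region:
#' `M0a = <M0t>_rt * exp(TE * (1/T2*_rt - 1/T2*_a)) / lambda_rt`,
#' with the reference tissue's T2* and lambda and the arterial-blood T2*.
#' Bias correction, when requested, must be applied to the M0t map before
#' this call (see [correct_bias()]).
#'
#' @param m0t `m0_map` of kind `"M0t"`.
#' @param mask Logical 3D mask from [build_rt_mask()].
#' @param opts [calib_options()] (TE in ms; T2* values in ms).
#' @param tissue_kind `"csf"`, `"wm"` or `"gm"`.
#' @return `m0_map` with scalar `values`, kind `"M0a"`,
#'   method `"RT-<tissue>"`.
#' @export
m0a_reference_tissue <- function(m0t, mask, opts = calib_options(),
                                 tissue_kind = c("csf", "wm", "gm")) {
  tissue_kind <- match.arg(tissue_kind)
  stopifnot(inherits(m0t, "m0_map"))
  if (!any(mask)) stop("reference-tissue mask is empty")
  k <- opts$constants
  t2_rt <- k$t2star[[tissue_kind]]
  lam_rt <- k$lambda[[tissue_kind]]
  mean_m0t <- mean(m0t$values[mask], na.rm = TRUE)
  m0a <- mean_m0t * exp(opts$te_ms * (1 / t2_rt - 1 / opts$t2star_blood_ms)) /
    lam_rt
  new_m0_map(m0a, kind = "M0a",
             method = paste0("RT-", toupper(tissue_kind)),
             options = list(tissue_kind = tissue_kind,
                            n_mask = sum(mask), te_ms = opts$te_ms,
                            t2star_rt_ms = t2_rt,
                            t2star_blood_ms = opts$t2star_blood_ms,
                            lambda_rt = lam_rt,
                            m0t_method = m0t$method,
                            m0t_options = m0t$options))
}

#' Voxelwise M0a map
#'
#' Extrapolates M0a in every voxel from the local M0t:
#' `M0a(i) = M0t(i) * exp(TE * (1/T2*_t(i) - 1/T2*_a)) / lambda_t(i)`,
#' with PVE-weighted tissue T2* and the chosen lambda variant, followed by
#' in-plane median smoothing (default kernel 3 x 3 voxels = 10.5 mm physical
#' width at the 3.5 mm in-plane voxel). Voxels whose M0a falls below 10% of
#' the brain median are masked to `NA` so the later division cannot blow up.
#'
#' @param m0t `m0_map` of kind `"M0t"`.
#' @param tissue `tissue_maps`.
#' @param opts [calib_options()]: lambda variant, smoothing, TE, T2* blood.
#' @param floor_frac Relative floor for usable M0a (fraction of brain
#'   median).
#' @return `m0_map` with 3D `values` (`NA` outside usable brain), kind
#'   `"M0a"`, method `"Voxel"`.
#' @export
m0a_voxelwise <- function(m0t, tissue, opts = calib_options(),
                          floor_frac = 0.1) {
  stopifnot(inherits(m0t, "m0_map"))
  .check_same_grid(m0t$values, tissue$pve_gm, "m0t and tissue")
  k <- opts$constants
  lam <- lambda_map(tissue, opts$lambda_variant, constants = k)
  s <- tissue$pve_gm + tissue$pve_wm + tissue$pve_csf
  t2s <- array(NA_real_, dim(s))
  def <- s > 0
  t2mix <- tissue$pve_gm * k$t2star[["gm"]] + tissue$pve_wm *
    k$t2star[["wm"]] + tissue$pve_csf * k$t2star[["csf"]]
  t2s[def] <- t2mix[def]
  m0a <- m0t$values * exp(opts$te_ms * (1 / t2s - 1 / opts$t2star_blood_ms)) /
    lam
  usable <- tissue$brain_mask & is.finite(m0a)
  m0a[!usable] <- NA_real_
  if (opts$smoothing != "none") {
    size <- if (opts$smoothing == "3x3") 3L else 5L
    m0a <- .median_filter_inplane(m0a, size, usable)
  }
  med <- stats::median(m0a[usable], na.rm = TRUE)
  m0a[usable & (is.na(m0a) | m0a < floor_frac * med)] <- NA_real_
  new_m0_map(m0a, kind = "M0a", method = "Voxel",
             options = list(lambda_variant = opts$lambda_variant,
                            smoothing = opts$smoothing,
                            te_ms = opts$te_ms,
                            t2star_blood_ms = opts$t2star_blood_ms,
                            floor_frac = floor_frac,
                            m0t_method = m0t$method,
                            m0t_options = m0t$options))
}
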