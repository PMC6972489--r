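#' Specification of the digital ASL phantom
#'
#' The phantom is a concentric-shell "brain": a CSF ventricle core, a white
#' matter shell, a gray matter rim and a thin film of sulcal CSF, embedded in
#' background. Binary tissue labels are blurred to produce realistic partial
#' volume estimates (PVEs).
#'
#' @param grid_shape Integer 3-vector, voxels per axis (in-plane >= 16).
#' @param voxel_size_mm Numeric 3-vector, mm (default 3.5 x 3.5 x 5.0, the
#'   2D EPI protocol voxel).
#' @param pve_blur_fwhm_mm FWHM of the Gaussian applied to the binary labels
#'   to create partial volumes; 0 keeps PVEs binary. The default of one
#'   in-plane voxel (3.5 mm) emulates the partial voluming produced by
#'   resampling sharp segmentation boundaries onto the ASL grid, while
#'   keeping restrictive (PVE >= 0.9) reference masks nearly homogeneous,
#'   as such masks are on real co-registered segmentations.
#' @param seed Random seed consumed by noise generation downstream (the
#'   geometry itself is deterministic).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 8L),
                         voxel_size_mm = c(3.5, 3.5, 5.0),
                         pve_blur_fwhm_mm = 3.5,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be a positive integer 3-vector")
  if (any(grid_shape[1:2] < 16L))
    stop("grid_shape must be at least 16 voxels in-plane")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be a positive 3-vector")
  if (pve_blur_fwhm_mm < 0) stop("pve_blur_fwhm_mm must be non-negative")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 pve_blur_fwhm_mm = pve_blur_fwhm_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the digital phantom: tissue maps and ground truth
#'
#' Generates GM/WM/CSF partial volume maps plus the complete ground truth
#' needed to simulate ASL data and to check every downstream stage: CBF, ATT
#' and arterial blood volume maps, the tissue equilibrium magnetization M0t,
#' PVE-weighted T1 / T2* / lambda maps, a smooth multiplicative
#' coil-sensitivity bias field and the presaturation efficiency A.
#'
#' Pure-tissue voxels carry exactly the [asl_tissue_constants()] values;
#' mixed voxels carry PVE-weighted combinations. M0t is
#' `lambda * m0_blood`, which makes the reference-tissue and voxelwise
#' calibration routes mutually consistent: both recover the same arterial
#' magnetization `m0_blood`.
#'
#' The bias field mimics a multi-channel receive coil: sensitivity is lowest
#' at the centre of the head and rises toward the periphery, scaled to the
#' requested peak-to-trough ratio and normalised to mean 1 over the brain.
#'
#' @param spec A [phantom_spec()].
#' @param cbf_gm,cbf_wm Ground-truth perfusion of pure GM / WM, mL/100 g/min.
#' @param att_gm,att_wm Ground-truth arterial transit time of pure GM / WM, s.
#' @param abv_gm Arterial blood volume fraction in pure GM (scaled by PVE_GM
#'   elsewhere); CSF and background carry none.
#' @param m0_blood Equilibrium magnetization of arterial blood, signal units.
#' @param bias_ptt Peak-to-trough ratio of the coil-sensitivity field over the
#'   brain; 1 gives a perfectly flat field.
#' @param presat_A Presaturation efficiency in (0, 1].
#' @return A list with elements `tissue` (class `tissue_maps`: `pve_gm`,
#'   `pve_wm`, `pve_csf`, `ventricle_mask`, `brain_mask`, `voxel_size_mm`)
#'   and `truth` (class `ground_truth`: `cbf`, `att`, `att_art`, `abv`,
#'   `m0t`, `t1`, `t2star`, `lambda`, `bias_field`, `m0_blood`, `presat_A`).
#' @export
make_phantom <- function(spec = phantom_spec(),
                         cbf_gm = 60, cbf_wm = 20,
                         att_gm = 0.7, att_wm = 1.0,
                         abv_gm = 0.01,
                         m0_blood = 1000,
                         bias_ptt = 1.3,
                         presat_A = 0.90) {
  d <- spec$grid_shape
  co <- .norm_coords(d)
  # in-plane elliptical radius, 1 at the brain surface; the layout is
  # columnar (identical across slices) so the ventricle core survives
  # through-plane partial-voluming on coarse 5 mm slices
  r <- sqrt((co$x / 0.95)^2 + (co$y / 0.85)^2)

  lab <- array("background", d)
  lab[r < 1.00] <- "csf_sulcal"
  lab[r < 0.88] <- "gm"
  lab[r < 0.62] <- "wm"
  lab[r < 0.28] <- "csf_ventricle"

  for (cls in c("gm", "wm", "csf_ventricle"))
    if (!any(lab == cls))
      stop("phantom configuration error: tissue class '", cls,
           "' is empty; enlarge grid_shape")
  if (!any(lab == "csf_sulcal"))
    stop("phantom configuration error: tissue class 'csf_sulcal' is empty")

  bin <- function(cls) array(as.numeric(lab %in% cls), d)
  g <- bin("gm"); w <- bin("wm"); c_ <- bin(c("csf_ventricle", "csf_sulcal"))
  if (spec$pve_blur_fwhm_mm > 0) {
    sigma_vox <- (spec$pve_blur_fwhm_mm / 2.3548) / spec$voxel_size_mm
    g <- .gauss_blur3d(g, sigma_vox)
    w <- .gauss_blur3d(w, sigma_vox)
    c_ <- .gauss_blur3d(c_, sigma_vox)
  }
  s <- g + w + c_
  brain <- s >= 0.5
  norm <- ifelse(brain, s, Inf)     # outside brain -> PVEs forced to 0
  pve_gm <- g / norm; pve_wm <- w / norm; pve_csf <- c_ / norm

  ventricle <- lab == "csf_ventricle"

  tissue <- structure(
    list(pve_gm = pve_gm, pve_wm = pve_wm, pve_csf = pve_csf,
         ventricle_mask = ventricle, brain_mask = brain,
         voxel_size_mm = spec$voxel_size_mm),
    class = "tissue_maps")

  k <- asl_tissue_constants()
  wsum <- pve_gm + pve_wm + pve_csf           # 1 inside brain, 0 outside
  mix <- function(v) {
    out <- pve_gm * v[["gm"]] + pve_wm * v[["wm"]] + pve_csf * v[["csf"]]
    out[!brain] <- 0
    out
  }
  t1 <- mix(k$t1); t1[!brain] <- 1e6          # background never recovers signal
  t2star <- mix(k$t2star); t2star[!brain] <- 1
  lambda <- mix(k$lambda)

  cbf <- cbf_gm * pve_gm + cbf_wm * pve_wm
  perf_w <- pve_gm + pve_wm
  att <- array(att_wm, d)
  att[perf_w > 0] <- (att_gm * pve_gm[perf_w > 0] +
                      att_wm * pve_wm[perf_w > 0]) / perf_w[perf_w > 0]
  abv <- abv_gm * pve_gm
  att_art <- pmax(att - 0.3, 0.1)

  m0t <- lambda * m0_blood

  # centre-dark coil profile: quadratic in the ellipsoidal 3D radius
  r3 <- sqrt(r^2 + co$z^2)
  raw <- 1 + pmin(r3, 1.2)^2
  bias <- raw
  if (bias_ptt != 1) {
    rng <- range(raw[brain])
    # affine rescale so max/min over brain equals bias_ptt
    lo <- 2 / (bias_ptt + 1); hi <- bias_ptt * lo
    bias <- lo + (raw - rng[1]) / diff(rng) * (hi - lo)
  } else bias <- array(1, d)
  bias <- bias / mean(bias[brain])

  truth <- structure(
    list(cbf = cbf, att = att, att_art = att_art, abv = abv, m0t = m0t,
         t1 = t1, t2star = t2star, lambda = lambda, bias_field = bias,
         m0_blood = m0_blood, presat_A = presat_A),
    class = "ground_truth")

  list(tissue = tissue, truth = truth)
}

#' @export
print.tissue_maps <- function(x, ...) {
  d <- dim(x$pve_gm)
  cat("<tissue_maps> grid ", paste(d, collapse = "x"),
      ", brain voxels ", sum(x$brain_mask),
      ", ventricle voxels ", sum(x$ventricle_mask), "\n", sep = "")
  invisible(x)
}

#' PVE-weighted tissue parameter map
#'
#' Mixes a per-tissue constant triple into a per-voxel map using the partial
#' volume estimates (the same construction as the PVE-weighted lambda).
#'
#' @param tissue A `tissue_maps` object.
#' @param values Named numeric vector with elements `gm`, `wm`, `csf`.
#' @param fill Value outside the brain mask.
#' @return 3D array.
#' @export
pve_weighted_map <- function(tissue, values, fill = NA_real_) {
  out <- tissue$pve_gm * values[["gm"]] + tissue$pve_wm * values[["wm"]] +
    tissue$pve_csf * values[["csf"]]
  out[!tissue$brain_mask] <- fill
  out
}
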