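#' Tissue relaxation and partition-coefficient constants
#'
#' Literature constants used throughout calibration post-processing:
#' longitudinal relaxation time T1 (s), apparent transverse relaxation time
#' T2* (ms) and brain--blood water partition coefficient lambda (mL/g) for
#' gray matter, white matter and CSF at 3T.
#'
#' @return A list with named numeric vectors `t1` (s), `t2star` (ms) and
#'   `lambda` (mL/g), each with elements `gm`, `wm`, `csf`.
#' @export
#' @examples
#' asl_tissue_constants()$lambda[["csf"]]
asl_tissue_constants <- function() {
  list(
    t1     = c(gm = 1.3,  wm = 1.0,  csf = 4.3),
    t2star = c(gm = 60,   wm = 50,   csf = 400),
    lambda = c(gm = 0.98, wm = 0.82, csf = 1.15)
  )
}

#' Calibration options
#'
#' One point in the calibration post-processing option grid, together with
#' the physical constants Eq.-level formulas need.
#'
#' @param lambda_variant Partition-coefficient handling for the voxelwise
#'   method: `"pve"` (PVE-weighted, default), `"avg"` (single brain average
#'   0.5*lambda_GM + 0.5*lambda_WM = 0.90) or `"tspec"` (majority tissue).
#' @param smoothing Median-filter option for the voxelwise M0a map:
#'   `"3x3"` (in-plane kernel of physical width 3 x 3.5 mm = 10.5 mm,
#'   default), `"5x5"` (17.5 mm) or `"none"`.
#' @param bias_correction Logical; apply coil-sensitivity bias correction in
#'   reference-tissue calibration (default `TRUE`).
#' @param t2star_blood_ms T2* of arterial blood in ms (default 50; not a
#'   tissue-table value, exposed because the M0a formulas require it).
#' @param te_ms Echo time in ms. Values below 1 are rejected as a likely
#'   seconds/ms unit mix-up.
#' @param alpha Labeling (inversion) efficiency in (0, 1].
#' @param constants Tissue constants, see [asl_tissue_constants()].
#' @return An object of class `calib_options`.
#' @export
calib_options <- function(lambda_variant = c("pve", "avg", "tspec"),
                          smoothing = c("3x3", "5x5", "none"),
                          bias_correction = TRUE,
                          t2star_blood_ms = 50,
                          te_ms = 19,
                          alpha = 0.98,
                          constants = asl_tissue_constants()) {
  lambda_variant <- match.arg(lambda_variant)
  smoothing <- match.arg(smoothing)
  if (!is.numeric(te_ms) || te_ms < 0)
    stop("te_ms must be a non-negative echo time in milliseconds")
  if (te_ms > 0 && te_ms < 1)
    stop("te_ms = ", te_ms, " looks like seconds; supply the echo time in ms")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (t2star_blood_ms <= 0) stop("t2star_blood_ms must be positive")
  structure(
    list(lambda_variant = lambda_variant, smoothing = smoothing,
         bias_correction = bias_correction, t2star_blood_ms = t2star_blood_ms,
         te_ms = te_ms, alpha = alpha, constants = constants),
    class = "calib_options")
}

#' @export
print.calib_options <- function(x, ...) {
  cat("<calib_options>\n",
      " lambda variant : ", x$lambda_variant, "\n",
      " smoothing      : ", x$smoothing, "\n",
      " bias correction: ", x$bias_correction, "\n",
      " T2*_blood (ms) : ", x$t2star_blood_ms, "\n",
      " TE (ms)        : ", x$te_ms, "\n",
      " alpha          : ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Acquisition parameters for a simulated ASL sequence
#'
#' Describes either a multi-TI PICORE/Q2TIPS-style pulsed ASL acquisition
#' (presaturation, no background suppression) or a multi-PLD pseudo-continuous
#' acquisition (background-suppressed, with a separate long-TR calibration
#' scan). Defaults reproduce the two study protocols the package emulates.
#'
#' The Q2TIPS module truncates the PASL bolus: for TI < 1000 ms the bolus
#' duration is TI - 25 ms, otherwise 750 ms.
#'
#' @param sequence `"PASL_Q2TIPS"` or `"pCASL"`.
#' @param ti_or_pld_s Strictly increasing TI (PASL) or PLD (pCASL) values, s.
#' @param te_ms Echo time, ms.
#' @param tr_s Repetition time, s.
#' @param slice_time_ms Per-slice acquisition offset for ascending 2D
#'   multi-slice readout, ms; effective time at slice s is
#'   nominal + (s - 1) * slice_time.
#' @param n_repeats Control-label pairs per TI/PLD.
#' @param label_duration_s pCASL labeling duration, s (ignored for PASL,
#'   whose bolus follows the Q2TIPS rule).
#' @param background_suppression Logical.
#' @param bs_factor Static-tissue attenuation factor left by background
#'   suppression (pCASL only; the bolus attenuation is conventionally folded
#'   into `alpha`).
#' @param calib_tr_s TR of the separate calibration scan, s (pCASL only).
#' @param alpha Labeling efficiency.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(sequence = c("PASL_Q2TIPS", "pCASL"),
                       ti_or_pld_s = NULL,
                       te_ms = NULL, tr_s = NULL, slice_time_ms = NULL,
                       n_repeats = 8,
                       label_duration_s = 1.4,
                       background_suppression = NULL,
                       bs_factor = 0.3,
                       calib_tr_s = NULL,
                       alpha = NULL) {
  sequence <- match.arg(sequence)
  if (sequence == "PASL_Q2TIPS") {
    if (is.null(ti_or_pld_s)) ti_or_pld_s <- seq(0.4, 2.4, by = 0.2)
    if (is.null(te_ms)) te_ms <- 19
    if (is.null(tr_s)) tr_s <- 2.5
    if (is.null(slice_time_ms)) slice_time_ms <- 50
    if (is.null(background_suppression)) background_suppression <- FALSE
    if (is.null(alpha)) alpha <- 0.98
  } else {
    if (is.null(ti_or_pld_s)) ti_or_pld_s <- seq(0.25, 1.5, by = 0.25)
    if (is.null(te_ms)) te_ms <- 13
    if (is.null(tr_s)) tr_s <- 4.0
    if (is.null(slice_time_ms)) slice_time_ms <- 45.2
    if (is.null(background_suppression)) background_suppression <- TRUE
    if (is.null(calib_tr_s)) calib_tr_s <- 6.0
    if (is.null(alpha)) alpha <- 0.85
  }
  if (any(diff(ti_or_pld_s) <= 0))
    stop("ti_or_pld_s must be strictly increasing")
  if (te_ms <= 0) stop("te_ms must be positive")
  if (slice_time_ms < 0) stop("slice_time_ms must be non-negative")
  structure(
    list(sequence = sequence, ti_or_pld_s = ti_or_pld_s, te_ms = te_ms,
         tr_s = tr_s, slice_time_ms = slice_time_ms, n_repeats = n_repeats,
         label_duration_s = label_duration_s,
         background_suppression = background_suppression,
         bs_factor = bs_factor, calib_tr_s = calib_tr_s, alpha = alpha),
    class = "acq_params")
}

#' Q2TIPS bolus duration rule
#'
#' Bolus duration of the pulsed-ASL label at a given TI: the Q2TIPS module
#' limits the bolus to 750 ms; for TI < 1000 ms the saturation would act
#' before the bolus ends, giving a duration of TI - 25 ms.
#'
#' @param ti_s TI values in seconds.
#' @return Bolus durations in seconds.
#' @export
#' @examples
#' pasl_bolus_duration(c(0.8, 1.2))  # 0.775, 0.750
pasl_bolus_duration <- function(ti_s) {
  ifelse(ti_s < 1.0, ti_s - 0.025, 0.750)
}

# internal: seconds <-> ms guard used in a few places
.ms_to_s <- function(ms) ms / 1000
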