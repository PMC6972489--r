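#' Run one full calibration pipeline
#'
#' Glue from fitted relative perfusion to absolute GM CBF for a single
#' choice of M0t generation method, M0a derivation method and post-processing
#' options. Reference-tissue paths optionally estimate a bias field from the
#' M0t map and divide both the M0t map and the relative CBF map by it before
#' calibration; the voxelwise path needs no such correction because the
#' division by the voxelwise M0a cancels any multiplicative field.
#'
#' @param perf `perfusion_maps` (relative CBF etc.) from [fit_volume()].
#' @param ds `asl_dataset` (needed for CtrAvg / SatRec M0t generation).
#' @param tissue `tissue_maps`.
#' @param calib Optional raw calibration scan (`m0_map`) for LongTR.
#' @param m0t_method `"SatRec"`, `"CtrAvg"` or `"LongTR"`.
#' @param m0a_method `"rt-csf"`, `"rt-wm"`, `"rt-gm"` or `"voxel"`.
#' @param opts [calib_options()].
#' @param ti_s CtrAvg TI (default: longest acquired).
#' @param t1_correction T1-relaxation correction for CtrAvg/LongTR.
#' @param A CtrAvg presaturation efficiency.
#' @param estimate_A SatRec: estimate A (default) or fix it at 1.
#' @param pve_threshold RT mask threshold (0.9 restrictive, 0.6 extensive).
#' @param intersect_ventricles RT-CSF: intersect the ventricle labels.
#' @param m0t Optional precomputed `m0_map` of kind `"M0t"`, bypassing
#'   `m0t_method` (used by [option_sweep()] to avoid refitting).
#' @param gm_pve_threshold GM mask threshold for the summary statistics.
#' @param subject_id,session_id Carried into the result.
#' @return A `cbf_result` with `gm_mean`/`gm_median` fields attached.
#' @export
run_calibration <- function(perf, ds = NULL, tissue, calib = NULL,
                            m0t_method = c("SatRec", "CtrAvg", "LongTR"),
                            m0a_method = c("voxel", "rt-csf", "rt-wm", "rt-gm"),
                            opts = calib_options(),
                            ti_s = NULL, t1_correction = TRUE, A = 0.90,
                            estimate_A = TRUE,
                            pve_threshold = 0.9,
                            intersect_ventricles = NULL,
                            m0t = NULL,
                            gm_pve_threshold = 0.9,
                            subject_id = NA_character_,
                            session_id = NA_character_) {
  m0t_method <- match.arg(m0t_method)
  m0a_method <- match.arg(m0a_method)
  if (is.null(m0t)) {
    m0t <- switch(m0t_method,
      SatRec = m0t_satrec(ds, tissue, estimate_A = estimate_A)$m0t,
      CtrAvg = m0t_ctravg(ds, tissue, ti_s = ti_s,
                          t1_correction = t1_correction, A = A),
      LongTR = {
        if (is.null(calib)) stop("LongTR needs the separate calibration scan")
        m0t_longtr(calib, tissue, t1_correction = t1_correction)
      })
  }
  cbf_rel <- perf$cbf_rel
  if (m0a_method != "voxel" && isTRUE(opts$bias_correction)) {
    bias <- estimate_bias_field(m0t, tissue, opts)
    m0t <- correct_bias(m0t, bias, tissue)
    cbf_rel <- correct_bias(cbf_rel, bias, tissue)
  }
  m0a <- if (m0a_method == "voxel") {
    m0a_voxelwise(m0t, tissue, opts)
  } else {
    kind <- sub("rt-", "", m0a_method)
    if (is.null(intersect_ventricles))
      intersect_ventricles <- kind == "csf" && pve_threshold >= 0.9
    mask <- build_rt_mask(tissue, kind, pve_threshold = pve_threshold,
                          intersect_ventricles = intersect_ventricles)
    m0a_reference_tissue(m0t, mask, opts, kind)
  }
  res <- calibrate_cbf(list(cbf_rel = cbf_rel), m0a, alpha = opts$alpha,
                       subject_id = subject_id, session_id = session_id)
  gs <- gm_summary(res, tissue, pve_threshold = gm_pve_threshold)
  res$gm_mean <- gs$mean
  res$gm_median <- gs$median
  res$m0t_method <- m0t_method
  res
}

#' Table of calibration option points
#'
#' Builds the one-at-a-time option grid around the defaults for a given M0t
#' generation method: every M0a derivation method with its default options,
#' plus each single-option deviation (mask restrictiveness, bias correction,
#' smoothing kernel, lambda variant, TI choice, T1 correction, presaturation
#' efficiency handling).
#'
#' @param m0t_method `"SatRec"`, `"CtrAvg"` or `"LongTR"`.
#' @param ti_long_s,ti_short_s CtrAvg TI choices, s.
#' @return Data frame, one row per option point, with `label` and
#'   `is_default` columns.
#' @export
default_option_grid <- function(m0t_method = c("SatRec", "CtrAvg", "LongTR"),
                                ti_long_s = 2.4, ti_short_s = 0.8) {
  m0t_method <- match.arg(m0t_method)
  base <- data.frame(
    m0t_method = m0t_method, m0a_method = NA_character_,
    ti_s = if (m0t_method == "CtrAvg") ti_long_s else NA_real_,
    t1_correction = TRUE, A = 0.90, estimate_A = TRUE,
    pve_threshold = 0.9, intersect_ventricles = NA,
    bias_correction = TRUE, lambda_variant = "pve", smoothing = "3x3",
    label = "default", is_default = TRUE, stringsAsFactors = FALSE)
  rows <- list()
  add <- function(m0a, label, ...) {
    r <- base
    r$m0a_method <- m0a; r$label <- label
    mods <- list(...)
    for (nm in names(mods)) r[[nm]] <- mods[[nm]]
    r$is_default <- label == "default"
    rows[[length(rows) + 1]] <<- r
  }
  for (m0a in c("rt-csf", "rt-wm", "rt-gm", "voxel")) {
    add(m0a, "default")
    # M0t-side options
    if (m0t_method == "SatRec") add(m0a, "A_fixed_100", estimate_A = FALSE)
    if (m0t_method == "CtrAvg") {
      add(m0a, "short_TI", ti_s = ti_short_s)
      add(m0a, "no_T1_correction", t1_correction = FALSE)
      add(m0a, "A_100", A = 1.0)
    }
    if (m0t_method == "LongTR") add(m0a, "no_T1_correction",
                                    t1_correction = FALSE)
    # M0a-side options
    if (m0a == "rt-csf") {
      add(m0a, "intermediate_mask", pve_threshold = 0.6,
          intersect_ventricles = TRUE)
      add(m0a, "extensive_mask", pve_threshold = 0.6,
          intersect_ventricles = FALSE)
      add(m0a, "no_bias_correction", bias_correction = FALSE)
    } else if (m0a %in% c("rt-wm", "rt-gm")) {
      add(m0a, "extensive_mask", pve_threshold = 0.6)
      add(m0a, "no_bias_correction", bias_correction = FALSE)
    } else {
      add(m0a, "smooth_5x5", smoothing = "5x5")
      add(m0a, "no_smoothing", smoothing = "none")
      add(m0a, "lambda_avg", lambda_variant = "avg")
      add(m0a, "lambda_tspec", lambda_variant = "tspec")
    }
  }
  do.call(rbind, rows)
}

#' Sweep calibration options over datasets
#'
#' Evaluates every option point of a grid on each prepared dataset and
#' reports GM CBF (mean and median) per (subject, session, M0a method,
#' option), together with the percent difference of the mean relative to the
#' default option of the same method pair. Default rows have delta exactly 0.
#'
#' @param bases List of prepared inputs; each element is a list with
#'   `subject`, `session`, `perf`, `ds`, `tissue` and optionally `calib`.
#' @param grid Option grid, defaults to
#'   [default_option_grid()] of `m0t_method`.
#' @param m0t_method Used when `grid` is `NULL`.
#' @param opts_base Base [calib_options()]; per-row options override its
#'   `bias_correction`, `lambda_variant` and `smoothing` fields.
#' @return Tidy data frame: one row per (subject, session, m0a_method,
#'   option point).
#' @export
option_sweep <- function(bases, grid = NULL,
                         m0t_method = c("SatRec", "CtrAvg", "LongTR"),
                         opts_base = calib_options()) {
  m0t_method <- match.arg(m0t_method)
  if (is.null(grid)) grid <- default_option_grid(m0t_method)
  out <- list()
  for (b in bases) {
    m0t_cache <- new.env(parent = emptyenv())
    get_m0t <- function(row) {
      key <- paste(row$m0t_method, row$ti_s, row$t1_correction, row$A,
                   row$estimate_A, sep = "|")
      if (!is.null(m0t_cache[[key]])) return(m0t_cache[[key]])
      v <- switch(row$m0t_method,
        SatRec = m0t_satrec(b$ds, b$tissue,
                            estimate_A = row$estimate_A)$m0t,
        CtrAvg = m0t_ctravg(b$ds, b$tissue, ti_s = row$ti_s,
                            t1_correction = row$t1_correction, A = row$A),
        LongTR = m0t_longtr(b$calib, b$tissue,
                            t1_correction = row$t1_correction))
      m0t_cache[[key]] <- v
      v
    }
    for (i in seq_len(nrow(grid))) {
      row <- grid[i, ]
      opts <- opts_base
      opts$bias_correction <- row$bias_correction
      opts$lambda_variant <- row$lambda_variant
      opts$smoothing <- row$smoothing
      res <- run_calibration(
        b$perf, ds = b$ds, tissue = b$tissue, calib = b$calib,
        m0a_method = row$m0a_method, opts = opts,
        pve_threshold = row$pve_threshold,
        intersect_ventricles = if (is.na(row$intersect_ventricles)) NULL
                               else row$intersect_ventricles,
        m0t = get_m0t(row),
        subject_id = b$subject, session_id = b$session)
      out[[length(out) + 1]] <- data.frame(
        subject = b$subject, session = b$session,
        m0t_method = row$m0t_method, m0a_method = row$m0a_method,
        option = row$label, is_default = row$is_default,
        gm_mean = res$gm_mean, gm_median = res$gm_median,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  # percent delta of the mean vs the default row of the same method pair
  tab$delta_pct <- NA_real_
  for (i in seq_len(nrow(tab))) {
    ref <- tab$gm_mean[tab$subject == tab$subject[i] &
                       tab$session == tab$session[i] &
                       tab$m0a_method == tab$m0a_method[i] &
                       tab$m0t_method == tab$m0t_method[i] &
                       tab$is_default]
    tab$delta_pct[i] <- (tab$gm_mean[i] / ref[1] - 1) * 100
  }
  tab
}
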