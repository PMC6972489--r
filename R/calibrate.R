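#' Absolute CBF calibration
#'
#' Converts relative perfusion to absolute units:
#' `CBF = CBF_rel / (alpha * M0a) * 6000` mL/100 g/min. A scalar M0a
#' (reference-tissue path) divides the whole map; a voxelwise M0a map divides
#' voxel by voxel, with masked (`NA`) M0a voxels propagating to masked CBF,
#' never infinities.
#'
#' @param perf `perfusion_maps` from [fit_volume()] (or a list with a
#'   `cbf_rel` array).
#' @param m0a `m0_map` of kind `"M0a"` (scalar or volume).
#' @param alpha Labeling efficiency in (0, 1].
#' @param subject_id,session_id Optional identifiers carried in the result.
#' @return Object of class `cbf_result`: `cbf_map` (mL/100 g/min), the
#'   options/provenance, and identifiers.
#' @export
calibrate_cbf <- function(perf, m0a, alpha = 0.98,
                          subject_id = NA_character_,
                          session_id = NA_character_) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  stopifnot(inherits(m0a, "m0_map"))
  if (m0a$kind != "M0a") stop("m0a must be an M0a map, got kind ", m0a$kind)
  cbf_rel <- perf$cbf_rel
  if (length(m0a$values) == 1) {
    if (!is.finite(m0a$values) || m0a$values == 0)
      stop("scalar M0a is zero or non-finite")
    cbf <- cbf_rel / (alpha * m0a$values) * 6000
  } else {
    .check_same_grid(cbf_rel, m0a$values, "cbf_rel and M0a")
    denom <- alpha * m0a$values
    cbf <- cbf_rel / denom * 6000
    cbf[!is.finite(cbf)] <- NA_real_
    cbf[is.na(m0a$values) | m0a$values == 0] <- NA_real_
  }
  structure(list(cbf_map = cbf, m0a_method = m0a$method,
                 options = m0a$options, alpha = alpha,
                 subject_id = subject_id, session_id = session_id),
            class = "cbf_result")
}

#' @export
print.cbf_result <- function(x, ...) {
  cat("<cbf_result> method=", x$m0a_method, ", grid ",
      paste(dim(x$cbf_map), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Gray-matter summary CBF
#'
#' Mean and median CBF over the GM mask (`PVE_GM >= pve_threshold`). Both
#' statistics are returned because group comparisons conventionally use the
#' mean while coefficient-of-variation analyses use the median.
#'
#' @param cbf `cbf_result` or bare 3D CBF array.
#' @param tissue `tissue_maps`.
#' @param pve_threshold GM PVE threshold, default 0.9.
#' @return Named list: `mean`, `median`, `n_voxels`.
#' @export
gm_summary <- function(cbf, tissue, pve_threshold = 0.9) {
  cbf_map <- if (inherits(cbf, "cbf_result")) cbf$cbf_map else cbf
  mask <- tissue$pve_gm >= pve_threshold & is.finite(cbf_map)
  if (!any(mask)) stop("empty GM mask at threshold ", pve_threshold)
  list(mean = mean(cbf_map[mask]), median = stats::median(cbf_map[mask]),
       n_voxels = sum(mask))
}

#' Inter- and intra-subject coefficients of variation
#'
#' Standard test-retest reproducibility metrics on per-subject, per-session
#' GM summary values: `CV_intra` is the within-subject across-session SD
#' divided by the subject mean, averaged across subjects (percent);
#' `CV_inter` is the SD of subject means divided by the grand mean (percent).
#'
#' @param gm_values Data frame with columns `subject`, `session`, `value`.
#' @return Object of class `repro_report`: `cv_inter`, `cv_intra` (percent),
#'   `subject_means`, `n_subjects`, `n_sessions`.
#' @export
cv_metrics <- function(gm_values) {
  stopifnot(all(c("subject", "session", "value") %in% names(gm_values)))
  subs <- unique(gm_values$subject)
  if (length(subs) < 2) stop("cv_metrics needs at least 2 subjects")
  per_sub <- lapply(subs, function(s) gm_values$value[gm_values$subject == s])
  n_sess <- vapply(per_sub, length, 0L)
  if (any(n_sess < 2))
    stop("CV_intra is undefined with a single session per subject")
  sub_means <- vapply(per_sub, mean, 0)
  cv_intra <- mean(vapply(per_sub, function(v) stats::sd(v) / mean(v), 0)) * 100
  cv_inter <- stats::sd(sub_means) / mean(sub_means) * 100
  structure(list(cv_inter = cv_inter, cv_intra = cv_intra,
                 subject_means = stats::setNames(sub_means, subs),
                 n_subjects = length(subs), n_sessions = n_sess),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("<repro_report> CV_inter = %.2f%%, CV_intra = %.2f%% (%d subjects)\n",
              x$cv_inter, x$cv_intra, x$n_subjects))
  invisible(x)
}

#' Jackknife comparison of reproducibility across methods
#'
#' Leave-one-subject-out jackknife replicates of CV_inter and CV_intra per
#' method, followed by pairwise paired t-tests between methods on the
#' replicates (P < 0.05, unadjusted). Methods with identical values produce
#' no significant difference (degenerate zero-variance differences are
#' reported with p = 1).
#'
#' @param gm_values Data frame with columns `subject`, `session`, `method`,
#'   `value`.
#' @param alpha_level Significance level, default 0.05.
#' @return List: `replicates` (data frame method x left-out subject with both
#'   CVs) and `pairwise` (data frame with method pair, metric, mean
#'   difference, p value, significant flag).
#' @export
jackknife_compare <- function(gm_values, alpha_level = 0.05) {
  stopifnot(all(c("subject", "session", "method", "value") %in%
                names(gm_values)))
  methods <- unique(gm_values$method)
  subs <- unique(gm_values$subject)
  if (length(subs) < 3) stop("jackknife needs at least 3 subjects")
  reps <- do.call(rbind, lapply(methods, function(m) {
    dm <- gm_values[gm_values$method == m, ]
    do.call(rbind, lapply(subs, function(s) {
      cv <- cv_metrics(dm[dm$subject != s, c("subject", "session", "value")])
      data.frame(method = m, left_out = s, cv_inter = cv$cv_inter,
                 cv_intra = cv$cv_intra, stringsAsFactors = FALSE)
    }))
  }))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    do.call(rbind, lapply(c("cv_inter", "cv_intra"), function(metric) {
      a <- reps[reps$method == p[1], metric][order(reps[reps$method == p[1], "left_out"])]
      b <- reps[reps$method == p[2], metric][order(reps[reps$method == p[2], "left_out"])]
      dif <- b - a
      pval <- if (stats::sd(dif) < 1e-12) 1
              else stats::t.test(dif)$p.value
      data.frame(method_a = p[1], method_b = p[2], metric = metric,
                 mean_diff = mean(dif), p_value = pval,
                 significant = pval < alpha_level, stringsAsFactors = FALSE)
    }))
  }))
  list(replicates = reps, pairwise = pw)
}
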