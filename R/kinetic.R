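#' Kinetic model parameters
#'
#' Parameters of the general kinetic model with an added macrovascular
#' (arterial) compartment, used both for forward simulation and fitting.
#'
#' `f_rel` is the relative perfusion amplitude in arterial-magnetization
#' normalised units (per second): the measured difference signal is
#' `M0a * forward_signal(t, p)`, so after calibration
#' `CBF = f_rel_signal / (alpha * M0a) * 6000` in mL/100 g/min.
#'
#' @param f_rel Relative perfusion, 1/s units when normalised; >= 0.
#' @param att Arterial transit time to tissue, s, in (0, 5].
#' @param abv Arterial blood volume fraction, in [0, 0.2].
#' @param tau Bolus duration, s.
#' @param t1_blood Longitudinal relaxation of arterial blood, s.
#' @param t1_tissue Apparent tissue T1 governing label decay after exchange, s.
#' @param att_art Arrival time of the macrovascular compartment, s;
#'   must not exceed `att`.
#' @return Object of class `kinetic_params`.
#' @export
kinetic_params <- function(f_rel, att, abv = 0, tau = 0.75,
                           t1_blood = 1.65, t1_tissue = 1.3,
                           att_art = max(att - 0.3, 0.05)) {
  if (f_rel < 0) stop("f_rel must be non-negative")
  if (att <= 0 || att > 5) stop("att must lie in (0, 5] s")
  if (abv < 0 || abv > 0.2) stop("abv must lie in [0, 0.2]")
  if (att_art > att + 1e-12) stop("att_art must not exceed att")
  structure(list(f_rel = f_rel, att = att, abv = abv, tau = tau,
                 t1_blood = t1_blood, t1_tissue = t1_tissue,
                 att_art = att_art),
            class = "kinetic_params")
}

# Normalised tissue delivery kernel: integral over the bolus of the arterial
# input decayed at blood T1 during transit and at apparent tissue T1 after
# arrival. Amplitude-free; multiply by 2 * f_rel for the tissue signal.
.tissue_kernel <- function(t, att, tau, t1b, t1t, sequence) {
  u <- pmin(t, att + tau)
  out <- numeric(length(t))
  on <- t > att
  if (!any(on)) return(out)
  if (sequence == "PASL_Q2TIPS") {
    k <- 1 / t1t - 1 / t1b
    if (abs(k) > 1e-8) {
      out[on] <- exp(-t[on] / t1t) * (exp(k * u[on]) - exp(k * att)) / k
    } else {
      out[on] <- exp(-t[on] / t1t) * (u[on] - att)
    }
  } else {
    out[on] <- exp(-att / t1b) * t1t *
      (exp(-(t[on] - u[on]) / t1t) - exp(-(t[on] - att) / t1t))
  }
  out
}

#' Tissue compartment of the ASL difference signal
#'
#' Single well-mixed compartment general kinetic model. The labeled bolus
#' arrives at `att`; for pulsed labeling the label decays with blood T1 until
#' delivery, for pseudo-continuous labeling the plug decays for the transit
#' time only; after arrival the label relaxes with the apparent tissue T1.
#' The signal is zero before `att`, continuous in `t`, and decays to zero as
#' `t` grows.
#'
#' @param t Time since labeling (PASL TI, or labeling onset for pCASL so that
#'   `t = label_duration + PLD`), seconds; vectorised.
#' @param p A [kinetic_params()] object.
#' @param sequence `"PASL_Q2TIPS"` or `"pCASL"`.
#' @return Difference signal in M0a-normalised units.
#' @export
tissue_signal <- function(t, p, sequence = c("PASL_Q2TIPS", "pCASL")) {
  sequence <- match.arg(sequence)
  stopifnot(all(t >= 0))
  2 * p$f_rel * .tissue_kernel(t, p$att, p$tau, p$t1_blood, p$t1_tissue,
                               sequence)
}

#' Macrovascular (arterial) compartment of the difference signal
#'
#' Non-exchanging box-car of labeled blood transiting large vessels: nonzero
#' only for `att_art <= t < att_art + tau`, amplitude `2 * abv` with blood-T1
#' decay (decay to current time for pulsed labeling, to the arterial arrival
#' time for pseudo-continuous labeling).
#'
#' @inheritParams tissue_signal
#' @return Difference signal in M0a-normalised units.
#' @export
arterial_signal <- function(t, p, sequence = c("PASL_Q2TIPS", "pCASL")) {
  sequence <- match.arg(sequence)
  stopifnot(all(t >= 0))
  inside <- t >= p$att_art & t < p$att_art + p$tau
  dec <- if (sequence == "PASL_Q2TIPS") exp(-t / p$t1_blood)
         else exp(-p$att_art / p$t1_blood)
  2 * p$abv * dec * inside
}

#' Total forward ASL difference signal
#'
#' Sum of the tissue and macrovascular compartments; linear in
#' `(f_rel, abv)` at fixed timing parameters.
#'
#' @inheritParams tissue_signal
#' @return Difference signal in M0a-normalised units.
#' @export
forward_signal <- function(t, p, sequence = c("PASL_Q2TIPS", "pCASL")) {
  sequence <- match.arg(sequence)
  tissue_signal(t, p, sequence) + arterial_signal(t, p, sequence)
}

# Arterial-compartment design candidates for one slice. The box-car support
# {m : att_art <= t_m < att_art + tau_m} is piecewise constant in att_art, so
# only finitely many arterial designs exist; we enumerate one representative
# arrival time per plateau. Returns the candidate arrival times, the design
# matrix A (n_t x K, including the blood-decay weight) and its column norms.
.arterial_candidates <- function(t, tau, sequence, t1b) {
  bp <- sort(unique(c(t, t - tau, 0.01)))
  bp <- bp[bp > 0]
  mids <- (bp[-length(bp)] + bp[-1]) / 2
  cand <- sort(unique(c(bp, mids)))
  cols <- lapply(cand, function(atta) {
    inside <- t >= atta & t < atta + tau
    dec <- if (sequence == "PASL_Q2TIPS") exp(-t / t1b) else exp(-atta / t1b)
    2 * dec * inside
  })
  A <- do.call(cbind, cols)
  keep <- colSums(A != 0) > 0 & !duplicated(t(A != 0))
  list(atta = cand[keep], A = A[, keep, drop = FALSE],
       a22 = colSums(A[, keep, drop = FALSE]^2))
}

# Variable projection over the arterial plateau candidates: for a fixed
# tissue design Xf, solve the nonnegative 2-column least squares against
# every admissible arterial column in closed form and return the best.
.varpro_best <- function(y, Xf, cand, att, b2, yy) {
  a11 <- sum(Xf * Xf); b1 <- sum(Xf * y)
  admissible <- cand$atta <= att
  best <- list(coef = c(0, 0), rss = yy, atta = max(att - 0.3, 0.01))
  if (a11 > 0) {
    c1 <- max(b1 / a11, 0)
    r <- yy - 2 * c1 * b1 + c1 * c1 * a11
    if (r < best$rss) best <- list(coef = c(c1, 0), rss = r, atta = best$atta)
  }
  if (any(admissible)) {
    A <- cand$A[, admissible, drop = FALSE]
    a22 <- cand$a22[admissible]
    b2a <- b2[admissible]
    a12 <- as.vector(crossprod(A, Xf))
    det <- a11 * a22 - a12 * a12
    ok <- det > 1e-10 * pmax(a11 * a22, 1e-300)
    c1 <- ifelse(ok, (a22 * b1 - a12 * b2a) / det, NA_real_)
    c2 <- ifelse(ok, (a11 * b2a - a12 * b1) / det, NA_real_)
    both <- ok & c1 >= 0 & c2 >= 0
    rss2 <- yy - 2 * c1 * b1 - 2 * c2 * b2a + c1^2 * a11 +
      2 * c1 * c2 * a12 + c2^2 * a22
    rss2[!both] <- Inf
    # arterial-only fits
    c2o <- pmax(b2a / a22, 0)
    rsso <- yy - 2 * c2o * b2a + c2o^2 * a22
    k2 <- which.min(rss2); ko <- which.min(rsso)
    if (length(k2) && rss2[k2] < best$rss)
      best <- list(coef = c(c1[k2], c2[k2]), rss = rss2[k2],
                   atta = cand$atta[admissible][k2])
    if (length(ko) && rsso[ko] < best$rss)
      best <- list(coef = c(0, c2o[ko]), rss = rsso[ko],
                   atta = cand$atta[admissible][ko])
  }
  best
}

#' Average control-label differences per TI/PLD
#'
#' Averages the pairwise control minus label differences across repeats,
#' yielding the mean difference image series used for kinetic fitting, and
#' the per-volume model times (for pCASL the model time is
#' `label_duration + PLD`).
#'
#' @param ds An `asl_dataset` from [simulate_asl_series()].
#' @return List with `dm` (4D array x,y,z,time), `t_nominal_s` (model time
#'   per frame), `tau_s` (bolus duration per frame), `slice_time_s`,
#'   `sequence`, `te_ms`, `alpha`.
#' @export
average_differences <- function(ds) {
  stopifnot(inherits(ds, "asl_dataset"))
  tis <- unique(ds$meta$vol_ti_s)
  d <- dim(ds$control)[1:3]
  dm <- array(0, c(d, length(tis)))
  for (i in seq_along(tis)) {
    sel <- which(ds$meta$vol_ti_s == tis[i])
    acc <- array(0, d)
    for (v in sel) acc <- acc + (ds$control[, , , v] - ds$label[, , , v])
    dm[, , , i] <- acc / length(sel)
  }
  tmod <- if (ds$meta$sequence == "pCASL")
    tis + ds$meta$label_duration_s else tis
  tau <- if (ds$meta$sequence == "pCASL")
    rep(ds$meta$label_duration_s, length(tis)) else pasl_bolus_duration(tis)
  list(dm = dm, t_nominal_s = tmod, tau_s = tau,
       slice_time_s = ds$meta$slice_time_ms / 1000,
       sequence = ds$meta$sequence, te_ms = ds$meta$te_ms,
       alpha = ds$meta$alpha)
}

#' Voxelwise kinetic-model fitting
#'
#' Fits the extended kinetic model (tissue + arterial compartments) to the
#' mean difference signal at each voxel by bounded nonlinear least squares,
#' using slice-time-corrected effective times. The amplitudes (relative CBF
#' and aBV) are solved by variable projection at every candidate timing; the
#' arrival times are optimised by a coarse grid followed by Nelder-Mead
#' refinement, which keeps the fit deterministic and robust to the box-car
#' non-smoothness of the arterial term.
#'
#' All-zero voxels are returned flagged (`converged = FALSE`) with
#' `f_rel = 0` rather than silently zeroed.
#'
#' @param diffs Output of [average_differences()] (or a compatible list).
#' @param tissue Optional `tissue_maps`; supplies the brain mask
#'   (PVE sum > 0.1) and the PVE-weighted apparent tissue T1.
#' @param mask Optional logical 3D array overriding the tissue-derived mask.
#' @param t1_blood Blood T1, s.
#' @param t1_tissue Apparent tissue T1: scalar or 3D map; defaults to the
#'   PVE-weighted map when `tissue` is given, else 1.3 s.
#' @param att_bounds Bounds on the transit time, s.
#' @param att_grid_step Spacing of the initial ATT search grid, s.
#' @return Object of class `perfusion_maps`: `cbf_rel`, `att`, `abv`,
#'   `att_art`, `fit_rss`, `converged`, plus `mask` and fit metadata.
#' @export
fit_volume <- function(diffs, tissue = NULL, mask = NULL,
                       t1_blood = 1.65, t1_tissue = NULL,
                       att_bounds = c(0.1, 3.0), att_grid_step = 0.15) {
  d <- dim(diffs$dm)[1:3]
  nt <- dim(diffs$dm)[4]
  if (nt < 4) stop("at least 4 distinct effective times are required")
  if (is.null(mask)) {
    mask <- if (!is.null(tissue))
      (tissue$pve_gm + tissue$pve_wm + tissue$pve_csf) > 0.1
    else array(TRUE, d)
  }
  if (is.null(t1_tissue)) {
    t1_tissue <- if (!is.null(tissue))
      pve_weighted_map(tissue, asl_tissue_constants()$t1, fill = 1.3)
    else 1.3
  }
  t1map <- if (length(t1_tissue) == 1) array(t1_tissue, d) else t1_tissue

  cbf_rel <- array(0, d); att <- array(NA_real_, d)
  abv <- array(0, d); atta <- array(NA_real_, d)
  rss <- array(NA_real_, d); conv <- array(FALSE, d)

  max_t <- max(diffs$t_nominal_s) + diffs$slice_time_s * (d[3] - 1)
  att_grid <- seq(att_bounds[1] + 0.05, min(att_bounds[2], max_t),
                  by = att_grid_step)
  tau_use <- diffs$tau_s

  for (z in seq_len(d[3])) {
    teff <- diffs$t_nominal_s + (z - 1) * diffs$slice_time_s
    cand <- .arterial_candidates(teff, tau_use, diffs$sequence, t1_blood)
    idx <- which(matrix(mask[, , z], d[1], d[2]), arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      y <- diffs$dm[i, j, z, ]
      if (all(abs(y) < 1e-12)) {
        cbf_rel[i, j, z] <- 0; abv[i, j, z] <- 0
        att[i, j, z] <- 0.7; atta[i, j, z] <- 0.4
        rss[i, j, z] <- 0; conv[i, j, z] <- FALSE
        next
      }
      # per-frame tau enters through the design columns directly
      fit <- .fit_voxel_frames(y, teff, tau_use, diffs$sequence,
                               t1_blood, t1map[i, j, z],
                               att_grid, cand, att_bounds)
      cbf_rel[i, j, z] <- fit$f_rel; att[i, j, z] <- fit$att
      abv[i, j, z] <- fit$abv; atta[i, j, z] <- fit$att_art
      rss[i, j, z] <- fit$rss; conv[i, j, z] <- fit$converged
    }
  }
  structure(list(cbf_rel = cbf_rel, att = att, abv = abv, att_art = atta,
                 fit_rss = rss, converged = conv, mask = mask,
                 sequence = diffs$sequence, t1_blood = t1_blood),
            class = "perfusion_maps")
}

# One-voxel fit with per-frame bolus durations (vector tau, one per time
# point). The model is linear in (f_rel, abv) and the arterial arrival is a
# plateau index, so the only continuous nonlinear parameter is att: coarse
# grid, then golden-section refinement via optimize() around the best cell.
# .tissue_kernel is elementwise in (t, tau), so designs are vectorised.
.fit_voxel_frames <- function(y, t, tau, sequence, t1b, t1t,
                              att_grid, cand, att_bounds) {
  b2 <- as.vector(crossprod(cand$A, y))
  yy <- sum(y * y)
  obj <- function(att) {
    Xf <- 2 * .tissue_kernel(t, att, tau, t1b, t1t, sequence)
    .varpro_best(y, Xf, cand, att, b2, yy)
  }
  rss_grid <- vapply(att_grid, function(a) obj(a)$rss, 0)
  ng <- length(att_grid)
  # refine every local minimum of the grid profile: with few time points the
  # profile can be multimodal and the global basin need not hold the lowest
  # grid point
  locmin <- which(rss_grid <= c(Inf, rss_grid[-ng]) &
                  rss_grid <= c(rss_grid[-1], Inf))
  locmin <- locmin[order(rss_grid[locmin])]
  if (length(locmin) > 3) locmin <- locmin[1:3]
  att <- att_grid[which.min(rss_grid)]
  best_rss <- min(rss_grid)
  for (k in locmin) {
    lo <- att_grid[max(k - 1, 1)]; hi <- att_grid[min(k + 1, ng)]
    if (hi > lo) {
      op <- stats::optimize(function(a) obj(a)$rss, c(lo, hi), tol = 1e-7)
      if (op$objective < best_rss) { att <- op$minimum; best_rss <- op$objective }
    }
  }
  # the active arterial plateau can switch within a bracket, carving narrow
  # secondary dips that golden-section search skips: finish with a fine local
  # sweep around the incumbent plus one last polish
  fine <- seq(max(att - 0.12, att_bounds[1]),
              min(att + 0.12, att_bounds[2]), by = 0.02)
  rss_fine <- vapply(fine, function(a) obj(a)$rss, 0)
  kf <- which.min(rss_fine)
  if (rss_fine[kf] < best_rss) { att <- fine[kf]; best_rss <- rss_fine[kf] }
  op <- stats::optimize(function(a) obj(a)$rss,
                        c(max(att - 0.02, att_bounds[1]),
                          min(att + 0.02, att_bounds[2])), tol = 1e-8)
  if (op$objective < best_rss) att <- op$minimum
  fin <- obj(att)
  # recompute the winning rss exactly (the quadratic-form shortcut can lose
  # precision on near-perfect fits)
  Xf <- 2 * .tissue_kernel(t, att, tau, t1b, t1t, sequence)
  atta_idx <- which(cand$atta == fin$atta)
  Xa <- if (fin$coef[2] > 0 && length(atta_idx))
    cand$A[, atta_idx[1]] else 0
  r <- y - fin$coef[1] * Xf - fin$coef[2] * Xa
  list(f_rel = fin$coef[1], abv = fin$coef[2], att = att,
       att_art = min(fin$atta, att), rss = sum(r * r), converged = TRUE)
}

#' @export
print.perfusion_maps <- function(x, ...) {
  cat("<perfusion_maps> grid ", paste(dim(x$cbf_rel), collapse = "x"),
      ", fitted voxels ", sum(x$mask),
      ", converged ", sum(x$converged), "\n", sep = "")
  invisible(x)
}
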