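# Internal array helpers shared by the phantom, bias-field and smoothing code.

# Separable Gaussian blur of a 3D array, sigma per axis in voxels.
# Zero-padded boundaries (values outside the grid contribute 0), which is the
# behaviour the partial-volume construction relies on.
.gauss_blur3d <- function(x, sigma_vox) {
  stopifnot(length(dim(x)) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    x <- .conv_along(x, k, ax)
  }
  x
}

# 1D convolution of a 3D array along axis `ax` with kernel k (odd length),
# zero padding.
.conv_along <- function(x, k, ax) {
  d <- dim(x)
  half <- (length(k) - 1L) / 2L
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - 1L - half
    src <- seq_len(d[ax]) + off
    ok <- src >= 1L & src <= d[ax]
    if (!any(ok)) next
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (ax == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * x[idx_src, , ]
    if (ax == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * x[, idx_src, ]
    if (ax == 3L) out[, , idx_dst] <- out[, , idx_dst] + k[j] * x[, , idx_src]
  }
  out
}

# In-plane (x,y) median filter with square kernel `size` (odd), restricted to
# `mask`: only voxels inside the mask are filtered, and only masked neighbours
# enter each median (no mixing with background zeros). NA neighbours ignored.
.median_filter_inplane <- function(x, size, mask) {
  stopifnot(size %% 2 == 1)
  d <- dim(x)
  half <- (size - 1L) / 2L
  out <- x
  offs <- expand.grid(dx = -half:half, dy = -half:half)
  for (z in seq_len(d[3])) {
    sl <- x[, , z]
    mk <- mask[, , z]
    if (!any(mk)) next
    stack <- array(NA_real_, c(d[1], d[2], nrow(offs)))
    for (o in seq_len(nrow(offs))) {
      dx <- offs$dx[o]; dy <- offs$dy[o]
      xs <- seq_len(d[1]) + dx
      ys <- seq_len(d[2]) + dy
      okx <- xs >= 1 & xs <= d[1]
      oky <- ys >= 1 & ys <= d[2]
      tmp <- matrix(NA_real_, d[1], d[2])
      vals <- sl[xs[okx], ys[oky], drop = FALSE]
      mvals <- mk[xs[okx], ys[oky], drop = FALSE]
      vals[!mvals] <- NA_real_
      tmp[which(okx), which(oky)] <- vals
      stack[, , o] <- tmp
    }
    med <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
    sl[mk] <- med[mk]
    out[, , z] <- sl
  }
  out
}

# Normalised coordinate grids in [-1, 1] per axis for a 3D dim.
.norm_coords <- function(d) {
  cx <- if (d[1] > 1) (seq_len(d[1]) - (d[1] + 1) / 2) / ((d[1] - 1) / 2) else 0
  cy <- if (d[2] > 1) (seq_len(d[2]) - (d[2] + 1) / 2) / ((d[2] - 1) / 2) else 0
  cz <- if (d[3] > 1) (seq_len(d[3]) - (d[3] + 1) / 2) / ((d[3] - 1) / 2) else 0
  list(x = array(rep(cx, times = d[2] * d[3]), d),
       y = array(rep(rep(cy, each = d[1]), times = d[3]), d),
       z = array(rep(cz, each = d[1] * d[2]), d))
}

.check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must share the same grid (", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}
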