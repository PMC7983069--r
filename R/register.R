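#' Estimate the rigid XY shift between two frames
#'
#' Finds the integer pixel translation that maximizes the normalized
#' cross-correlation (NCC) between a reference and a moving frame. The NCC
#' at each candidate shift is computed over the overlap region only, so the
#' estimate is free of wrap-around artifacts. The returned `(dy, dx)` is the
#' displacement to apply to the moving frame to align it to the reference:
#' if the moving frame content is the reference translated by `(+a, +b)`,
#' the estimate is `(-a, -b)`.
#'
#' Ties in the correlation peak are broken by the smallest shift magnitude,
#' then lexicographically by `(dy, dx)`.
#'
#' @param reference,moving numeric matrices of identical dimension.
#' @param max_shift maximum absolute shift searched in either axis
#'   (default: a quarter of the smaller image dimension).
#' @param method `"ncc"` (normalized, the default) or `"cc"` (plain
#'   zero-mean cross-correlation).
#' @param ncc_threshold peak NCC below which the estimate is flagged
#'   `low_confidence` (default 0.2).
#' @param min_overlap minimum fraction of the frame area that must overlap
#'   for a shift to be considered (default 0.5).
#' @return list with integer `dy`, `dx`, the peak correlation `ncc`, and a
#'   logical `low_confidence` flag.
#' @export
estimate_shift <- function(reference, moving, max_shift = NULL,
                           method = c("ncc", "cc"), ncc_threshold = 0.2,
                           min_overlap = 0.5) {
  method <- match.arg(method)
  assert_matrix_image(reference, "reference")
  assert_matrix_image(moving, "moving")
  assert_same_dim(reference, moving)
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop_orx("cannot register constant (zero-variance) images",
             class = "orx_registration_error")
  H <- nrow(reference); W <- ncol(reference)
  if (is.null(max_shift)) max_shift <- floor(min(H, W) / 4)
  ncc <- ncc_surface(reference, moving, max_shift, min_overlap,
                     normalized = method == "ncc")
  sh <- ncc$shifts
  best <- which(ncc$value >= max(ncc$value, na.rm = TRUE) - 1e-12)
  if (length(best) > 1) {
    mag <- sh$dy[best]^2 + sh$dx[best]^2
    best <- best[order(mag, sh$dy[best], sh$dx[best])][1]
  }
  list(dy = sh$dy[best], dx = sh$dx[best],
       ncc = ncc$value[best],
       low_confidence = ncc$value[best] < ncc_threshold)
}

# FFT-accelerated sliding sums: for every shift (dy, dx) compute
# sum over the overlap of ref, mov, ref*mov, ref^2, mov^2 and the overlap
# pixel count, then assemble the overlap-normalized correlation.
ncc_surface <- function(ref, mov, max_shift, min_overlap, normalized = TRUE) {
  H <- nrow(ref); W <- ncol(ref)
  P <- 2 * H; Q <- 2 * W   # zero-padded FFT size (>= H + H - 1)
  pad <- function(m) { out <- matrix(0, P, Q); out[1:H, 1:W] <- m; out }
  Fc <- function(m) stats::fft(pad(m))
  corr <- function(A_f, B_f) {
    # cc[dy,dx] = sum_yx A[y,x] * B[y-dy, x-dx]
    Re(stats::fft(A_f * Conj(B_f), inverse = TRUE)) / (P * Q)
  }
  ones <- matrix(1, H, W)
  f_ref <- Fc(ref); f_mov <- Fc(mov); f_one <- Fc(ones)
  f_ref2 <- Fc(ref^2); f_mov2 <- Fc(mov^2)
  s_rm <- corr(f_ref, f_mov)
  n_ov <- corr(f_one, f_one)
  s_r <- corr(f_ref, f_one)
  s_m <- corr(f_one, f_mov)
  s_r2 <- corr(f_ref2, f_one)
  s_m2 <- corr(f_one, f_mov2)
  dys <- -max_shift:max_shift
  dxs <- -max_shift:max_shift
  idx_y <- ifelse(dys >= 0, dys + 1L, P + dys + 1L)
  idx_x <- ifelse(dxs >= 0, dxs + 1L, Q + dxs + 1L)
  shifts <- expand.grid(dy = dys, dx = dxs)
  take <- function(m) as.vector(m[idx_y, idx_x, drop = FALSE])
  n <- pmax(take(n_ov), 1)
  num <- take(s_rm) - take(s_r) * take(s_m) / n
  value <- if (normalized) {
    va <- pmax(take(s_r2) - take(s_r)^2 / n, 0)
    vb <- pmax(take(s_m2) - take(s_m)^2 / n, 0)
    den <- sqrt(va * vb)
    ifelse(den > 1e-12, num / den, -Inf)
  } else num / n
  value[n < min_overlap * H * W] <- -Inf
  list(shifts = shifts, value = value)
}

#' Register a well time series against its pretreatment frame
#'
#' Shifts are estimated on the NAD(P)H channel of every frame against the
#' first (pretreatment) frame and the identical shift is applied to the
#' paired FAD frame. The common region -- the rectangle covered by every
#' shifted frame -- is computed from the shift range and all output frames
#' are cropped to it, discarding image areas that do not overlap across the
#' series.
#'
#' @param series a [well_series] with at least 2 frames.
#' @param ... passed to [estimate_shift].
#' @return list with elements `series` (the registered, cropped
#'   [well_series]), `shifts` (data frame: frame, dy, dx, ncc,
#'   low_confidence), and `common_region` (`c(y0, y1, x0, x1)`, 1-based
#'   inclusive in pre-crop coordinates).
#' @export
register_series <- function(series, ...) {
  stopifnot(inherits(series, "well_series"))
  nf <- length(series$nadh)
  if (nf < 2)
    stop_orx("need >= 2 frames to register", class = "orx_registration_error")
  H <- nrow(series$nadh[[1]]); W <- ncol(series$nadh[[1]])
  sh <- data.frame(frame = seq_len(nf), dy = 0L, dx = 0L, ncc = 1,
                   low_confidence = FALSE)
  for (i in 2:nf) {
    e <- estimate_shift(series$nadh[[1]], series$nadh[[i]], ...)
    sh$dy[i] <- e$dy; sh$dx[i] <- e$dx; sh$ncc[i] <- e$ncc
    sh$low_confidence[i] <- e$low_confidence
  }
  y0 <- 1 + max(c(0, sh$dy)); y1 <- H + min(c(0, sh$dy))
  x0 <- 1 + max(c(0, sh$dx)); x1 <- W + min(c(0, sh$dx))
  if (y0 > y1 || x0 > x1)
    stop_orx("registered frames have empty intersection",
             class = "orx_registration_error")
  nadh <- fad <- vector("list", nf)
  for (i in seq_len(nf)) {
    a <- shift_matrix(series$nadh[[i]], sh$dy[i], sh$dx[i])
    b <- shift_matrix(series$fad[[i]], sh$dy[i], sh$dx[i])
    nadh[[i]] <- a[y0:y1, x0:x1, drop = FALSE]
    fad[[i]] <- b[y0:y1, x0:x1, drop = FALSE]
  }
  out <- well_series(nadh, fad, series$times_h, series$treatment,
                     series$well_id)
  list(series = out, shifts = sh, common_region = c(y0, y1, x0, x1))
}

#' Compute the per-pixel optical redox ratio image
#'
#' The optical redox ratio (ORR) at pixel `(i, j)` is
#' `NAD(P)H / (FAD + NAD(P)H)`, a unitless value in `[0, 1]` that maps the
#' local oxidation-reduction state. Pixels where both channels are zero
#' carry no signal and are set to `NaN`; they are excluded from all
#' downstream statistics (never coerced to 0, which would bias minima).
#'
#' @param nadh,fad nonnegative numeric matrices of identical dimension.
#' @return numeric matrix of ORR values (`NaN` where undefined).
#' @export
compute_orr <- function(nadh, fad) {
  assert_matrix_image(nadh, "nadh")
  assert_matrix_image(fad, "fad")
  assert_same_dim(nadh, fad)
  tot <- nadh + fad
  orr <- nadh / tot
  orr[tot == 0] <- NaN
  orr
}
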