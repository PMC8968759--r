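#' Cauchy probability density profile
#'
#' Evaluates `C(x) = 1 / (pi * gamma * (1 + ((x - x0)/gamma)^2))`, the
#' heavy-tailed curve used as the model of a vessel's cross-section
#' intensity dip. The value is strictly positive and maximal (`1/(pi*gamma)`)
#' at `x = x0`.
#'
#' @param x Numeric vector of offsets in pixels.
#' @param gamma Positive scale parameter (pixels).
#' @param x0 Peak shift (pixels).
#' @return Numeric vector of density values.
#' @examples
#' cauchyProfile(0)            # 1/pi
#' cauchyProfile(1)            # 1/(2*pi): halved at x = gamma
#' @export
cauchyProfile <- function(x, gamma = 1, x0 = 0) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive number")
  1 / (pi * gamma * (1 + ((x - x0) / gamma)^2))
}

#' Build the base (unrotated) matched-filter kernel
#'
#' Returns an `L x T` matrix whose every row holds the negated Cauchy
#' profile sampled at integer offsets `-(T-1)/2 .. (T-1)/2` (negated so a
#' dark vessel on a brighter background gives a positive response), then
#' mean-subtracted so the kernel sums to ~0 and ignores constant background.
#' The vessel axis runs along the rows; the cross-section varies along the
#' columns.
#'
#' @param params A [CauchyParams-class] object.
#' @return `L x T` numeric matrix with `|sum| < 1e-10 * T * L * max|kernel|`.
#' @examples
#' k <- buildKernel(cauchyParams())
#' dim(k)        # 8 x 9
#' sum(k)        # ~0
#' @export
buildKernel <- function(params = cauchyParams()) {
  stopifnot(is(params, "CauchyParams"))
  validObject(params)
  offs <- seq_len(params@T) - 1 - (params@T - 1) / 2
  row <- -cauchyProfile(offs, params@gamma, params@x0)
  k <- matrix(row, nrow = params@L, ncol = params@T, byrow = TRUE)
  k - mean(k)
}

# smallest odd square support that contains the base kernel at any rotation
.bankSide <- function(params) {
  s <- ceiling(sqrt(params@T^2 + params@L^2))
  if (s %% 2 == 0) s + 1L else as.integer(s)
}

# rotate a square kernel about its centre by `theta` (radians) using
# inverse-mapped bilinear interpolation; out-of-support samples are 0
.rotateKernel <- function(k, theta) {
  s <- nrow(k)
  c0 <- (s + 1) / 2
  rc <- expand.grid(r = seq_len(s), c = seq_len(s))
  dr <- rc$r - c0; dc <- rc$c - c0
  # inverse rotation of output coordinates into the source frame
  sr <- cos(theta) * dr + sin(theta) * dc + c0
  sc <- -sin(theta) * dr + cos(theta) * dc + c0
  r0 <- floor(sr); c0i <- floor(sc)
  fr <- sr - r0; fc <- sc - c0i
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= s & ci >= 1 & ci <= s
    v <- numeric(length(ri))
    v[ok] <- k[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0i) +
         (1 - fr) * fc       * val(r0, c0i + 1) +
         fr       * (1 - fc) * val(r0 + 1, c0i) +
         fr       * fc       * val(r0 + 1, c0i + 1)
  matrix(out, s, s)
}

#' Build the rotated matched-filter bank
#'
#' Embeds the base kernel of [buildKernel()] centred in a square support
#' whose side is the smallest odd integer not below `sqrt(T^2 + L^2)`, then
#' rotates it by `k * pi / nOrientations` for `k = 0 .. nOrientations - 1`
#' with bilinear interpolation. Each rotated kernel is re-centred to zero
#' mean (interpolation breaks exact zero-mean), preserving the bank's
#' defining invariance to constant background.
#'
#' @param params A [CauchyParams-class] object.
#' @return A [MatchedFilterBank-class] with `nOrientations` kernels.
#' @examples
#' bank <- buildBank(cauchyParams())
#' length(bankKernels(bank))   # 12
#' @export
buildBank <- function(params = cauchyParams()) {
  stopifnot(is(params, "CauchyParams"))
  validObject(params)
  side <- .bankSide(params)
  base <- buildKernel(params)
  emb <- matrix(0, side, side)
  r0 <- (side - params@L) %/% 2
  c0 <- (side - params@T) %/% 2
  emb[r0 + seq_len(params@L), c0 + seq_len(params@T)] <- base
  n <- params@nOrientations
  angles <- (seq_len(n) - 1) * pi / n
  kernels <- lapply(angles, function(th) {
    k <- if (th == 0) emb else .rotateKernel(emb, th)
    k - mean(k)
  })
  new("MatchedFilterBank", kernels = kernels, orientations = angles,
      params = params)
}

# reflect-pad a matrix by p pixels on every side (edge row/col repeated
# mirror: row p, p-1, ..., 1 above the first row)
.padReflect <- function(m, p) {
  H <- nrow(m); W <- ncol(m)
  if (p >= H || p >= W)
    stop("raster too small for reflect padding of ", p, " pixels")
  ri <- c(p:1, 1:H, H:(H - p + 1))
  ci <- c(p:1, 1:W, W:(W - p + 1))
  m[ri, ci, drop = FALSE]
}

#' Maximum response of a filter bank
#'
#' Correlates the input channel with every kernel of the bank (reflect
#' padding at the borders) and keeps the per-pixel maximum over
#' orientations. Because the kernels are zero-mean, a constant image gives
#' a ~0 response everywhere; vessels matching a kernel's orientation and
#' width produce strong positive peaks.
#'
#' @param channel 2-D numeric matrix of finite intensities.
#' @param bank A [MatchedFilterBank-class].
#' @return Numeric matrix of the same dimensions as `channel`.
#' @export
maxResponse <- function(channel, bank) {
  if (!is.matrix(channel) || !all(is.finite(channel)))
    stop("'channel' must be a finite-valued numeric matrix")
  stopifnot(is(bank, "MatchedFilterBank"))
  if (length(bank@kernels) == 0L) stop("empty filter bank")
  side <- nrow(bank@kernels[[1]])
  p <- (side - 1) %/% 2
  padded <- .padReflect(channel, p)
  out <- NULL
  for (k in bank@kernels) {
    # EBImage::filter2 convolves (flips the kernel); flip back to correlate
    flipped <- k[side:1, side:1, drop = FALSE]
    r <- EBImage::filter2(padded, flipped, boundary = "circular")
    r <- r[p + seq_len(nrow(channel)), p + seq_len(ncol(channel)),
           drop = FALSE]
    out <- if (is.null(out)) r else pmax(out, r)
  }
  unclass(out)
}

#' Rescale a raster to the unit interval
#'
#' Affine min-max map onto `[0, 1]`. A constant raster (degenerate range)
#' maps to all zeros.
#'
#' @param raster Finite numeric matrix or array.
#' @return Object of the same shape with values in `[0, 1]`.
#' @examples
#' rescaleUnit(matrix(c(0, 5, 10, 5), 2))
#' @export
rescaleUnit <- function(raster) {
  if (!all(is.finite(raster))) stop("'raster' must be finite-valued")
  rng <- range(raster)
  if (rng[1] == rng[2]) {
    raster[] <- 0
    return(raster)
  }
  (raster - rng[1]) / (rng[2] - rng[1])
}
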