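#' Preprocessing configuration
#'
#' @param clipLimit CLAHE contrast clip limit (relative to the uniform
#'   histogram height; 0 disables clipping).
#' @param tiles Integer vector of length 2: the CLAHE tile grid.
#' @return Named list used by [buildFeatureMap()] and [applyClahe()].
#' @export
preprocessConfig <- function(clipLimit = 2, tiles = c(8L, 8L)) {
  stopifnot(length(tiles) == 2, all(tiles >= 1), clipLimit >= 0)
  list(clipLimit = clipLimit, tiles = as.integer(tiles))
}

#' Standardize an intensity channel
#'
#' Centres and scales a channel to zero mean and unit standard deviation:
#' `(I - mu) / sigma`. When a mask is supplied, `mu` and `sigma` are
#' computed over `mask == 1` pixels only, so the black surround outside the
#' field of view does not distort the statistics; the transform is still
#' applied to every pixel. A constant region (`sigma = 0`) returns all
#' zeros.
#'
#' @param channel Finite numeric matrix.
#' @param mask Optional 0/1 matrix selecting the statistics region.
#' @return Numeric matrix of the same dimensions.
#' @examples
#' standardizeChannel(matrix(c(0, 2, 0, 2), 2))
#' @export
standardizeChannel <- function(channel, mask = NULL) {
  if (!is.matrix(channel) || !all(is.finite(channel)))
    stop("'channel' must be a finite-valued numeric matrix")
  if (is.null(mask)) {
    vals <- channel
  } else {
    if (!all(dim(mask) == dim(channel)))
      stop("'mask' dimensions do not match 'channel'")
    vals <- channel[mask == 1]
    if (length(vals) == 0) stop("statistics region is empty")
  }
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))   # population sd, as in image statistics
  if (!is.finite(sigma) || sigma == 0) {
    channel[] <- 0
    return(channel)
  }
  (channel - mu) / sigma
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to a single channel: the image is divided into a grid of
#' tiles, each tile's histogram is clipped at `clipLimit` times the uniform
#' height and equalized, and tile mappings are bilinearly interpolated.
#' Internally the raster is reflect-padded to tile-size multiples and
#' cropped back afterwards. Input may be `[0, 1]` doubles or 0..255
#' integers; the output is returned on the same scale (rounded back to the
#' 8-bit grid for integer input).
#'
#' @param channel 2-D numeric matrix.
#' @param clipLimit Contrast clip limit (see [preprocessConfig()]).
#' @param tiles Length-2 integer vector: tile grid dimensions.
#' @return Matrix of the same dimensions and scale as the input.
#' @export
applyClahe <- function(channel, clipLimit = 2, tiles = c(8L, 8L)) {
  if (!is.matrix(channel)) stop("'channel' must be a 2-D matrix")
  if (!all(is.finite(channel))) stop("'channel' must be finite-valued")
  eightBit <- max(channel) > 1
  x <- if (eightBit) channel / 255 else channel
  H <- nrow(x); W <- ncol(x)
  ph <- (tiles[1] - H %% tiles[1]) %% tiles[1]
  pw <- (tiles[2] - W %% tiles[2]) %% tiles[2]
  xp <- x
  if (ph > 0) xp <- rbind(xp, xp[H:(H - ph + 1), , drop = FALSE])
  if (pw > 0) xp <- cbind(xp, xp[, W:(W - pw + 1), drop = FALSE])
  y <- EBImage::clahe(EBImage::Image(xp), nx = tiles[1], ny = tiles[2],
                      bins = 256L, limit = clipLimit)
  y <- as.matrix(y@.Data)[seq_len(H), seq_len(W), drop = FALSE]
  y <- pmin(pmax(y, 0), 1)
  if (eightBit) round(y * 255) else y
}

#' Build the Cauchy-G-B feature map
#'
#' The preprocessing pipeline that turns a fundus image into the network
#' input: (a) CLAHE on each colour channel; (b) per-channel
#' standardization, with statistics restricted to the FOV when a mask is
#' present; (c) maximum matched-filter response computed on the processed
#' green channel; (d) unit-rescaling of all three output planes;
#' (e) assembly as (response, green, blue) -- the raw red plane is
#' discarded. Pixels outside the FOV are zeroed in all planes.
#'
#' With `features = "rgb"` the matched-filter step is skipped and the
#' preprocessed red channel is kept in plane 1; this ablation is used to
#' quantify the contribution of the response channel.
#'
#' @param img A [FundusImage-class].
#' @param bank A [MatchedFilterBank-class]; ignored for `features = "rgb"`.
#' @param cfg A [preprocessConfig()] list.
#' @param features `"cauchy-gb"` (default) or `"rgb"` (ablation).
#' @return A [FeatureMap-class] with the same height and width as `img`.
#' @export
buildFeatureMap <- function(img, bank = buildBank(), cfg = preprocessConfig(),
                            features = c("cauchy-gb", "rgb")) {
  stopifnot(is(img, "FundusImage"))
  features <- match.arg(features)
  d <- dim(img@rgb)
  if (length(d) != 3 || d[3] != 3) stop("image must have 3 channels")
  fov <- img@fovMask
  proc <- array(0, d)
  for (ch in 1:3) {
    x <- applyClahe(img@rgb[, , ch], cfg$clipLimit, cfg$tiles)
    proc[, , ch] <- standardizeChannel(x, fov)
  }
  plane1 <- if (features == "cauchy-gb") {
    maxResponse(proc[, , 2], bank)
  } else {
    proc[, , 1]
  }
  planes <- array(0, d)
  planes[, , 1] <- rescaleUnit(plane1)
  planes[, , 2] <- rescaleUnit(proc[, , 2])
  planes[, , 3] <- rescaleUnit(proc[, , 3])
  if (!is.null(fov)) {
    for (ch in 1:3) planes[, , ch] <- planes[, , ch] * fov
  }
  new("FeatureMap", planes = planes, sourceId = img@id)
}
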