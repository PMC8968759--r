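setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Cauchy matched-filter parameters
#'
#' Parameters of the vessel cross-section template. The template models the
#' intensity dip across a vessel as a Cauchy probability density
#' `C(x) = 1 / (pi * gamma * (1 + ((x - x0)/gamma)^2))`, sampled at `T`
#' integer offsets across the vessel (the template "trunk") and repeated
#' over `L` rows along the vessel axis. The bank holds `nOrientations`
#' rotated copies covering `[0, pi)`.
#'
#' @slot gamma Scale of the Cauchy profile in pixels; controls the slope of
#'   the dip. Must be positive.
#' @slot x0 Horizontal shift of the profile peak in pixels.
#' @slot T Cross-section truncation width in pixels (odd, at least 3).
#' @slot L Template extent along the vessel axis in pixels (at least 1).
#' @slot nOrientations Number of rotated copies in the bank (at least 1).
#'
#' @seealso [cauchyParams()] for the user-facing constructor with the
#'   reference configuration `gamma = 1, x0 = 0, T = 9, L = 8,
#'   nOrientations = 12`.
#' @export
setClass("CauchyParams",
  representation(gamma = "numeric", x0 = "numeric", T = "integer",
                 L = "integer", nOrientations = "integer"),
  prototype(gamma = 1, x0 = 0, T = 9L, L = 8L, nOrientations = 12L))

setValidity("CauchyParams", function(object) {
  msg <- character()
  if (length(object@gamma) != 1 || !is.finite(object@gamma) || object@gamma <= 0)
    msg <- c(msg, "'gamma' must be a single positive number")
  if (length(object@x0) != 1 || !is.finite(object@x0))
    msg <- c(msg, "'x0' must be a single finite number")
  if (length(object@T) != 1 || object@T < 3L || object@T %% 2L == 0L)
    msg <- c(msg, "'T' must be an odd integer >= 3")
  if (length(object@L) != 1 || object@L < 1L)
    msg <- c(msg, "'L' must be a positive integer")
  if (length(object@nOrientations) != 1 || object@nOrientations < 1L)
    msg <- c(msg, "'nOrientations' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Oriented bank of Cauchy matched-filter kernels
#'
#' An ordered set of square, odd-sided, zero-mean 2-D kernels, each the base
#' Cauchy template rotated by `k * pi / nOrientations`. The kernels are
#' negated Cauchy profiles, so dark vessels on a brighter background yield
#' positive correlation responses.
#'
#' @slot kernels List of square numeric matrices, all with the same odd side.
#' @slot orientations Rotation angles in radians, in `[0, pi)`.
#' @slot params The [CauchyParams-class] object the bank was built from.
#'
#' @seealso [buildBank()], [maxResponse()]
#' @export
setClass("MatchedFilterBank",
  representation(kernels = "list", orientations = "numeric",
                 params = "CauchyParams"))

setValidity("MatchedFilterBank", function(object) {
  msg <- character()
  nk <- length(object@kernels)
  if (nk == 0L) msg <- c(msg, "bank must contain at least one kernel")
  if (nk != length(object@orientations))
    msg <- c(msg, "lengths of 'kernels' and 'orientations' differ")
  if (nk != object@params@nOrientations)
    msg <- c(msg, "kernel count does not match params@nOrientations")
  sides <- vapply(object@kernels, function(k) {
    if (!is.matrix(k) || nrow(k) != ncol(k)) return(-1L) else nrow(k)
  }, integer(1))
  if (any(sides < 0) || length(unique(sides)) > 1 || any(sides %% 2L == 0L))
    msg <- c(msg, "kernels must be square matrices sharing one odd side length")
  for (k in object@kernels) {
    if (abs(mean(k)) >= 1e-10 * max(abs(k))) {
      msg <- c(msg, "kernels must be zero-mean")
      break
    }
  }
  if (nk > 1) {
    sp <- diff(object@orientations)
    if (any(abs(sp - pi / nk) > 1e-12))
      msg <- c(msg, "orientation spacing must equal pi / nOrientations")
  }
  if (length(msg)) msg else TRUE
})

#' A fundus image with optional masks
#'
#' Container for one RGB fundus photograph together with its circular
#' field-of-view (FOV) mask and, when available, a manually traced binary
#' vessel map. Intensities are stored as doubles in `[0, 1]`; masks are
#' strictly 0/1 integer matrices with the same height and width as the image.
#'
#' @slot rgb `H x W x 3` numeric array, values in `[0, 1]`.
#' @slot fovMask `H x W` 0/1 matrix marking the retinal disc, or `NULL`.
#' @slot gtMask `H x W` 0/1 matrix of reference vessel pixels, or `NULL`.
#' @slot id Character label identifying the image.
#'
#' @seealso [fundusImage()], [readFundusImage()], [generatePhantom()]
#' @export
setClass("FundusImage",
  representation(rgb = "array", fovMask = "matrixOrNULL",
                 gtMask = "matrixOrNULL", id = "character"))

.checkMask <- function(mask, dims, what) {
  if (is.null(mask)) return(character())
  msg <- character()
  if (!all(dim(mask) == dims))
    msg <- c(msg, sprintf("'%s' dimensions do not match the image", what))
  if (!all(mask %in% c(0, 1)))
    msg <- c(msg, sprintf("'%s' must be strictly 0/1-valued", what))
  msg
}

setValidity("FundusImage", function(object) {
  msg <- character()
  d <- dim(object@rgb)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "'rgb' must be an H x W x 3 array")
  if (!all(is.finite(object@rgb)))
    msg <- c(msg, "'rgb' must be finite")
  msg <- c(msg, .checkMask(object@fovMask, d[1:2], "fovMask"),
           .checkMask(object@gtMask, d[1:2], "gtMask"))
  if (length(object@id) != 1) msg <- c(msg, "'id' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Three-plane Cauchy-G-B feature map
#'
#' The network input raster: plane 1 is the unit-rescaled maximum response
#' of the Cauchy matched-filter bank, planes 2 and 3 are the preprocessed
#' (CLAHE + standardized + rescaled) green and blue channels. All values
#' lie in `[0, 1]`.
#'
#' @slot planes `H x W x 3` numeric array in `[0, 1]`, ordered
#'   (response, green, blue).
#' @slot sourceId Identifier of the source [FundusImage-class].
#'
#' @seealso [buildFeatureMap()]
#' @export
setClass("FeatureMap",
  representation(planes = "array", sourceId = "character"))

setValidity("FeatureMap", function(object) {
  msg <- character()
  d <- dim(object@planes)
  if (length(d) != 3 || d[3] != 3)
    msg <- c(msg, "'planes' must be an H x W x 3 array")
  if (!all(is.finite(object@planes)) || min(object@planes) < 0 ||
      max(object@planes) > 1)
    msg <- c(msg, "'planes' values must lie in [0, 1]")
  if (length(object@sourceId) != 1)
    msg <- c(msg, "'sourceId' must be a single string")
  if (length(msg)) msg else TRUE
})

#' A set of aligned input/label patches
#'
#' Square crops of a feature map together with the corresponding crops of
#' the reference vessel map, their source coordinates, and train/val/test
#' split tags.
#'
#' @slot inputs `size x size x 3 x N` numeric array in `[0, 1]`.
#' @slot labels `size x size x N` 0/1 numeric array.
#' @slot coords `N x 2` integer matrix of top-left (row, col) positions
#'   (1-based) in the source raster.
#' @slot sourceIds Character vector of length `N`.
#' @slot split Character vector of length `N`; `"train"`, `"val"`, `"test"`
#'   or `""` when untagged.
#'
#' @seealso [sampleTrainingPatches()], [augmentFlips()], [splitTrainVal()]
#' @export
setClass("PatchSet",
  representation(inputs = "array", labels = "array", coords = "matrix",
                 sourceIds = "character", split = "character"))

setValidity("PatchSet", function(object) {
  msg <- character()
  di <- dim(object@inputs); dl <- dim(object@labels)
  if (length(di) != 4 || di[1] != di[2])
    msg <- c(msg, "'inputs' must be a size x size x C x N array")
  if (length(dl) != 3 || any(dl[1:2] != di[1:2]))
    msg <- c(msg, "'labels' must be a size x size x N array matching 'inputs'")
  n <- di[4]
  if (dl[3] != n || nrow(object@coords) != n ||
      length(object@sourceIds) != n || length(object@split) != n)
    msg <- c(msg, "field lengths are inconsistent with the patch count")
  if (n > 0) {
    if (min(object@inputs) < 0 || max(object@inputs) > 1)
      msg <- c(msg, "'inputs' values must lie in [0, 1]")
    if (!all(object@labels %in% c(0, 1)))
      msg <- c(msg, "'labels' must be strictly 0/1-valued")
    if (!all(object@split %in% c("", "train", "val", "test")))
      msg <- c(msg, "'split' tags must be train/val/test or empty")
  }
  if (length(msg)) msg else TRUE
})

#' Tiling geometry of a test image
#'
#' Records how a raster was reflect-padded and cut into non-overlapping
#' square tiles, so that per-tile predictions can be stitched back and the
#' padding cropped off.
#'
#' @slot height,width Original raster dimensions in pixels.
#' @slot padBottom,padRight Reflect padding added to reach multiples of
#'   `size`.
#' @slot size Tile side in pixels.
#' @slot coords Integer matrix of tile top-left (row, col) positions in the
#'   padded raster, row-major order.
#'
#' @seealso [tileImage()], [reassembleTiles()]
#' @export
setClass("TileGeometry",
  representation(height = "integer", width = "integer",
                 padBottom = "integer", padRight = "integer",
                 size = "integer", coords = "matrix"))

setValidity("TileGeometry", function(object) {
  msg <- character()
  H <- object@height + object@padBottom
  W <- object@width + object@padRight
  if (H %% object@size != 0 || W %% object@size != 0)
    msg <- c(msg, "padded dimensions must be divisible by 'size'")
  if (nrow(object@coords) != (H %/% object@size) * (W %/% object@size))
    msg <- c(msg, "'coords' must cover the padded raster exactly once")
  if (length(msg)) msg else TRUE
})

#' Pixel-level evaluation report
#'
#' Confusion counts inside the field of view, the four headline metrics,
#' the ROC point list over a global-threshold sweep, its trapezoidal area
#' (AUROC), and the per-threshold metric table used to justify the default
#' operating point `tau = 0.5`.
#'
#' @slot counts Named integer vector with elements `TP`, `TN`, `FP`, `FN`.
#' @slot acc,sen,spc,prc Accuracy, sensitivity, specificity and precision
#'   in `[0, 1]`; `NA` where the defining ratio is 0/0.
#' @slot roc Two-column matrix of (FPR, TPR) points sorted by FPR,
#'   including (0, 0) and (1, 1).
#' @slot auroc Trapezoidal area under the ROC points.
#' @slot tauTable Data frame with one row per threshold: `tau`, `acc`,
#'   `sen`, `spc`, `prc`.
#'
#' @seealso [evaluateSegmentation()], [rocSweep()], [tauSensitivity()]
#' @export
setClass("EvalReport",
  representation(counts = "integer", acc = "numeric", sen = "numeric",
                 spc = "numeric", prc = "numeric", roc = "matrix",
                 auroc = "numeric", tauTable = "data.frame"))

#' U-Net model handle
#'
#' Wraps the compiled network (an external pointer) together with its
#' configuration. The pointer does not survive serialization; use
#' [unetWeights()] / [setUnetWeights()] or [saveUnet()] / [loadUnet()] to
#' persist a model.
#'
#' @slot ptr External pointer to the compiled network.
#' @slot config Named list: `inputSize`, `depth`, `baseFilters`, `nClasses`,
#'   `seed`.
#'
#' @seealso [buildUnet()], [predictPatches()], [trainUnet()]
#' @export
setClass("UNetModel",
  representation(ptr = "externalptr", config = "list"))
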