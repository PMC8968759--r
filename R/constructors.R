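#' Create Cauchy matched-filter parameters
#'
#' The defaults are the reference configuration for DRIVE-scale images:
#' `gamma = 1` pixel, centred profile (`x0 = 0`), a 9-pixel cross-section
#' trunk, an 8-pixel template length, and 12 orientations spaced `pi/12`.
#'
#' @param gamma Positive scale of the Cauchy profile (pixels).
#' @param x0 Peak shift (pixels); 0 centres the dip on the template axis.
#' @param T Odd cross-section truncation width (pixels, >= 3).
#' @param L Template extent along the vessel axis (pixels, >= 1).
#' @param nOrientations Number of rotated bank members (>= 1).
#' @return A [CauchyParams-class] object.
#' @examples
#' cauchyParams()
#' cauchyParams(gamma = 1.5, nOrientations = 18)
#' @export
cauchyParams <- function(gamma = 1, x0 = 0, T = 9L, L = 8L,
                         nOrientations = 12L) {
  new("CauchyParams", gamma = as.numeric(gamma), x0 = as.numeric(x0),
      T = as.integer(T), L = as.integer(L),
      nOrientations = as.integer(nOrientations))
}

#' Create a fundus image object
#'
#' @param rgb `H x W x 3` numeric array. 8-bit integer arrays (values in
#'   0..255) are rescaled to `[0, 1]`.
#' @param fovMask,gtMask Optional `H x W` 0/1 matrices.
#' @param id Character label.
#' @return A [FundusImage-class] object.
#' @export
fundusImage <- function(rgb, fovMask = NULL, gtMask = NULL, id = "image") {
  rgb <- .asUnitArray(rgb)
  if (!is.null(fovMask)) storage.mode(fovMask) <- "double"
  if (!is.null(gtMask)) storage.mode(gtMask) <- "double"
  new("FundusImage", rgb = rgb, fovMask = fovMask, gtMask = gtMask, id = id)
}

# accept [0,1] doubles or 0..255 integers
.asUnitArray <- function(x) {
  if (!all(is.finite(x))) stop("image intensities must be finite")
  storage.mode(x) <- "double"
  if (max(x) > 1) x <- x / 255
  if (min(x) < 0 || max(x) > 1)
    stop("image intensities must be in [0, 1] or 0..255")
  x
}

# ---- accessors ----------------------------------------------------------

#' @describeIn fundusImage The `H x W x 3` intensity array.
#' @param x A `FundusImage` object.
#' @export
imageData <- function(x) x@rgb

#' @describeIn fundusImage The FOV mask (or `NULL`).
#' @export
fovMask <- function(x) x@fovMask

#' @describeIn fundusImage The reference vessel mask (or `NULL`).
#' @export
gtMask <- function(x) x@gtMask

#' @describeIn fundusImage The image identifier.
#' @export
imageId <- function(x) x@id

#' Accessors for matched-filter banks
#'
#' @param x A [MatchedFilterBank-class].
#' @return `bankKernels()` returns the list of kernels, `bankOrientations()`
#'   the angles in radians, `bankParams()` the [CauchyParams-class].
#' @export
bankKernels <- function(x) x@kernels

#' @rdname bankKernels
#' @export
bankOrientations <- function(x) x@orientations

#' @rdname bankKernels
#' @export
bankParams <- function(x) x@params

#' Accessors for feature maps
#'
#' @param x A [FeatureMap-class].
#' @return `featurePlanes()` returns the `H x W x 3` array; `sourceId()`
#'   the originating image id.
#' @export
featurePlanes <- function(x) x@planes

#' @rdname featurePlanes
#' @export
sourceId <- function(x) x@sourceId

#' Accessors for patch sets
#'
#' @param x A [PatchSet-class].
#' @return `patchInputs()`: `size x size x C x N` array; `patchLabels()`:
#'   `size x size x N` array; `patchCoords()`: `N x 2` matrix;
#'   `patchSplit()`: character tags; `nPatches()`: patch count.
#' @export
patchInputs <- function(x) x@inputs

#' @rdname patchInputs
#' @export
patchLabels <- function(x) x@labels

#' @rdname patchInputs
#' @export
patchCoords <- function(x) x@coords

#' @rdname patchInputs
#' @export
patchSplit <- function(x) x@split

#' @rdname patchInputs
#' @export
nPatches <- function(x) dim(x@inputs)[4]

# ---- show methods -------------------------------------------------------

setMethod("show", "CauchyParams", function(object) {
  cat(sprintf(
    "CauchyParams: gamma=%g, x0=%g, T=%d, L=%d, %d orientations\n",
    object@gamma, object@x0, object@T, object@L, object@nOrientations))
})

setMethod("show", "MatchedFilterBank", function(object) {
  s <- nrow(object@kernels[[1]])
  cat(sprintf(
    "MatchedFilterBank: %d kernels (%dx%d), angles 0..%.4f rad (step pi/%d)\n",
    length(object@kernels), s, s, max(object@orientations),
    object@params@nOrientations))
})

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("FundusImage '%s': %d x %d, fov=%s, gt=%s\n", object@id,
              d[1], d[2], !is.null(object@fovMask), !is.null(object@gtMask)))
})

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@planes)
  cat(sprintf("FeatureMap (Cauchy-G-B) of '%s': %d x %d x 3 in [0,1]\n",
              object@sourceId, d[1], d[2]))
})

setMethod("show", "PatchSet", function(object) {
  d <- dim(object@inputs)
  tab <- table(factor(object@split, levels = c("train", "val", "test", "")))
  cat(sprintf(
    "PatchSet: %d patches of %dx%dx%d (train=%d, val=%d, test=%d, untagged=%d)\n",
    d[4], d[1], d[2], d[3], tab[["train"]], tab[["val"]], tab[["test"]],
    tab[[""]]))
})

setMethod("show", "TileGeometry", function(object) {
  cat(sprintf(
    "TileGeometry: %d x %d raster, pad (%d, %d), %d tiles of %d\n",
    object@height, object@width, object@padBottom, object@padRight,
    nrow(object@coords), object@size))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (within FOV):\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", object@counts[["TP"]],
              object@counts[["TN"]], object@counts[["FP"]],
              object@counts[["FN"]]))
  cat(sprintf("  Acc=%.4f Sen=%.4f Spc=%.4f Prc=%.4f AUROC=%.4f\n",
              object@acc, object@sen, object@spc, object@prc, object@auroc))
})

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "UNetModel: %dx%dx%d input, depth %d, base %d filters, %s parameters\n",
    cfg$inputSize[1], cfg$inputSize[2], cfg$inputSize[3], cfg$depth,
    cfg$baseFilters, format(nParams(object), big.mark = ",")))
})
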