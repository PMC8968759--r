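.readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    jpg = , jpeg = {
      # EBImage stores images transposed (x = first dim); restore H x W
      im <- EBImage::readImage(path)
      a <- im@.Data
      if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(x)) == 3 && dim(x)[3] == 4) x <- x[, , 1:3]  # drop alpha
  x
}

.readMask <- function(path) {
  x <- .readRaster(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  # DRIVE-style masks are 0/255; binarize above the 8-bit midpoint
  (x > 127 / 255) * 1
}

#' Read a fundus image trio from disk
#'
#' Reads an RGB image (TIFF/PNG/JPEG) plus optional FOV and ground-truth
#' masks (PNG/TIFF; any value above the 8-bit midpoint becomes 1) and
#' validates that all rasters share the image dimensions.
#'
#' @param imagePath Path to the RGB image.
#' @param fovPath,gtPath Optional mask paths.
#' @param id Label; defaults to the image file name without extension.
#' @return A [FundusImage-class].
#' @export
readFundusImage <- function(imagePath, fovPath = NULL, gtPath = NULL,
                            id = NULL) {
  rgb <- .readRaster(imagePath)
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("not a 3-channel image: ", imagePath)
  checkDims <- function(m, path) {
    if (!all(dim(m) == dim(rgb)[1:2]))
      stop("dimension mismatch between ", imagePath, " and ", path)
    m
  }
  fov <- if (!is.null(fovPath)) checkDims(.readMask(fovPath), fovPath)
  gt <- if (!is.null(gtPath)) checkDims(.readMask(gtPath), gtPath)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(imagePath))
  fundusImage(rgb, fovMask = fov, gtMask = gt, id = id)
}

#' Read a DRIVE-layout directory
#'
#' Scans `dir/images`, `dir/1st_manual` and `dir/mask` (the layout written
#' by [generateDataset()] and used by the DRIVE benchmark) and pairs files
#' by their leading identifier.
#'
#' @param dir Dataset root directory.
#' @return List of [FundusImage-class] objects.
#' @export
readDriveDirectory <- function(dir) {
  imgDir <- file.path(dir, "images")
  files <- sort(list.files(imgDir, pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                           ignore.case = TRUE))
  if (length(files) == 0) stop("no images found under ", imgDir)
  lapply(files, function(f) {
    id <- sub("[_.].*$", "", f)
    findOne <- function(sub, pattern) {
      hits <- list.files(file.path(dir, sub), pattern = pattern,
                         full.names = TRUE)
      if (length(hits) >= 1) hits[1] else NULL
    }
    readFundusImage(file.path(imgDir, f),
                    fovPath = findOne("mask", paste0("^", id, "[_.]")),
                    gtPath = findOne("1st_manual", paste0("^", id, "[_.]")),
                    id = id)
  })
}

#' Persist and reload probability maps
#'
#' Probability maps are stored as single-plane 32-bit float TIFF (lossless
#' to float precision) with a JSON sidecar recording the value range.
#'
#' @param prob `H x W` matrix with values in `[0, 1]`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @export
writeProbabilityMap <- function(prob, path) {
  if (min(prob) < 0 || max(prob) > 1) stop("'prob' must lie in [0, 1]")
  tiff::writeTIFF(prob, path, bits.per.sample = 32L)
  jsonlite::write_json(list(min = min(prob), max = max(prob),
                            height = nrow(prob), width = ncol(prob)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProbabilityMap
#' @return `readProbabilityMap()`: the `H x W` probability matrix.
#' @export
readProbabilityMap <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}
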