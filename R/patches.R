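#' Sample overlapped training patches
#'
#' Draws `nPatches` square crops whose centres are uniform-random over FOV
#' pixels lying at least `size/2` from the raster border (so no patch needs
#' padding). Patches may overlap. Label patches are cut from the reference
#' vessel map at the same coordinates. Sampling is reproducible for a fixed
#' seed.
#'
#' @param fm A [FeatureMap-class].
#' @param gt `H x W` 0/1 matrix of reference vessel pixels.
#' @param fov `H x W` 0/1 FOV mask.
#' @param nPatches Number of patches to draw (default 500, the per-image
#'   count used for DRIVE-scale training images).
#' @param size Patch side in pixels (default 64).
#' @param seed Integer seed.
#' @return A [PatchSet-class] with empty split tags.
#' @export
sampleTrainingPatches <- function(fm, gt, fov, nPatches = 500L, size = 64L,
                                  seed = 1L) {
  stopifnot(is(fm, "FeatureMap"))
  d <- dim(fm@planes)
  if (!all(dim(gt) == d[1:2]) || !all(dim(fov) == d[1:2]))
    stop("'gt' and 'fov' must match the feature-map dimensions")
  half <- size %/% 2
  rows <- row(fov); cols <- col(fov)
  admissible <- which(fov == 1 &
                      rows - half >= 1 & rows - half + size - 1 <= d[1] &
                      cols - half >= 1 & cols - half + size - 1 <= d[2])
  if (length(admissible) == 0)
    stop("no admissible patch centre: FOV too small for patch size ", size)
  idx <- withr::with_seed(seed,
    admissible[sample.int(length(admissible), nPatches, replace = TRUE)])
  cr <- ((idx - 1) %% d[1]) + 1
  cc <- ((idx - 1) %/% d[1]) + 1
  r0 <- cr - half
  c0 <- cc - half
  inputs <- array(0, c(size, size, 3, nPatches))
  labels <- array(0, c(size, size, nPatches))
  for (i in seq_len(nPatches)) {
    ri <- r0[i] + seq_len(size) - 1
    ci <- c0[i] + seq_len(size) - 1
    inputs[, , , i] <- fm@planes[ri, ci, ]
    labels[, , i] <- gt[ri, ci]
  }
  new("PatchSet", inputs = inputs, labels = labels,
      coords = cbind(row = as.integer(r0), col = as.integer(c0)),
      sourceIds = rep(fm@sourceId, nPatches),
      split = rep("", nPatches))
}

.flipPatch <- function(a, horizontal, vertical) {
  # flips act on the spatial dims (1 = rows, 2 = cols) of a 2- or 3-d array
  if (vertical) a <- if (length(dim(a)) == 3) a[dim(a)[1]:1, , , drop = FALSE]
                     else a[dim(a)[1]:1, , drop = FALSE]
  if (horizontal) a <- if (length(dim(a)) == 3) a[, dim(a)[2]:1, , drop = FALSE]
                       else a[, dim(a)[2]:1, drop = FALSE]
  a
}

#' Flip augmentation
#'
#' Expands a patch set four-fold: identity, horizontal flip, vertical flip,
#' and both. Inputs and labels are flipped jointly, so the per-patch vessel
#' pixel count is invariant. With 20 training images at 500 patches each
#' this yields the 40,000 patches available for training and validation.
#'
#' @param ps A non-empty [PatchSet-class].
#' @return A [PatchSet-class] with `4 * nPatches(ps)` patches; coordinates,
#'   source ids and split tags are replicated.
#' @export
augmentFlips <- function(ps) {
  stopifnot(is(ps, "PatchSet"))
  n <- nPatches(ps)
  if (n == 0) stop("empty PatchSet")
  d <- dim(ps@inputs)
  variants <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                   c(TRUE, TRUE))
  inputs <- array(0, c(d[1], d[2], d[3], 4 * n))
  labels <- array(0, c(d[1], d[2], 4 * n))
  for (v in seq_along(variants)) {
    h <- variants[[v]][1]; vv <- variants[[v]][2]
    for (i in seq_len(n)) {
      j <- (v - 1) * n + i
      inputs[, , , j] <- .flipPatch(ps@inputs[, , , i], h, vv)
      labels[, , j] <- .flipPatch(ps@labels[, , i], h, vv)
    }
  }
  new("PatchSet", inputs = inputs, labels = labels,
      coords = ps@coords[rep(seq_len(n), 4), , drop = FALSE],
      sourceIds = rep(ps@sourceIds, 4), split = rep(ps@split, 4))
}

#' Random train/validation split
#'
#' Tags `round(N * valFraction)` patches as `"val"` and the rest as
#' `"train"`, by a seeded patch-level random partition (the split is over
#' all extracted patches, not over images).
#'
#' @param ps A [PatchSet-class].
#' @param valFraction Fraction held out for validation, in (0, 1);
#'   default 0.1.
#' @param seed Integer seed.
#' @return The patch set with split tags assigned.
#' @export
splitTrainVal <- function(ps, valFraction = 0.1, seed = 1L) {
  stopifnot(is(ps, "PatchSet"))
  if (valFraction <= 0 || valFraction >= 1)
    stop("'valFraction' must lie strictly between 0 and 1")
  n <- nPatches(ps)
  nVal <- round(n * valFraction)
  valIdx <- withr::with_seed(seed, sample.int(n, nVal))
  split <- rep("train", n)
  split[valIdx] <- "val"
  initialize(ps, split = split)
}

#' Cut a raster into non-overlapping tiles
#'
#' Reflect-pads the bottom and right edges to multiples of `size`, then
#' cuts the padded raster into disjoint square tiles in row-major order.
#' This is the test-time counterpart of overlapped training sampling: each
#' pixel is predicted exactly once and [reassembleTiles()] restores the
#' original geometry.
#'
#' @param x A [FeatureMap-class], a 2-D matrix, or an `H x W x C` array.
#' @param size Tile side in pixels (default 64).
#' @return List with `tiles` (a list of `size x size (x C)` arrays) and
#'   `geometry` (a [TileGeometry-class]).
#' @export
tileImage <- function(x, size = 64L) {
  if (is(x, "FeatureMap")) x <- x@planes
  d <- dim(x)
  if (is.null(d) || length(d) < 2 || any(d[1:2] == 0)) stop("empty raster")
  H <- d[1]; W <- d[2]
  padB <- (size - H %% size) %% size
  padR <- (size - W %% size) %% size
  ri <- c(1:H, if (padB > 0) H:(H - padB + 1))
  ci <- c(1:W, if (padR > 0) W:(W - padR + 1))
  xp <- if (length(d) == 2) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  nR <- (H + padB) %/% size
  nC <- (W + padR) %/% size
  coords <- cbind(row = rep((0:(nR - 1)) * size + 1L, each = nC),
                  col = rep((0:(nC - 1)) * size + 1L, times = nR))
  tiles <- lapply(seq_len(nrow(coords)), function(i) {
    ri <- coords[i, 1] + seq_len(size) - 1
    ci <- coords[i, 2] + seq_len(size) - 1
    if (length(d) == 2) xp[ri, ci, drop = FALSE] else xp[ri, ci, , drop = FALSE]
  })
  geom <- new("TileGeometry", height = as.integer(H), width = as.integer(W),
              padBottom = as.integer(padB), padRight = as.integer(padR),
              size = as.integer(size), coords = coords)
  list(tiles = tiles, geometry = geom)
}

#' Stitch predicted tiles back into a full raster
#'
#' Inverse of [tileImage()] for single-plane tiles: places each tile at its
#' recorded position and crops the reflect padding, recovering the original
#' `H x W` raster exactly when fed the tiles of `tileImage`.
#'
#' @param predTiles List of `size x size` matrices in the same row-major
#'   order as the geometry's coordinates.
#' @param geom The [TileGeometry-class] returned by [tileImage()].
#' @return `H x W` numeric matrix.
#' @export
reassembleTiles <- function(predTiles, geom) {
  stopifnot(is(geom, "TileGeometry"))
  if (length(predTiles) != nrow(geom@coords))
    stop("tile count (", length(predTiles), ") does not match geometry (",
         nrow(geom@coords), ")")
  Hp <- geom@height + geom@padBottom
  Wp <- geom@width + geom@padRight
  out <- matrix(0, Hp, Wp)
  s <- geom@size
  for (i in seq_along(predTiles)) {
    t <- predTiles[[i]]
    if (length(dim(t)) == 3) t <- t[, , 1]
    ri <- geom@coords[i, 1] + seq_len(s) - 1
    ci <- geom@coords[i, 2] + seq_len(s) - 1
    out[ri, ci] <- t
  }
  out[seq_len(geom@height), seq_len(geom@width), drop = FALSE]
}
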