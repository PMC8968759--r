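#' Synthetic fundus-phantom specification
#'
#' Describes the generator that emulates the aspects of a fundus
#' photograph this pipeline depends on: a circular field of view on a black
#' surround, a reddish low-contrast background with smooth illumination
#' falloff, dark curvilinear vessel trees whose cross-section intensity dip
#' follows a Cauchy profile (scale tied to the vessel width), the dip
#' strongest in the green channel, extra noise in the red channel, and
#' additive Gaussian noise. It does not model pathology, the optic disc,
#' or texture, so results on phantoms demonstrate pipeline correctness and
#' learnability, not clinical performance.
#'
#' @param height,width Raster dimensions in pixels (defaults 584 x 565,
#'   the DRIVE image scale); both at least 128.
#' @param nTrees Number of vessel trees grown from the FOV boundary.
#' @param widthRange Vessel full widths in pixels, within `[1, 15]`.
#' @param depthRange Per-tree contrast: peak intensity dip in the green
#'   channel, in intensity units on `[0, 1]`.
#' @param profile Cross-section shape; only `"cauchy"` is supported.
#' @param backgroundRgb Mean background colour (red-dominant by default).
#' @param noiseSigma Additive Gaussian noise standard deviation (the red
#'   channel receives twice this level, emulating its noisiness).
#' @param seed Integer seed; the whole phantom is a pure function of the
#'   spec.
#' @return Named specification list for [generatePhantom()].
#' @export
phantomSpec <- function(height = 584L, width = 565L, nTrees = 6L,
                        widthRange = c(1, 7), depthRange = c(0.15, 0.35),
                        profile = "cauchy",
                        backgroundRgb = c(0.72, 0.42, 0.22),
                        noiseSigma = 0.06, seed = 1L) {
  if (height < 128 || width < 128) stop("dimensions must be at least 128")
  if (widthRange[1] < 1 || widthRange[2] > 15 ||
      widthRange[1] > widthRange[2])
    stop("'widthRange' must lie within [1, 15]")
  if (noiseSigma < 0) stop("'noiseSigma' must be non-negative")
  if (!identical(profile, "cauchy")) stop("only the 'cauchy' profile is supported")
  list(height = as.integer(height), width = as.integer(width),
       nTrees = as.integer(nTrees), widthRange = widthRange,
       depthRange = depthRange, profile = profile,
       backgroundRgb = backgroundRgb, noiseSigma = noiseSigma,
       seed = as.integer(seed))
}

# branching-random-walk constants (no claim of biological realism)
.PH_STEP_JITTER <- 0.07    # sd of per-step direction change (radians)
.PH_BRANCH_PROB <- 0.012   # per-step branching probability
.PH_BRANCH_SHRINK <- 0.72  # child width factor at a branch
.PH_WIDTH_DECAY <- 0.997   # per-step width shrink
.PH_MAX_STEPS <- 450L      # per-branch step cap

#' Generate a synthetic fundus phantom
#'
#' Grows `nTrees` vessel trees from seeds on the FOV boundary as branching
#' random walks with smoothly drifting directions and slowly shrinking
#' widths, renders each centreline with a normalized Cauchy cross-section
#' profile (scale `gamma = width/2`), subtracts the profile from a
#' red-dominant background (full depth in green, reduced in red and blue),
#' adds Gaussian noise, and snaps intensities to the 8-bit grid so that
#' files written by [generateDataset()] round-trip exactly. The ground
#' truth mask marks pixels where the normalized profile exceeds half its
#' peak -- the visible core a human annotator would trace -- and is always
#' contained in the FOV.
#'
#' @param spec A [phantomSpec()] list.
#' @return A [FundusImage-class] with `gtMask` and `fovMask` set.
#' @examples
#' img <- generatePhantom(phantomSpec(height = 192, width = 192, nTrees = 2,
#'                                    seed = 7))
#' mean(gtMask(img)[fovMask(img) == 1])   # vessel fraction of the FOV
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  H <- spec$height; W <- spec$width
  withr::with_seed(spec$seed, {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    R <- min(H, W) / 2 - 2
    dy <- matrix(seq_len(H) - cy, H, W)
    dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
    dist <- sqrt(dy^2 + dx^2)
    fov <- (dist <= R) * 1

    # walk the trees first, collecting centreline points (row, col, width,
    # depth); rendering happens in a second pass
    wmax <- spec$widthRange[2]; wmin <- spec$widthRange[1]
    pts <- vector("list", spec$nTrees)
    for (t in seq_len(spec$nTrees)) {
      depth <- runif(1, spec$depthRange[1], spec$depthRange[2])
      phi0 <- runif(1, 0, 2 * pi)
      start <- c(cy + (R - 3) * sin(phi0), cx + (R - 3) * cos(phi0))
      # initial direction: inward, jittered
      dir0 <- atan2(cy - start[1], cx - start[2]) + rnorm(1, 0, 0.3)
      w0 <- runif(1, wmin + 0.4 * (wmax - wmin), wmax)
      queue <- list(list(pos = start, dir = dir0, w = w0))
      treePts <- list()
      while (length(queue) > 0) {
        br <- queue[[1]]; queue <- queue[-1]
        pos <- br$pos; dir <- br$dir; w <- br$w
        for (s in seq_len(.PH_MAX_STEPS)) {
          if (w < wmin) break
          if (sqrt((pos[1] - cy)^2 + (pos[2] - cx)^2) > R - 1) break
          treePts[[length(treePts) + 1]] <- c(pos[1], pos[2], w, depth)
          dir <- dir + rnorm(1, 0, .PH_STEP_JITTER)
          pos <- pos + c(sin(dir), cos(dir))
          w <- w * .PH_WIDTH_DECAY
          if (runif(1) < .PH_BRANCH_PROB && w * .PH_BRANCH_SHRINK >= wmin) {
            side <- sample(c(-1, 1), 1)
            queue <- c(queue, list(list(
              pos = pos, dir = dir + side * runif(1, 0.3, 0.8),
              w = w * .PH_BRANCH_SHRINK)))
            dir <- dir - side * runif(1, 0.1, 0.3)
            w <- w * 0.9
          }
        }
      }
      pts[[t]] <- do.call(rbind, treePts)
    }
    pts <- do.call(rbind, pts)

    # render: per-point max of the normalized Cauchy cross-section
    # (gamma = width/2, truncated at 4*gamma) and of the depth-scaled dip
    Pnorm <- matrix(0, H, W)
    Pint <- matrix(0, H, W)
    for (i in seq_len(nrow(pts))) {
      r <- pts[i, 1]; c <- pts[i, 2]; w <- pts[i, 3]; depth <- pts[i, 4]
      gam <- w / 2
      rad <- ceiling(4 * gam + 1)
      r1 <- max(1, floor(r - rad)); r2 <- min(H, ceiling(r + rad))
      c1 <- max(1, floor(c - rad)); c2 <- min(W, ceiling(c + rad))
      if (r1 > r2 || c1 > c2) next
      rr <- r1:r2; cc <- c1:c2
      v <- 1 / (1 + outer((rr - r)^2, (cc - c)^2, "+") / gam^2)
      Pnorm[rr, cc] <- pmax(Pnorm[rr, cc], v)
      Pint[rr, cc] <- pmax(Pint[rr, cc], depth * v)
    }

    gt <- (Pnorm >= 0.5) * fov

    # smooth illumination falloff plus a low-frequency shading field
    illum <- 1 - 0.25 * (dist / R)^2
    shade <- 0.03 * outer(sin(2 * pi * seq_len(H) / H + runif(1, 0, 2 * pi)),
                          cos(2 * pi * seq_len(W) / W + runif(1, 0, 2 * pi)))
    dip <- c(0.35, 1, 0.55)        # dip strongest in green
    noiseMul <- c(2, 1, 1)         # red channel is the noisy one
    rgb <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      plane <- spec$backgroundRgb[ch] * illum + shade - dip[ch] * Pint
      plane <- plane + matrix(rnorm(H * W, 0, spec$noiseSigma * noiseMul[ch]),
                              H, W)
      plane <- pmin(pmax(plane, 0), 1) * fov
      rgb[, , ch] <- round(plane * 255) / 255
    }
    fundusImage(rgb, fovMask = fov, gtMask = gt,
                id = sprintf("phantom-%d", spec$seed))
  })
}

#' Write a DRIVE-layout phantom dataset
#'
#' Generates `nImages` phantoms with distinct derived seeds and writes them
#' in the DRIVE directory dialect: `images/<id>.tif` (8-bit RGB TIFF),
#' `1st_manual/<id>_manual1.png` and `mask/<id>_mask.png` (binary PNG;
#' PNG stands in for DRIVE's GIF masks). Written files read back exactly
#' because phantom intensities live on the 8-bit grid.
#'
#' @param nImages Number of images (>= 1).
#' @param spec Template [phantomSpec()]; each image reuses it with its own
#'   derived seed.
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed from which per-image seeds are derived.
#' @return Invisibly, a manifest data frame with columns `id`, `image`,
#'   `gt`, `mask`, `seed`.
#' @export
generateDataset <- function(nImages, spec = phantomSpec(), outDir,
                            seed = 1L) {
  if (nImages < 1) stop("'nImages' must be at least 1")
  for (d in file.path(outDir, c("images", "1st_manual", "mask"))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE))
      stop("cannot create directory: ", d)
  }
  seeds <- withr::with_seed(seed, sample.int(2^31 - 2, nImages))
  rows <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    spec$seed <- seeds[i]
    img <- generatePhantom(spec)
    id <- sprintf("%02d", i)
    paths <- c(image = file.path(outDir, "images", paste0(id, ".tif")),
               gt = file.path(outDir, "1st_manual", paste0(id, "_manual1.png")),
               mask = file.path(outDir, "mask", paste0(id, "_mask.png")))
    ok <- tryCatch({
      tiff::writeTIFF(img@rgb, paths[["image"]], bits.per.sample = 8L)
      png::writePNG(img@gtMask, paths[["gt"]])
      png::writePNG(img@fovMask, paths[["mask"]])
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed to write ", paths[["image"]], ": ", conditionMessage(ok))
    rows[[i]] <- data.frame(id = id, image = paths[["image"]],
                            gt = paths[["gt"]], mask = paths[["mask"]],
                            seed = seeds[i])
  }
  invisible(do.call(rbind, rows))
}
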