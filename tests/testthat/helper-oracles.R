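# Independent oracles, implemented as literally as possible so they stay
# decoupled from the package's vectorized/FFT code paths.

# mirror an out-of-range index back into 1..n (edge repeated: 0 -> 1,
# -1 -> 2, n+1 -> n, ...)
reflectIndex <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

# brute-force per-pixel, per-orientation, per-tap correlation with reflect
# padding; returns the max response over kernels
bruteMaxResponse <- function(channel, kernels) {
  H <- nrow(channel); W <- ncol(channel)
  out <- matrix(-Inf, H, W)
  for (k in kernels) {
    s <- nrow(k)
    p <- (s - 1) %/% 2
    for (r in 1:H) {
      for (cc in 1:W) {
        acc <- 0
        for (kr in 1:s) {
          for (kc in 1:s) {
            sr <- reflectIndex(r + kr - 1 - p, H)
            sc <- reflectIndex(cc + kc - 1 - p, W)
            acc <- acc + k[kr, kc] * channel[sr, sc]
          }
        }
        if (acc > out[r, cc]) out[r, cc] <- acc
      }
    }
  }
  out
}

# brute-force pixel-category counting
bruteConfusion <- function(pred, gt, fov) {
  tp <- tn <- fp <- fn <- 0L
  for (r in seq_len(nrow(pred))) {
    for (cc in seq_len(ncol(pred))) {
      if (fov[r, cc] != 1) next
      if (pred[r, cc] == 1 && gt[r, cc] == 1) tp <- tp + 1L
      else if (pred[r, cc] == 0 && gt[r, cc] == 0) tn <- tn + 1L
      else if (pred[r, cc] == 1 && gt[r, cc] == 0) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# dark bar of full width `barWidth` through the image centre at angle
# `theta` (direction (cos theta, sin theta) in (row, col) coordinates) on a
# bright background
barImage <- function(side, theta, barWidth = 3, bg = 1, fg = 0.4) {
  c0 <- (side + 1) / 2
  img <- matrix(bg, side, side)
  for (r in 1:side) {
    for (cc in 1:side) {
      d <- abs(-(r - c0) * sin(theta) + (cc - c0) * cos(theta))
      if (d <= barWidth / 2) img[r, cc] <- fg
    }
  }
  img
}

# pixels on the bar's centreline, away from the border
barCenterline <- function(side, theta, margin = 10) {
  c0 <- (side + 1) / 2
  keep <- matrix(FALSE, side, side)
  for (r in (margin + 1):(side - margin)) {
    for (cc in (margin + 1):(side - margin)) {
      d <- abs(-(r - c0) * sin(theta) + (cc - c0) * cos(theta))
      if (d <= 0.5) keep[r, cc] <- TRUE
    }
  }
  keep
}
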