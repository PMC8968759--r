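#' Training configuration
#'
#' Reference settings: Adam (`beta1 = 0.9`, `beta2 = 0.999`) with an
#' initial learning rate of 0.01 that shrinks by a factor 0.9 at each
#' 10-epoch boundary when the validation loss has saturated, binary
#' cross-entropy on the vessel-probability plane, 200 epochs.
#'
#' "Saturated" is operationalized as: the best validation loss improved by
#' less than `plateauTol` over the last `decayEvery` epochs. Setting
#' `plateauTol = Inf` makes the decay unconditional every `decayEvery`
#' epochs.
#'
#' @param epochs Training epochs (default 200).
#' @param eta0 Initial learning rate (default 0.01).
#' @param decay Multiplicative shrink factor in (0, 1) (default 0.9).
#' @param decayEvery Epochs between decay checkpoints (default 10).
#' @param beta1,beta2 Adam moment decay rates (defaults 0.9, 0.999).
#' @param batchSize Patches per gradient step (default 32).
#' @param plateauTol Minimum best-val-loss improvement counting as progress
#'   (default 1e-4).
#' @param seed Integer seed governing shuffling.
#' @return Named configuration list for [trainUnet()].
#' @export
trainConfig <- function(epochs = 200L, eta0 = 0.01, decay = 0.9,
                        decayEvery = 10L, beta1 = 0.9, beta2 = 0.999,
                        batchSize = 32L, plateauTol = 1e-4, seed = 1L) {
  if (decay <= 0 || decay >= 1) stop("'decay' must lie in (0, 1)")
  if (eta0 <= 0) stop("'eta0' must be positive")
  if (epochs < 1) stop("'epochs' must be at least 1")
  list(epochs = as.integer(epochs), eta0 = eta0, decay = decay,
       decayEvery = as.integer(decayEvery), beta1 = beta1, beta2 = beta2,
       batchSize = as.integer(batchSize), plateauTol = plateauTol,
       seed = as.integer(seed))
}

#' Plateau-gated decaying learning-rate schedule
#'
#' The rate starts at `eta0`. At each completed `decayEvery`-epoch boundary
#' the best validation loss inside the last window is compared with the
#' best before it; if the improvement is below `plateauTol` ("saturated"),
#' the rate is multiplied by `decay`. The rate for epoch `k` (0-based) is
#' therefore `eta0 * decay^d` with `d` the number of triggered boundaries,
#' and is non-increasing in the epoch index.
#'
#' @param epoch 0-based epoch index about to start.
#' @param history Numeric vector of validation losses of completed epochs.
#' @param cfg A [trainConfig()] list.
#' @return The learning rate for `epoch`.
#' @examples
#' lrSchedule(0, numeric(0), trainConfig())   # 0.01
#' @export
lrSchedule <- function(epoch, history, cfg = trainConfig()) {
  if (epoch < 0) stop("'epoch' must be non-negative")
  k <- cfg$decayEvery
  nBound <- min(epoch, length(history)) %/% k
  decays <- 0L
  for (b in seq_len(nBound)) {
    upto <- b * k
    windowBest <- min(history[seq_len(upto)])
    prevBest <- if (upto > k) min(history[seq_len(upto - k)]) else history[1]
    if (prevBest - windowBest < cfg$plateauTol) decays <- decays + 1L
  }
  cfg$eta0 * cfg$decay^decays
}

.stackPatches <- function(ps, which) {
  idx <- which(ps@split %in% which)
  list(x = ps@inputs[, , , idx, drop = FALSE],
       y = ps@labels[, , idx, drop = FALSE], n = length(idx))
}

#' Train the U-Net
#'
#' Minimizes binary cross-entropy on the train-tagged patches with Adam,
#' evaluating the validation loss each epoch and applying the
#' plateau-gated learning-rate schedule of [lrSchedule()]. The weights with
#' the best validation loss are restored at the end. Shuffling is seeded,
#' so two runs with identical configuration and patches coincide.
#'
#' @param model A [UNetModel-class]; updated in place.
#' @param patches A [PatchSet-class] with train and val split tags.
#' @param cfg A [trainConfig()] list.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best-validation weights restored) and
#'   `history`, a data frame with one row per epoch: `epoch`, `lr`,
#'   `trainLoss`, `valLoss`.
#' @export
trainUnet <- function(model, patches, cfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(model, "UNetModel"), is(patches, "PatchSet"))
  tr <- .stackPatches(patches, "train")
  va <- .stackPatches(patches, "val")
  if (tr$n == 0) stop("no patches tagged 'train'")
  if (va$n == 0) stop("no patches tagged 'val'")
  if (!all(tr$y %in% c(0, 1))) stop("labels must be binary")

  history <- data.frame(epoch = integer(), lr = numeric(),
                        trainLoss = numeric(), valLoss = numeric())
  valHist <- numeric(0)
  bestVal <- Inf
  bestWeights <- NULL
  order_seed <- cfg$seed

  for (ep in seq_len(cfg$epochs)) {
    lr <- lrSchedule(ep - 1L, valHist, cfg)
    ord <- withr::with_seed(order_seed + ep, sample.int(tr$n))
    lossSum <- 0; nb <- 0
    for (start in seq(1, tr$n, by = cfg$batchSize)) {
      sel <- ord[start:min(start + cfg$batchSize - 1, tr$n)]
      loss <- .unet_train_batch(model@ptr,
                                tr$x[, , , sel, drop = FALSE],
                                tr$y[, , sel, drop = FALSE],
                                lr, cfg$beta1, cfg$beta2, 1e-8)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep,
             " (learning rate ", lr, "); aborting")
      lossSum <- lossSum + loss; nb <- nb + 1
    }
    valLoss <- .unet_eval_loss(model@ptr, va$x, va$y)
    if (!is.finite(valLoss)) stop("non-finite validation loss at epoch ", ep)
    valHist <- c(valHist, valLoss)
    history <- rbind(history,
                     data.frame(epoch = ep, lr = lr,
                                trainLoss = lossSum / nb, valLoss = valLoss))
    if (valLoss < bestVal) {
      bestVal <- valLoss
      bestWeights <- unetWeights(model)
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train %.5f  val %.5f",
                      ep, lr, lossSum / nb, valLoss))
  }
  if (!is.null(bestWeights)) setUnetWeights(model, bestWeights)
  list(model = model, history = history)
}

#' End-to-end segmentation of a fundus image
#'
#' Full inference pipeline: [buildFeatureMap()] on the image,
#' non-overlapping tiling at the model's patch size, batch prediction,
#' stitching with [reassembleTiles()], zeroing of probabilities outside the
#' FOV, and binarization at `prob >= tau`.
#'
#' @param img A [FundusImage-class].
#' @param bank A [MatchedFilterBank-class].
#' @param model A trained [UNetModel-class].
#' @param tau Global probability threshold (default 0.5, the operating
#'   point at which the threshold-sensitivity table is flattest).
#' @param cfg A [preprocessConfig()] list.
#' @param features Feature-map variant passed to [buildFeatureMap()].
#' @return List with `prob` (H x W probability matrix) and `binary`
#'   (H x W 0/1 matrix).
#' @export
segmentImage <- function(img, bank, model, tau = 0.5,
                         cfg = preprocessConfig(),
                         features = c("cauchy-gb", "rgb")) {
  stopifnot(is(img, "FundusImage"), is(model, "UNetModel"))
  fm <- buildFeatureMap(img, bank, cfg, features = match.arg(features))
  size <- model@config$inputSize[1]
  tl <- tileImage(fm, size = size)
  n <- length(tl$tiles)
  inputs <- array(0, c(size, size, 3, n))
  for (i in seq_len(n)) inputs[, , , i] <- tl$tiles[[i]]
  probs <- predictPatches(model, inputs)
  prob <- reassembleTiles(lapply(seq_len(n), function(i) probs[, , i]),
                          tl$geometry)
  if (!is.null(img@fovMask)) prob <- prob * img@fovMask
  list(prob = prob, binary = (prob >= tau) * 1)
}
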