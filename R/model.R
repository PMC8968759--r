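#' U-Net configuration
#'
#' The reference architecture maps `64 x 64 x 3` feature patches to
#' `64 x 64 x 1` vessel-probability patches: an encoder of `depth` steps
#' (two 3x3 same-padding convolutions + 2x2 max pooling each, filters
#' doubling from `baseFilters`), a two-convolution bottleneck, a decoder of
#' `depth` steps (2x nearest upsampling, skip concatenation, two
#' convolutions), and a 1x1 two-class SoftMax head reduced to the
#' vessel-class plane. ReLU everywhere except the head.
#'
#' @param inputSize Length-3 integer vector (side, side, channels); the
#'   side must be divisible by `2^depth`.
#' @param depth Number of down/up-sampling steps (default 4).
#' @param baseFilters Filters in the first encoder level (default 32);
#'   doubled at each level.
#' @param nClasses SoftMax classes (default 2: vessel / background).
#' @return Named configuration list for [buildUnet()].
#' @export
unetConfig <- function(inputSize = c(64L, 64L, 3L), depth = 4L,
                       baseFilters = 32L, nClasses = 2L) {
  inputSize <- as.integer(inputSize)
  depth <- as.integer(depth)
  if (length(inputSize) != 3 || inputSize[1] != inputSize[2])
    stop("'inputSize' must be (side, side, channels) with a square side")
  if (inputSize[1] %% 2^depth != 0)
    stop("input side ", inputSize[1], " is not divisible by 2^depth = ",
         2^depth)
  if (nClasses < 2) stop("'nClasses' must be at least 2")
  list(inputSize = inputSize, depth = depth,
       baseFilters = as.integer(baseFilters), nClasses = as.integer(nClasses))
}

#' SoftMax class probabilities
#'
#' Converts a vector of per-class activations `a_k` at one pixel into
#' probabilities `p_k = exp(a_k) / sum_k' exp(a_k')`, numerically
#' stabilized by subtracting `max(a)` before exponentiation. The output
#' sums to 1.
#'
#' @param activations Finite numeric vector of length >= 2.
#' @return Numeric vector of probabilities summing to 1.
#' @examples
#' softmaxProbability(c(0, log(3)))   # 0.25, 0.75
#' @export
softmaxProbability <- function(activations) {
  if (length(activations) < 2 || !all(is.finite(activations)))
    stop("'activations' must be a finite vector of length >= 2")
  e <- exp(activations - max(activations))
  e / sum(e)
}

#' Build a U-Net model
#'
#' Allocates the compiled network with He-initialized weights drawn from a
#' generator seeded by `seed`; construction, forward passes and training
#' are fully deterministic for a fixed seed.
#'
#' @param cfg A [unetConfig()] list.
#' @param seed Integer seed for weight initialization.
#' @return A [UNetModel-class] handle.
#' @export
buildUnet <- function(cfg = unetConfig(), seed = 1L) {
  ptr <- .unet_create(cfg$depth, cfg$baseFilters, cfg$inputSize[3],
                      cfg$nClasses, as.integer(seed))
  cfg$seed <- as.integer(seed)
  new("UNetModel", ptr = ptr, config = cfg)
}

#' Number of trainable parameters
#'
#' @param model A [UNetModel-class].
#' @return Parameter count (weights + biases) as a double.
#' @export
nParams <- function(model) {
  stopifnot(is(model, "UNetModel"))
  .unet_n_params(model@ptr)
}

#' Predict vessel probabilities for a batch of patches
#'
#' Runs the forward pass in batches and returns the vessel-class SoftMax
#' plane per patch. Batch order is preserved and patches are independent.
#'
#' @param model A [UNetModel-class].
#' @param inputs `size x size x C x N` array in `[0, 1]` (an empty batch,
#'   `N = 0`, returns an empty array).
#' @param batchSize Patches per forward pass (default 32).
#' @param classes If `TRUE`, return the full `size x size x K x N` SoftMax
#'   tensor instead of the vessel plane.
#' @return `size x size x N` array of probabilities in `[0, 1]` (or the
#'   full class tensor).
#' @export
predictPatches <- function(model, inputs, batchSize = 32L, classes = FALSE) {
  stopifnot(is(model, "UNetModel"))
  d <- dim(inputs)
  if (length(d) != 4) stop("'inputs' must be a 4-d array (size, size, C, N)")
  if (d[3] != model@config$inputSize[3])
    stop("channel count does not match the model")
  n <- d[4]
  if (n == 0) return(.unet_forward(model@ptr, inputs, classes))
  K <- model@config$nClasses
  out <- if (classes) array(0, c(d[1], d[2], K, n)) else array(0, c(d[1], d[2], n))
  for (start in seq(1, n, by = batchSize)) {
    end <- min(start + batchSize - 1, n)
    chunk <- inputs[, , , start:end, drop = FALSE]
    res <- .unet_forward(model@ptr, chunk, classes)
    if (classes) out[, , , start:end] <- res else out[, , start:end] <- res
  }
  out
}

#' Extract or restore model weights
#'
#' The external pointer inside a [UNetModel-class] does not survive
#' serialization; these accessors move the weights through plain R lists.
#'
#' @param model A [UNetModel-class].
#' @return `unetWeights()`: a list with one `(W, b, k)` entry per
#'   convolution layer.
#' @export
unetWeights <- function(model) {
  stopifnot(is(model, "UNetModel"))
  .unet_get_weights(model@ptr)
}

#' @rdname unetWeights
#' @param weights A list previously produced by `unetWeights()` for a model
#'   of identical configuration.
#' @return `setUnetWeights()`: the model, invisibly, with weights replaced.
#' @export
setUnetWeights <- function(model, weights) {
  stopifnot(is(model, "UNetModel"))
  .unet_set_weights(model@ptr, weights)
  invisible(model)
}

#' Save / load a trained model
#'
#' Persists the configuration and weights to a single checkpoint file
#' (RDS), plus an optional JSON architecture summary for audit.
#'
#' @param model A [UNetModel-class].
#' @param path Checkpoint file path.
#' @param summaryPath Optional path for a JSON architecture summary.
#' @export
saveUnet <- function(model, path, summaryPath = NULL) {
  stopifnot(is(model, "UNetModel"))
  saveRDS(list(config = model@config, weights = unetWeights(model)), path)
  if (!is.null(summaryPath)) {
    cfg <- model@config
    jsonlite::write_json(
      list(inputSize = cfg$inputSize, depth = cfg$depth,
           baseFilters = cfg$baseFilters, nClasses = cfg$nClasses,
           nParams = nParams(model)),
      summaryPath, auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname saveUnet
#' @return `loadUnet()`: the restored [UNetModel-class].
#' @export
loadUnet <- function(path) {
  ck <- readRDS(path)
  model <- buildUnet(ck$config[c("inputSize", "depth", "baseFilters",
                                 "nClasses")], seed = ck$config$seed)
  setUnetWeights(model, ck$weights)
  model
}
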