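# Small shared fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

# 256x256 phantom with a couple of trees: fast to generate, large enough
# for 64-pixel patches
smallPhantom <- function(seed = 11) {
  key <- paste0("phantom", seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- generatePhantom(
      phantomSpec(height = 256L, width = 256L, nTrees = 3L, seed = seed))
  }
  .fixtureCache[[key]]
}

smallFeatureMap <- function(seed = 11) {
  key <- paste0("fm", seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- buildFeatureMap(smallPhantom(seed), defaultBank())
  }
  .fixtureCache[[key]]
}

defaultBank <- function() {
  if (is.null(.fixtureCache$bank)) .fixtureCache$bank <- buildBank()
  .fixtureCache$bank
}

# learnable toy patches: a dark vertical bar in plane 1 at a random column,
# labelled as vessel
makeToyPatches <- function(n = 24L, size = 32L, seed = 13) {
  withr::with_seed(seed, {
    inputs <- array(runif(size * size * 3 * n, 0.4, 0.6),
                    c(size, size, 3, n))
    labels <- array(0, c(size, size, n))
    for (i in seq_len(n)) {
      cc <- sample(4:(size - 3), 1)
      cols <- (cc - 1):(cc + 1)
      inputs[, cols, 1, i] <- inputs[, cols, 1, i] + 0.4
      labels[, cols, i] <- 1
    }
    inputs <- pmin(inputs, 1)
    ps <- new("PatchSet", inputs = inputs, labels = labels,
              coords = cbind(rep(1L, n), rep(1L, n)),
              sourceIds = rep("toy", n), split = rep("", n))
    splitTrainVal(ps, 0.25, seed = seed)
  })
}
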