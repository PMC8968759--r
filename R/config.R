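#' Pipeline configuration
#'
#' One nested configuration object covering every stage, round-trippable
#' through YAML. Unknown keys are rejected on read, so typos fail loudly
#' instead of silently falling back to defaults.
#'
#' @param filters,preprocess,patches,model,training,evaluation Optional
#'   named lists overriding the per-stage defaults.
#' @param seed Global seed.
#' @return Nested named list.
#' @export
pipelineConfig <- function(filters = list(), preprocess = list(),
                           patches = list(), model = list(),
                           training = list(), evaluation = list(),
                           seed = 1L) {
  defaults <- list(
    filters = list(gamma = 1, x0 = 0, T = 9L, L = 8L, nOrientations = 12L),
    preprocess = list(clipLimit = 2, tiles = c(8L, 8L)),
    patches = list(nPatches = 500L, size = 64L, valFraction = 0.1),
    model = list(inputSize = c(64L, 64L, 3L), depth = 4L,
                 baseFilters = 32L, nClasses = 2L),
    training = list(epochs = 200L, eta0 = 0.01, decay = 0.9,
                    decayEvery = 10L, beta1 = 0.9, beta2 = 0.999,
                    batchSize = 32L, plateauTol = 1e-4),
    evaluation = list(tau = 0.5, tauGrid = c(0.01, 0.99, 0.01)),
    seed = 1L)
  override <- list(filters = filters, preprocess = preprocess,
                   patches = patches, model = model, training = training,
                   evaluation = evaluation, seed = seed)
  for (sec in setdiff(names(override), "seed")) {
    unknown <- setdiff(names(override[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in '", sec, "': ", paste(unknown, collapse = ", "))
    defaults[[sec]] <- modifyList(defaults[[sec]], override[[sec]])
  }
  defaults$seed <- as.integer(seed)
  defaults
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `readPipelineConfig()`: the validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("filters", "preprocess", "patches", "model", "training",
             "evaluation", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  args <- raw[setdiff(names(raw), "seed")]
  args$seed <- if (is.null(raw$seed)) 1L else raw$seed
  do.call(pipelineConfig, args)
}

#' @rdname readPipelineConfig
#' @param cfg A [pipelineConfig()] list.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Stable hash used to tag run logs, so identical configuration + seed can
#' be linked to identical outputs of the deterministic stages.
#'
#' @param cfg Any R object (typically a [pipelineConfig()]).
#' @return Character hash.
#' @export
configHash <- function(cfg) rlang::hash(cfg)
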