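#' @keywords internal
"_PACKAGE"

#' Derive a deterministic per-stage seed from a global seed
#'
#' Every stage of the pipeline draws its randomness from a seed computed as a
#' deterministic hash of the global seed and the stage name, so toggling one
#' stage on or off never perturbs the random stream of another.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds valid R integers
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

# internal: stop with a consistent error class
ecn_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "epicrossnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: sigmoid with overflow-safe tails
sigmoid <- function(x) 1 / (1 + exp(-x))

# internal: numerically clipped probability for BCE
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
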