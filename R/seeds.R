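#' Derive a deterministic child seed for a named pipeline stage
#'
#' All generators in the package are seeded from one master seed; each stage
#' derives its own stream so that adding a stage never perturbs the draws of
#' another. The derivation is a fixed integer hash of the stage name combined
#' with the master seed, kept inside the 32-bit signed range R requires.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage (e.g. `"pools"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(stage), length(stage) == 1L, nzchar(stage))
  codes <- utf8ToInt(stage)
  h <- sum(as.numeric(codes) * (seq_along(codes) * 1009 + 7)) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# set.seed only when the caller supplied one; generators stay usable inside
# an outer set.seed() when seed = NULL
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
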