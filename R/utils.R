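# Internal helpers shared across modules.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Derive a stage-specific random seed from a master seed
#'
#' All stochastic stages of the pipeline (simulation, train/test split, patch
#' sampling, weight initialization, bootstrap, embedding) draw their seed
#' deterministically from one master seed and a stage name, so that changing
#' the master seed re-randomizes everything coherently while changing one
#' stage's seed (by overriding it) perturbs only that stage.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name, e.g. `"simulate"`.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- (abs(master_seed) %% 2147483647)
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# stop() with a consistent prefix for argument contract violations
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_pos_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
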