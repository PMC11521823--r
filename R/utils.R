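# Internal helpers shared across stages.

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a 31-bit integer
#' seed, so that skipping or reordering stages never shifts the random stream
#' of another stage.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  # splitmix-like integer hash on the stage string, folded into the master
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
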