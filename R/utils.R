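#' Named seed substreams
#'
#' All randomness in a run flows from one master seed. Stage-, species- and
#' replicate-level seeds are derived by hashing a label path together with
#' the master seed, so any sub-computation is reproducible in isolation and
#' independent of execution order. The result is a valid 32-bit seed.
#'
#' @param master Integer master seed.
#' @param ... Labels (coerced to character) identifying the substream, e.g.
#'   `seed_for(42, "pa_exclusion", "sp007", 3)`.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
seed_for <- function(master, ...) {
  lab <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 5381
  for (k in utf8ToInt(lab)) h <- (h * 33 + k) %% 2147483647
  as.integer((h + as.numeric(master) * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
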