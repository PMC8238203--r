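# Internal utilities: deterministic seed derivation and RNG scoping.

#' Derive a child seed from a master seed and a stage label
#'
#' Every source of randomness in the pipeline draws its seed through this
#' function, so that stages (and repetitions within a stage) are mutually
#' independent yet fully replayable from one master seed.
#'
#' @param master Integer master seed.
#' @param ... Further atomic components (stage name, locus key, repetition
#'   index, ...) folded into the hash.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(1, "rank", 3)
childSeed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "\r")
  h <- 5381
  for (ch in utf8ToInt(parts)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Stratified sampling helper: sample `k` indices from `idx` without replacement.
sampleIdx <- function(idx, k) {
  if (length(idx) == 1L) return(if (k >= 1L) idx else integer(0))
  sample(idx, k)
}

stopIfEmpty <- function(x, what) {
  if (length(x) == 0L) stop(what, " must be non-empty", call. = FALSE)
  invisible(x)
}
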