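# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' Every source of randomness in the package draws its seed from a master
#' seed through a named substream, so that independent pipeline stages do
#' not share random streams and reruns are bit-reproducible.
#'
#' @param master_seed Integer master seed.
#' @param label Character label naming the stream (e.g. `"subsample"`).
#' @param index Integer index within the stream (e.g. the draw number).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master_seed, label, index = 1L) {
  stopifnot(length(master_seed) == 1L, is.finite(master_seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # 64-bit-safe mixing in double arithmetic; result stays well below 2^31
  x <- (abs(master_seed) %% 2147483647) * 48271 %% 2147483647
  x <- (x + h * 69621 + index * 16807) %% 2147483646
  as.integer(x + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded internals do not
#' perturb user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

logit <- function(p) log(p / (1 - p))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_no_call <- function(...) stop(..., call. = FALSE)
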