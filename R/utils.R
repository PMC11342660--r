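#' Derive a reproducible integer seed from a base seed and labels
#'
#' Deterministic string hash used to give every independent random stream
#' (climate noise, disturbance draws, harvest phases) its own seed below
#' 2^31, derived from a single user-facing base seed. Streams that must be
#' shared between paired scenarios (common random numbers) simply omit the
#' scenario factors from the label set.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the stream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "site1", "disturbance")
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_config <- function(...) {
  stop(structure(class = c("forestmit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
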