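#' @keywords internal
"_PACKAGE"

## Deterministic seed fan-out. A master seed plus a character context is
## mapped to a child seed in [1, 2^31 - 2]; all arithmetic stays below 2^53
## so it is exact in doubles on every platform.
MOD31 <- 2147483647

hash_string <- function(s) {
  h <- 2166136261 %% MOD31
  for (b in utf8ToInt(s)) {
    h <- (h * 127 + b) %% MOD31
  }
  h
}

#' Derive a child seed from a master seed and a context label
#'
#' Every source of randomness in the pipeline (fold plan, augmentation draws,
#' landmark choice, hyperparameter search, boosting subsampling, synthetic
#' image generation) draws its seed from the master seed through this
#' function, so one integer reproduces a whole run.
#'
#' @param master integer master seed.
#' @param ... character or numeric context components (e.g. stage name,
#'   image id, replicate index).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  ctx <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- (((master %% MOD31) * 48271) %% MOD31 + hash_string(ctx)) %% MOD31
  as.integer(h %% (MOD31 - 2L) + 1)
}

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

## Stable short fingerprint of any R object (via its canonical JSON form).
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_histocad <- function(...) stop(..., call. = FALSE)
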