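# Internal helpers shared across modules.

# Deterministic derivation of child seeds from a master seed. Keeps every
# derived seed a positive 32-bit integer so set.seed() accepts it anywhere.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  raw <- utils::head(utf8ToInt(key), 64L)
  h <- 0
  for (v in raw) h <- (h * 31 + v) %% 2147483563
  as.integer(h + 1L)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_genecut <- function(msg, class) {
  rlang::abort(msg, class = c(class, "genecut_error"))
}

`%||%` <- rlang::`%||%`
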