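#' @keywords internal
"_PACKAGE"

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# One deterministic sub-seed per key, derived from a master seed.
# Keys are sorted so the mapping is independent of input order.
derive_seeds <- function(seed, keys, salt = 0L) {
  keys <- as.character(keys)
  with_seed(as.integer(seed) + as.integer(salt), {
    s <- sample.int(.Machine$integer.max - 1L, length(keys))
  })
  names(s) <- keys
  s
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

field_key <- function(plate, well, site) sprintf("%s_%s_s%d", plate, well, as.integer(site))
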