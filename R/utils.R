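# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. All exported stochastic operations funnel through
# this so that results are reproducible from their `seed` argument alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed fan-out: one root seed in a config is mapped
# to distinct 31-bit child seeds by stage name, so stages draw from
# independent streams while the whole run stays reproducible.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# assert x is a numeric matrix with unique row/col names
check_descriptor_matrix <- function(m, what = "descriptor matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop(what, " must have unique row names (entity ids)")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop(what, " must have unique column names (descriptor names)")
  invisible(m)
}
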