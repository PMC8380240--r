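#' @keywords internal
"_PACKAGE"

## Internal RNG helpers. Several stages (fold assignment, permutation tests,
## the synthetic generator, LIBSVM's internal CV shuffle) consume the RNG;
## these helpers keep every stage reproducible from a single user seed while
## leaving the caller's RNG state untouched.

# Evaluate `code` under `seed`, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic child seed derivation: one user-facing seed fans out to
# per-stage seeds so stages can be re-run in isolation. Kept < 2^31.
child_seed <- function(seed, stage, index = 0L) {
  stage_off <- c(design = 11L, folds = 23L, inner = 37L, perm = 53L,
                 svr = 71L, pipeline = 89L)
  off <- stage_off[[stage]]
  (as.integer(seed) %% 1000000L) * 1009L + off * 10007L + as.integer(index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
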