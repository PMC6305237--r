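#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a user seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_domain <- function(...) {
  stop(structure(class = c("ednascope_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("ednascope_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
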