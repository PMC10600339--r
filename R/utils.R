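# internal helpers

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a per-sample seed from a base seed, staying within 32-bit range
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_len3 <- function(x, name) {
  if (length(x) != 3 || any(!is.finite(x)))
    stopf("'%s' must be 3 finite numbers", name)
}
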