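# Internal numeric and RNG helpers.

#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix; tolerates -Inf entries.
row_log_sum_exp <- function(W) {
  m <- W[, 1L]
  nc <- ncol(W)
  if (nc > 1L) for (k in 2L:nc) m <- pmax(m, W[, k])
  finite <- is.finite(m)
  out <- m
  if (any(finite)) {
    Wf <- W[finite, , drop = FALSE] - m[finite]
    out[finite] <- m[finite] + log(rowSums(exp(Wf)))
  }
  out
}

# Derive a stream-specific child seed from one master seed.  Keeps every
# subsystem independently reproducible from the single config seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483629
  }
  as.integer(h %% 2147483647)
}

# Evaluate fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
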