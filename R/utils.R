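# internal helpers shared across modules

# classed conditions so callers can distinguish failure modes programmatically
stop_sniffsel <- function(class, message, call. = FALSE) {
  cond <- structure(
    class = c(class, "sniffsel_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness goes through this; no global state leaks.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream splitting: child seed k of a master seed, kept < 2^31.
# A fixed multiplicative mix keeps distinct (seed, k) pairs well separated.
child_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k + 1L)) {
    s <- (s * 48271) %% 2147483647
  }
  as.integer(s %% 2147483562) + 1L
}

# Gauss-Hermite nodes/weights by Golub-Welsch (symmetric tridiagonal eigen).
# Used for deterministic moments of functions of a normal latent trait.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  b <- sqrt(seq_len(n - 1) / 2)
  A <- matrix(0, n, n)
  idx <- seq_len(n - 1)
  A[cbind(idx, idx + 1)] <- b
  A[cbind(idx + 1, idx)] <- b
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_pct <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", formatC(100 * x, format = "f", digits = digits))
}
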