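# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps the package's determinism contracts local.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic arithmetic derivation of per-repeat seeds from a master seed.
# An LCG map (not R's RNG) so seed r is identical regardless of how many
# repeats are requested.
derive_seeds <- function(master, n) {
  m <- 2147483647
  x <- as.double(master %% m)
  out <- integer(n)
  for (r in seq_len(n)) {
    x <- (1103515245 * x + 12345 + r) %% m
    out[r] <- as.integer(x)
  }
  out
}

col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

CLASS_LEVELS <- c("HQ", "AQ", "LQ", "Ea")

as_class_factor <- function(x) {
  x <- as.character(x)
  known <- x %in% CLASS_LEVELS
  lev <- c(CLASS_LEVELS[CLASS_LEVELS %in% x], sort(unique(x[!known])))
  factor(x, levels = lev)
}
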