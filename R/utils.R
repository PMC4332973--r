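# internal helpers shared across the package

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. All seeded entry points in the package route through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-(repeat, fold) fit seed from one user seed; stays inside
# 32-bit integer range.
derive_seed <- function(seed, rep_idx, fold_idx) {
  as.integer((abs(as.numeric(seed)) + 7919 * rep_idx + 104729 * fold_idx) %%
               2147483647)
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  }
  as.integer(x)
}

check_positive_real <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive real", name), call. = FALSE)
  }
  as.numeric(x)
}

# Solve (I/C + A) z = B via Cholesky; A symmetric positive semi-definite.
ridge_chol_solve <- function(A, B, C) {
  n <- nrow(A)
  M <- A + diag(1 / C, n)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    # fall back to a generic solve if rounding pushed M off PD
    return(solve(M, B))
  }
  backsolve(R, forwardsolve(t(R), B))
}
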