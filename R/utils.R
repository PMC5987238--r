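#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif sd median quantile
#' @importFrom utils head tail write.csv
NULL

# Internal input checks ------------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid("%s must be finite numeric", what)
  }
  invisible(x)
}

check_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid("%s must be a positive finite scalar", what)
  }
  invisible(x)
}

# Seed handling: every stochastic entry point takes a `seed` and restores the
# caller's RNG state on exit, so library code never perturbs a session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic sub-seed derivation (keeps derived seeds < 2^31).
derive_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# Stratified fold assignment: returns an integer fold id per row, each class
# spread as evenly as possible across folds. Deterministic given seed.
stratified_folds <- function(labels, n_folds, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < n_folds) {
        stop_invalid("class %d has fewer rows (%d) than folds (%d)",
                     cl, length(idx), n_folds)
      }
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}
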