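# Four-level db6 wavelet packet decomposition plus per-subband zero-lag
# higher-order cumulants and Shannon energy entropy (120 features per cycle).
#
# The packet tree splits BOTH approximation and detail branches at every
# level, so levels 1-4 hold 2+4+8+16 = 30 subbands. With periodized
# boundary handling the transform is orthogonal: coefficient counts per
# level sum to the signal length and energy is conserved level by level.

# Daubechies-6 decomposition low-pass filter (12 taps); the high-pass is the
# quadrature mirror: hi[m] = (-1)^(m+1) * lo[L-1-m].
DB6_LO <- c(-1.07730108530847959e-03, 4.77725751094551076e-03,
            5.53842201161496126e-04, -3.15820393174860298e-02,
            2.75228655303057269e-02, 9.75016055873230425e-02,
            -1.29766867567261940e-01, -2.26264693965439828e-01,
            3.15250351709197629e-01, 7.51133908021095364e-01,
            4.94623890398453059e-01, 1.11540743350109467e-01)
DB6_HI <- rev(DB6_LO) * rep_len(c(-1, 1), length(DB6_LO))

wavelet_filters <- function(wavelet = "db6") {
  if (!identical(wavelet, "db6")) {
    stop_invalid("only the db6 mother wavelet is implemented")
  }
  list(lo = DB6_LO, hi = DB6_HI)
}

# One periodized analysis step. Convention (matching the common
# periodization mode of wavelet toolboxes): for even N,
#   a[k] = sum_m lo[m] * x[(2(k-1) + L/2 - m) mod N + 1],  k = 1..N/2
# Odd-length inputs are extended by repeating the last sample.
dwt_step_periodic <- function(x, flt) {
  n <- length(x)
  if (n %% 2L == 1L) {
    x <- c(x, x[n])
    n <- n + 1L
  }
  L <- length(flt$lo)
  half <- n %/% 2L
  ks <- seq_len(half)
  a <- numeric(half)
  d <- numeric(half)
  for (m in seq_len(L)) {
    idx <- (2L * (ks - 1L) + L %/% 2L - (m - 1L)) %% n + 1L
    xv <- x[idx]
    a <- a + flt$lo[m] * xv
    d <- d + flt$hi[m] * xv
  }
  list(a = a, d = d)
}

#' Wavelet packet decomposition of a pulse cycle
#'
#' Full packet tree with the db6 mother wavelet: at every level both the
#' approximation (A) and detail (D) branches are split again, yielding
#' `2^l` subbands at level `l` and 30 subbands across levels 1-4. Subbands
#' are returned in natural (breadth-first filter-bank) order: level 1 A, D;
#' level 2 AA, AD, DA, DD; and so on.
#'
#' @param x numeric cycle samples.
#' @param wavelet mother wavelet name (only `"db6"`).
#' @param max_level decomposition depth (default 4).
#' @param boundary boundary handling (only `"periodic"`, which keeps the
#'   transform orthogonal and energy-conserving).
#' @return List of class `wpd_tree`; each element is a list with `level`,
#'   `node` (0-based within level), `path` (e.g. `"AD"`), `coefficients`.
#' @export
wpd_decompose <- function(x, wavelet = "db6", max_level = 4L,
                          boundary = "periodic") {
  check_finite_numeric(x, "x")
  boundary <- match.arg(boundary, "periodic")
  flt <- wavelet_filters(wavelet)
  if (length(x) < 2^max_level) {
    stop_invalid("cycle of length %d too short for level %d (need >= %d samples)",
                 length(x), max_level, 2^max_level)
  }
  nodes <- list(list(level = 0L, node = 0L, path = "", coefficients = x))
  out <- list()
  for (lev in seq_len(max_level)) {
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nd <- nodes[[i]]
      st <- dwt_step_periodic(nd$coefficients, flt)
      nxt[[2L * i - 1L]] <- list(level = lev, node = 2L * nd$node,
                                 path = paste0(nd$path, "A"),
                                 coefficients = st$a)
      nxt[[2L * i]] <- list(level = lev, node = 2L * nd$node + 1L,
                            path = paste0(nd$path, "D"),
                            coefficients = st$d)
    }
    nodes <- nxt
    out <- c(out, nodes)
  }
  class(out) <- "wpd_tree"
  out
}

#' @export
print.wpd_tree <- function(x, ...) {
  lv <- vapply(x, `[[`, 0L, "level")
  cat(sprintf("<wpd_tree: %d subbands, levels %s>\n", length(x),
              paste(sprintf("%d:%d", sort(unique(lv)), table(lv)),
                    collapse = " ")))
  invisible(x)
}

#' Zero-lag cumulants of a coefficient sequence
#'
#' Biased estimators at lag zero: with the sample mean removed and
#' \eqn{m_k = N^{-1} \sum x^k}, the second-, third- and fourth-order
#' cumulants are \eqn{c_2 = m_2} (the variance \eqn{\sigma^2}),
#' \eqn{c_3 = m_3} and \eqn{c_4 = m_4 - 3 m_2^2}. These are raw
#' (un-normalized) cumulants — the numerators of skewness and kurtosis, not
#' the standardized ratios.
#'
#' @param x numeric vector (>= 2 values).
#' @return Named numeric `c(c2, c3, c4)`.
#' @examples
#' zero_lag_cumulants(c(1, -1, 1, -1))  # c2 = 1, c3 = 0, c4 = -2
#' @export
zero_lag_cumulants <- function(x) {
  check_finite_numeric(x, "x")
  if (length(x) < 2L) stop_invalid("need at least 2 values")
  x <- x - mean(x)
  m2 <- mean(x^2)
  c(c2 = m2, c3 = mean(x^3), c4 = mean(x^4) - 3 * m2^2)
}

#' Shannon energy entropy of a coefficient sequence
#'
#' Non-normalized Shannon entropy of the squared coefficients,
#' \eqn{E = -\sum_i s_i^2 \ln s_i^2} with the convention
#' \eqn{0 \ln 0 = 0}. Computed on the raw coefficients (no centring, no
#' normalization), so it can take either sign.
#'
#' @param x numeric coefficient vector.
#' @return Scalar energy entropy.
#' @examples
#' shannon_energy_entropy(c(1, 1))  # 0
#' shannon_energy_entropy(2)        # -4*log(4)
#' @export
shannon_energy_entropy <- function(x) {
  check_finite_numeric(x, "x")
  s2 <- x^2
  -sum(ifelse(s2 > 0, s2 * log(s2), 0))
}

#' Extract the 120 wavelet-packet features of a pulse cycle
#'
#' Decomposes the cycle (db6, 4 levels, periodized) and computes, per
#' subband, the zero-lag cumulants and the Shannon energy entropy. The 90
#' HOS features are laid out in order-major blocks over the 30 subbands in
#' (level, node) order: `HOS1..HOS30` are the second-order cumulants of
#' subbands 1..30, `HOS31..HOS60` the third-order, `HOS61..HOS90` the
#' fourth-order; `E1..E30` are the per-subband energy entropies.
#'
#' @param x numeric cycle samples.
#' @param wavelet,max_level,boundary passed to [wpd_decompose()].
#' @return Named numeric vector of length 120 (`HOS1..HOS90`, `E1..E30`).
#' @export
extract_wpd_features <- function(x, wavelet = "db6", max_level = 4L,
                                 boundary = "periodic") {
  tree <- wpd_decompose(x, wavelet, max_level, boundary)
  cums <- vapply(tree, function(nd) zero_lag_cumulants(nd$coefficients),
                 numeric(3L))
  ent <- vapply(tree, function(nd) shannon_energy_entropy(nd$coefficients),
                numeric(1L))
  n_sub <- length(tree)
  out <- c(cums[1L, ], cums[2L, ], cums[3L, ], ent)
  names(out) <- c(paste0("HOS", seq_len(3L * n_sub)),
                  paste0("E", seq_len(n_sub)))
  out
}
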