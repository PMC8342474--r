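# Walsh-Hadamard bases in sequency order, the 2D fast transform, and the
# low-frequency-first square sampling path used for compressive sensing.

bit_reverse <- function(x, m) {
  r <- integer(length(x))
  for (i in seq_len(m)) {
    r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(x, 1L))
    x <- bitwShiftR(x, 1L)
  }
  r
}

gray_to_binary <- function(g) {
  b <- g
  s <- bitwShiftR(g, 1L)
  while (any(s > 0L)) {
    b <- bitwXor(b, s)
    s <- bitwShiftR(s, 1L)
  }
  b
}

# permutation p with W_sequency = W_natural[p, ]: p[s + 1] is the natural
# (Sylvester) row index whose Walsh function has sequency s
sequency_permutation <- function(side) {
  m <- as.integer(round(log2(side)))
  h <- 0:(side - 1L)
  s <- gray_to_binary(bit_reverse(h, m))
  p <- integer(side)
  p[s + 1L] <- h + 1L
  p
}

is_pow2 <- function(n) {
  n >= 1 && abs(n - 2^round(log2(n))) < .Machine$double.eps * 4
}

#' Walsh matrix in sequency order
#'
#' Builds the `2^m x 2^m` orthogonal +/-1 Walsh-Hadamard matrix with rows
#' sorted by sequency: row `k` (0-based) has exactly `k` sign changes, the
#' Hadamard analogue of increasing spatial frequency. The matrix is
#' symmetric and satisfies `W %*% t(W) == 2^m * I`.
#'
#' @param m non-negative integer; the matrix has side `2^m`.
#' @return integer matrix of +1/-1 entries.
#' @examples
#' walsh_sequency_matrix(1)
#' @export
walsh_sequency_matrix <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 0 || m != round(m)) {
    rlang::abort("`m` must be a single non-negative integer.",
      class = "holopix_invalid")
  }
  m <- as.integer(m)
  H <- matrix(1L, 1L, 1L)
  if (m > 0) {
    block <- matrix(c(1L, 1L, 1L, -1L), 2L, 2L, byrow = TRUE)
    for (i in seq_len(m)) H <- kronecker(block, H)
  }
  H <- H[sequency_permutation(2L^m), , drop = FALSE]
  storage.mode(H) <- "integer"
  H
}

# enumerate sequency pairs (u, v) along expanding square shells of
# max(u, v) = k: (0,k)..(k,k) then (k,k-1)..(k,0)
square_shell_uv <- function(side) {
  uv <- matrix(0L, side^2, 2L)
  idx <- 1L
  for (k in 0:(side - 1L)) {
    if (k == 0L) {
      uv[idx, ] <- c(0L, 0L)
      idx <- idx + 1L
      next
    }
    for (u in 0:k) {
      uv[idx, ] <- c(u, k)
      idx <- idx + 1L
    }
    for (v in (k - 1L):0L) {
      uv[idx, ] <- c(k, v)
      idx <- idx + 1L
    }
  }
  uv
}

#' Hadamard measurement plan
#'
#' Fixes the pattern bookkeeping for a `side x side` acquisition: the 2D
#' basis `H_n` of linear order `n` is the outer product of the 1D sequency
#' rows `u` and `v`, and `n` enumerates the pairs `(u, v)` along the square
#' sampling path (expanding shells of `max(u, v)`), so low orders are low
#' spatial frequencies and a prefix of orders is a compressive measurement.
#' Order 1 is always the all-ones (DC) pattern.
#'
#' @param side pixels per image edge; must be a power of 2.
#' @param ordering `"sequency"` (default; square-path enumeration) or
#'   `"natural"` (Sylvester row-major order, mainly for testing).
#' @return a `hadamard_plan` with fields `side`, `n_total`, `uv`
#'   (`n_total x 2` integer matrix, the index map `n -> (u, v)`), `path`
#'   (permutation of orders defining acquisition order) and `ordering`.
#' @export
hadamard_plan <- function(side = 256L, ordering = c("sequency", "natural")) {
  ordering <- match.arg(ordering)
  if (length(side) != 1 || is.na(side) || side < 1 || !is_pow2(side)) {
    rlang::abort("`side` must be a power of 2.", class = "holopix_invalid")
  }
  side <- as.integer(side)
  n_total <- side^2
  if (ordering == "sequency") {
    uv <- square_shell_uv(side)
  } else {
    uv <- cbind(rep(0:(side - 1L), each = side), rep(0:(side - 1L), times = side))
  }
  lookup <- matrix(NA_integer_, side, side)
  lookup[cbind(uv[, 1] + 1L, uv[, 2] + 1L)] <- seq_len(n_total)
  structure(
    list(
      side = side, n_total = n_total, uv = uv, path = seq_len(n_total),
      ordering = ordering, order_lookup = lookup,
      seq_perm = if (ordering == "sequency") sequency_permutation(side) else seq_len(side)
    ),
    class = "hadamard_plan"
  )
}

#' @export
print.hadamard_plan <- function(x, ...) {
  cat(sprintf("<hadamard_plan> side %d (%d patterns), %s ordering\n",
              x$side, x$n_total, x$ordering))
  invisible(x)
}

#' Single illumination pattern
#'
#' Returns basis pattern `n` of a plan. The bipolar (+1/-1) form is the
#' orthogonal Hadamard basis `H_n`; the binary (0/1) form is the
#' Hadamard-like pattern a binary-amplitude modulator can display,
#' `(H_n + 1) / 2`, equivalently `H_n = 2 * binary - all_ones`.
#'
#' @param plan a [hadamard_plan()].
#' @param n linear order, `1 <= n <= n_total`.
#' @param polarity `"bipolar"` or `"binary"`.
#' @return an `sph_pattern`: list with `values` (side x side matrix),
#'   `polarity`, `order`, `u`, `v`.
#' @export
basis_pattern <- function(plan, n, polarity = c("bipolar", "binary")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(plan, "hadamard_plan"))
  if (length(n) != 1 || is.na(n) || n < 1 || n > plan$n_total || n != round(n)) {
    rlang::abort(sprintf("order `n` must be in 1..%d.", plan$n_total),
      class = "holopix_invalid")
  }
  n <- as.integer(n)
  W <- walsh_row_cache(plan)
  u <- plan$uv[n, 1]
  v <- plan$uv[n, 2]
  vals <- outer(W[u + 1L, ], W[v + 1L, ])
  if (polarity == "binary") vals <- (vals + 1L) / 2L
  structure(
    list(values = vals, polarity = polarity, order = n, u = u, v = v),
    class = "sph_pattern"
  )
}

# 1D Walsh matrix for a plan's ordering (sequency rows, or Sylvester rows
# for the natural ordering); memoised on the plan's side
walsh_row_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(plan) {
    key <- paste0(plan$ordering, plan$side)
    if (is.null(cache[[key]])) {
      m <- as.integer(round(log2(plan$side)))
      W <- matrix(1L, 1L, 1L)
      if (m > 0) {
        block <- matrix(c(1L, 1L, 1L, -1L), 2L, 2L, byrow = TRUE)
        for (i in seq_len(m)) W <- kronecker(block, W)
      }
      if (plan$ordering == "sequency") W <- W[plan$seq_perm, , drop = FALSE]
      cache[[key]] <- W
    }
    cache[[key]]
  }
})

# in-place butterfly: natural-order (Sylvester) FWHT applied to each column,
# O(n log n) per column, no normalisation
fwht_columns <- function(M) {
  n <- nrow(M)
  h <- 1L
  while (h < n) {
    step <- 2L * h
    for (start in seq.int(1L, n, by = step)) {
      i <- start:(start + h - 1L)
      j <- i + h
      a <- M[i, , drop = FALSE]
      b <- M[j, , drop = FALSE]
      M[i, ] <- a + b
      M[j, ] <- a - b
    }
    h <- step
  }
  M
}

# 2D transform on a matrix: W X W^T / side with W in the plan's row order.
# The sequency Walsh matrix is symmetric, so this map is its own inverse.
fwht2_matrix <- function(X, plan) {
  if (!all(dim(X) == plan$side)) {
    rlang::abort("image side does not match the plan.", class = "holopix_invalid")
  }
  Y <- fwht_columns(X)
  Y <- t(fwht_columns(t(Y)))
  p <- plan$seq_perm
  Y[p, p, drop = FALSE] / plan$side
}

coeffs_tibble <- function(order, u, v, value, kind, side) {
  out <- tibble::tibble(order = as.integer(order), u = as.integer(u),
                        v = as.integer(v), value = value)
  class(out) <- c("sph_coeffs", class(out))
  attr(out, "kind") <- kind
  attr(out, "side") <- side
  out
}

#' @export
print.sph_coeffs <- function(x, ...) {
  cat(sprintf("# Hadamard coefficients (%s basis), side %d\n",
              attr(x, "kind"), attr(x, "side")))
  NextMethod()
}

#' Forward 2D fast Walsh-Hadamard transform
#'
#' Decomposes the object onto the orthogonal bipolar bases with the
#' symmetric normalisation `a_n = (1 / sqrt(N)) * sum_r O(r) H_n(r)`,
#' `N = side^2`, so the transform is unitary (its own inverse) and energy
#' is preserved (Parseval). Runs in `O(N log N)` via the butterfly.
#'
#' @param image a [complex_image()] or a square (complex) matrix.
#' @param plan a [hadamard_plan()] with matching side.
#' @return an `sph_coeffs` tibble (`order`, `u`, `v`, `value`) of kind
#'   `"bipolar"` covering all `N` orders in plan order.
#' @export
fwht2 <- function(image, plan) {
  X <- as_complex_matrix(image)
  A <- fwht2_matrix(X, plan)
  coeffs_tibble(
    seq_len(plan$n_total), plan$uv[, 1], plan$uv[, 2],
    A[cbind(plan$uv[, 1] + 1L, plan$uv[, 2] + 1L)],
    kind = "bipolar", side = plan$side
  )
}

#' Inverse 2D fast Walsh-Hadamard transform
#'
#' Resynthesises `O(r) = (1 / sqrt(N)) * sum_n a_n H_n(r)` from bipolar
#' coefficients. Orders absent from `coeffs` are treated as exactly zero —
#' this zero-filling is the compressive reconstruction rule.
#'
#' @param coeffs an `sph_coeffs` tibble (kind `"bipolar"`).
#' @param plan the matching [hadamard_plan()].
#' @return a square complex matrix.
#' @export
ifwht2 <- function(coeffs, plan) {
  cs <- attr(coeffs, "side")
  if (!is.null(cs) && !is.na(cs) && cs != plan$side) {
    rlang::abort("coefficient set side does not match the plan.",
      class = "holopix_invalid")
  }
  if (any(coeffs$order < 1 | coeffs$order > plan$n_total)) {
    rlang::abort("coefficient orders outside the plan.", class = "holopix_invalid")
  }
  A <- matrix(0 + 0i, plan$side, plan$side)
  A[cbind(coeffs$u + 1L, coeffs$v + 1L)] <- coeffs$value
  fwht2_matrix(A, plan)
}

#' Square sampling path
#'
#' The acquisition order of the patterns: sequency pairs `(u, v)` traversed
#' in expanding square shells of `max(u, v) = 0, 1, 2, ...` (boustrophedon
#' within each shell), so spatial frequency is nondecreasing shell by shell
#' and truncating the path at sampling ratio `SR` keeps a low-pass square of
#' side about `side * sqrt(SR)` in sequency space. Because the plan's linear
#' order already enumerates `(u, v)` along this path, the result is the
#' identity permutation `1..N`.
#'
#' @param plan a sequency-ordered [hadamard_plan()].
#' @return integer vector of orders (a permutation starting at 1).
#' @export
square_path <- function(plan) {
  stopifnot(inherits(plan, "hadamard_plan"))
  if (plan$ordering != "sequency") {
    rlang::abort("the square sampling path is defined for sequency ordering.",
      class = "holopix_invalid")
  }
  plan$path
}

#' Export the sampling path as CSV
#'
#' Writes columns `n`, `u`, `v` in acquisition order.
#'
#' @param plan a [hadamard_plan()].
#' @param path output CSV file.
#' @return the output path, invisibly.
#' @export
write_path_csv <- function(plan, path) {
  df <- data.frame(n = plan$path, u = plan$uv[plan$path, 1],
                   v = plan$uv[plan$path, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export one binary pattern as an 8-bit PNG
#'
#' @param plan a [hadamard_plan()].
#' @param n pattern order.
#' @param path output PNG file.
#' @return the output path, invisibly.
#' @export
write_pattern_png <- function(plan, n, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    rlang::abort("package `png` is required for pattern export.")
  }
  p <- basis_pattern(plan, n, "binary")
  png::writePNG(p$values, path)
  invisible(path)
}
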