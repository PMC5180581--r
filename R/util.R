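# Shared low-level helpers: seed derivation, digit/code conversions and
# toroidal ring convolutions used by sensing, food growth and density maps.

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based seed splitting: every run (and every arm of an
#' experiment) draws its own seed from the master seed and an integer counter,
#' so replicate runs are independent streams and adding or removing log output
#' can never perturb the dynamics. The result is always in `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param k integer counter (stream index).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, k) {
  m <- as.double(master) %% 2147483647
  as.integer((m * 48271 + as.double(k) * 12345 + 1) %% 2147483647)
}

# integer digits (most significant first) of `code` in base `base`, width `n`
code_to_digits <- function(code, base, n) {
  out <- integer(n)
  for (i in n:1) {
    out[i] <- code %% base
    code <- code %/% base
  }
  out
}

digits_to_code <- function(d, base) {
  code <- 0
  for (x in d) code <- code * base + x
  code
}

# complement of digit d over an alphabet of size k: d <-> k - 1 - d
comp_digits <- function(d, k) (k - 1L) - d

# shift a matrix by (dx, dy) with wraparound (torus) or zero fill (bounded)
shift_mat <- function(m, dx, dy, torus = TRUE) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (torus) {
    ri <- ((seq_len(n1) - 1L - dx) %% n1) + 1L
    ci <- ((seq_len(n2) - 1L - dy) %% n2) + 1L
    m[ri, ci, drop = FALSE]
  } else {
    out <- matrix(0, n1, n2)
    rs <- max(1L, 1L + dx):min(n1, n1 + dx)
    cs <- max(1L, 1L + dy):min(n2, n2 + dy)
    if (length(rs) > 0 && length(cs) > 0)
      out[rs, cs] <- m[rs - dx, cs - dy, drop = FALSE]
    out
  }
}

# sum of the matrix over the ring of cells at Chebyshev distance 1..r
# (the focal cell itself is excluded)
conv_ring <- function(m, r = 1L, torus = TRUE) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0L && dy == 0L) next
    out <- out + shift_mat(m, dx, dy, torus)
  }
  out
}

# the eight Moore displacement vectors, in fixed order N, NE, E, SE, S, SW, W, NW
moore_dirs <- function() {
  cbind(dx = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
        dy = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L))
}

# wrap or clamp a coordinate vector onto 1..n
wrap_coord <- function(x, n, torus = TRUE) {
  if (torus) ((x - 1L) %% n) + 1L else pmin(pmax(x, 1L), n)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
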