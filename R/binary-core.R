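#' Binary decomposition of a positive integer
#'
#' Writes `n = sum_j 2^(q_j)` with strictly increasing bit positions
#' `q_1 < ... < q_s` (`s` is the binary weight of `n`) and forms the suffix
#' sums `M_i = sum_{j >= i} 2^(q_j)`, the index language in which every closed
#' formula of this package is written.  The conventions `q_0 = 0`,
#' `M_0 = n + 1` and `M_(s+1) = 0` are part of the object: `bit_position(d, 0)`
#' and `suffix_sum(d, 0)`/`suffix_sum(d, s + 1)` return them.
#'
#' @param n a positive integer (below 2^53).
#' @return an object of class `binary_decomposition` with fields `n`, `s`
#'   (binary weight), `q` (bit positions `q_1..q_s`) and `M` (suffix sums
#'   `M_0..M_(s+1)`).
#' @examples
#' d <- decompose(13)       # 13 = 1 + 4 + 8
#' d$q                      # 0 2 3
#' suffix_sum(d, 2)         # 12
#' @seealso [bit_position()], [suffix_sum()], [shift_decomposition()]
#' @export
decompose <- function(n) {
  stopifnot(length(n) == 1L, is.numeric(n))
  if (!is.finite(n) || n < 1 || n != floor(n))
    stop("n must be a positive integer")
  raw <- hr_decompose(n)
  structure(
    list(n = n, s = raw$s, q = raw$q[-1L], M = raw$M),
    class = "binary_decomposition"
  )
}

#' Bit position accessor
#'
#' `q_i(n)` for `i = 1..s`; index 0 returns the convention `q_0 = 0`.
#' @param d a [decompose()] object.
#' @param i index in `0..s`.
#' @export
bit_position <- function(d, i) {
  stopifnot(inherits(d, "binary_decomposition"), i >= 0, i <= d$s)
  if (i == 0) 0 else d$q[i]
}

#' Suffix sum accessor
#'
#' `M_i(n) = sum_{j >= i} 2^(q_j)` for `i = 1..s`; index 0 returns `n + 1` and
#' index `s + 1` returns 0 (the out-of-range value consistent with the
#' telescoping manipulations the formulas rely on).
#' @inheritParams bit_position
#' @export
suffix_sum <- function(d, i) {
  stopifnot(inherits(d, "binary_decomposition"), i >= 0, i <= d$s + 1)
  d$M[i + 1L]
}

#' @export
print.binary_decomposition <- function(x, ...) {
  cat(sprintf("binary decomposition of %s: s = %d\n  q = (%s)\n  M[0..s+1] = (%s)\n",
              format(x$n, scientific = FALSE), x$s,
              paste(x$q, collapse = ", "),
              paste(format(x$M, scientific = FALSE, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Decomposition of 2n from that of n
#'
#' Doubling shifts every bit position up by one and preserves the binary
#' weight: `s_(2n) = s_n` and `q_i(2n) = q_i(n) + 1`.
#' @inheritParams decompose
#' @return the [decompose()] object of `2 * n`.
#' @export
shift_decomposition <- function(n) decompose(2 * n)

#' Iterated ceiling/floor halving
#'
#' Applies the maps `phi_0(n) = floor(n/2)` and `phi_1(n) = ceiling(n/2)` in
#' the order given by `bits = (b_m, ..., b_0)` (least significant applied
#' first), which by the rounding lemma equals
#' `floor((n + sum_i b_i 2^i) / 2^(m+1))`.
#'
#' @param bits a non-empty vector of 0/1, most significant first.
#' @inheritParams decompose
#' @return a single non-negative integer.
#' @examples
#' phi_compose(c(1, 0), 13)   # floor-half then ceiling-half: 3
#' @export
phi_compose <- function(bits, n) {
  if (length(bits) < 1L) stop("bits must be non-empty")
  stopifnot(all(bits %in% c(0, 1)))
  hr_phi_compose(as.integer(bits), n)
}
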