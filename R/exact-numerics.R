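#' Bernoulli numbers (first kind)
#'
#' `B_0 = 1` and, for `m >= 1`, `sum_{k=0}^{m} choose(m+1, k) B_k = 0`; in the
#' first-kind convention `B_1 = -1/2` and the odd numbers beyond `B_1` vanish.
#' Values are exact rationals, computed by the defining recurrence and
#' memoized.
#'
#' @param m non-negative integer order.
#' @return a [rational()] scalar.
#' @examples
#' bernoulli_number(2)    # 1/6
#' bernoulli_number(12)   # -691/2730
#' @export
bernoulli_number <- function(m) {
  stopifnot(length(m) == 1L, m >= 0, m == floor(m))
  new_rational(hr_bernoulli(as.integer(m)))
}

#' Bernoulli polynomials
#'
#' `B_m(x) = sum_{k=0}^{m} choose(m, k) B_k x^(m-k)`, evaluated exactly at a
#' rational argument.
#'
#' @inheritParams bernoulli_number
#' @param x evaluation point (number, `"p/q"` string or [rational()]).
#' @return a [rational()] scalar.
#' @export
bernoulli_poly <- function(m, x) {
  stopifnot(length(m) == 1L, m >= 0, m == floor(m))
  new_rational(hr_bernoulli_poly(as.integer(m), .rat_chr(x)))
}

#' Geometric-type power sums T(d, n, x)
#'
#' `T(d, n, x) = sum_{k=0}^{n-1} k^d x^k` with the convention `0^0 = 1` and
#' `T(d, 0, x) = 0`.  For `d = 0, 1` the closed forms (branching on `x = 1`)
#' are used; higher `d` is summed directly.
#'
#' @param d non-negative integer exponent on `k`.
#' @param n number of terms (from `k = 0`).
#' @param x nonzero base (number, `"p/q"` string or [rational()]).
#' @return a [rational()] scalar.
#' @examples
#' t_sum(1, 3, 2)   # 0*1 + 1*2 + 2*4 = 10
#' @export
t_sum <- function(d, n, x) {
  stopifnot(length(d) == 1L, d >= 0, d == floor(d), n >= 0, n == floor(n))
  new_rational(hr_tsum(as.integer(d), n, .rat_chr(x)))
}

#' Faulhaber power sums
#'
#' `sum_{k=1}^{n-1} k^d`, evaluated through the Bernoulli-number expansion
#' (`method = "bernoulli"`) or by direct summation (`method = "direct"`, the
#' oracle the expansion is tested against).
#'
#' @inheritParams t_sum
#' @param n upper limit (the sum runs to `n - 1`), `n >= 1`.
#' @param method `"bernoulli"` or `"direct"`.
#' @return a [rational()] scalar (an integer value).
#' @export
faulhaber <- function(d, n, method = c("bernoulli", "direct")) {
  method <- match.arg(method)
  stopifnot(length(d) == 1L, d >= 0, d == floor(d), n >= 1, n == floor(n))
  new_rational(hr_faulhaber(as.integer(d), n, direct = method == "direct"))
}
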