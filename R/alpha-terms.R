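#' Inner sums S_n^(d,m)
#'
#' `S_n^(d,m)(a) = sum_{j=1}^{s_n - 1} q_j(n)^d (2^-m a)^(q_j(n))
#' M_{j+1}(n)^m`, the single-n building block of the alpha sums.  Note the
#' upper limit `s_n - 1` (empty when `n` is a power of two), in contrast with
#' the gamma sums of [gamma_sum()] whose inner index runs to `s_k`; with the
#' `0^0 = 1` convention the two ranges differ precisely by the `M_(s+1) = 0`
#' term when `m = 0`.
#'
#' @param n positive integer.
#' @param d non-negative integer (`k^d` exponent).
#' @param m non-negative integer (power of the suffix sums).
#' @param a nonzero rational coefficient.
#' @return a [rational()] scalar.
#' @export
s_term <- function(n, d, m, a) {
  stopifnot(n >= 1, d >= 0, m >= 0)
  new_rational(hr_s_term(n, as.integer(d), as.integer(m), .rat_chr(a)))
}

#' The alpha sums and their closed form
#'
#' `alpha_n^(d,m)(a) = sum_{k=1}^{n-1} S_k^(d,m)(a)`.  The `"bruteforce"`
#' method evaluates this double sum literally (any `d >= 0`) and is the oracle
#' the `"closed"` method is tested against.  The closed form (valid for
#' `d = 0, 1`) is the Bernoulli/T expression
#' \deqn{\frac{1}{2(m+1)} \sum_{i=1}^{s_n} \sum_{j=0}^{m} \binom{m+1}{j} B_j
#'   2^j M_i^{m+1-j} (T(d, q_i, a 2^{j-m}) - T(d, q_{i-1}, a 2^{j-m}))
#'   + \sum_{i=1}^{s_n-1} q_i^d (a 2^{-m})^{q_i} (n - M_i) M_{i+1}^m
#'   - T(d, q_{s_n}, 2a)\,\delta_{m=0}.}
#'
#' @inheritParams s_term
#' @param method `"closed"` or `"bruteforce"`.
#' @return a [rational()] scalar; `alpha_1 = 0` (empty sum).
#' @examples
#' alpha_sum(5, 0, 0, 1)                        # 1
#' alpha_sum(5, 0, 0, 2, method = "bruteforce") # 1
#' @export
alpha_sum <- function(n, d, m, a, method = c("closed", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(n >= 1, d >= 0, m >= 0)
  if (method == "closed" && !d %in% c(0, 1))
    stop("the closed form of alpha is stated for d = 0, 1 only")
  new_rational(hr_alpha(n, as.integer(d), as.integer(m), .rat_chr(a),
                        closed = method == "closed"))
}

#' Alpha values over a whole index range
#'
#' Values of `alpha_n^(d,m)(a)` for `n = 1..n_max` in one pass (the brute
#' force accumulates the `S` terms incrementally).
#'
#' @inheritParams alpha_sum
#' @param n_max largest index.
#' @return a [rational()] vector of length `n_max`.
#' @export
alpha_profile <- function(n_max, d, m, a, method = c("closed", "bruteforce")) {
  method <- match.arg(method)
  if (method == "closed" && !d %in% c(0, 1))
    stop("the closed form of alpha is stated for d = 0, 1 only")
  new_rational(hr_alpha_range(as.integer(n_max), as.integer(d), as.integer(m),
                              .rat_chr(a), closed = method == "closed"))
}

#' Special reduced forms of alpha^(0,0) and alpha^(1,0)
#'
#' The short expressions available for `m = 0`: three branches
#' (`a = 1`, `a = 1/2`, otherwise) for `d = 0`, and the `T`-based form for
#' `d = 1` (stated away from `a = 1, 1/2`).  They must agree with
#' [alpha_sum()] and are exercised as a consistency check in the test suite.
#'
#' @inheritParams s_term
#' @param d 0 or 1.
#' @export
alpha_special <- function(n, d, a) {
  stopifnot(n >= 1, d %in% c(0, 1))
  a <- .rat_chr(a)
  if (d == 1 && (q_eq(a, "1") || q_eq(a, "1/2")))
    stop("the reduced alpha^(1,0) form is stated for a != 1, 1/2")
  new_rational(hr_alpha_special(n, as.integer(d), a))
}

#' The gamma double sums and their Bernoulli-polynomial closed form
#'
#' `gamma_l(d,p,m)(a) = sum_{k=1}^{2^l - 1} sum_{i=1}^{s_k} q_i(k)^d
#' (2^-m a)^(q_i(k)) M_{i+1}(k)^p` (inner index up to `s_k`, so the
#' `M_(s_k+1) = 0` term enters through `0^0 = 1` when `p = 0`).  The
#' `"bruteforce"` method is the literal double sum for any indices; the
#' `"closed"` method is the Bernoulli-polynomial expression, stated for
#' `p < m`, with the `(a 2^{-(m-1)})^{l-1} (l-1)^d` correction when `p = 0`.
#'
#' @param l the range exponent (sum over `k < 2^l`); `gamma_0 = 0`.
#' @inheritParams alpha_sum
#' @param p power on the suffix sums (`p < m` for the closed form).
#' @export
gamma_sum <- function(l, d, p, m, a, method = c("closed", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(l >= 0, d >= 0, p >= 0, m >= 0)
  if (method == "closed" && p >= m)
    stop("the closed form of gamma requires p < m")
  new_rational(hr_gamma(as.integer(l), as.integer(d), as.integer(p),
                        as.integer(m), .rat_chr(a),
                        closed = method == "closed"))
}

#' Consecutive differences of the monomial solutions
#'
#' The closed form for `y_n = x_n^(r,t)(a) - x_{n-1}^(r,t)(a)` (`n >= 2`),
#' written in the binary decomposition of `n - 1` through the `S` sums of
#' [s_term()]; `y_2 = 1` always.  The branch active when `a = 2^(t+l)` for
#' some `l` in `0..r-1` uses the `S^(1,i)` expansion of the telescoping
#' delta sum (the two forms of that sum are asserted equal in the tests).
#'
#' @param n index, `n >= 2`.
#' @param r,t toll exponents of `ceiling(n/2)^r * floor(n/2)^t`.
#' @inheritParams s_term
#' @return a [rational()] scalar equal to the difference of [x_monomial()]
#'   values.
#' @export
y_diff <- function(n, r, t, a) {
  stopifnot(n >= 2, r >= 0, t >= 0)
  new_rational(hr_y_closed(n, as.integer(r), as.integer(t), .rat_chr(a)))
}
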