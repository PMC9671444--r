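#' Bivariate polynomial toll functions
#'
#' The independent term of the recurrence is
#' `P(ceiling(n/2), floor(n/2))` with `P(x, y) = sum b_(r,t) x^r y^t`.
#' A toll polynomial stores the sparse coefficient table; zero coefficients
#' are dropped and duplicate `(r, t)` cells are combined.
#'
#' @param r,t non-negative integer exponent vectors (recycled against `coef`).
#' @param coef coefficients (numbers, `"p/q"` strings or [rational()]).
#' @return an object of class `toll_polynomial` with fields `r`, `t`, `b`.
#' @examples
#' toll_polynomial(c(1, 0), c(0, 1), c(1, 1))   # ceiling + floor = n
#' @export
toll_polynomial <- function(r = integer(), t = integer(), coef = character()) {
  stopifnot(length(r) == length(t), length(t) == length(coef))
  if (length(r) == 0L)
    return(structure(list(r = integer(), t = integer(), b = character()),
                     class = "toll_polynomial"))
  if (any(r < 0) || any(t < 0) || any(r != floor(r)) || any(t != floor(t)))
    stop("toll exponents must be non-negative integers")
  b <- vapply(seq_along(coef), function(i) .rat_chr(coef[i]), "")
  key <- paste(r, t)
  agg <- tapply(b, key, q_sum)
  rt <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  r <- as.integer(rt[, 1L]); t <- as.integer(rt[, 2L]); b <- unname(agg)
  keep <- !vapply(b, q_eq, TRUE, y = "0")
  o <- order(r[keep] + t[keep], r[keep])
  structure(list(r = r[keep][o], t = t[keep][o], b = b[keep][o]),
            class = "toll_polynomial")
}

#' @export
print.toll_polynomial <- function(x, ...) {
  if (length(x$r) == 0L) {
    cat("toll polynomial: 0\n")
    return(invisible(x))
  }
  terms <- sprintf("(%s) x^%d y^%d", x$b, x$r, x$t)
  cat("toll polynomial P(x, y) =", paste(terms, collapse = " + "),
      " [x = ceiling(n/2), y = floor(n/2)]\n")
  invisible(x)
}

#' Degree of a toll polynomial
#' @param toll a [toll_polynomial()].
#' @export
toll_degree <- function(toll) {
  stopifnot(inherits(toll, "toll_polynomial"))
  if (length(toll$r) == 0L) -Inf else as.numeric(max(toll$r + toll$t))
}

# internal toll algebra -------------------------------------------------------
toll_combine <- function(r, t, b) toll_polynomial(r, t, b)

toll_add <- function(p, q) toll_combine(c(p$r, q$r), c(p$t, q$t), c(p$b, q$b))

toll_scale <- function(p, c) {
  c <- .rat_chr(c)
  toll_combine(p$r, p$t, vapply(p$b, q_mul, "", y = c))
}

toll_mul <- function(p, q) {
  if (length(p$r) == 0L || length(q$r) == 0L) return(toll_polynomial())
  grid <- expand.grid(i = seq_along(p$r), j = seq_along(q$r))
  toll_combine(p$r[grid$i] + q$r[grid$j],
               p$t[grid$i] + q$t[grid$j],
               q_mul(p$b[grid$i], q$b[grid$j]))
}

#' Recurrence specifications
#'
#' Bundles the coefficient `a != 0`, the [toll_polynomial()] `P` and the
#' initial value `x_1` of
#' `x_n = a x_(ceiling(n/2)) + a x_(floor(n/2)) + P(ceiling(n/2), floor(n/2))`.
#'
#' @param a nonzero coefficient (number, `"p/q"` string or [rational()]);
#'   note that doubles are converted at their exact binary value.
#' @param toll a [toll_polynomial()].
#' @param x1 initial value (default 0).
#' @return an object of class `recurrence_spec`.
#' @export
recurrence_spec <- function(a, toll = toll_polynomial(), x1 = 0) {
  stopifnot(inherits(toll, "toll_polynomial"))
  a <- .rat_chr(a)
  if (q_eq(a, "0")) stop("a must be nonzero")
  structure(list(a = a, toll = toll, x1 = .rat_chr(x1)),
            class = "recurrence_spec")
}

#' @export
print.recurrence_spec <- function(x, ...) {
  cat(sprintf("half-recurrence: x_n = (%s) x_ceil(n/2) + (%s) x_floor(n/2) + P, x_1 = %s\n",
              x$a, x$a, x$x1))
  print(x$toll)
  invisible(x)
}

#' Read a recurrence specification from JSON
#'
#' The canonical interchange form is
#' `{"a": "p/q", "x1": "p/q", "toll": [[r, t, "p/q"], ...]}`; rationals may be
#' given as strings or plain integers.
#'
#' @param path path to a JSON file, or a JSON string.
#' @return a [recurrence_spec()].
#' @export
read_recurrence_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$a)) stop("JSON spec needs a field \"a\"")
  toll <- toll_polynomial()
  if (!is.null(x$toll) && length(x$toll)) {
    toll <- toll_polynomial(
      vapply(x$toll, function(e) as.numeric(e[[1L]]), 0),
      vapply(x$toll, function(e) as.numeric(e[[2L]]), 0),
      vapply(x$toll, function(e) .rat_chr(e[[3L]]), "")
    )
  }
  recurrence_spec(.rat_chr(x$a), toll, .rat_chr(x$x1 %||% 0))
}

#' Theorem-case profile of a monomial recurrence
#'
#' Resolves the special-case bookkeeping of the closed formula for given
#' `(r, t, a)`: `ell = log2(a) - t` when `a` is an exact power of two
#' (undefined otherwise, and always undefined for `a < 0`), the flag
#' `delta_ell` (1 iff `r > 0` and `ell` is in `0..r-1`, which activates the
#' excluded indices and the extra `alpha^(1,i)` block), the flag `delta_rt`
#' (1 iff `r > 0`, `t = 0`, `a != 1`), and the case label among
#' `a`, `b1`..`b4`, `c1`..`c4`.
#'
#' @inheritParams y_diff
#' @param a nonzero coefficient.
#' @return an object of class `case_profile`.
#' @examples
#' case_profile(2, 0, 2)    # ell = 1, case b4
#' @export
case_profile <- function(r, t, a) {
  stopifnot(r >= 0, t >= 0)
  p <- hr_case_profile(as.integer(r), as.integer(t), .rat_chr(a))
  structure(list(r = as.integer(r), t = as.integer(t), a = .rat_chr(a),
                 ell = p$ell, delta_ell = p$delta_ell, delta_rt = p$delta_rt,
                 which_case = p$which_case),
            class = "case_profile")
}

#' @export
print.case_profile <- function(x, ...) {
  cat(sprintf("case %s for (r = %d, t = %d, a = %s): ell = %s, delta_ell = %d, delta_rt = %d\n",
              x$which_case, x$r, x$t, x$a,
              if (is.na(x$ell)) "undefined" else format(x$ell), x$delta_ell,
              x$delta_rt))
  invisible(x)
}

#' Closed-form solution of the monomial recurrences
#'
#' Exact value of the solution of
#' `x_n = a x_(ceiling(n/2)) + a x_(floor(n/2)) + ceiling(n/2)^r floor(n/2)^t`
#' with `x_1 = 0`, evaluated from the general closed formula
#' (`method = "general"`) or from the nine case specializations
#' (`method = "cased"`); the two agree everywhere, which the test suite
#' asserts against the direct-recursion oracle.
#'
#' @param n positive integer (vectorized).
#' @inheritParams case_profile
#' @param method `"general"` or `"cased"`.
#' @return a [rational()] vector.
#' @examples
#' x_monomial(5, 1, 0, 1)    # 7
#' @export
x_monomial <- function(n, r, t, a, method = c("general", "cased")) {
  method <- match.arg(method)
  stopifnot(all(n >= 1), r >= 0, t >= 0)
  a <- .rat_chr(a)
  new_rational(vapply(n, function(nn)
    hr_x_monomial(nn, as.integer(r), as.integer(t), a,
                  cased = method == "cased"), ""))
}

#' @rdname x_monomial
#' @param n_max largest index; values for `n = 1..n_max` are returned in one
#'   pass (the alpha sums are cached across `n`).
#' @export
x_monomial_profile <- function(n_max, r, t, a, method = c("general", "cased")) {
  method <- match.arg(method)
  new_rational(hr_x_monomial_range(as.integer(n_max), as.integer(r),
                                   as.integer(t), .rat_chr(a),
                                   cased = method == "cased"))
}

#' Homogeneous part of the solution
#'
#' `((2a)^q + (2a - 1)(n a^q - (2a)^q)) x_1` with `q = q_(s_n)(n)`: the
#' solution of the homogeneous equation (zero toll) with initial value `x_1`.
#'
#' @inheritParams x_monomial
#' @param x1 initial value.
#' @export
homogeneous_term <- function(n, a, x1) {
  a <- .rat_chr(a); x1 <- .rat_chr(x1)
  new_rational(vapply(n, function(nn) hr_homogeneous(nn, a, x1), ""))
}

#' Solve a dividing-by-a-half recurrence in closed form
#'
#' The headline operation: the exact solution of
#' `x_n = a x_(ceiling(n/2)) + a x_(floor(n/2)) + P(ceiling(n/2), floor(n/2))`
#' as `sum b_(r,t) x_n^(r,t)(a)` plus the homogeneous part, every ingredient a
#' finite sum over the binary decomposition of `n`.  With
#' `method = "oracle"` the recurrence is instead evaluated directly by
#' memoized recursion on the two halves — the ground truth the closed form is
#' validated against.
#'
#' @param spec a [recurrence_spec()].
#' @param n positive integers (vectorized).
#' @param method `"closed"` or `"oracle"`.
#' @return a [rational()] vector.
#' @examples
#' sackin <- recurrence_spec(1, toll_polynomial(c(1, 0), c(0, 1), c(1, 1)))
#' solve_recurrence(sackin, 8)                       # 24
#' solve_recurrence(sackin, 8, method = "oracle")    # 24
#' @export
solve_recurrence <- function(spec, n, method = c("closed", "oracle")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "recurrence_spec"), all(n >= 1))
  new_rational(hr_solve(as.numeric(n), spec$a,
                        as.integer(spec$toll$r), as.integer(spec$toll$t),
                        spec$toll$b, spec$x1, oracle = method == "oracle"))
}

#' @rdname solve_recurrence
#' @param n_max largest index; returns the solution at every `n = 1..n_max`
#'   (the oracle then runs bottom-up in linear time).
#' @export
solve_profile <- function(spec, n_max, method = c("closed", "oracle")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "recurrence_spec"))
  new_rational(hr_solve_range(as.integer(n_max), spec$a,
                              as.integer(spec$toll$r), as.integer(spec$toll$t),
                              spec$toll$b, spec$x1,
                              oracle = method == "oracle"))
}

#' Expand a univariate toll p(n) into the bivariate table
#'
#' Uses `n = ceiling(n/2) + floor(n/2)`: each power `n^k` becomes
#' `sum_j choose(k, j) x^j y^(k-j)`.
#'
#' @param coef coefficients of `p(n) = coef[1] + coef[2] n + ...` (ascending).
#' @return a [toll_polynomial()].
#' @examples
#' toll_from_univariate(c(0, 1))   # p(n) = n -> x + y
#' @export
toll_from_univariate <- function(coef) {
  r <- integer(); t <- integer(); b <- character()
  for (k in seq_along(coef)) {
    ck <- .rat_chr(coef[k])
    if (q_eq(ck, "0")) next
    deg <- k - 1L
    for (j in 0:deg) {
      r <- c(r, j); t <- c(t, deg - j)
      b <- c(b, q_mul(ck, sprintf("%.0f", choose(deg, j))))
    }
  }
  toll_polynomial(r, t, b)
}

#' Expand a (-1)^n toll factor
#'
#' `(-1)^n = 1 - 2 (ceiling(n/2) - floor(n/2))`, so a toll
#' `coef * (-1)^n * base(n)` becomes the bivariate product
#' `coef * (1 - 2x + 2y) * base`.
#'
#' @param coef the constant multiplying `(-1)^n`.
#' @param base optional [toll_polynomial()] multiplied by the sign factor
#'   (default: the constant 1).
#' @return a [toll_polynomial()].
#' @examples
#' alternating_toll(1)   # (-1)^n -> 1 - 2x + 2y
#' @export
alternating_toll <- function(coef = 1, base = NULL) {
  sign_poly <- toll_polynomial(c(0L, 1L, 0L), c(0L, 0L, 1L), c("1", "-2", "2"))
  out <- toll_scale(sign_poly, coef)
  if (!is.null(base)) {
    stopifnot(inherits(base, "toll_polynomial"))
    out <- toll_mul(out, base)
  }
  out
}

# Q(y - 1) from ascending coefficients of Q
.poly_shift_minus1 <- function(coef) {
  d <- length(coef) - 1L
  if (d < 0L) return(character())
  out <- rep("0", d + 1L)
  for (k in 0:d) {
    ck <- .rat_chr(coef[k + 1L])
    if (q_eq(ck, "0")) next
    for (j in 0:k) {
      term <- q_mul(ck, sprintf("%.0f", choose(k, j) * (-1)^(k - j)))
      out[j + 1L] <- q_add(out[j + 1L], term)
    }
  }
  out
}

# univariate polynomial in y = floor(n/2) as a toll
.poly_in_floor <- function(coef) {
  if (length(coef) == 0L) return(toll_polynomial())
  toll_polynomial(rep(0L, length(coef)), seq_along(coef) - 1L,
                  vapply(coef, .rat_chr, ""))
}

#' Half-recurrence for an even/odd interleaved pair
#'
#' Many integer sequences are defined by the pair
#' `a_(2n) = C a_n + C a_(n-1) + P(n)`, `a_(2n+1) = 2C a_n + Q(n)`.  The
#' shifted sequence `x_n = a_(n-1)` then satisfies the half-recurrence with
#' coefficient `C` and toll
#' `Q(floor(n/2) - 1) + (ceiling(n/2) - floor(n/2)) (P(floor(n/2)) - Q(floor(n/2) - 1))`,
#' which this helper expands into the bivariate table.
#'
#' @param C the pair's coefficient (nonzero).
#' @param P,Q ascending coefficient vectors of the two polynomials.
#' @param x1 initial value `x_1 = a_0` (default 0).
#' @return a [recurrence_spec()].
#' @examples
#' stephan_spec(-1, P = c(0, 1), Q = c(1, 1))   # toll floor(n/2)
#' @export
stephan_spec <- function(C, P = numeric(), Q = numeric(), x1 = 0) {
  qs <- .poly_shift_minus1(Q)              # Q(y - 1)
  qs_toll <- .poly_in_floor(qs)
  diff_toll <- toll_add(.poly_in_floor(P), toll_scale(qs_toll, "-1"))
  xy <- toll_polynomial(c(1L, 0L), c(0L, 1L), c("1", "-1"))
  recurrence_spec(C, toll_add(qs_toll, toll_mul(xy, diff_toll)), x1 = x1)
}

#' Exhaustive closed-form vs direct-recursion cross-validation
#'
#' Evaluates the closed formula and the memoized direct recursion for every
#' `n = 1..n_max`, every monomial toll with `(r, t)` in `{0..rt_max}^2`,
#' every coefficient in `a_values` and initial values cycled from
#' `x1_values`, and counts exact-equality failures; optionally the nine case
#' specializations are compared against the general formula on the same grid.
#' The default `a_values` hit every case of the closed formula's dispatch
#' (both `a = 1/2` branches, `a = 1`, positive and negative non-powers of
#' two, rationals, and the powers of two that activate the excluded-index
#' blocks).
#'
#' @param n_max largest index checked.
#' @param rt_max largest toll exponent per variable.
#' @param a_values character vector of `"p/q"` coefficients.
#' @param x1_values character vector of `"p/q"` initial values, recycled
#'   over the `(a, r, t)` combinations.
#' @param check_cased also compare the case specializations.
#' @return a list with `n_checked`, `mismatch_solve_oracle`,
#'   `mismatch_cased_general` and `first_mismatch` (empty string when all
#'   agree).
#' @examples
#' oracle_grid_check(n_max = 32, rt_max = 1, a_values = c("1", "2"))
#' @export
oracle_grid_check <- function(n_max = 128, rt_max = 3,
                              a_values = c("1", "-1", "2", "-2", "4", "8",
                                           "1/2", "-1/2", "3", "1/3", "3/2", "5"),
                              x1_values = "0", check_cased = TRUE) {
  stopifnot(n_max >= 1, rt_max >= 0, length(a_values) >= 1)
  a_values <- vapply(a_values, .rat_chr, "", USE.NAMES = FALSE)
  x1_values <- vapply(x1_values, .rat_chr, "", USE.NAMES = FALSE)
  hr_grid_check(as.integer(n_max), as.integer(rt_max), a_values, x1_values,
                check_cased = check_cased)
}

#' Does a toll force the identically-zero solution?
#'
#' With `x_1 = 0` the solution vanishes for every `n` exactly when the toll
#' polynomial satisfies `P(x, x) = P(x, x - 1) = 0`, i.e.
#' `P(x, y) = (x - y)(x - y - 1) Q(x, y)`.  In coefficients this is, for every
#' `k = 0..d`:
#' `sum_j b_(j,k-j) = 0` and
#' `sum_{l=1}^{d-k} sum_{j=0}^{k} choose(l+j, j) b_(l+j,k-j) = 0`.
#'
#' @param toll a [toll_polynomial()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' vanishing_check(toll_polynomial(c(2, 1, 0, 1, 0), c(0, 1, 2, 0, 1),
#'                                 c(1, -2, 1, -1, 1)))   # (x-y)(x-y-1)
#' @export
vanishing_check <- function(toll) {
  stopifnot(inherits(toll, "toll_polynomial"))
  if (length(toll$r) == 0L) return(TRUE)
  d <- max(toll$r + toll$t)
  bco <- function(r, t) {
    i <- which(toll$r == r & toll$t == t)
    if (length(i)) toll$b[i] else "0"
  }
  for (k in 0:d) {
    s1 <- "0"
    for (j in 0:k) s1 <- q_add(s1, bco(j, k - j))
    if (!q_eq(s1, "0")) return(FALSE)
    if (d - k >= 1) {
      s2 <- "0"
      for (l in 1:(d - k)) for (j in 0:k)
        s2 <- q_add(s2, q_mul(sprintf("%.0f", choose(l + j, j)), bco(l + j, k - j)))
      if (!q_eq(s2, "0")) return(FALSE)
    }
  }
  TRUE
}
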