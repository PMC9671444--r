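# Named integer sequences solved in closed form by the recurrence machinery,
# each registered with up to three independent evaluators: the closed formula,
# the memoized half-recurrence oracle, and (where one exists) a definitional
# computation that never touches the recurrence.

.dec <- function(n) hr_decompose(n)   # list(n, s, q[0..s], M[0..s+1])
.int_chr <- function(x) sprintf("%.0f", x)

#' Minimum Sackin index of a bifurcating tree with n leaves
#'
#' Closed form `(q_s + 2) n - 2^(q_s + 1)` with `q_s = floor(log2(n))`: the
#' Sackin index of the maximally balanced tree (sequence A003314, the binary
#' entropy function).  Equals the solution of the half-recurrence with
#' `a = 1`, toll `n`, `x_1 = 0`.
#'
#' @param n positive integers (vectorized).
#' @return a [rational()] vector (integer values).
#' @examples
#' sackin_min(c(5, 8))   # 12, 24
#' @export
sackin_min <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); qs <- d$q[d$s + 1L]
    .int_chr((qs + 2) * nn - 2^(qs + 1))
  }, ""))
}

#' Minimum Colless index of a bifurcating tree with n leaves
#'
#' Closed form `sum_{i=1}^{s-1} 2^(q_i) (q_s - q_i - 2(s - i - 1))`
#' (sequence A296062); 0 at powers of two.  Solution of the recurrence with
#' `a = 1`, toll `ceiling(n/2) - floor(n/2)`.
#'
#' @inheritParams sackin_min
#' @export
colless_min <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]
    if (s == 1L) return("0")
    i <- seq_len(s - 1L)
    .int_chr(sum(2^q[i] * (q[s] - q[i] - 2 * (s - i - 1))))
  }, ""))
}

#' Minimum Total Cophenetic index of a tree with n leaves
#'
#' Closed form `choose(n, 2) - s_n n - sum_{i=1}^{s} 2^(q_i - 1) (q_i - 2i)`
#' (sequence A174605).  Solution of the recurrence with `a = 1`, toll
#' `choose(ceiling(n/2), 2) + choose(floor(n/2), 2)`.
#'
#' @inheritParams sackin_min
#' @export
cophenetic_min <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]
    i <- seq_len(s)
    .int_chr(choose(nn, 2) - s * nn - sum(2^(q - 1) * (q - 2 * i)))
  }, ""))
}

#' Maximum rooted Quartet index of a bifurcating tree with n leaves
#'
#' Closed form
#' `(9n^4 - 42n^3 + 63n^2 - 6n + 6n sum_i (1 + v_i)(1 + 3 v_i)
#'   - 18 sum_i M_i (1 + v_i)^2) / 504` with `v_i = M_i / 2^(q_i) =
#' floor(n / 2^(q_i))` (sequence A300445).  Solution of the recurrence with
#' `a = 1`, toll `choose(ceiling(n/2), 2) choose(floor(n/2), 2)`.
#'
#' @inheritParams sackin_min
#' @export
quartet_max <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]; M <- d$M[2:(s + 1L)]
    v <- M / 2^q
    val <- 9 * nn^4 - 42 * nn^3 + 63 * nn^2 - 6 * nn +
      6 * nn * sum((1 + v) * (1 + 3 * v)) - 18 * sum(M * (1 + v)^2)
    .int_chr(val / 504)
  }, ""))
}

#' Lebesgue constants of the Walsh system
#'
#' `lambda_n = s_n - sum_{i=1}^{s_n} 2^(-q_i) (n - M_i)`, the integral norms
#' of the partial-sum kernels of the Walsh orthogonal system.  They satisfy
#' the half-recurrence with `a = 1/2`, toll
#' `(ceiling(n/2) - floor(n/2)) / 2` and `lambda_1 = 1`.
#'
#' @inheritParams sackin_min
#' @return a [rational()] vector (dyadic rationals).
#' @examples
#' walsh_lebesgue(3)   # 3/2
#' @export
walsh_lebesgue <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]; M <- d$M[2:(s + 1L)]
    qs <- q[s]
    num <- s * 2^qs - sum(2^(qs - q) * (nn - M))
    q_div(.int_chr(num), .int_chr(2^qs))
  }, ""))
}

#' Takagi-related alternating-toll sequence
#'
#' The solution of `x_n = x_(ceiling(n/2)) + x_(floor(n/2)) + (-1)^n` with
#' initial value `x1`:
#' `2^(q_s + 2) + (x1 - 3) n - 1 - 2 sum_{i=1}^{s-1} 2^(q_i)(q_s - q_i - 2(s - i))`.
#' For `x1 = 1` this equals the odd-indexed subsequence `a_(2n-1)` of
#' A268289, for which [monroe_job()] is the definitional formula.
#'
#' @inheritParams sackin_min
#' @param x1 initial value (default 1).
#' @export
takagi_related <- function(n, x1 = 1) {
  x1 <- .rat_chr(x1)
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]; qs <- q[s]
    corr <- if (s > 1L) {
      i <- seq_len(s - 1L)
      sum(2^q[i] * (qs - q[i] - 2 * (s - i)))
    } else 0
    base <- 2^(qs + 2) - 1 - 2 * corr
    q_add(.int_chr(base), q_mul(q_sub(x1, "3"), .int_chr(nn)))
  }, ""))
}

#' Digit-wise formula for A268289
#'
#' `a_(m-1) = sum_{j=0}^{q_s(m)} ((floor(m/2^j) + 1) mod 2) 2^j +
#' (-1)^((floor(m/2^j) + 1) mod 2) (m mod 2^j)`: the definitional evaluation
#' of the sequence whose odd-indexed terms coincide with [takagi_related()]
#' at `x1 = 1` (`x_n = a_(2n-1)`).
#'
#' @param m positive integers (vectorized); returns `a_(m-1)`.
#' @return a [rational()] vector (integer values).
#' @export
monroe_job <- function(m) {
  new_rational(vapply(m, function(mm) {
    qs <- floor(log2(mm))
    acc <- 0
    for (j in 0:qs) {
      par <- (floor(mm / 2^j) + 1) %% 2
      acc <- acc + par * 2^j + (-1)^par * (mm %% 2^j)
    }
    .int_chr(acc)
  }, ""))
}

#' Feigenbaum-related alternating digit sum (A005536, shifted)
#'
#' `x_n = (1/4) sum_{i=1}^{s} 2^(q_i) (1 - (-1)^(q_i) +
#' 4 sum_{j > i} (-1)^(q_j))`: the solution of
#' `x_n = -x_(ceiling(n/2)) - x_(floor(n/2)) + floor(n/2)` with `x_1 = 0`,
#' equal to the partial sums `sum_{k <= n-1} sum_i (-1)^(q_i(k))` of the
#' alternating binary digit counts.
#'
#' @inheritParams sackin_min
#' @export
stanton_kocay <- function(n) {
  new_rational(vapply(n, function(nn) {
    d <- .dec(nn); s <- d$s; q <- d$q[-1L]
    acc <- 0
    for (i in seq_len(s)) {
      tail_sum <- if (i < s) sum((-1)^q[(i + 1):s]) else 0
      acc <- acc + 2^q[i] * (1 - (-1)^q[i] + 4 * tail_sum)
    }
    .int_chr(acc / 4)
  }, ""))
}

# sigma_1,m: closed form for the shifted bitwise-AND sums (a_{1,n} = sigma_{1,n+1})
.sigma1 <- function(m) {
  d <- .dec(m); s <- d$s; q <- d$q[-1L]
  M <- d$M[2:(s + 1L)]; Mnext <- d$M[3:(s + 2L)]
  0.5 * sum(q * 2^q * (m - 2^q - 2 * Mnext)) - sum((m - M) * Mnext)
}

#' Bitwise AND/XOR/OR convolution sums
#'
#' `a_1(n) = sum_{k=1}^{n-1} (k AND (n-k))`, `a_2` with XOR, `a_3` with OR
#' (sequences A006581, A006582, A006583).  The closed forms come from the
#' `a = 2` half-recurrences of the shifted sequences: `a_1(n) = sigma_1(n+1)`
#' with
#' `sigma_1(m) = (1/2) sum_i q_i 2^(q_i) (m - 2^(q_i) - 2 M_(i+1))
#'             - sum_i (m - M_i) M_(i+1)`,
#' then `a_3(n) = 2 choose(n, 2) - a_1(n)` and `a_2 = a_3 - a_1`.
#'
#' @inheritParams sackin_min
#' @return a [rational()] vector of length 3 (AND, XOR, OR) for scalar `n`,
#'   or a 3-row matrix of strings for vector `n`.
#' @examples
#' bitwise_sums(5)   # 4, 12, 16
#' @export
bitwise_sums <- function(n) {
  vals <- vapply(n, function(nn) {
    a1 <- .sigma1(nn + 1)
    a3 <- 2 * choose(nn, 2) - a1
    c(and = .int_chr(a1), xor = .int_chr(a3 - a1), or = .int_chr(a3))
  }, c(and = "", xor = "", or = ""))
  if (length(n) == 1L) new_rational(vals) else vals
}

# definitional bitwise sums (direct loops)
.bitwise_def <- function(n, op) {
  f <- switch(op, and = bitwAnd, xor = bitwXor, or = bitwOr)
  vapply(n, function(nn) {
    if (nn < 2) return("0")
    k <- seq_len(nn - 1)
    .int_chr(sum(as.numeric(f(k, nn - k))))
  }, "")
}

# definitional A005536 partial sums, computed incrementally over k
.stanton_def <- function(n) {
  nmax <- max(n)
  inner <- vapply(seq_len(max(nmax - 1, 1)), function(k) {
    d <- .dec(k); sum((-1)^d$q[-1L])
  }, 0)
  cums <- c(0, cumsum(inner))
  vapply(n, function(nn) .int_chr(cums[nn]), "")
}

# ---------------------------------------------------------------------------
# sequence registry

.seq_registry <- function() {
  tree_def <- function(fn) function(n) {
    vapply(n, function(nn) .int_chr(fn(max_balanced_tree(nn))), "")
  }
  list(
    A003314 = list(
      label = "minimum Sackin index S(B_n)",
      closed = function(n) unclass(sackin_min(n)),
      spec = recurrence_spec(1, toll_polynomial(c(1, 0), c(0, 1), c(1, 1))),
      definitional = tree_def(sackin_index), def_cost = "tree"),
    A296062 = list(
      label = "minimum Colless index C(B_n)",
      closed = function(n) unclass(colless_min(n)),
      spec = recurrence_spec(1, toll_polynomial(c(1, 0), c(0, 1), c(1, -1))),
      definitional = tree_def(colless_index), def_cost = "tree"),
    A174605 = list(
      label = "minimum Total Cophenetic index Phi(B_n)",
      closed = function(n) unclass(cophenetic_min(n)),
      spec = recurrence_spec(1, toll_polynomial(c(2, 0, 1, 0), c(0, 2, 0, 1),
                                                c("1/2", "1/2", "-1/2", "-1/2"))),
      definitional = tree_def(cophenetic_index), def_cost = "tree"),
    A300445 = list(
      label = "maximum rooted Quartet index rQI(B_n)",
      closed = function(n) unclass(quartet_max(n)),
      spec = recurrence_spec(1, toll_polynomial(c(1, 2, 1, 2), c(1, 1, 2, 2),
                                                c("1/4", "-1/4", "-1/4", "1/4"))),
      definitional = tree_def(quartet_index), def_cost = "tree"),
    walsh = list(
      label = "Walsh Lebesgue constants lambda_n",
      closed = function(n) unclass(walsh_lebesgue(n)),
      spec = recurrence_spec("1/2", toll_polynomial(c(1, 0), c(0, 1),
                                                    c("1/2", "-1/2")), x1 = 1),
      definitional = NULL, def_cost = "none"),
    A268289 = list(
      label = "Takagi-related alternating sums a_(2n-1)",
      closed = function(n) unclass(takagi_related(n, 1)),
      spec = recurrence_spec(1, alternating_toll(1), x1 = 1),
      definitional = function(n) unclass(monroe_job(2 * n)), def_cost = "log"),
    A005536 = list(
      label = "alternating binary digit partial sums x_n = a_(n-1)",
      closed = function(n) unclass(stanton_kocay(n)),
      spec = recurrence_spec(-1, toll_polynomial(0L, 1L, "1")),
      definitional = .stanton_def, def_cost = "log"),
    A006581 = list(
      label = "sum of k AND (n-k)",
      closed = function(n) vapply(n, function(nn) .int_chr(.sigma1(nn + 1)), ""),
      spec = recurrence_spec(2, toll_polynomial(c(1, 0), c(1, 2), c("1", "-1"))),
      shift = 1L,
      definitional = function(n) .bitwise_def(n, "and"), def_cost = "linear"),
    A006582 = list(
      label = "sum of k XOR (n-k)",
      closed = function(n) vapply(n, function(nn) {
        a1 <- .sigma1(nn + 1); .int_chr(2 * choose(nn, 2) - 2 * a1)
      }, ""),
      oracle = function(n_max) {
        s1 <- .seq_oracle_col(.seq_registry()$A006581, n_max)
        s3 <- .seq_oracle_col(.seq_registry()$A006583, n_max)
        q_sub(s3, s1)
      },
      definitional = function(n) .bitwise_def(n, "xor"), def_cost = "linear"),
    A006583 = list(
      label = "sum of k OR (n-k)",
      closed = function(n) vapply(n, function(nn) {
        .int_chr(2 * choose(nn, 2) - .sigma1(nn + 1))
      }, ""),
      spec = recurrence_spec(2, toll_polynomial(c(1, 0, 0, 1, 0), c(0, 1, 0, 1, 2),
                                                c("2", "4", "-6", "-1", "1"))),
      shift = 1L,
      definitional = function(n) .bitwise_def(n, "or"), def_cost = "linear")
  )
}

.seq_lookup <- function(name) {
  reg <- .seq_registry()
  if (name %in% names(reg)) return(reg[[name]])
  stop("unknown sequence '", name, "'; available: ",
       paste(names(reg), collapse = ", "))
}

# oracle column for n = 1..n_max via the recurrence (with optional index shift)
.seq_oracle_col <- function(entry, n_max) {
  if (!is.null(entry$oracle)) return(entry$oracle(n_max))
  shift <- entry$shift %||% 0L
  vals <- unclass(solve_profile(entry$spec, n_max + shift, method = "oracle"))
  vals[(1L + shift):(n_max + shift)]
}

#' Named sequences available for cross-validation
#'
#' @return a data frame with the registry names and descriptions.
#' @export
named_sequences <- function() {
  reg <- .seq_registry()
  data.frame(name = names(reg),
             label = vapply(reg, function(e) e$label, ""),
             has_definitional = vapply(reg, function(e) !is.null(e$definitional), TRUE),
             row.names = NULL)
}

#' Evaluate a named sequence
#'
#' @param name registry name (see [named_sequences()]).
#' @param from,to inclusive index range.
#' @param evaluator `"closed"`, `"oracle"` or `"definitional"`.
#' @return a [rational()] vector.
#' @examples
#' sequence_values("A006581", 2, 5)   # 0 1 2 4
#' @export
sequence_values <- function(name, from = 1, to, evaluator = c("closed", "oracle", "definitional")) {
  evaluator <- match.arg(evaluator)
  stopifnot(from >= 1, to >= from)
  entry <- .seq_lookup(name)
  idx <- seq(from, to)
  out <- switch(evaluator,
    closed = entry$closed(idx),
    oracle = .seq_oracle_col(entry, to)[idx],
    definitional = {
      if (is.null(entry$definitional))
        stop("sequence '", name, "' has no definitional evaluator")
      entry$definitional(idx)
    })
  new_rational(out)
}

#' Cross-validate a named sequence
#'
#' Fills the closed-form, recurrence-oracle and (where available)
#' definitional columns for `n = 1..n_max` and checks exact entrywise
#' agreement.  Definitional evaluators costing O(n) per term (the direct
#' bitwise sums and the tree constructions) are computed up to
#' `definitional_max` (default `min(n_max, 256)`); cheaper definitional
#' evaluators run over the full range.
#'
#' @param name registry name (see [named_sequences()]).
#' @param n_max largest index.
#' @param definitional_max cap for the expensive definitional evaluators.
#' @return a `sequence_report`: a data frame with columns `n`, `closed`,
#'   `oracle`, `definitional` (NA beyond its range) and attribute/field
#'   `agree`.
#' @examples
#' rep5 <- cross_validate("A006581", 64)
#' attr(rep5, "agree")   # TRUE
#' @export
cross_validate <- function(name, n_max, definitional_max = NULL) {
  entry <- .seq_lookup(name)
  idx <- seq_len(n_max)
  closed <- entry$closed(idx)
  oracle <- .seq_oracle_col(entry, n_max)
  defn <- rep(NA_character_, n_max)
  if (!is.null(entry$definitional)) {
    cap <- definitional_max %||%
      if (entry$def_cost %in% c("linear", "tree")) min(n_max, 256L) else n_max
    cap <- min(cap, n_max)
    defn[seq_len(cap)] <- entry$definitional(seq_len(cap))
  }
  agree <- identical(closed, oracle) &&
    all(is.na(defn) | defn == closed)
  out <- data.frame(n = idx, closed = closed, oracle = oracle,
                    definitional = defn, stringsAsFactors = FALSE)
  attr(out, "agree") <- agree
  attr(out, "sequence") <- name
  class(out) <- c("sequence_report", "data.frame")
  out
}

#' @export
print.sequence_report <- function(x, ...) {
  cat(sprintf("sequence %s: %d terms, agree = %s\n",
              attr(x, "sequence"), nrow(x), attr(x, "agree")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
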