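#' Exact rational scalars
#'
#' The closed formulas in this package dispatch on exact equalities (for
#' instance whether the coefficient `a` is an exact power of two) and produce
#' values far beyond the 2^53 integer range of doubles, so every user-facing
#' quantity is carried as an exact rational.  A `rational` vector stores
#' canonical `"p/q"` strings (reduced, `q > 0`, integers printed without a
#' denominator) and supports the usual arithmetic and comparison operators
#' through exact big-integer arithmetic.
#'
#' Doubles are converted *verbatim* as binary values: any double is a dyadic
#' rational, so `as_rational(0.1)` is the exact binary approximation of 1/10
#' (`3602879701896397/36028797018963968`), not `1/10`.  Write `"1/10"` when
#' the decimal fraction is meant.
#'
#' @param num numerator: a whole number, a string like `"p"`, `"p/q"`, or a
#'   rational vector.
#' @param den denominator (defaults to 1); same accepted forms.
#' @return a `rational` vector.
#' @examples
#' rational(3, 4) + rational("1/4")   # 1
#' as_rational("2/6")                 # canonical "1/3"
#' rational(2)^10                     # 1024, exactly
#' @export
rational <- function(num, den = 1) {
  r <- hr_q_arith("/", vapply(num, .rat_chr, ""), vapply(den, .rat_chr, ""))
  new_rational(r)
}

#' @rdname rational
#' @param x object to coerce.
#' @export
as_rational <- function(x) {
  if (is_rational(x)) return(x)
  new_rational(vapply(x, .rat_chr, "", USE.NAMES = FALSE))
}

#' @rdname rational
#' @export
is_rational <- function(x) inherits(x, "halfrec_rational")

new_rational <- function(x) {
  structure(unname(as.character(x)), class = "halfrec_rational")
}

# exact scalar -> canonical "p/q" string; doubles are taken at their exact
# binary value (every double is dyadic)
.rat_chr <- function(x) {
  if (is_rational(x)) return(unclass(x)[[1L]])
  if (is.character(x)) return(hr_q_canonical(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("expected a finite number or a \"p/q\" string", call. = FALSE)
  if (x == floor(x)) return(sprintf("%.0f", x))
  k <- 0L
  while (x != floor(x) && k < 1100L) {
    x <- x * 2
    k <- k + 1L
  }
  hr_q_arith("/", sprintf("%.0f", x), hr_q_pow("2", k))
}

#' @export
Ops.halfrec_rational <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(new_rational(hr_q_arith("-", "0", unclass(e1))))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " is not defined for rationals")
  }
  a <- unclass(as_rational(e1))
  b <- unclass(as_rational(e2))
  switch(.Generic,
    "+" = , "-" = , "*" = , "/" = new_rational(hr_q_arith(.Generic, a, b)),
    "^" = {
      k <- as.numeric(b)
      if (any(k != floor(k))) stop("rational powers need integer exponents")
      new_rational(hr_q_pow(a, k))
    },
    "==" = hr_q_arith("cmp", a, b) == "0",
    "!=" = hr_q_arith("cmp", a, b) != "0",
    "<"  = hr_q_arith("cmp", a, b) == "-1",
    ">"  = hr_q_arith("cmp", a, b) == "1",
    "<=" = hr_q_arith("cmp", a, b) != "1",
    ">=" = hr_q_arith("cmp", a, b) != "-1",
    stop(.Generic, " is not defined for rationals")
  )
}

#' @export
as.character.halfrec_rational <- function(x, ...) unclass(x)

#' @export
as.double.halfrec_rational <- function(x, ...) {
  vapply(unclass(x), function(s) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) as.numeric(parts) else as.numeric(parts[1L]) / as.numeric(parts[2L])
  }, 0, USE.NAMES = FALSE)
}

#' @export
format.halfrec_rational <- function(x, ...) unclass(x)

#' @export
print.halfrec_rational <- function(x, ...) {
  cat("<rational>", format(x), "\n")
  invisible(x)
}

#' @export
`[.halfrec_rational` <- function(x, i) new_rational(unclass(x)[i])

#' @export
c.halfrec_rational <- function(...) {
  new_rational(unlist(lapply(list(...), function(e) unclass(as_rational(e)))))
}

#' @export
rep.halfrec_rational <- function(x, ...) new_rational(rep(unclass(x), ...))

# internal scalar helpers on canonical strings (avoid class dispatch overhead)
q_add <- function(x, y) hr_q_arith("+", x, y)
q_sub <- function(x, y) hr_q_arith("-", x, y)
q_mul <- function(x, y) hr_q_arith("*", x, y)
q_div <- function(x, y) hr_q_arith("/", x, y)
q_eq  <- function(x, y) hr_q_arith("cmp", x, y) == "0"
q_pow <- function(x, k) hr_q_pow(x, k)
q_sum <- function(xs) Reduce(q_add, xs, accumulate = FALSE, right = FALSE) %||% "0"

`%||%` <- function(a, b) if (is.null(a)) b else a
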