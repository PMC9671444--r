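test_that("case profiles resolve the formula dispatch", {
  p <- case_profile(2, 0, 2)
  expect_equal(p$ell, 1); expect_equal(p$delta_ell, 1)
  expect_identical(p$which_case, "b4")
  p <- case_profile(1, 1, 3)
  expect_true(is.na(p$ell)); expect_equal(p$delta_ell, 0)
  expect_identical(p$which_case, "c3")
  p <- case_profile(1, 0, 1)
  expect_equal(p$ell, 0); expect_equal(p$delta_ell, 1); expect_equal(p$delta_rt, 0)
  expect_identical(p$which_case, "b2")
  # a = 2^k with ell out of range leaves the sums unfiltered
  p <- case_profile(1, 3, 2)
  expect_equal(p$ell, -2); expect_equal(p$delta_ell, 0)
  expect_identical(p$which_case, "c3")
  expect_identical(case_profile(0, 2, "1/2")$which_case, "a")
  expect_identical(case_profile(2, 0, "1/2")$which_case, "b1")
  expect_identical(case_profile(2, 0, 7)$which_case, "b3")
  expect_identical(case_profile(2, 1, "1/2")$which_case, "c1")
  expect_identical(case_profile(2, 1, 1)$which_case, "c2")
  expect_identical(case_profile(2, 1, 4)$which_case, "c4")
  expect_equal(case_profile(3, 0, -4)$delta_ell, 0)   # a < 0: ell undefined
  expect_error(case_profile(1, 0, 0), "nonzero")
})

test_that("monomial solutions match the direct recursion on hand cases", {
  expect_identical(chr(x_monomial(5, 1, 0, 1)), "7")
  expect_identical(chr(x_monomial(5, 0, 1, 1)), "5")
  expect_identical(chr(x_monomial(8, 1, 0, 1)), "12")
  expect_identical(chr(x_monomial(1, 3, 2, "7/2")), "0")   # x_1 = 0
  expect_error(x_monomial(5, 1, 0, 0), "nonzero")
  expect_error(x_monomial(0, 1, 0, 1))
})

test_that("closed form, case specializations and oracle agree on a dense grid", {
  res <- oracle_grid_check(n_max = 128, rt_max = 3, a_values = a_grid_full,
                           x1_values = random_rationals(48, seed = 11),
                           check_cased = TRUE)
  expect_equal(res$mismatch_solve_oracle, 0)
  expect_equal(res$mismatch_cased_general, 0)
  expect_equal(res$n_checked, 128 * 16 * length(a_grid_full))
})

test_that("the homogeneous part solves the zero-toll equation", {
  expect_identical(chr(homogeneous_term(3, 2, 1)), "10")
  expect_identical(chr(homogeneous_term(7, 1, 5)), "35")   # x_n = x_1 n at a = 1
  expect_identical(chr(homogeneous_term(9, "1/3", 0)), "0")
  hom <- recurrence_spec("-3/2", x1 = "2/7")
  expect_identical(unclass(solve_profile(hom, 100)),
                   unclass(solve_profile(hom, 100, method = "oracle")))
})

test_that("worked recurrences reproduce their known solutions", {
  # constant toll, a = 1: x_n = (x1 + c) n - c
  cst <- recurrence_spec(1, toll_polynomial(0, 0, 1), x1 = 0)
  expect_identical(chr(solve_recurrence(cst, 9)), "8")
  expect_identical(unclass(solve_profile(cst, 200)), sprintf("%d", 0:199))
  # n^2 satisfies the a = 2 equation with toll floor - ceiling
  sq <- recurrence_spec(2, toll_polynomial(c(0, 1), c(1, 0), c("1", "-1")), x1 = 1)
  expect_identical(chr(solve_recurrence(sq, 11)), "121")
  expect_identical(unclass(solve_profile(sq, 2000)), sprintf("%d", (1:2000)^2))
  # Walsh Lebesgue recurrence
  wl <- recurrence_spec("1/2", toll_polynomial(c(1, 0), c(0, 1), c("1/2", "-1/2")),
                        x1 = 1)
  expect_identical(chr(solve_recurrence(wl, 3)), "3/2")
  # Sackin / Colless recursions via the oracle
  sk <- recurrence_spec(1, toll_polynomial(c(1, 0), c(0, 1), c(1, 1)))
  expect_identical(chr(solve_recurrence(sk, 5, method = "oracle")), "12")
  cl <- recurrence_spec(1, toll_polynomial(c(1, 0), c(0, 1), c(1, -1)))
  expect_identical(chr(solve_recurrence(cl, 7, method = "oracle")), "2")
})

test_that("power-of-two indices follow the geometric closed form", {
  # x_{2^m} = 2^((r+t)(m-1)) m at a = 2^(r+t-1), else ((2a)^m - 2^(m(r+t)))/(2a - 2^(r+t))
  for (a in c("1", "2", "8", "1/2", "3", "-1", "3/2")) {
    ar <- as_rational(a)
    for (r in 0:3) {
      for (t in 0:3) {
        rt <- r + t
        for (m in 1:12) {
          lhs <- x_monomial(2^m, r, t, a)
          rhs <- if (ar == rational(2)^(rt - 1)) {
            rational(2)^(rt * (m - 1)) * rational(m)
          } else {
            (( rational(2) * ar)^m - rational(2)^(m * rt)) /
              (rational(2) * ar - rational(2)^rt)
          }
          expect_true(lhs == rhs,
                      label = sprintf("power-of-two form a=%s r=%d t=%d m=%d",
                                      a, r, t, m))
        }
      }
    }
  }
})

test_that("all powers of the parity toll share one solution", {
  # tolls (ceil - floor)^m have the same solution for every m >= 1
  for (a in c("1", "2", "1/2", "-1", "3")) {
    for (m in 1:4) {
      for (n in c(2:12, 63, 64, 100, 128)) {
        lhs <- x_monomial(n, 1, 0, a) - x_monomial(n, 0, 1, a)
        rhs <- rational(0)
        for (p in 0:m)
          rhs <- rhs + rational(choose(m, p) * (-1)^(m - p)) * x_monomial(n, p, m - p, a)
        expect_true(lhs == rhs)
      }
    }
  }
})

test_that("univariate and alternating tolls expand correctly", {
  tv <- toll_from_univariate(c(0, 1))                    # p(n) = n
  expect_identical(paste(tv$r, tv$t, tv$b), c("0 1 1", "1 0 1"))
  tv <- toll_from_univariate(c(0, "-1/2", "1/2"))        # p(n) = C(n, 2)
  expect_setequal(paste(tv$r, tv$t, tv$b),
                  c("2 0 1/2", "1 1 1", "0 2 1/2", "1 0 -1/2", "0 1 -1/2"))
  expect_identical(toll_degree(toll_from_univariate(1)), 0)
  expect_identical(length(toll_from_univariate(0)$r), 0L)
  # expansion solves like the univariate toll: check against the oracle
  spec <- recurrence_spec("3/2", toll_from_univariate(c("1/3", 2, 0, 1)), x1 = "1/2")
  expect_identical(unclass(solve_profile(spec, 128)),
                   unclass(solve_profile(spec, 128, method = "oracle")))
  at <- alternating_toll(1)                              # (-1)^n
  expect_setequal(paste(at$r, at$t, at$b), c("0 0 1", "1 0 -2", "0 1 2"))
  expect_identical(length(alternating_toll(0)$r), 0L)
  at3 <- alternating_toll(3)
  expect_setequal(at3$b, c("3", "-6", "6"))
  # the expansion really encodes (-1)^n: compare with a literal recursion
  sp <- recurrence_spec(1, alternating_toll(1), x1 = 0)
  v <- as.numeric(as_rational(unclass(solve_profile(sp, 64))))
  w <- numeric(64)
  for (n in 2:64) w[n] <- w[ceiling(n / 2)] + w[n %/% 2] + (-1)^n
  expect_identical(v, w)
})

test_that("even/odd interleaved pairs reduce to half-recurrences", {
  ss <- stephan_spec(1, P = numeric(), Q = numeric())
  expect_identical(length(ss$toll$r), 0L)                # homogeneous
  ss <- stephan_spec(-1, P = c(0, 1), Q = c(1, 1))       # toll floor(n/2)
  expect_identical(paste(ss$toll$r, ss$toll$t, ss$toll$b), "0 1 1")
  expect_identical(ss$a, "-1")
  # the AND-sum pair: a_{2n} = 2a_n + 2a_{n-1} + n, a_{2n+1} = 4a_n
  g1 <- stephan_spec(2, P = c(0, 1), Q = numeric())
  ref <- recurrence_spec(2, toll_polynomial(c(1, 0), c(1, 2), c("1", "-1")))
  expect_identical(unclass(solve_profile(g1, 200, method = "oracle")),
                   unclass(solve_profile(ref, 200, method = "oracle")))
  # consistency: the pair recurrence itself reproduces the interleaved values
  x <- as.numeric(as_rational(unclass(solve_profile(g1, 101, method = "oracle"))))
  aa <- x[-1]                                            # a_n = x_{n+1}
  for (n in 2:49) {
    expect_equal(aa[2 * n], 2 * aa[n] + 2 * aa[n - 1] + n)
    expect_equal(aa[2 * n + 1], 4 * aa[n])
  }
})

test_that("the vanishing criterion characterizes identically-zero solutions", {
  base <- toll_polynomial(c(2, 1, 0, 1, 0), c(0, 1, 2, 0, 1),
                          c(1, -2, 1, -1, 1))             # (x-y)(x-y-1)
  expect_true(vanishing_check(base))
  expect_false(vanishing_check(toll_polynomial(c(1, 0), c(0, 1), c(1, 1))))
  q1 <- toll_polynomial(c(1, 0), c(1, 0), c(3, 2))        # 3xy + 2
  prod1 <- halfrec:::toll_mul(base, q1)
  expect_true(vanishing_check(prod1))
  spec <- recurrence_spec("5/2", prod1, x1 = 0)
  expect_identical(unique(unclass(solve_profile(spec, 200))), "0")
  expect_identical(unique(unclass(solve_profile(spec, 200, method = "oracle"))), "0")
  # a failing toll yields a nonzero value by n = 16
  bad <- toll_polynomial(c(2, 0), c(0, 2), c(1, -1))      # x^2 - y^2
  expect_false(vanishing_check(bad))
  vals <- unclass(solve_profile(recurrence_spec(1, bad), 16))
  expect_true(any(vals != "0"))
  expect_true(vanishing_check(toll_polynomial()))
})

test_that("JSON round trips a recurrence specification", {
  js <- '{"a": "2", "x1": "1", "toll": [[0, 1, "1"], [1, 0, "-1"]]}'
  spec <- read_recurrence_json(js)
  expect_identical(chr(solve_recurrence(spec, 11)), "121")
  js2 <- '{"a": 1, "toll": [[1, 0, 1], [0, 1, 1]]}'
  expect_identical(chr(solve_recurrence(read_recurrence_json(js2), 8)), "24")
  expect_error(read_recurrence_json('{"x1": "1"}'), "\"a\"")
})
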