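test_that("S inner sums match hand-worked cases", {
  expect_identical(chr(s_term(4, 1, 2, "5")), "0")   # s_4 = 1: empty sum
  expect_identical(chr(s_term(4, 0, 0, "7")), "0")
  expect_identical(chr(s_term(3, 0, 0, "1")), "1")
  expect_identical(chr(s_term(3, 0, 1, "2")), "2")   # (2/2)^0 * M_2(3)
})

test_that("the alpha closed form equals the definitional double sum", {
  expect_identical(chr(alpha_sum(5, 0, 0, 1)), "1")
  expect_identical(chr(alpha_sum(5, 0, 0, 2)), "1")
  expect_identical(chr(alpha_sum(1, 0, 3, "5")), "0")   # empty structures
  expect_identical(chr(alpha_sum(2, 1, 2, "7", method = "bruteforce")), "0")
  for (a in a_grid_small) {
    for (d in 0:1) {
      for (m in 0:4) {
        expect_identical(
          unclass(alpha_profile(512, d, m, a, method = "closed")),
          unclass(alpha_profile(512, d, m, a, method = "bruteforce")),
          label = sprintf("alpha closed vs brute, d=%d m=%d a=%s", d, m, a)
        )
      }
    }
  }
  expect_error(alpha_sum(5, 2, 0, 1), "d = 0, 1")
})

test_that("the reduced alpha^(0,0) and alpha^(1,0) forms agree with the general one", {
  ns <- c(1:64, 100, 255, 256, 511, 512)
  for (a in a_grid_small) {
    expect_identical(vapply(ns, function(n) chr(alpha_special(n, 0, a)), ""),
                     vapply(ns, function(n) chr(alpha_sum(n, 0, 0, a)), ""))
    if (!a %in% c("1", "1/2")) {
      expect_identical(vapply(ns, function(n) chr(alpha_special(n, 1, a)), ""),
                       vapply(ns, function(n) chr(alpha_sum(n, 1, 0, a)), ""))
    }
  }
})

test_that("the gamma closed form equals the literal double sum", {
  expect_identical(chr(gamma_sum(0, 1, 0, 2, "5")), "0")
  expect_identical(chr(gamma_sum(2, 0, 0, 0, "1", method = "bruteforce")), "4")
  expect_identical(chr(gamma_sum(2, 0, 1, 1, "1", method = "bruteforce")), "2")
  # gamma_l(d,0,m) = 2^(l-1) T(d, l, a 2^-m)
  expect_identical(chr(gamma_sum(3, 0, 0, 1, "1")),
                   chr(rational(4) * t_sum(0, 3, "1/2")))
  for (a in a_grid_small) {
    for (l in 0:8) {
      for (d in 0:1) {
        for (m in 1:3) {
          for (p in 0:(m - 1)) {
            expect_identical(chr(gamma_sum(l, d, p, m, a)),
                             chr(gamma_sum(l, d, p, m, a, method = "bruteforce")),
                             label = sprintf("gamma l=%d d=%d p=%d m=%d a=%s",
                                             l, d, p, m, a))
          }
        }
      }
    }
  }
  expect_error(gamma_sum(2, 0, 1, 1, "1"), "p < m")
})

test_that("running peak and bit-position sums match their T-based closed forms", {
  # sum_{k<n} q_s(k)^d x^(q_s(k))  and  sum_{k<n} sum_i q_i(k)^d x^(q_i(k))
  for (x in c("1", "2", "1/2", "-1", "3", "1/3")) {
    for (d in 0:1) {
      r <- halfrec:::hr_peak_sum_range(512L, d, x)
      expect_identical(r$lhs, r$rhs, label = sprintf("peak sums d=%d x=%s", d, x))
      r <- halfrec:::hr_bit_sum_range(512L, d, x)
      expect_identical(r$lhs, r$rhs, label = sprintf("bit sums d=%d x=%s", d, x))
    }
  }
})

test_that("first differences of the monomial solutions match their closed form", {
  expect_identical(chr(y_diff(2, 3, 2, "5")), "1")      # y_2 = 1 always
  expect_identical(chr(y_diff(5, 0, 0, "2")), "4")      # a^(q_s(4)) = 4
  expect_identical(chr(y_diff(5, 1, 0, "1")), "3")
  for (a in c("1", "2", "1/2", "-1", "8", "3")) {
    for (r in 0:3) {
      for (t in 0:3) {
        x <- unclass(x_monomial_profile(256, r, t, a))
        y <- vapply(2:256, function(n) chr(y_diff(n, r, t, a)), "")
        expect_identical(y, unclass(as_rational(x[2:256]) - as_rational(x[1:255])),
                         label = sprintf("y vs diff r=%d t=%d a=%s", r, t, a))
      }
    }
  }
})

test_that("the two forms of the telescoping delta sum agree", {
  # sum_j M_{j+1}^(t+l) (q_{j+1} - q_j)  ==  a^{q_s} q_s + sum_i C(t+l,i) S^(1,i)
  # for a = 2^(t+l), the identity behind the delta_ell branch
  for (tl in 0:3) {
    a <- chr(2^tl)
    for (n in c(1:128, 255, 256)) {
      lhs <- halfrec:::hr_y_delta_sum(n, as.integer(tl))
      d <- decompose(n); qs <- d$q[d$s]
      rhs <- as_rational(a)^qs * rational(qs)
      if (tl > 0) {
        for (i in 0:(tl - 1)) rhs <- rhs + rational(choose(tl, i)) * s_term(n, 1, i, a)
      }
      expect_identical(lhs, chr(rhs))
    }
  }
})

test_that("alpha vanishes at n = 1 in every formulation", {
  for (a in a_grid_small) {
    for (d in 0:1) {
      for (m in 0:3) {
        expect_identical(chr(alpha_sum(1, d, m, a)), "0")
        expect_identical(chr(alpha_sum(1, d, m, a, method = "bruteforce")), "0")
      }
    }
  }
})
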