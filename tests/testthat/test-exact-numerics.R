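test_that("Bernoulli numbers satisfy their defining recurrence", {
  expect_identical(chr(bernoulli_number(0)), "1")
  expect_identical(chr(bernoulli_number(1)), "-1/2")
  expect_identical(chr(bernoulli_number(2)), "1/6")
  expect_identical(chr(bernoulli_number(3)), "0")
  expect_identical(chr(bernoulli_number(12)), "-691/2730")
  for (m in 1:20) {
    acc <- rational(0)
    for (k in 0:m) acc <- acc + rational(choose(m + 1, k)) * bernoulli_number(k)
    expect_true(acc == 0)
  }
  # odd Bernoulli numbers beyond B_1 vanish
  for (k in 1:9) expect_identical(chr(bernoulli_number(2 * k + 1)), "0")
})

test_that("Bernoulli polynomials obey the reflection and shift identities", {
  expect_identical(chr(bernoulli_poly(1, 0)), "-1/2")
  for (m in 0:8) {
    # B_m(0) = B_m = (-1)^m B_m(1)
    expect_true(bernoulli_poly(m, 0) == bernoulli_number(m))
    expect_true(bernoulli_poly(m, 1) * rational((-1)^m) == bernoulli_number(m))
    # B_m(2) = (-1)^m B_m + m
    expect_true(bernoulli_poly(m, 2) ==
                  rational((-1)^m) * bernoulli_number(m) + rational(m))
  }
  # translation identity B_m(x + y) = sum_k C(m,k) B_k(x) y^(m-k)
  pts <- list(c("1/2", "1/3"), c("2", "-1/2"), c("-3/4", "5"), c("0", "7/2"))
  for (m in 0:6) {
    for (p in pts) {
      x <- as_rational(p[1]); y <- as_rational(p[2])
      lhs <- bernoulli_poly(m, x + y)
      rhs <- rational(0)
      for (k in 0:m)
        rhs <- rhs + rational(choose(m, k)) * bernoulli_poly(k, x) * y^(m - k)
      expect_true(lhs == rhs)
    }
  }
})

test_that("T(d, n, x) matches its closed forms and recurrence", {
  expect_identical(chr(t_sum(0, 4, 1)), "4")
  expect_identical(chr(t_sum(1, 3, 2)), "10")
  expect_identical(chr(t_sum(1, 3, 1)), "3")       # C(3,2)
  expect_identical(chr(t_sum(2, 0, 5)), "0")       # empty sum
  expect_error(t_sum(0, 4, 0), "x != 0")
  # closed forms for d = 0,1 equal direct summation
  for (x in c("2", "1/2", "-1", "3", "-2", "1/3", "1")) {
    for (n in c(0:12, 30)) {
      for (d in 0:1) {
        direct <- rational(0)
        for (k in seq_len(n) - 1) direct <- direct + rational(k)^d * as_rational(x)^k
        expect_true(t_sum(d, n, x) == direct)
      }
    }
  }
  # T(1,n,x) = x/(1-x) (T(0,n,x) - n x^(n-1)) for x != 1
  for (x in c("2", "1/2", "-1", "3", "-2", "1/3")) {
    xr <- as_rational(x)
    for (n in c(1:16, 31, 64)) {
      lhs <- t_sum(1, n, x)
      rhs <- xr / (rational(1) - xr) * (t_sum(0, n, x) - rational(n) * xr^(n - 1))
      expect_true(lhs == rhs)
    }
  }
})

test_that("the Bernoulli power-sum expansion equals direct summation", {
  expect_identical(chr(faulhaber(1, 5)), "10")
  expect_identical(chr(faulhaber(0, 5)), "4")
  expect_identical(chr(faulhaber(3, 4)), "36")
  for (d in 0:6) {
    for (n in c(1:40, 100, 200)) {
      expect_identical(chr(faulhaber(d, n)), chr(faulhaber(d, n, method = "direct")))
    }
  }
})
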