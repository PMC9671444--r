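test_that("binary decompositions match hand-worked cases", {
  d <- decompose(13)                       # 13 = 1 + 4 + 8
  expect_equal(d$s, 3)
  expect_equal(d$q, c(0, 2, 3))
  expect_equal(d$M, c(14, 13, 12, 8, 0))
  d5 <- decompose(5)                       # 5 = 1 + 4
  expect_equal(d5$s, 2)
  expect_equal(d5$q, c(0, 2))
  expect_equal(suffix_sum(d5, 1), 5)
  expect_equal(suffix_sum(d5, 2), 4)
  d8 <- decompose(8)                       # power of two
  expect_equal(d8$s, 1)
  expect_equal(d8$q, 3)
  expect_equal(suffix_sum(d8, 1), 8)
})

test_that("decomposition invariants hold over a large range", {
  set.seed(99)
  for (n in c(1:4096, sample(4097:1e5, 200))) {
    d <- decompose(n)
    expect_true(all(diff(d$q) > 0))
    expect_identical(sum(2^d$q), as.numeric(n))           # round trip
    expect_equal(d$q[d$s], floor(log2(n)))
    expect_equal(d$M[2], n)                               # M_1 = n
    expect_equal(d$M[1], n + 1)                           # M_0 = n + 1
    expect_equal(d$M[d$s + 2], 0)                         # M_{s+1} = 0
    # M_i = 2^{q_i} floor(n / 2^{q_i})
    expect_equal(d$M[2:(d$s + 1)], 2^d$q * floor(n / 2^d$q))
  }
  expect_equal(bit_position(decompose(6), 0), 0)          # q_0 convention
  expect_error(decompose(0), "positive")
})

test_that("bit positions concatenate across disjoint ranges", {
  # for M >= 2 and 1 <= p < 2^(q_1(M)), the decomposition of M + p is the
  # decomposition of p followed by that of M -- exhaustively to 1024
  for (M in 2:1023) {
    q1 <- decompose(M)$q[1]
    if (q1 == 0) next
    for (p in seq_len(min(2^q1 - 1, 1024 - M))) {
      dM <- decompose(M); dp <- decompose(p); dMp <- decompose(M + p)
      expect_identical(dMp$s, dp$s + dM$s)
      expect_identical(dMp$q, c(dp$q, dM$q))
    }
  }
})

test_that("doubling shifts bit positions by one", {
  for (n in c(1, 5, 13, 100, 777)) {
    d <- decompose(n); d2 <- shift_decomposition(n)
    expect_equal(d2$s, d$s)
    expect_equal(d2$q, d$q + 1)
  }
  expect_equal(shift_decomposition(5)$q, c(1, 3))
})

test_that("iterated ceiling/floor halving equals its closed form", {
  expect_equal(phi_compose(c(1, 0), 13), 3)
  expect_equal(phi_compose(0, 7), 3)
  expect_equal(phi_compose(c(1, 1, 1), 1), 1)
  # phi_{b_m...b_0}(n) = floor((n + sum b_i 2^i) / 2^(m+1)), all strings <= 6
  for (m in 0:5) {
    masks <- expand.grid(rep(list(0:1), m + 1))
    for (row in seq_len(nrow(masks))) {
      bits <- as.numeric(masks[row, ])        # b_m ... b_0
      offset <- sum(bits * 2^(m:0))
      for (n in c(1:40, 511, 512)) {
        expect_equal(phi_compose(bits, n), floor((n + offset) / 2^(m + 1)))
      }
    }
  }
  expect_error(phi_compose(integer(), 4), "non-empty")
})
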