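test_that("closed forms reproduce hand-computed sequence values", {
  expect_identical(chr(sackin_min(c(2, 5, 8))), c("2", "12", "24"))
  expect_identical(chr(colless_min(c(5, 7))), c("2", "2"))
  expect_identical(chr(colless_min(2^(1:10))), rep("0", 10))
  expect_identical(chr(cophenetic_min(c(2, 4, 5))), c("0", "2", "5"))
  expect_identical(chr(quartet_max(c(3, 4, 5))), c("0", "1", "3"))
  expect_identical(chr(walsh_lebesgue(c(1, 3))), c("1", "3/2"))
  expect_identical(chr(walsh_lebesgue(2^(0:10))), rep("1", 11))
  expect_identical(chr(takagi_related(2, x1 = 1)), "3")
  expect_identical(chr(takagi_related(1, x1 = "4/7")), "4/7")
  expect_identical(chr(takagi_related(6, x1 = 1)), chr(monroe_job(12)))
  expect_identical(chr(stanton_kocay(c(1, 2))), c("0", "1"))
  st <- recurrence_spec(-1, toll_polynomial(0, 1, 1))
  expect_identical(chr(stanton_kocay(9)),
                   chr(solve_recurrence(st, 9, method = "oracle")))
  expect_identical(chr(bitwise_sums(5)), c("4", "12", "16"))
  expect_identical(chr(bitwise_sums(2)), c("1", "0", "1"))   # 1 AND/XOR/OR 1
  expect_identical(chr(bitwise_sums(16)),
                   sprintf("%d", c(bitwise_direct(16, "and"),
                                   bitwise_direct(16, "xor"),
                                   bitwise_direct(16, "or"))))
})

test_that("every registered sequence cross-validates on all its evaluators", {
  for (nm in named_sequences()$name) {
    rep_ <- cross_validate(nm, 512)
    expect_true(attr(rep_, "agree"), label = paste("sequence", nm))
    expect_identical(rep_$closed, rep_$oracle, label = paste("columns of", nm))
  }
  expect_error(cross_validate("A000000", 10), "unknown sequence")
  expect_error(sequence_values("walsh", 1, 5, evaluator = "definitional"),
               "no definitional")
})

test_that("sequence evaluator access works over index windows", {
  expect_identical(chr(sequence_values("A006581", 2, 5)), c("1", "0", "4", "4"))
  expect_identical(chr(sequence_values("A003314", 5, 8, evaluator = "oracle")),
                   c("12", "16", "20", "24"))
  expect_identical(chr(sequence_values("A006583", 5, 5, evaluator = "definitional")),
                   "16")
})

test_that("AND + XOR = OR for the bitwise convolution sums", {
  a1 <- unclass(sequence_values("A006581", 1, 512))
  a2 <- unclass(sequence_values("A006582", 1, 512))
  a3 <- unclass(sequence_values("A006583", 1, 512))
  expect_identical(chr(as_rational(a1) + as_rational(a2)), a3)
})

test_that("the alternating-toll solution interleaves into the digit-sum sequence", {
  # x_n = a_(2n-1): closed form vs the digit-wise formula at doubled index
  n <- 1:512
  expect_identical(unclass(takagi_related(n, x1 = 1)), unclass(monroe_job(2 * n)))
})
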