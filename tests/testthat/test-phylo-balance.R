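test_that("Newick parsing validates and round-trips", {
  tr <- parse_newick("((a,b),(c,d));")
  expect_equal(length(tr$tip.label), 4)
  expect_equal(colless_index(tr), 0)
  tr2 <- parse_newick("(a,(b,(c,d)));")          # caterpillar on 4 leaves
  expect_equal(sackin_index(tr2), 9)
  tr3 <- parse_newick("((a:1,b:2)x:3,c:1);")     # lengths/labels ignored
  expect_equal(sackin_index(tr3), 5)
  rt <- parse_newick(write_newick(tr2))
  expect_equal(sackin_index(rt), sackin_index(tr2))
  expect_setequal(rt$tip.label, tr2$tip.label)
  expect_error(parse_newick("((a,b),(c,d))"), ";")
  expect_error(parse_newick("((a,b),(c,d);"), "unbalanced")
  expect_error(parse_newick("((a,b)),(c,d));"), "position")
  expect_error(parse_newick("((a,b),(a,d));"), "duplicate")
})

test_that("extreme-shape constructors build the intended topologies", {
  k4 <- caterpillar_tree(4)
  st <- halfrec:::.tree_stats(k4)
  expect_equal(sort(st$depth[1:4]), c(1, 2, 3, 3))
  k2 <- caterpillar_tree(2)
  expect_equal(sackin_index(k2), 2)
  k7 <- caterpillar_tree(7)
  st7 <- halfrec:::.tree_stats(k7)
  # every internal node has a leaf child
  for (v in 8:13) expect_true(any(st7$kids[[v]] <= 7))
  b4 <- max_balanced_tree(4)
  expect_equal(colless_index(b4), 0)
  b7 <- max_balanced_tree(7)
  st7 <- halfrec:::.tree_stats(b7)
  expect_setequal(st7$kappa[st7$kids[[st7$root]]], c(4, 3))
  b6 <- max_balanced_tree(6)
  st6 <- halfrec:::.tree_stats(b6)
  expect_setequal(st6$kappa[st6$kids[[st6$root]]], c(3, 3))
  # every internal node splits its leaves as evenly as possible
  for (n in c(2:40, 100, 255)) {
    st <- halfrec:::.tree_stats(max_balanced_tree(n))
    for (v in (n + 1):(2 * n - 1)) {
      kk <- st$kappa[st$kids[[v]]]
      expect_lte(abs(kk[1] - kk[2]), 1)
    }
  }
})

test_that("index definitions match hand-worked trees", {
  expect_equal(sackin_index(caterpillar_tree(4)), 9)
  expect_equal(sackin_index(max_balanced_tree(4)), 8)
  expect_equal(colless_index(caterpillar_tree(4)), 3)
  expect_equal(colless_index(max_balanced_tree(8)), 0)
  expect_equal(cophenetic_index(parse_newick("(a,b);")), 0)
  expect_equal(cophenetic_index(caterpillar_tree(4)), 4)
  expect_equal(quartet_index(max_balanced_tree(4)), 1)
  for (n in 4:12) expect_equal(quartet_index(caterpillar_tree(n)), 0)
  # single leaf: all indices vanish
  leaf <- max_balanced_tree(1)
  expect_equal(sackin_index(leaf), 0)
  expect_equal(cophenetic_index(leaf), 0)
})

test_that("multifurcating trees get Sackin/cophenetic but not Colless/quartet", {
  tr <- parse_newick("((a,b,c),(d,e));")
  expect_equal(sackin_index(tr), 10)
  expect_equal(cophenetic_index(tr), cophenetic_index(tr, method = "pairs"))
  expect_error(colless_index(tr), "bifurcating")
  expect_error(quartet_index(tr), "bifurcating")
  b <- balance_indices(tr)
  expect_true(is.na(b$colless) && is.na(b$quartet))
  expect_equal(b$sackin, 10)
})

test_that("balanced-tree indices equal the recurrence closed forms", {
  ns <- 2:256
  expect_identical(vapply(ns, function(n) sprintf("%.0f", sackin_index(max_balanced_tree(n))), ""),
                   unclass(sackin_min(ns)))
  expect_identical(vapply(ns, function(n) sprintf("%.0f", colless_index(max_balanced_tree(n))), ""),
                   unclass(colless_min(ns)))
  expect_identical(vapply(ns, function(n) sprintf("%.0f", cophenetic_index(max_balanced_tree(n))), ""),
                   unclass(cophenetic_min(ns)))
  ns <- 2:64
  expect_identical(vapply(ns, function(n) sprintf("%.0f", quartet_index(max_balanced_tree(n))), ""),
                   unclass(quartet_max(ns)))
})

test_that("the two cophenetic evaluators agree on random trees", {
  set.seed(42)
  for (i in 1:200) {
    tr <- ape::rtree(sample(4:64, 1))
    expect_equal(cophenetic_index(tr), cophenetic_index(tr, method = "pairs"))
  }
})

test_that("the two quartet evaluators agree on random trees", {
  set.seed(43)
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:25, 1))
    expect_equal(quartet_index(tr), quartet_index(tr, method = "bruteforce"))
  }
})

test_that("random bifurcating trees sit inside the closed-form extremes", {
  set.seed(44)
  for (i in 1:60) {
    n <- sample(4:80, 1)
    tr <- ape::rtree(n)
    expect_gte(sackin_index(tr), as.numeric(sackin_min(n)))
    expect_gte(colless_index(tr), as.numeric(colless_min(n)))
    expect_gte(cophenetic_index(tr), as.numeric(cophenetic_min(n)))
    expect_lte(quartet_index(tr), as.numeric(quartet_max(n)))
  }
})

test_that("extreme values and normalization behave per index orientation", {
  ex <- extreme_values("colless", 8)
  expect_equal(ex$min, 0); expect_equal(ex$max, 21)
  ex <- extreme_values("quartet", 4)
  expect_equal(ex$min, 0); expect_equal(ex$max, 1)
  ex <- extreme_values("sackin", 2)
  expect_equal(ex$min, ex$max)                     # unique topology
  expect_identical(chr(normalize_index("colless", max_balanced_tree(16))), "0")
  expect_identical(chr(normalize_index("colless", caterpillar_tree(16))), "1")
  expect_identical(chr(normalize_index("quartet", parse_newick("((a,b),(c,d));"))), "0")
  expect_identical(chr(normalize_index("quartet", caterpillar_tree(6))), "1")
  expect_error(normalize_index("sackin", caterpillar_tree(2)), "n = 2")
  set.seed(45)
  for (i in 1:25) {
    tr <- ape::rtree(sample(5:40, 1))
    for (idx in c("sackin", "colless", "cophenetic", "quartet")) {
      v <- normalize_index(idx, tr)
      expect_true(v >= 0 && v <= 1)
    }
  }
})
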