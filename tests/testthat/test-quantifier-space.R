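test_that("structure indexing follows the lexicographic convention and is bijective", {
  expect_equal(structure_from_index(7, 3), c(TRUE, TRUE, TRUE))
  expect_equal(structure_from_index(0, 3), c(FALSE, FALSE, FALSE))
  expect_equal(structure_from_index(5, 3), c(TRUE, FALSE, TRUE))
  expect_error(structure_from_index(8, 3), "index")
  expect_error(structure_from_index(-1, 3), "index")

  for (n in c(1L, 3L, 6L, 10L)) {
    idx <- 0:(2^n - 1)
    back <- vapply(idx, function(i) {
      index_of_structure(structure_from_index(i, n))
    }, numeric(1))
    expect_identical(back, as.numeric(idx))
  }
  # rows of all_structures() agree with structure_from_index()
  S <- all_structures(4)
  expect_equal(nrow(S), 16L)
  for (i in c(0L, 5L, 15L)) {
    expect_equal(S[i + 1L, ], structure_from_index(i, 4))
  }
})

test_that("substructure relation matches its definition and is a partial order", {
  expect_true(is_substructure(c(FALSE, TRUE, TRUE, FALSE, FALSE),
                              c(FALSE, TRUE, TRUE, TRUE, TRUE)))
  expect_false(is_substructure(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE)))
  expect_error(is_substructure(c(TRUE), c(TRUE, FALSE)), "equal length")

  set.seed(11)
  n <- 6
  for (rep in 1:200) {
    M1 <- runif(n) < 0.5; M2 <- runif(n) < 0.5; M3 <- runif(n) < 0.5
    expect_true(is_substructure(M1, M1)) # reflexive
    if (is_substructure(M1, M2) && is_substructure(M2, M1)) {
      expect_identical(M1, M2)           # antisymmetric
    }
    if (is_substructure(M1, M2) && is_substructure(M2, M3)) {
      expect_true(is_substructure(M1, M3)) # transitive
    }
    # definitional equivalence: true-set containment
    expect_identical(is_substructure(M1, M2), all(which(M1) %in% which(M2)))
  }
})

test_that("make_quantifier tabulates truth conditions in index order", {
  allq <- make_quantifier(function(M) all(M), 3)
  expect_identical(as.logical(allq),
                   c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(as.logical(make_quantifier(function(M) TRUE, 2)),
                   rep(TRUE, 4))
  # count >= 2 at n = 3: true exactly on the 4 structures with >= 2 T bits
  q <- make_quantifier(function(M) sum(M) >= 2, 3)
  expected <- vapply(0:7, function(i) sum(structure_from_index(i, 3)) >= 2,
                     logical(1))
  expect_identical(as.logical(q), expected)
  expect_equal(sum(q), 4)
})

test_that("named quantifiers realize their standard definitions", {
  expect_identical(as.logical(named_quantifier("some", 2)),
                   c(FALSE, TRUE, TRUE, TRUE))
  expect_identical(as.logical(named_quantifier("all", 3)),
                   as.logical(make_quantifier(function(M) all(M), 3)))
  # between 2 and 4 at n = 10: choose(10,2)+choose(10,3)+choose(10,4) structures
  q <- named_quantifier("between", 10, lo = 2, hi = 4)
  expect_equal(sum(q), sum(choose(10, 2:4)))
  # ultrafilter: true exactly on structures whose bit i is T
  uf <- named_quantifier("ultrafilter", 3, i = 3)
  expect_identical(as.logical(uf),
                   vapply(0:7, function(k) structure_from_index(k, 3)[3],
                          logical(1)))
  # conjunction of two ultrafilters
  cj <- named_quantifier("conj_ultrafilter", 4, i = 1, j = 4)
  expect_identical(as.logical(cj),
                   as.logical(named_quantifier("ultrafilter", 4, i = 1) &
                                named_quantifier("ultrafilter", 4, i = 4)))
  # parity includes the empty structure (count 0 is even)
  expect_true(named_quantifier("even", 3)[1])
  expect_error(named_quantifier("at_least", 3, k = 5), "k")
  expect_error(named_quantifier("ultrafilter", 3, i = 0), "i")
  expect_error(named_quantifier("between", 3, lo = 2, hi = 1), "lo")
})

test_that("degeneracy is the larger output-class proportion", {
  expect_equal(degeneracy(named_quantifier("const", 5, value = TRUE)), 1)
  expect_equal(degeneracy(named_quantifier("all", 3)), 0.875)
  expect_equal(degeneracy(named_quantifier("between", 10, lo = 3, hi = 5)),
               sum(choose(10, 3:5)) / 1024)  # 582/1024 T entries
})

test_that("binary monotonicity agrees with the pair-counting oracle", {
  set.seed(21)
  for (n in 2:4) {
    qs <- c(
      list(named_quantifier("some", n), named_quantifier("all", n),
           named_quantifier("even", n),
           named_quantifier("ultrafilter", n, i = 1),
           named_quantifier("const", n, value = FALSE)),
      lapply(1:25, function(k) as_quantifier(random_table(n), n))
    )
    for (q in qs) {
      expect_identical(is_monotone(q, "up"), oracle_is_monotone(q, "up"))
      expect_identical(is_monotone(q, "down"), oracle_is_monotone(q, "down"))
    }
  }
  expect_true(is_monotone(named_quantifier("at_least", 10, k = 4), "up"))
  expect_false(is_monotone(named_quantifier("even", 10), "up"))
  expect_false(is_monotone(named_quantifier("even", 10), "down"))
  expect_true(is_monotone(named_quantifier("const", 4, value = TRUE), "up"))
  expect_true(is_monotone(named_quantifier("const", 4, value = TRUE), "down"))
})

test_that("quantity (permutation invariance) holds exactly for count-determined tables", {
  expect_true(is_quantitative(named_quantifier("between", 10, lo = 2, hi = 4)))
  expect_false(is_quantitative(named_quantifier("ultrafilter", 4, i = 2)))
  expect_true(is_quantitative(named_quantifier("const", 4, value = TRUE)))

  set.seed(31)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    q <- as_quantifier(random_table(n), n)
    expect_identical(is_quantitative(q), oracle_is_quantitative(q))
  }

  # a quantitative table is invariant under any fixed bit permutation
  set.seed(32)
  n <- 6
  perm <- sample.int(n)
  cnt_tab <- runif(n + 1) < 0.5
  q <- make_quantifier(function(M) cnt_tab[sum(M) + 1L], n)
  permuted <- vapply(0:(2^n - 1), function(i) {
    M <- structure_from_index(i, n)
    q[index_of_structure(M[perm]) + 1L]
  }, logical(1))
  expect_identical(as.logical(q), permuted)
})

test_that("quantitative enumeration matches closed forms and full enumeration", {
  expect_equal(count_quantitative(1), list(total = 4L, monotone = 4L))
  expect_equal(count_quantitative(2), list(total = 8L, monotone = 6L))
  cq <- count_quantitative(10)
  expect_equal(cq$total, 2048L)
  expect_equal(cq$monotone, 22L)

  # exhaustive cross-check over all 2^(2^n) quantifiers at n = 2, 3
  for (n in 2:3) {
    tabs <- all_structures(2^n)  # rows enumerate all truth tables
    quant <- apply(tabs, 1, function(q) is_quantitative(as_quantifier(q)))
    mono <- apply(tabs, 1, function(q) {
      is_monotone(as_quantifier(q), "up") || is_monotone(as_quantifier(q), "down")
    })
    expect_equal(sum(quant), count_quantitative(n)$total)
    expect_equal(sum(quant & mono), count_quantitative(n)$monotone)
  }
})

test_that("quantifier serialization round-trips", {
  q <- named_quantifier("some", 3)
  s <- quantifier_to_string(q)
  expect_identical(s, "01111111")
  expect_identical(as.logical(as_quantifier(s)), as.logical(q))
  expect_error(as_quantifier("010"), "power of two")
  expect_error(as_quantifier("01x1"), "0.*1")
})
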