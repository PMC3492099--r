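test_that("cube coverage honors fixed literals and don't-cares", {
  expect_true(cube_covers("-0-0", c(0, 0, 0, 0)))
  expect_false(cube_covers("-0-0", c(0, 0, 0, 1)))
  expect_true(cube_covers("----", c(1, 0, 1, 1)))
  expect_true(cube_covers("-0-0", "0000"))
  expect_error(cube_covers("-0-0", c(0, 0)), "widths differ")
})

test_that("adjacent cubes merge into a single wider cube", {
  expect_equal(merge_adjacent("111", "011"), "-11")
  expect_null(merge_adjacent("111", "100"))
  expect_equal(merge_adjacent("-11", "-01"), "--1")
  expect_null(merge_adjacent("-11", "011"))  # mismatched don't-care profile
})

test_that("a merged cube covers exactly the union of its parents' minterms", {
  set.seed(5)
  n <- 4
  pool <- oracle_all_cubes(n)
  found <- 0
  for (i in 1:400) {
    a <- sample(pool, 1); b <- sample(pool, 1)
    m <- merge_adjacent(a, b)
    if (!is.null(m)) {
      found <- found + 1
      expect_setequal(oracle_minterms(m),
                      union(oracle_minterms(a), oracle_minterms(b)))
    }
  }
  expect_gt(found, 5)
})

test_that("prime implicants of the worked table include the published cubes", {
  pr <- prime_implicants(worked_example_tf())
  expect_true(all(c("-0-0", "--1-") %in% pr))
  # every on-set minterm is covered by at least one prime
  f <- worked_example_tf()
  for (m in f$on_set) {
    expect_true(any(vapply(pr, function(cb) m %in% cube_minterms(cb), logical(1))))
  }
})

test_that("prime implicants match brute-force maximal-cube enumeration", {
  set.seed(17)
  for (i in 1:5) {
    f <- random_tf(5)
    expect_setequal(prime_implicants(f),
                    oracle_prime_cubes(f$on_set, f$off_set, 5))
  }
})

test_that("a function true everywhere reduces to the single all-dash cube", {
  f <- truth_function(4, on_set = 0:15, off_set = integer(0))
  expect_equal(prime_implicants(f), "----")
  expect_equal(qm_minimize(f)$cubes, "----")
})

test_that("exact minimization reproduces the worked two-rule reduction", {
  cov <- qm_minimize(worked_example_tf())
  expect_setequal(cov$cubes, c("-0-0", "--1-"))
  f3 <- truth_function(3, on_set = c(3, 7), off_set = setdiff(0:7, c(3, 7)))
  expect_equal(qm_minimize(f3)$cubes, "-11")
  # single minterm, no don't-cares
  f1 <- truth_function(3, on_set = 5, off_set = setdiff(0:7, 5))
  expect_equal(qm_minimize(f1)$cubes, "101")
  # empty on-set
  f0 <- truth_function(3, on_set = integer(0), off_set = 0:7)
  expect_length(qm_minimize(f0)$cubes, 0L)
})

test_that("exact minimization attains the brute-force minimum cover size", {
  set.seed(23)
  confirmed <- 0L
  for (i in 1:40) {
    n <- sample(3:6, 1)
    f <- random_tf(n)
    if (!length(f$on_set)) next
    cov <- qm_minimize(f)
    expect_true(covers_equivalent(cov, f))
    ok <- oracle_confirms_minimum(f$on_set, f$off_set, n, length(cov$cubes))
    if (!is.na(ok)) {
      expect_true(ok)
      confirmed <- confirmed + 1L
    }
  }
  expect_gte(confirmed, 30L)  # the enumeration budget may skip a few
})

test_that("exact minimization is deterministic and refuses oversized inputs", {
  set.seed(29)
  f <- random_tf(6)
  expect_identical(qm_minimize(f)$cubes, qm_minimize(f)$cubes)
  f17 <- truth_function(17, on_set = 0, off_set = 1)
  expect_error(qm_minimize(f17), "espresso")
})

test_that("heuristic minimization finds a two-cube cover of the worked table", {
  f <- worked_example_tf()
  cov <- espresso_minimize(f)
  expect_length(cov$cubes, 2L)
  expect_true(covers_equivalent(cov, f))
})

test_that("heuristic covers are sound, complete, and never beat the exact size", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    f <- random_tf(n)
    if (!length(f$on_set)) next
    esp <- espresso_minimize(f)
    expect_true(covers_equivalent(esp, f))
    # soundness re-checked explicitly against every off minterm
    for (cb in esp$cubes) {
      expect_false(any(cube_minterms(cb) %in% f$off_set))
    }
    qm <- qm_minimize(f)
    expect_gte(length(esp$cubes), length(qm$cubes))
  }
})

test_that("re-minimizing a minimal cover's function is a fixed point in size", {
  # exact minimizer: a provable fixed point (a smaller cover of the realized
  # function would also cover the original on-set)
  set.seed(37)
  for (i in 1:10) {
    f <- random_tf(5)
    if (!length(f$on_set)) next
    qm <- qm_minimize(f)
    realized_on <- sort(unique(unlist(lapply(qm$cubes, cube_minterms))))
    g <- truth_function(5, on_set = realized_on,
                        off_set = setdiff(0:31, realized_on))
    expect_equal(length(qm_minimize(g)$cubes), length(qm$cubes))
    # the heuristic carries no minimality guarantee, but can never beat the
    # exact size
    expect_gte(length(espresso_minimize(g)$cubes), length(qm$cubes))
  }
  # the worked two-rule cover is an espresso fixed point
  realized <- sort(unique(unlist(lapply(c("-0-0", "--1-"), cube_minterms))))
  g <- truth_function(4, on_set = realized, off_set = setdiff(0:15, realized))
  expect_length(espresso_minimize(g)$cubes, 2L)
})

test_that("cover equivalence detects missing and spurious coverage", {
  f <- worked_example_tf()
  expect_true(covers_equivalent(logic_cover(c("-0-0", "--1-"), 4), f))
  expect_false(covers_equivalent(logic_cover(character(0), 4), f))
  expect_false(covers_equivalent(logic_cover("----", 4), f))  # hits the off-set
  expect_error(covers_equivalent(logic_cover("-0-0", 4),
                                 truth_function(3, 0, 1)), "widths differ")
})

test_that("espresso requires an explicit off-set beyond the enumeration guard", {
  f <- truth_function(22, on_set = c(0, 3), off_set = c(1, 2))
  cov <- espresso_minimize(f)
  expect_true(all(nchar(cov$cubes) == 22L))
  f_big <- truth_function(22, on_set = c(0, 3), dc_set = c(5, 6))
  expect_error(espresso_minimize(f_big), "off-set")
  f23 <- truth_function(23, on_set = 0, off_set = 1)
  expect_error(espresso_minimize(f23), "heuristic limit")
})
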