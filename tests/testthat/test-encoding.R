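test_that("DNA one-hot encoding follows the A/C/G/T block layout", {
  expect_equal(encode_dna("A"), c(1L, 0L, 0L, 0L))
  expect_equal(encode_dna("ACGT"),
               c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  win <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
  expect_length(encode_dna(win), 56L)
  expect_error(encode_dna("ACGN"), "position 4")
  # lowercase accepted
  expect_equal(encode_dna("acgt"), encode_dna("ACGT"))
})

test_that("protein encoding uses 21-bit blocks with full-name residue order", {
  v <- encode_protein("AAAAATAAAAA")
  expect_length(v, 231L)
  expect_equal(v[1], 1L)                      # A is rank 1 of block 1
  # T at window position -1 (block 5) sets bit 4*21 + 17 = 101
  w <- encode_protein("AAAATAAAAAA")
  expect_equal(which(w[(4 * 21 + 1):(5 * 21)] == 1L), 17L)
  expect_equal(which(w == 1L)[5], 101L)
  # unknown residue category
  x <- encode_protein("XAAAASAAAAA")
  expect_equal(which(x[1:21] == 1L), 21L)
  expect_error(encode_protein("AAAA"), "expected 11")
  expect_error(encode_protein("AAAAABAAAAA"), "unrecognized residue 'B'")
})

test_that("block sums are exactly one for every window position", {
  set.seed(7)
  for (i in 1:20) {
    dna <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
    m <- matrix(encode_dna(dna), nrow = 4)
    expect_true(all(colSums(m) == 1L))
    aa <- paste(sample(protein_alphabet(), 11, replace = TRUE), collapse = "")
    p <- matrix(encode_protein(aa), nrow = 21)
    expect_true(all(colSums(p) == 1L))
  }
})

test_that("variable meanings reproduce the published DNA variable table", {
  anchors <- list(
    list(26, 7, "C"), list(33, 9, "A"), list(29, 8, "A"), list(40, 10, "T"),
    list(23, 6, "G"), list(39, 10, "G"), list(25, 7, "A"),
    list(1, 1, "A")
  )
  for (a in anchors) {
    m <- variable_meaning(a[[1]], "dna")
    expect_equal(m$window_position, a[[2]])
    expect_equal(m$symbol, a[[3]])
    expect_equal(m$description,
                 sprintf("Nucleotide %d is/is not %s", a[[2]], a[[3]]))
  }
})

test_that("variable meanings reproduce the published protein variable table", {
  anchors <- list(
    list(183, 3, "P"), list(101, -1, "T"), list(143, 1, "T"), list(204, 4, "P"),
    list(99, -1, "P"), list(185, 3, "T"), list(206, 4, "T"), list(163, 2, "S"),
    list(88, -1, "D"), list(36, -4, "P"), list(180, 3, "K"), list(100, -1, "S"),
    list(2, -5, "R"), list(162, 2, "P"), list(227, 5, "T"), list(78, -2, "P"),
    list(142, 1, "S"), list(164, 2, "T"), list(74, -2, "L"), list(148, 2, "A")
  )
  for (a in anchors) {
    m <- variable_meaning(a[[1]], "protein")
    expect_equal(m$window_position, a[[2]])
    expect_equal(m$symbol, a[[3]])
    expect_equal(m$description,
                 sprintf("Amino Acid in Position %d is/is not %s", a[[2]], a[[3]]))
  }
  expect_error(variable_meaning(232, "protein"), "out of range")
})

test_that("variable_index inverts variable_meaning over the whole layout", {
  for (kind in c("dna", "protein")) {
    all_m <- variable_meanings(kind)
    idx <- variable_index(all_m$window_position, all_m$symbol, kind)
    expect_equal(idx, all_m$index)
  }
})

test_that("encoding round-trips: meanings of set bits recover the sequence", {
  set.seed(11)
  for (i in 1:10) {
    win <- paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = "")
    bits <- encode_dna(win)
    m <- variable_meaning(which(bits == 1L), "dna")
    expect_equal(paste(m$symbol[order(m$window_position)], collapse = ""), win)
    aa <- paste(sample(protein_alphabet(), 11, replace = TRUE), collapse = "")
    bits <- encode_protein(aa)
    mp <- variable_meaning(which(bits == 1L), "protein")
    expect_equal(paste(mp$symbol[order(mp$window_position)], collapse = ""), aa)
  }
})

test_that("threshold binarization matches the worked float-table example", {
  # two patterns (.8,.9) and (.7,.8), single threshold .5 -> both become 11,
  # which contradicts labels 1 and 0
  ds <- binarize_continuous(data.frame(A = c(.8, .7), B = c(.9, .8)),
                            thresholds = list(.5, .5), labels = c(1, 0))
  expect_equal(unname(ds$patterns), rbind(c(1L, 1L), c(1L, 1L)))
  cleaned <- clean_dataset(ds, policy = "drop")
  expect_equal(nrow(cleaned$patterns), 0L)
  expect_equal(cleaning_report(cleaned)$action, "contradiction_dropped")
  # moving feature A's threshold to .7 resolves the contradiction
  ds2 <- binarize_continuous(data.frame(A = c(.8, .7), B = c(.9, .8)),
                             thresholds = list(.7, .5), labels = c(1, 0))
  expect_equal(unname(ds2$patterns), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(nrow(clean_dataset(ds2)$patterns), 2L)
})

test_that("multi-threshold binarization yields one-hot interval bits", {
  ds <- binarize_continuous(data.frame(X = c(0.1, 0.5, 0.9)),
                            thresholds = list(c(.25, .75)))
  expect_equal(unname(ds$patterns),
               rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  expect_error(binarize_continuous(data.frame(X = 1), thresholds = list(c(.7, .5))),
               "strictly increasing")
})

test_that("cleaning collapses duplicates with multiplicity and resolves by majority", {
  m <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L), c(1L, 0L), c(0L, 1L))
  ds <- encoded_dataset(m, c(1L, 1L, 1L, 1L, 0L))
  out <- clean_dataset(ds)
  expect_equal(nrow(out$patterns), 2L)
  expect_equal(out$multiplicity[out$labels == 1L], 4L)

  # 2 positives vs 1 negative on the same pattern
  m2 <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L))
  ds2 <- encoded_dataset(m2, c(1L, 1L, 0L))
  expect_equal(nrow(clean_dataset(ds2, "drop")$patterns), 0L)
  maj <- clean_dataset(ds2, "majority")
  expect_equal(maj$labels, 1L)
  expect_equal(maj$multiplicity, 2L)
  # exact ties are removed even under majority
  ds3 <- encoded_dataset(rbind(c(0L, 1L), c(0L, 1L)), c(1L, 0L))
  expect_equal(nrow(clean_dataset(ds3, "majority")$patterns), 0L)
})

test_that("cleaned datasets contain no duplicate or contradictory patterns", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rbinom(60, 1, 0.5), ncol = 4)
    ds <- clean_dataset(encoded_dataset(m, rbinom(15, 1, 0.5)))
    keys <- apply(ds$patterns, 1, paste, collapse = "")
    expect_false(any(duplicated(keys)))
    # identity on an already-clean dataset
    again <- clean_dataset(ds)
    expect_equal(again$patterns, ds$patterns)
    expect_equal(again$labels, ds$labels)
  }
})
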