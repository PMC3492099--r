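test_that("split plans reproduce the 90/10 and balanced protocols", {
  pos <- sample_negative_windows(73, seed = 61)   # any 73 distinct windows
  neg <- sample_negative_windows(400, seed = 62)
  splits <- build_splits(pos, neg, n_replicates = 3, train_fraction = 0.9,
                         seed = 63)
  for (sp in splits) {
    n_train_pos <- sum(sp$train$label == 1)
    expect_true(n_train_pos %in% c(65L, 66L))
    expect_equal(sum(sp$train$label == 0), n_train_pos)
    expect_true(length(sp$test_positives) %in% c(7L, 8L))
    expect_length(intersect(sp$train$sequence[sp$train$label == 1],
                            sp$test_positives), 0L)
  }
  # balanced test sets for the glycosylation protocol
  bal <- build_splits(pos, neg, n_replicates = 2, train_fraction = 0.85,
                      balanced_test = TRUE, seed = 64)
  for (sp in bal) {
    expect_equal(sum(sp$test$label == 1), sum(sp$test$label == 0))
  }
  # 50/50 on ten positives
  s5 <- build_splits(pos[1:10], neg, n_replicates = 1, train_fraction = 0.5,
                     seed = 65)[[1]]
  expect_equal(sum(s5$train$label == 1), 5L)
  expect_length(s5$test_positives, 5L)
  expect_error(build_splits(pos, neg[1:10], seed = 1), "negative pool")
})

test_that("training on the worked truth table recovers the published rules", {
  mod <- train_site_model(worked_example_dataset(), kind = "generic", k = 4)
  expect_setequal(mod$rules$rules$cube, c("-0-0", "--1-"))
  expect_equal(mod$rules$rules$score, c(4, 4))
  expect_equal(mod$rules$method, "quine-mccluskey")
})

test_that("a single positive pattern yields one rule of score one", {
  m <- rbind(c(1L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L), c(0L, 1L, 0L))
  ds <- encoded_dataset(m, c(1L, 0L, 0L, 0L))
  mod <- train_site_model(ds, kind = "generic", k = 3)
  expect_equal(nrow(mod$rules$rules), 1L)
  expect_equal(mod$rules$rules$score, 1)
  expect_true(cube_covers(mod$rules$rules$cube, c(1, 0, 1)))
  # the rule never covers a negative pattern
  for (i in 2:4) expect_false(cube_covers(mod$rules$rules$cube, m[i, ]))
})

test_that("an all-contradictory training set is rejected", {
  m <- rbind(c(1L, 0L), c(1L, 0L))
  ds <- encoded_dataset(m, c(1L, 0L))
  expect_error(train_site_model(ds, kind = "generic", k = 2), "contradictory")
})

test_that("scan output length is window count L - w + 1", {
  rep <- tfbs_replicate(seed = 71, n_sites = 20, bg_len = 3000, k = 8)
  set.seed(72)
  for (L in c(3000, 2117, 14)) {
    seq_i <- substr(rep$sequence, 1, L)
    sc <- scan_sequence(seq_i, rep$model)
    expect_equal(nrow(sc), L - 14 + 1)
    expect_equal(sc$start, seq_len(L - 14 + 1))
  }
  expect_error(scan_sequence("ACGT", rep$model), "shorter than the window")
})

test_that("a lone implanted site scores positive at start 1", {
  rep <- tfbs_replicate(seed = 73, n_sites = 30, bg_len = 5000, k = 8)
  # build a sequence that is exactly one consensus site
  spec <- rep$spec
  chars <- rep("A", 14)
  for (p in names(spec$fixed_positions)) chars[as.integer(p)] <- spec$fixed_positions[[p]]
  site <- paste(chars, collapse = "")
  sc <- scan_sequence(site, rep$model)
  expect_equal(nrow(sc), 1L)
  expect_gt(sc$score[1], 0)
})

test_that("training-set sensitivity is 100% at the all-rules cutoff", {
  rep <- tfbs_replicate(seed = 79, n_sites = 20, bg_len = 3000, k = 8)
  train <- rep$model$training
  pos <- train$patterns[train$labels == 1L, , drop = FALSE]
  sc <- score_patterns(pos, rep$model$rules)
  expect_true(all(apply_cutoff(sc)))
})

test_that("prediction-to-truth matching is greedy one-to-one within tolerance", {
  m <- match_predictions(102, 100, tolerance = 2)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
  m <- match_predictions(103, 100, tolerance = 2)
  expect_equal(c(m$TP, m$FP, m$FN), c(0L, 1L, 1L))
  m <- match_predictions(c(99, 101), 100, tolerance = 2)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 1L, 0L))
  expect_equal(m$matches$pred, 99L)   # nearest-first, lowest position tie-break
  m <- match_predictions(c(100, 103), c(101, 102), tolerance = 2)
  expect_equal(m$TP, 2L)
  m <- match_predictions(integer(0), c(5, 10), tolerance = 2)
  expect_equal(c(m$TP, m$FP, m$FN), c(0L, 0L, 2L))
})

test_that("evaluation reports the published percentage definitions", {
  r <- evaluate_predictions(list(TP = 7, FP = 219, FN = 1))
  expect_equal(r$sensitivity, 87.5)
  expect_equal(r$ppv, 100 * 7 / 226, tolerance = 1e-10)
  expect_equal(evaluate_predictions(list(TP = 0, FP = 3, FN = 5))$sensitivity, 0)
  expect_equal(evaluate_predictions(list(TP = 4, FP = 0, FN = 2))$ppv, 100)
  expect_true(is.na(evaluate_predictions(list(TP = 0, FP = 0, FN = 2))$ppv))
  expect_true(is.na(evaluate_predictions(list(TP = 0, FP = 4, FN = 0))$sensitivity))
})

test_that("S/T window classification pads protein ends with the unknown symbol", {
  gspec <- glyco_spec(n_pos = 60, n_neg = 60)
  train <- generate_glyco_dataset(gspec, seed = 83)
  mod <- train_site_model(train, kind = "glyco", k = 10,
                          minimizer = "espresso", center = "T")
  # no central residue -> empty result
  expect_equal(nrow(classify_st_windows("AAAGGA", mod)), 0L)
  # T at position 3 of a short protein: the +-5 window needs 3 left pad X's
  res <- classify_st_windows("AATAAAAAAA", mod)
  expect_equal(res$position, 3L)
  expect_equal(res$window, "XXXAATAAAAA")
  expect_equal(res$residue, "T")
  # every T with full flanks yields one row
  res2 <- classify_st_windows("AAAAAATAAAAATAAAAAA", mod)
  expect_equal(res2$position, c(7L, 13L))
})

test_that("glyco models recover the planted positional preferences", {
  gspec <- glyco_spec(n_pos = 150, n_neg = 150)
  train <- generate_glyco_dataset(gspec, seed = 89)
  mod <- train_site_model(train, kind = "glyco", k = 14,
                          minimizer = "espresso", center = "T")
  me <- mod$rules$meanings
  lits <- lapply(mod$rules$rules$cube, function(cb) strsplit(cb, "")[[1]])
  # every positive "is T" condition sits at a favored position
  for (ch in lits) {
    t1 <- me$window_position[ch == "1" & me$symbol == "T"]
    expect_true(all(t1 %in% c(-4, -2, 2, 4)))
  }
  # the most popular rule never demands "not T" at a favored position
  t0_top <- me$window_position[lits[[1]] == "0" & me$symbol == "T"]
  expect_true(all(t0_top %in% c(1, 3, 5)))
  # and the leading rules do use a favored "is T" condition
  lead_t1 <- unlist(lapply(lits[1:3], function(ch) {
    me$window_position[ch == "1" & me$symbol == "T"]
  }))
  expect_gt(length(lead_t1), 0)
})

test_that("end-to-end synthetic recovery finds implanted sites", {
  rep <- tfbs_replicate(seed = 97)
  sc <- scan_sequence(rep$sequence, rep$model)
  pred <- sc$start[apply_cutoff(sc$score)]
  m <- match_predictions(pred, rep$heldout_starts, tolerance = 2)
  r <- evaluate_predictions(m)
  expect_gte(r$sensitivity, 50)  # single replicate; the acceptance suite pools 10
  # most rule literals concentrate on the implanted core positions
  lits <- rule_literal_positions(rep$model)
  expect_gt(mean(lits %in% 6:10), 0.5)
})
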