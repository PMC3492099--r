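# End-to-end workflow: build training/test splits, train the digital-rule
# model (encode -> SVM-RFE -> project -> clean -> minimize -> score), scan
# DNA, classify S/T protein windows, and evaluate predictions.

#' Build seeded train/test splits
#'
#' Each replicate trains on a random `train_fraction` of the positive
#' windows plus an equal number of negatives sampled (without replacement)
#' from the pool; the remaining positives are held out for testing. With
#' `balanced_test = TRUE` an equal number of unused negatives is held out
#' too (the glycosylation protocol); otherwise the held-out positives are
#' meant to be implanted into background sequence (the binding-site
#' protocol).
#'
#' @param positives Character vector of positive windows.
#' @param negatives Character vector (pool) of negative windows.
#' @param n_replicates Number of splits.
#' @param train_fraction Fraction of positives used for training (0 < f < 1).
#' @param balanced_test Hold out negatives to balance the test set?
#' @param seed Optional integer seed.
#' @return A list of replicates, each a list with `train` (tibble
#'   `sequence`, `label`, `id`), `test_positives`, and `test` (balanced
#'   tibble, or `NULL`).
#' @export
build_splits <- function(positives, negatives, n_replicates = 10L,
                         train_fraction = 0.9, balanced_test = FALSE,
                         seed = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  P <- length(positives)
  n_train_pos <- ceiling(train_fraction * P)
  n_test_pos <- P - n_train_pos
  need_neg <- n_train_pos + if (balanced_test) n_test_pos else 0L
  if (length(negatives) < need_neg) {
    abort(sprintf("negative pool has %d windows; %d needed", length(negatives), need_neg))
  }
  lapply(seq_len(n_replicates), function(r) {
    pos_idx <- sample.int(P, n_train_pos)
    neg_idx <- sample.int(length(negatives), need_neg)
    train <- tibble(
      sequence = c(positives[pos_idx], negatives[neg_idx[seq_len(n_train_pos)]]),
      label = rep(c(1L, 0L), c(n_train_pos, n_train_pos)),
      id = c(paste0("pos", pos_idx), paste0("neg", neg_idx[seq_len(n_train_pos)]))
    )
    test_pos <- positives[setdiff(seq_len(P), pos_idx)]
    test <- NULL
    if (balanced_test) {
      tn <- negatives[neg_idx[n_train_pos + seq_len(n_test_pos)]]
      test <- tibble(sequence = c(test_pos, tn),
                     label = rep(c(1L, 0L), c(length(test_pos), length(tn))))
    }
    list(train = train, test_positives = test_pos, test = test)
  })
}

#' Train a digital-rule site model
#'
#' Runs the full rule-extraction pipeline on a labeled training set:
#' one-hot encode the windows, rank variables by SVM-RFE and keep the top
#' `k`, project the dataset onto them, collapse duplicates and remove
#' contradictions, build the partially-specified boolean function (every
#' unseen reduced pattern is a don't-care), minimize it (exactly up to
#' `exact_limit` variables, otherwise with the ESPRESSO-style heuristic),
#' and score the resulting rules by training popularity.
#'
#' @param train A data frame with columns `sequence` and `label`, or a
#'   pre-encoded [encoded_dataset()].
#' @param kind `"tfbs"` (14-nt DNA windows), `"glyco"` (11-residue protein
#'   windows), or `"generic"` (pre-encoded input).
#' @param k Number of top variables to keep (default 22, the practical
#'   width limit of the heuristic minimizer).
#' @param cost SVM soft-margin penalty.
#' @param policy Contradiction policy for [clean_dataset()].
#' @param cutoff Default [score cutoff][cutoff_all_rules] stored with the
#'   model.
#' @param exact_limit,heuristic_limit Width limits for the two minimizers.
#' @param minimizer `"auto"` (exact iff `k <= exact_limit`), `"exact"`, or
#'   `"espresso"`.
#' @param center Central residue for glycosylation models (`"S"` or `"T"`).
#' @return An object of class `site_model`.
#' @export
train_site_model <- function(train, kind = c("tfbs", "glyco", "generic"),
                             k = 22L, cost = 1,
                             policy = c("drop", "majority"),
                             cutoff = cutoff_all_rules(),
                             exact_limit = 16L, heuristic_limit = 22L,
                             minimizer = c("auto", "exact", "espresso"),
                             center = "T") {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  minimizer <- match.arg(minimizer)
  if (inherits(train, "encoded_dataset")) {
    ds <- train
    window <- NA_integer_
  } else {
    stopifnot(is.data.frame(train), all(c("sequence", "label") %in% names(train)))
    if (!any(train$label == 1L) || !any(train$label == 0L)) {
      abort("training set must contain both classes")
    }
    enc_kind <- if (kind == "glyco") "protein" else "dna"
    ds <- encode_dataset(train, kind = enc_kind)
    window <- nchar(train$sequence[1])
  }
  k <- min(as.integer(k), ncol(ds$patterns))
  ranking <- rfe_rank(ds, k = k, cost = cost)
  proj <- project_dataset(ds, ranking)
  clean <- clean_dataset(proj, policy = policy)
  if (!any(clean$labels == 1L)) {
    abort("no positive patterns survive cleaning; the training set is contradictory")
  }
  n <- ncol(clean$patterns)
  w <- bit_weights(n)
  minterms <- as.integer(clean$patterns %*% w)
  f <- truth_function(n,
                      on_set = minterms[clean$labels == 1L],
                      off_set = minterms[clean$labels == 0L])
  use_exact <- switch(minimizer, auto = n <= exact_limit,
                      exact = TRUE, espresso = FALSE)
  cover <- if (use_exact) {
    qm_minimize(f, exact_limit = exact_limit)
  } else {
    # on ties, prefer keeping the literals the SVM ranked as informative
    col_rank <- match(sort(ranking$selected), ranking$selected)
    espresso_minimize(f, heuristic_limit = heuristic_limit,
                      keep_order = order(col_rank))
  }
  rules <- score_rules(cover, clean)
  structure(
    list(kind = kind, window = window, k = k, ranking = ranking,
         rules = rules, cutoff = cutoff, policy = policy,
         center = center, cost = cost,
         training = clean, truth = f),
    class = "site_model"
  )
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("<site_model> kind = %s, window = %s, %d selected variables, %d rule(s)\n",
              x$kind, x$window, x$k, nrow(x$rules$rules)))
  print(select(x$rules$rules, "cube", "score"), n = 10)
  invisible(x)
}

#' @method tidy site_model
#' @export
tidy.site_model <- function(x, ...) tidy(x$rules)

#' @method glance site_model
#' @export
glance.site_model <- function(x, ...) {
  tibble(kind = x$kind, window = x$window, k = x$k,
         n_rules = nrow(x$rules$rules),
         n_train_patterns = nrow(x$training$patterns),
         method = x$rules$method)
}

# score already-extracted windows under a model (encode + project + score)
score_windows <- function(model, windows) {
  enc_kind <- if (model$kind == "glyco") "protein" else "dna"
  ds <- encode_dataset(tibble(sequence = windows, label = 0L), kind = enc_kind)
  proj <- project_dataset(ds, model$ranking)
  score_patterns(proj, model$rules)
}

#' Predict labels for sequence windows
#'
#' @param object A `site_model`.
#' @param newdata Character vector of windows, or a data frame with a
#'   `sequence` column.
#' @param cutoff Score cutoff (defaults to the one stored in the model).
#' @param ... Unused.
#' @return A tibble with `sequence`, `score`, `n_rules_hit`, `positive`.
#' @export
predict.site_model <- function(object, newdata, cutoff = NULL, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$sequence
  sc <- score_windows(object, newdata)
  sc$sequence <- newdata
  sc$positive <- apply_cutoff(sc, cutoff %||% object$cutoff)
  select(sc, "sequence", "score", "n_rules_hit", "positive")
}

#' Scan a DNA sequence for binding sites
#'
#' Slides the model's window one nucleotide at a time along the forward
#' strand and scores every start position against the rule set, producing
#' `L - w + 1` scores for a sequence of length `L`.
#'
#' @param dna A DNA string (length >= the model window).
#' @param model A `site_model` of kind `"tfbs"`.
#' @return A tibble of class `scan_scores` with columns `start` (1-based),
#'   `score`, `n_rules_hit`.
#' @export
scan_sequence <- function(dna, model) {
  stopifnot(inherits(model, "site_model"))
  w <- model$window
  L <- nchar(dna)
  if (L < w) abort(sprintf("sequence length %d is shorter than the window (%d)", L, w))
  chars <- strsplit(toupper(dna), "")[[1]]
  n_starts <- L - w + 1L
  sel <- sort(model$ranking$selected)
  slot <- (sel - 1L) %/% 4L + 1L
  sym <- dna_alphabet()[sel - (slot - 1L) * 4L]
  m <- matrix(0L, nrow = n_starts, ncol = length(sel))
  for (j in seq_along(sel)) {
    m[, j] <- as.integer(chars[seq_len(n_starts) + slot[j] - 1L] == sym[j])
  }
  sc <- score_patterns(m, model$rules)
  out <- tibble(start = seq_len(n_starts), score = sc$score,
                n_rules_hit = sc$n_rules_hit)
  class(out) <- c("scan_scores", class(out))
  out
}

#' Classify S/T-centered protein windows
#'
#' Only serine or threonine residues can be O-glycosylated, so prediction
#' walks the protein and scores an 11-residue window centered on every
#' occurrence of the model's central residue. Windows truncated by the
#' protein ends are padded with the unknown symbol `X`.
#'
#' @param protein A protein string.
#' @param model A `site_model` of kind `"glyco"`.
#' @param cutoff Score cutoff (defaults to the model's).
#' @return A tibble with `position`, `residue`, `window`, `score`,
#'   `n_rules_hit`, `positive`.
#' @export
classify_st_windows <- function(protein, model, cutoff = NULL) {
  stopifnot(inherits(model, "site_model"), model$kind == "glyco")
  chars <- strsplit(toupper(protein), "")[[1]]
  centers <- which(chars == model$center)
  if (!length(centers)) {
    return(tibble(position = integer(0), residue = character(0),
                  window = character(0), score = numeric(0),
                  n_rules_hit = integer(0), positive = logical(0)))
  }
  flank <- (model$window - 1L) %/% 2L
  padded <- c(rep("X", flank), chars, rep("X", flank))
  windows <- vapply(centers, function(i) {
    paste(padded[i:(i + 2L * flank)], collapse = "")
  }, character(1))
  sc <- score_windows(model, windows)
  tibble(position = centers, residue = chars[centers], window = windows,
         score = sc$score, n_rules_hit = sc$n_rules_hit,
         positive = apply_cutoff(sc, cutoff %||% model$cutoff))
}

#' Match predicted starts to true starts within a tolerance
#'
#' Greedy one-to-one matching, nearest pair first (ties broken by the
#' lowest predicted, then true, position): each true start is matched to at
#' most one prediction with `|pred - true| <= tolerance`. Matched pairs
#' count as TP, unmatched truths as FN, unmatched predictions as FP.
#'
#' @param pred_starts Integer vector of predicted start positions.
#' @param true_starts Integer vector of true start positions.
#' @param tolerance Maximum distance (nt) for a correct prediction.
#' @return A list with `TP`, `FP`, `FN`, and `matches` (tibble `pred`,
#'   `truth`, `distance`).
#' @export
match_predictions <- function(pred_starts, true_starts, tolerance = 2L) {
  stopifnot(tolerance >= 0)
  pred_starts <- as.integer(pred_starts)
  true_starts <- as.integer(true_starts)
  pairs <- tidyr::expand_grid(pred = pred_starts, truth = true_starts) %>%
    mutate(distance = abs(.data$pred - .data$truth)) %>%
    filter(.data$distance <= tolerance) %>%
    arrange(.data$distance, .data$pred, .data$truth)
  used_pred <- character(0); used_truth <- character(0)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- as.character(pairs$pred[i]); t <- as.character(pairs$truth[i])
    if (!(p %in% used_pred) && !(t %in% used_truth)) {
      keep[i] <- TRUE
      used_pred <- c(used_pred, p); used_truth <- c(used_truth, t)
    }
  }
  matches <- pairs[keep, ]
  list(TP = nrow(matches),
       FP = length(pred_starts) - nrow(matches),
       FN = length(true_starts) - nrow(matches),
       matches = matches)
}

#' Sensitivity and positive predictive value from match counts
#'
#' Sensitivity is the percentage of true sites recovered,
#' `100 * TP / (TP + FN)`; PPV is the percentage of positive predictions
#' that are correct, `100 * TP / (TP + FP)`. A ratio whose denominator is
#' zero is reported as `NA` (not applicable), never as 0.
#'
#' @param counts A list with `TP`, `FP`, `FN` (e.g. from
#'   [match_predictions()]), or the TP count if `fp`/`fn` are given.
#' @param fp,fn Optional explicit counts.
#' @return A one-row tibble: `TP`, `FP`, `FN`, `sensitivity`, `ppv`
#'   (percent).
#' @export
evaluate_predictions <- function(counts, fp = NULL, fn = NULL) {
  if (is.list(counts)) {
    tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  } else {
    tp <- counts
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  tibble(
    TP = tp, FP = fp, FN = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  )
}
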