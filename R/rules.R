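# Rule popularity scoring and score-based prediction cutoffs.

#' Score minimized rules by training-set popularity
#'
#' The score of a rule is the number of positive training patterns the rule
#' covers, counting the multiplicity recorded when duplicates were
#' collapsed. Popular rules describe many training examples; a test pattern
#' matched by popular (or many) rules is more likely a true positive.
#'
#' @param cover A `logic_cover` over the same variables as `training`.
#' @param training An [encoded_dataset()] (typically cleaned and projected).
#' @return An object of class `scored_rules`: a rule table sorted by
#'   descending score (ties by cube string), the variable meanings, and the
#'   cube width.
#' @export
score_rules <- function(cover, training) {
  stopifnot(inherits(cover, "logic_cover"), inherits(training, "encoded_dataset"))
  if (cover$n_vars != ncol(training$patterns)) {
    abort("cover width does not match dataset width")
  }
  pos <- training$labels == 1L
  mat <- training$patterns[pos, , drop = FALSE]
  mult <- training$multiplicity[pos]
  prov <- training$provenance[pos]
  rules <- tibble(
    cube = cover$cubes,
    score = vapply(cover$cubes, function(cb) {
      sum(mult[cube_covers_rows(cb, mat)])
    }, numeric(1), USE.NAMES = FALSE),
    covered = lapply(cover$cubes, function(cb) prov[cube_covers_rows(cb, mat)])
  ) %>%
    arrange(desc(.data$score), .data$cube)
  if (any(rules$score == 0)) {
    warn(sprintf("%d rule(s) cover no positive training pattern", sum(rules$score == 0)))
  }
  structure(
    list(rules = rules, n_vars = cover$n_vars, meanings = training$meanings,
         method = cover$method),
    class = "scored_rules"
  )
}

#' @export
print.scored_rules <- function(x, ...) {
  cat(sprintf("<scored_rules> %d rule(s) over %d variables\n",
              nrow(x$rules), x$n_vars))
  print(select(x$rules, "cube", "score"), n = 20)
  invisible(x)
}

#' @method tidy scored_rules
#' @export
tidy.scored_rules <- function(x, ...) {
  mutate(select(x$rules, "cube", "score"),
         conditions = render_conditions(.data$cube, x$meanings))
}

#' @method glance scored_rules
#' @export
glance.scored_rules <- function(x, ...) {
  tibble(n_rules = nrow(x$rules), n_vars = x$n_vars,
         total_score = sum(x$rules$score), method = x$method)
}

#' Score test patterns against a scored rule set
#'
#' Each pattern receives the sum of the scores of the rules it satisfies
#' (0 when it satisfies none, in which case the implicit negative rule
#' applies).
#'
#' @param patterns A 0/1 matrix, an [encoded_dataset()], or a character
#'   vector of 0/1 pattern strings.
#' @param rules A `scored_rules` object.
#' @return A tibble with columns `id`, `score`, `n_rules_hit`.
#' @export
score_patterns <- function(patterns, rules) {
  stopifnot(inherits(rules, "scored_rules"))
  ids <- NULL
  if (inherits(patterns, "encoded_dataset")) {
    ids <- patterns$provenance
    patterns <- patterns$patterns
  } else if (is.character(patterns)) {
    patterns <- do.call(rbind, lapply(strsplit(patterns, ""), as.integer))
  }
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != rules$n_vars) abort("pattern width does not match rules")
  score <- numeric(nrow(patterns))
  hits <- integer(nrow(patterns))
  for (i in seq_len(nrow(rules$rules))) {
    hit <- cube_covers_rows(rules$rules$cube[i], patterns)
    score[hit] <- score[hit] + rules$rules$score[i]
    hits[hit] <- hits[hit] + 1L
  }
  tibble(id = ids %||% as.character(seq_len(nrow(patterns))),
         score = score, n_rules_hit = hits)
}

#' Prediction cutoffs over pattern scores
#'
#' Three ways to turn scores into positive predictions:
#' * `cutoff_all_rules()` - positive iff the pattern satisfies at least one
#'   rule (score >= 1); maximal sensitivity.
#' * `cutoff_top_fraction(f)` - keep the top fraction `f` of the patterns
#'   that satisfy at least one rule; boundary ties are all kept. Raising
#'   the bar this way trades sensitivity for precision.
#' * `cutoff_min_score(s)` - positive iff score >= `s` (e.g. the combined
#'   score of the two most popular rules, to demand that both fire).
#'
#' @param f Fraction in (0, 1].
#' @param s Minimum score, >= 1.
#' @return A `score_cutoff` specification for [apply_cutoff()].
#' @export
cutoff_all_rules <- function() {
  structure(list(type = "all_rules"), class = "score_cutoff")
}

#' @rdname cutoff_all_rules
#' @export
cutoff_top_fraction <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f > 1) {
    abort("f must lie in (0, 1]")
  }
  structure(list(type = "top_fraction", f = f), class = "score_cutoff")
}

#' @rdname cutoff_all_rules
#' @export
cutoff_min_score <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || s < 1) abort("s must be >= 1")
  structure(list(type = "min_score", s = s), class = "score_cutoff")
}

#' Apply a cutoff to pattern scores
#'
#' @param scores Numeric scores, or the tibble returned by
#'   [score_patterns()].
#' @param cutoff A `score_cutoff` (default: every rule-satisfying pattern
#'   is positive).
#' @return Logical vector of positive predictions.
#' @export
apply_cutoff <- function(scores, cutoff = cutoff_all_rules()) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(inherits(cutoff, "score_cutoff"))
  threshold <- switch(
    cutoff$type,
    all_rules = 1,
    min_score = cutoff$s,
    top_fraction = {
      pos <- scores[scores > 0]
      if (!length(pos)) Inf
      else sort(pos, decreasing = TRUE)[ceiling(cutoff$f * length(pos))]
    }
  )
  scores >= threshold
}
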