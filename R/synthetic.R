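# Seeded synthetic datasets with the statistical structure of the two case
# studies: motif-implanted background DNA (a stand-in for experimentally
# verified binding sites inserted in genomic sequence) and 11-residue S/T
# protein windows with positional residue preferences (a stand-in for
# curated O-glycosylation windows).

#' Specification of a synthetic DNA motif
#'
#' A 14-nt window with a conserved core: `fixed_positions` names the
#' consensus nucleotide at each conserved position; every other position is
#' drawn from the background composition. Each conserved position is
#' substituted with a random other base at rate `mutation_rate`, emulating
#' the variability seen across real binding sites. The default core fixes
#' positions 6-10, echoing the central window positions that dominate
#' trained binding-site rules.
#'
#' @param length Window length (default 14).
#' @param fixed_positions Named character vector, names = positions,
#'   values = consensus nucleotides.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param background Composition over A, C, G, T (sums to 1).
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(length = 14L,
                       fixed_positions = c(`6` = "G", `7` = "C", `8` = "A",
                                           `9` = "A", `10` = "T"),
                       mutation_rate = 0.05,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  pos <- as.integer(names(fixed_positions))
  stopifnot(all(pos >= 1L & pos <= length),
            all(toupper(fixed_positions) %in% dna_alphabet()),
            mutation_rate >= 0, mutation_rate <= 1,
            length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-8)
  structure(list(length = as.integer(length),
                 fixed_positions = stats::setNames(toupper(as.character(fixed_positions)),
                                                   pos),
                 mutation_rate = mutation_rate,
                 background = stats::setNames(as.numeric(background), dna_alphabet())),
            class = "motif_spec")
}

#' Generate background DNA
#'
#' i.i.d. nucleotides from a given composition; reproducible under a fixed
#' seed.
#'
#' @param length Sequence length.
#' @param composition Probabilities for A, C, G, T.
#' @param seed Optional integer seed.
#' @return A single DNA string with attribute `seed`.
#' @export
generate_background_dna <- function(length,
                                    composition = c(0.25, 0.25, 0.25, 0.25),
                                    seed = NULL) {
  stopifnot(length > 0, length(composition) == 4L, all(composition >= 0),
            sum(composition) > 0)
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(dna_alphabet(), length, replace = TRUE,
                      prob = composition / sum(composition)), collapse = "")
  attr(seq, "seed") <- seed
  seq
}

sample_motif_instance <- function(spec) {
  chars <- sample(dna_alphabet(), spec$length, replace = TRUE,
                  prob = spec$background)
  for (p in names(spec$fixed_positions)) {
    i <- as.integer(p)
    base <- spec$fixed_positions[[p]]
    if (stats::runif(1) < spec$mutation_rate) {
      chars[i] <- sample(setdiff(dna_alphabet(), base), 1)
    } else {
      chars[i] <- base
    }
  }
  paste(chars, collapse = "")
}

#' Implant motif instances into a background sequence
#'
#' Writes `n_sites` non-overlapping motif instances (sampled from `spec`)
#' into the background at uniformly random positions separated by at least
#' `min_gap` nucleotides, and returns the modified sequence together with
#' the sorted true start positions (1-based).
#'
#' @param background A DNA string.
#' @param spec A [motif_spec()].
#' @param n_sites Number of instances to implant.
#' @param min_gap Minimum distance between the end of one site and the
#'   start of the next.
#' @param seed Optional integer seed.
#' @return A list with elements `sequence`, `true_starts`, and `sites`
#'   (the implanted window strings).
#' @export
implant_motifs <- function(background, spec, n_sites, min_gap = 10L, seed = NULL) {
  stopifnot(inherits(spec, "motif_spec"), n_sites >= 0)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(background)
  w <- spec$length
  if (n_sites == 0L) {
    return(list(sequence = background, true_starts = integer(0),
                sites = character(0)))
  }
  m <- L - w + 1L - (n_sites - 1L) * (w + min_gap)
  if (m < n_sites) {
    abort(sprintf("cannot pack %d sites of width %d with gap %d into %d nt",
                  n_sites, w, min_gap, L))
  }
  u <- sort(sample.int(m, n_sites))
  starts <- u + (seq_len(n_sites) - 1L) * (w + min_gap)
  chars <- strsplit(background, "")[[1]]
  sites <- character(n_sites)
  for (i in seq_len(n_sites)) {
    site <- sample_motif_instance(spec)
    sites[i] <- site
    chars[starts[i]:(starts[i] + w - 1L)] <- strsplit(site, "")[[1]]
  }
  list(sequence = paste(chars, collapse = ""), true_starts = starts,
       sites = sites)
}

#' Specification of a synthetic glycosylation-window dataset
#'
#' 11-residue windows centered on a fixed S or T. Positive windows draw
#' each flanking residue with probability proportional to a positional
#' preference weight; negative windows draw residues uniformly. The
#' default weights echo the flavor of the most popular learned rule for T
#' sites: threonine strongly favored at positions -4, -2, +2 and +4 and
#' disfavored at +1, +3 and +5.
#'
#' @param center `"T"` or `"S"`: the residue every window is centered on.
#' @param n_pos,n_neg Numbers of positive and negative windows.
#' @param weights Optional 20 x 10 matrix of positive preference weights,
#'   rows named by the standard residues, columns by positions
#'   `-5..-1, 1..5`. Defaults to uniform with the T adjustments above.
#' @param unknown_rate Probability that a flanking residue is replaced by
#'   the unknown symbol `X` (emulating truncated windows).
#' @return A `glyco_spec` object.
#' @export
glyco_spec <- function(center = c("T", "S"), n_pos = 300L, n_neg = 300L,
                       weights = NULL, unknown_rate = 0) {
  center <- match.arg(center)
  residues <- setdiff(protein_alphabet(), "X")
  positions <- c(-5:-1, 1:5)
  if (is.null(weights)) {
    weights <- matrix(1, nrow = length(residues), ncol = length(positions),
                      dimnames = list(residues, positions))
    weights[center, as.character(c(-4, -2, 2, 4))] <- 12
    weights[center, as.character(c(1, 3, 5))] <- 0.05
  }
  stopifnot(nrow(weights) == 20L, ncol(weights) == 10L, all(weights > 0),
            n_pos > 0, n_neg > 0, unknown_rate >= 0, unknown_rate <= 1)
  dimnames(weights) <- list(residues, positions)
  structure(list(center = center, n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), weights = weights,
                 unknown_rate = unknown_rate),
            class = "glyco_spec")
}

#' Generate a labeled glycosylation-style window dataset
#'
#' @param spec A [glyco_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `id`, `sequence` (11 residues, center
#'   fixed to the spec's S/T), `label` (1 = positive).
#' @export
generate_glyco_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "glyco_spec"))
  if (!is.null(seed)) set.seed(seed)
  residues <- rownames(spec$weights)
  draw_window <- function(positive) {
    flank <- vapply(seq_len(ncol(spec$weights)), function(j) {
      if (positive) sample(residues, 1, prob = spec$weights[, j])
      else sample(residues, 1)
    }, character(1))
    if (spec$unknown_rate > 0) {
      mask <- stats::runif(length(flank)) < spec$unknown_rate
      flank[mask] <- "X"
    }
    paste0(paste(flank[1:5], collapse = ""), spec$center,
           paste(flank[6:10], collapse = ""))
  }
  n <- spec$n_pos + spec$n_neg
  tibble(
    id = sprintf("win%04d", seq_len(n)),
    sequence = c(vapply(seq_len(spec$n_pos), function(i) draw_window(TRUE), character(1)),
                 vapply(seq_len(spec$n_neg), function(i) draw_window(FALSE), character(1))),
    label = rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  )
}

#' Sample random 14-nt background windows as negative examples
#'
#' @param n Number of windows.
#' @param width Window width (default 14).
#' @param composition Probabilities for A, C, G, T.
#' @param seed Optional integer seed.
#' @return Character vector of DNA windows.
#' @export
sample_negative_windows <- function(n, width = 14L,
                                    composition = c(0.25, 0.25, 0.25, 0.25),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(dna_alphabet(), width, replace = TRUE,
                 prob = composition / sum(composition)), collapse = "")
  }, character(1))
}
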