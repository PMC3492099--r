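#' Alphabets used by the one-hot encoders
#'
#' DNA uses the four nucleotides in A, C, G, T order. Protein uses the 20
#' standard residues ranked by the alphabetical order of their full names
#' (Ala, Arg, Asn, Asp, Cys, Gln, Glu, Gly, His, Ile, Leu, Lys, Met, Phe,
#' Pro, Ser, Thr, Trp, Tyr, Val), with `X` ("unknown", used for truncated
#' windows and non-standard residues) at rank 21.
#'
#' @return Character vector of one-letter symbols, in encoding rank order.
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' @rdname dna_alphabet
#' @export
protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

alphabet_for <- function(kind) {
  switch(kind, dna = dna_alphabet(), protein = protein_alphabet(),
         abort(paste0("unknown sequence kind: ", kind)))
}

#' One-hot encode a DNA sequence
#'
#' Each nucleotide becomes a 4-bit block with exactly one bit set:
#' A = 1000, C = 0100, G = 0010, T = 0001. A 14-nt window therefore
#' becomes 56 binary variables whose meanings stay directly readable
#' ("Nucleotide 7 is/is not C").
#'
#' @param seq A single DNA string over A/C/G/T (case-insensitive).
#' @return Integer vector of 0/1 bits, length `4 * nchar(seq)`.
#' @examples
#' encode_dna("ACGT")
#' @export
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "")[[1]]
  ranks <- match(chars, dna_alphabet())
  if (anyNA(ranks)) {
    bad <- which(is.na(ranks))[1]
    abort(sprintf("non-ACGT character '%s' at position %d", chars[bad], bad))
  }
  one_hot_bits(ranks, 4L)
}

#' One-hot encode a protein window
#'
#' Each residue becomes a 21-bit block: the 20 standard amino acids in
#' full-name alphabetical order plus an "unknown" category (`X`) at rank 21.
#' An 11-residue window becomes 231 binary variables.
#'
#' @param window A single residue string; characters must be standard
#'   one-letter codes or `X`.
#' @param width Expected window length (default 11); use `NA` to accept any.
#' @return Integer vector of 0/1 bits, length `21 * nchar(window)`.
#' @examples
#' length(encode_protein("AAAAATAAAAA"))
#' @export
encode_protein <- function(window, width = 11L) {
  stopifnot(is.character(window), length(window) == 1L)
  chars <- strsplit(toupper(window), "")[[1]]
  if (!is.na(width) && length(chars) != width) {
    abort(sprintf("window has %d residues; expected %d", length(chars), width))
  }
  ranks <- match(chars, protein_alphabet())
  if (anyNA(ranks)) {
    bad <- which(is.na(ranks))[1]
    abort(sprintf("unrecognized residue '%s' at position %d", chars[bad], bad))
  }
  one_hot_bits(ranks, 21L)
}

one_hot_bits <- function(ranks, block) {
  bits <- integer(block * length(ranks))
  bits[(seq_along(ranks) - 1L) * block + ranks] <- 1L
  bits
}

decode_bits <- function(bits, kind) {
  ab <- alphabet_for(kind)
  block <- length(ab)
  stopifnot(length(bits) %% block == 0L)
  m <- matrix(bits, nrow = block)
  paste(ab[apply(m, 2, function(b) which(b == 1L))], collapse = "")
}

window_position <- function(block, kind, window) {
  if (kind == "dna") block else block - (window + 1L) %/% 2L
}

#' Human-readable meaning of an encoded binary variable
#'
#' Inverts the one-hot layout: variable `index` corresponds to window slot
#' `ceiling(index / block)` and symbol rank `index - (slot - 1) * block`,
#' where the block size is 4 for DNA and 21 for protein. Protein window
#' positions are numbered relative to the central residue (-5..+5 for an
#' 11-residue window); DNA positions are 1-based.
#'
#' @param index Integer vector of 1-based variable indices.
#' @param kind `"dna"` or `"protein"`.
#' @param window Window length in residues/nucleotides (14 for DNA TFBS
#'   windows, 11 for protein glycosylation windows).
#' @return A tibble with columns `index`, `window_position`, `symbol`,
#'   `description`.
#' @examples
#' variable_meaning(26, "dna")
#' variable_meaning(101, "protein")
#' @export
variable_meaning <- function(index, kind = c("dna", "protein"),
                             window = if (kind == "dna") 14L else 11L) {
  kind <- match.arg(kind)
  ab <- alphabet_for(kind)
  block <- length(ab)
  index <- as.integer(index)
  if (any(index < 1L | index > block * window)) {
    abort(sprintf("variable index out of range 1..%d", block * window))
  }
  slot <- (index - 1L) %/% block + 1L
  rank <- index - (slot - 1L) * block
  pos <- window_position(slot, kind, window)
  noun <- if (kind == "dna") "Nucleotide" else "Amino Acid in Position"
  tibble(
    index = index,
    window_position = pos,
    symbol = ab[rank],
    description = sprintf("%s %d is/is not %s", noun, pos, ab[rank])
  )
}

#' Meanings for every variable of a window encoding
#'
#' @inheritParams variable_meaning
#' @return A tibble with one row per binary variable, in variable order.
#' @export
variable_meanings <- function(kind = c("dna", "protein"),
                              window = if (kind == "dna") 14L else 11L) {
  kind <- match.arg(kind)
  variable_meaning(seq_len(length(alphabet_for(kind)) * window), kind, window)
}

#' Variable index for a window position and symbol
#'
#' The inverse of [variable_meaning()]: `index = (slot - 1) * block + rank`.
#'
#' @param position Window position (1-based for DNA; -5..+5 style for protein).
#' @param symbol One-letter nucleotide or residue symbol.
#' @inheritParams variable_meaning
#' @return Integer variable index.
#' @export
variable_index <- function(position, symbol, kind = c("dna", "protein"),
                           window = if (kind == "dna") 14L else 11L) {
  kind <- match.arg(kind)
  ab <- alphabet_for(kind)
  block <- length(ab)
  slot <- if (kind == "dna") position else position + (window + 1L) %/% 2L
  rank <- match(toupper(symbol), ab)
  if (anyNA(rank)) abort("unknown symbol for this alphabet")
  if (any(slot < 1L | slot > window)) abort("position outside the window")
  as.integer((slot - 1L) * block + rank)
}

# ---- encoded datasets -------------------------------------------------------

#' Construct an encoded (binary) dataset
#'
#' The container carried through the whole pipeline: a 0/1 pattern matrix,
#' class labels, the per-variable meanings, a per-pattern multiplicity
#' (used by rule scoring after duplicates are collapsed), and a provenance
#' id per pattern.
#'
#' @param patterns Integer 0/1 matrix, one row per pattern.
#' @param labels Integer vector of 0/1 class labels, one per row.
#' @param meanings Tibble as returned by [variable_meanings()], one row per
#'   column of `patterns` (may be `NULL` for anonymous variables).
#' @param multiplicity Integer vector of occurrence counts (default all 1).
#' @param provenance Character vector of per-pattern source ids.
#' @return An object of class `encoded_dataset`.
#' @export
encoded_dataset <- function(patterns, labels, meanings = NULL,
                            multiplicity = NULL, provenance = NULL) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  labels <- as.integer(labels)
  stopifnot(nrow(patterns) == length(labels),
            all(patterns %in% c(0L, 1L)),
            all(labels %in% c(0L, 1L)))
  if (is.null(multiplicity)) multiplicity <- rep(1L, nrow(patterns))
  if (is.null(provenance)) provenance <- as.character(seq_len(nrow(patterns)))
  if (is.null(meanings)) {
    meanings <- tibble(index = seq_len(ncol(patterns)),
                       window_position = NA_integer_,
                       symbol = NA_character_,
                       description = paste0("Variable ", seq_len(ncol(patterns))))
  }
  stopifnot(nrow(meanings) == ncol(patterns),
            length(multiplicity) == nrow(patterns),
            length(provenance) == nrow(patterns))
  structure(
    list(patterns = patterns, labels = labels, meanings = as_tibble(meanings),
         multiplicity = as.integer(multiplicity),
         provenance = as.character(provenance)),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset> %d patterns x %d variables (%d positive, %d negative)\n",
              nrow(x$patterns), ncol(x$patterns),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  rep <- attr(x, "cleaning_report")
  if (!is.null(rep) && nrow(rep) > 0) {
    cat(sprintf("  cleaned: %d pattern groups merged/removed (see cleaning_report())\n",
                nrow(rep)))
  }
  invisible(x)
}

#' @method tidy encoded_dataset
#' @export
tidy.encoded_dataset <- function(x, ...) {
  tibble(pattern = pattern_strings(x$patterns),
         label = x$labels,
         multiplicity = x$multiplicity,
         provenance = x$provenance)
}

pattern_strings <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1, paste, collapse = "")
}

#' Encode labeled sequence windows into a binary dataset
#'
#' @param data A data frame with columns `sequence` and `label` (0/1); an
#'   optional `id` column provides provenance ids.
#' @param kind `"dna"` (4-bit blocks) or `"protein"` (21-bit blocks).
#' @return An [encoded_dataset()].
#' @examples
#' encode_dataset(
#'   tibble::tibble(sequence = c("ACGTACGTACGTAC", "TTTTTTTTTTTTTT"),
#'                  label = c(1, 0)), kind = "dna")
#' @export
encode_dataset <- function(data, kind = c("dna", "protein")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(data), all(c("sequence", "label") %in% names(data)))
  seqs <- toupper(data$sequence)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) abort("all sequences must share one length")
  window <- widths[1]
  enc <- if (kind == "dna") encode_dna else function(s) encode_protein(s, window)
  patterns <- do.call(rbind, lapply(seqs, enc))
  prov <- if ("id" %in% names(data)) as.character(data$id) else NULL
  encoded_dataset(patterns, data$label,
                  meanings = variable_meanings(kind, window),
                  provenance = prov)
}

#' Binarize continuous features by thresholding
#'
#' A feature with one threshold `t` becomes a single bit, 1 iff the value is
#' strictly greater than `t`. A feature with `k >= 2` strictly increasing
#' thresholds becomes `k + 1` one-hot interval-membership bits: below the
#' first threshold, between consecutive thresholds (boundaries inclusive),
#' and strictly above the last.
#'
#' @param values Data frame or matrix of numeric features (one column each).
#' @param thresholds A list with one numeric vector of cut points per
#'   feature (recycled if a single vector is given).
#' @param labels Optional 0/1 labels attached to the resulting dataset
#'   (default all 0).
#' @return An [encoded_dataset()]; variable descriptions record the
#'   feature/threshold each bit tests.
#' @export
binarize_continuous <- function(values, thresholds, labels = NULL) {
  values <- as.data.frame(values)
  if (!is.list(thresholds)) thresholds <- rep(list(thresholds), ncol(values))
  if (length(thresholds) == 1L) thresholds <- rep(thresholds, ncol(values))
  stopifnot(length(thresholds) == ncol(values))
  feat_names <- names(values)
  cols <- list(); descs <- character(0)
  for (j in seq_along(values)) {
    th <- as.numeric(thresholds[[j]])
    if (length(th) == 0L || is.unsorted(th, strictly = TRUE)) {
      abort(sprintf("thresholds for feature '%s' must be strictly increasing",
                    feat_names[j]))
    }
    x <- values[[j]]
    if (length(th) == 1L) {
      cols <- c(cols, list(as.integer(x > th)))
      descs <- c(descs, sprintf("%s > %g", feat_names[j], th))
    } else {
      k <- length(th)
      interval <- findInterval(x, th, left.open = FALSE)   # 0..k
      # boundary values belong to the enclosed interval, not the outer ones:
      # x == th[1] -> interval 1, x == th[k] -> interval k - 1 + 1 handled below
      low <- x < th[1]
      high <- x > th[k]
      mid <- pmin(pmax(interval, 1L), k - 1L)              # 1..k-1 middle slots
      slot <- ifelse(low, 1L, ifelse(high, k + 1L, mid + 1L))
      for (s in seq_len(k + 1L)) {
        cols <- c(cols, list(as.integer(slot == s)))
        descs <- c(descs,
                   if (s == 1L) sprintf("%s < %g", feat_names[j], th[1])
                   else if (s == k + 1L) sprintf("%s > %g", feat_names[j], th[k])
                   else sprintf("%g <= %s <= %g", th[s - 1L], feat_names[j], th[s]))
      }
    }
  }
  patterns <- do.call(cbind, cols)
  if (is.null(labels)) labels <- rep(0L, nrow(patterns))
  meanings <- tibble(index = seq_along(descs), window_position = NA_integer_,
                     symbol = NA_character_, description = descs)
  encoded_dataset(patterns, labels, meanings = meanings)
}

#' Remove duplicates and contradictions from an encoded dataset
#'
#' Logic minimization requires a contradiction-free function table: identical
#' input patterns must not carry different labels. Duplicate patterns are
#' collapsed to a single row whose multiplicity is the sum of the collapsed
#' multiplicities (rule scores later count these occurrences). Contradictory
#' groups are either removed outright (`policy = "drop"`) or resolved to
#' their majority label, with exact ties removed (`policy = "majority"`).
#'
#' @param ds An [encoded_dataset()].
#' @param policy `"drop"` (default) or `"majority"`.
#' @return A cleaned [encoded_dataset()]; the actions taken are recorded in
#'   a report retrievable with [cleaning_report()].
#' @export
clean_dataset <- function(ds, policy = c("drop", "majority")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ds, "encoded_dataset"))
  key <- pattern_strings(ds$patterns)
  df <- tibble(row = seq_along(key), key = key, label = ds$labels,
               mult = ds$multiplicity, prov = ds$provenance)
  grp <- df %>%
    group_by(.data$key) %>%
    summarise(n_pos = sum(.data$mult[.data$label == 1L]),
              n_neg = sum(.data$mult[.data$label == 0L]),
              first_row = min(.data$row),
              prov = paste(.data$prov, collapse = ","),
              n_rows = dplyr::n(), .groups = "drop") %>%
    arrange(.data$first_row)

  actions <- character(nrow(grp)); keep_label <- integer(nrow(grp))
  keep <- logical(nrow(grp))
  for (i in seq_len(nrow(grp))) {
    np <- grp$n_pos[i]; nn <- grp$n_neg[i]
    if (np > 0L && nn > 0L) {
      if (policy == "drop" || np == nn) {
        actions[i] <- if (policy == "drop") "contradiction_dropped" else "contradiction_tie_dropped"
        keep[i] <- FALSE
      } else {
        actions[i] <- "contradiction_majority"
        keep[i] <- TRUE
        keep_label[i] <- as.integer(np > nn)
      }
    } else {
      keep[i] <- TRUE
      keep_label[i] <- as.integer(np > 0L)
      actions[i] <- if (grp$n_rows[i] > 1L) "duplicates_merged" else "kept"
    }
  }
  report <- grp %>%
    mutate(action = actions) %>%
    filter(.data$action != "kept") %>%
    select(pattern = "key", "action", "n_pos", "n_neg")

  idx <- which(keep)
  rows <- grp$first_row[idx]
  out <- encoded_dataset(
    ds$patterns[rows, , drop = FALSE],
    keep_label[idx],
    meanings = ds$meanings,
    multiplicity = as.integer(pmax(grp$n_pos[idx], grp$n_neg[idx])),
    provenance = grp$prov[idx]
  )
  attr(out, "cleaning_report") <- report
  out
}

#' Report of the actions taken by [clean_dataset()]
#'
#' @param ds A dataset returned by [clean_dataset()].
#' @return A tibble with columns `pattern`, `action`, `n_pos`, `n_neg`
#'   (empty if nothing was merged or removed).
#' @export
cleaning_report <- function(ds) {
  rep <- attr(ds, "cleaning_report")
  if (is.null(rep)) {
    rep <- tibble(pattern = character(0), action = character(0),
                  n_pos = numeric(0), n_neg = numeric(0))
  }
  rep
}
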