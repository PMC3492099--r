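# Independent brute-force oracles for the logic minimizers. These never call
# the package's cube internals: cubes are strings, and coverage is computed
# against a precomputed minterm-by-variable bit table.

oracle_bit_table <- function(n) {
  # row m+1 = bits of minterm m, leftmost variable most significant
  t(vapply(0:(2^n - 1), function(m) as.integer(intToBits(m))[n:1],
           integer(n)))
}

oracle_minterms <- function(cube) {
  n <- nchar(cube)
  chars <- strsplit(cube, "")[[1]]
  tab <- oracle_bit_table(n)
  keep <- rep(TRUE, nrow(tab))
  for (j in seq_len(n)) {
    if (chars[j] != "-") keep <- keep & tab[, j] == as.integer(chars[j])
  }
  which(keep) - 1L
}

oracle_all_cubes <- function(n) {
  grid <- expand.grid(rep(list(c("0", "1", "-")), n), stringsAsFactors = FALSE)
  apply(grid, 1, paste, collapse = "")
}

# coverage matrix: rows = cubes, cols = minterms 0..2^n-1
oracle_coverage <- function(cubes, n) {
  tab <- oracle_bit_table(n)
  t(vapply(cubes, function(cb) {
    chars <- strsplit(cb, "")[[1]]
    keep <- rep(TRUE, nrow(tab))
    for (j in seq_len(n)) {
      if (chars[j] != "-") keep <- keep & tab[, j] == as.integer(chars[j])
    }
    keep
  }, logical(2^n)))
}

# all maximal cubes covering only on/dc minterms and at least one on minterm
oracle_prime_cubes <- function(on, off, n) {
  cubes <- oracle_all_cubes(n)
  cov <- oracle_coverage(cubes, n)
  off_cols <- off + 1L
  on_cols <- on + 1L
  valid <- !apply(cov[, off_cols, drop = FALSE], 1, any) &
    apply(cov[, on_cols, drop = FALSE], 1, any)
  vcubes <- cubes[valid]
  vcov <- cov[valid, , drop = FALSE]
  # cube i is maximal if no other valid cube strictly contains it
  nlit <- nchar(gsub("-", "", vcubes))
  is_max <- vapply(seq_along(vcubes), function(i) {
    for (w in which(nlit < nlit[i])) {
      if (all(vcov[w, vcov[i, ]])) return(FALSE)  # i strictly inside w
    }
    TRUE
  }, logical(1))
  sort(vcubes[is_max])
}

# minimality certificate: TRUE when no cover of k-1 brute-force primes
# exists (so k is the exact minimum, since any smaller cover extends to one
# of size k-1), FALSE when one does, NA when the enumeration would exceed
# the budget. Primes with identical on-set coverage are collapsed to one
# representative - interchangeable for cardinality - which keeps the subset
# enumeration small without sacrificing exactness.
oracle_confirms_minimum <- function(on, off, n, k, max_combos = 2e5) {
  if (!length(on)) return(k == 0L)
  if (k <= 1L) return(TRUE)   # a nonempty on-set needs at least one cube
  primes <- oracle_prime_cubes(on, off, n)
  cov <- oracle_coverage(primes, n)[, on + 1L, drop = FALSE]
  sig <- apply(cov, 1, paste, collapse = "")
  cov <- cov[!duplicated(sig), , drop = FALSE]
  s <- nrow(cov)
  if (k - 1L > s) return(TRUE)
  if (choose(s, k - 1L) > max_combos) return(NA)
  combos <- utils::combn(s, k - 1L, simplify = FALSE)
  for (cmb in combos) {
    if (all(apply(cov[cmb, , drop = FALSE], 2, any))) return(FALSE)
  }
  TRUE
}

# random partially-specified function. The on-set probability shrinks with
# width so the on-set stays at a few dozen minterms - the regime the
# pipeline produces (observed patterns scarce, don't-cares abundant) and one
# where the exhaustive oracles stay tractable.
random_tf <- function(n, p = NULL) {
  if (is.null(p)) {
    p_on <- min(0.25, 24 / 2^n)
    p <- c(on = p_on, off = 0.55 * (1 - p_on), dc = 0.45 * (1 - p_on))
  }
  out <- sample(c("1", "0", "-"), 2^n, replace = TRUE, prob = p)
  truth_function(n,
                 on_set = which(out == "1") - 1L,
                 off_set = which(out == "0") - 1L,
                 dc_set = which(out == "-") - 1L)
}

# the paper-style worked truth table: 4 inputs, on = patterns 1,3,4,9,11,12,
# dc = patterns 7,8,15,16 (minterm index reads A,B,C,D as a binary number)
worked_example_tf <- function() {
  truth_function(4,
                 on_set = c(0, 2, 3, 8, 10, 11),
                 off_set = c(1, 4, 5, 9, 12, 13),
                 dc_set = c(6, 7, 14, 15))
}

# the same table as a pre-encoded labeled dataset (don't-care rows omitted),
# keeping the original 1-based pattern numbers as provenance
worked_example_dataset <- function() {
  pats <- c("0000", "0001", "0010", "0011", "0100", "0101",
            "1000", "1001", "1010", "1011", "1100", "1101")
  labs <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L)
  ids <- c(1, 2, 3, 4, 5, 6, 9, 10, 11, 12, 13, 14)
  m <- do.call(rbind, lapply(strsplit(pats, ""), as.integer))
  encoded_dataset(m, labs, provenance = as.character(ids))
}

# one seeded replicate of the synthetic binding-site experiment
tfbs_replicate <- function(seed, n_sites = 60L, bg_len = 20000L,
                           train_fraction = 0.9, k = 22L, min_gap = 20L) {
  spec <- motif_spec()
  bg <- generate_background_dna(bg_len, seed = seed)
  imp <- implant_motifs(bg, spec, n_sites = n_sites, min_gap = min_gap,
                        seed = seed + 1000L)
  sites <- vapply(imp$true_starts, function(s) {
    substr(imp$sequence, s, s + spec$length - 1L)
  }, character(1))
  set.seed(seed + 2000L)
  n_train <- ceiling(train_fraction * n_sites)
  tr_idx <- sample(n_sites, n_train)
  neg <- sample_negative_windows(n_train, seed = seed + 3000L)
  train <- tibble::tibble(sequence = c(sites[tr_idx], neg),
                          label = rep(c(1L, 0L), each = n_train))
  model <- train_site_model(train, kind = "tfbs", k = k)
  list(model = model, sequence = imp$sequence,
       true_starts = imp$true_starts,
       heldout_starts = imp$true_starts[-tr_idx],
       spec = spec)
}

rule_literal_positions <- function(model) {
  unlist(lapply(model$rules$rules$cube, function(cb) {
    ch <- strsplit(cb, "")[[1]]
    model$rules$meanings$window_position[ch != "-"]
  }))
}
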