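# Two-level logic minimization over cubes written as strings in {0,1,-}.
# Internally a cube is a pair of integers: `value` (bits forced to 1) and
# `dcmask` (don't-care positions). The leftmost character of a cube string
# is the most significant bit, so minterm indices read a truth table with
# the first variable as the high-order bit.

bit_weights <- function(n) as.integer(2^((n - 1):0))

cube_to_vm <- function(cube) {
  chars <- strsplit(cube, "")[[1]]
  if (!all(chars %in% c("0", "1", "-"))) abort("cube characters must be 0, 1 or -")
  w <- bit_weights(length(chars))
  list(value = sum(w[chars == "1"]), dcmask = sum(w[chars == "-"]),
       n = length(chars))
}

vm_to_cube <- function(value, dcmask, n) {
  w <- bit_weights(n)
  vapply(seq_along(value), function(i) {
    ch <- ifelse(bitwAnd(dcmask[i], w) != 0L, "-",
                 ifelse(bitwAnd(value[i], w) != 0L, "1", "0"))
    paste(ch, collapse = "")
  }, character(1))
}

vm_covers <- function(value, dcmask, minterms, n) {
  care <- bitwXor(as.integer(2^n - 1), dcmask)
  bitwAnd(minterms, care) == value
}

#' Does a cube cover a binary pattern?
#'
#' A cube (product term) written over `{0,1,-}` covers a pattern iff the
#' pattern agrees with every fixed (non-`-`) literal.
#'
#' @param cube A cube string, e.g. `"-0-0"`.
#' @param pattern A 0/1 integer vector or a 0/1 string of the same width.
#' @return Logical scalar.
#' @examples
#' cube_covers("-0-0", c(0, 0, 0, 0))
#' cube_covers("-0-0", "0001")
#' @export
cube_covers <- function(cube, pattern) {
  if (is.character(pattern)) pattern <- as.integer(strsplit(pattern, "")[[1]])
  chars <- strsplit(cube, "")[[1]]
  if (length(chars) != length(pattern)) abort("cube and pattern widths differ")
  all(chars == "-" | chars == as.character(as.integer(pattern)))
}

# rows of a 0/1 matrix covered by a cube; works for any width
cube_covers_rows <- function(cube, m) {
  chars <- strsplit(cube, "")[[1]]
  if (length(chars) != ncol(m)) abort("cube width does not match pattern width")
  i1 <- which(chars == "1"); i0 <- which(chars == "0")
  ok <- rep(TRUE, nrow(m))
  if (length(i1)) ok <- ok & rowSums(m[, i1, drop = FALSE]) == length(i1)
  if (length(i0)) ok <- ok & rowSums(m[, i0, drop = FALSE]) == 0L
  ok
}

#' Minterms covered by a cube
#'
#' @param cube A cube string over `{0,1,-}`.
#' @return Sorted integer vector of covered minterm indices (0-based,
#'   leftmost variable most significant).
#' @export
cube_minterms <- function(cube) {
  vm <- cube_to_vm(cube)
  dc_bits <- bit_weights(vm$n)[bitwAnd(vm$dcmask, bit_weights(vm$n)) != 0L]
  out <- vm$value
  for (b in dc_bits) out <- c(out, out + b)
  sort(out)
}

#' Merge two cubes adjacent in one variable
#'
#' Implements the reduction axiom `A + !A = 1`: two cubes that agree on
#' their don't-care positions and differ in exactly one fixed literal merge
#' into a single cube with `-` at that position. Returns `NULL` when the
#' cubes are not adjacent.
#'
#' @param a,b Cube strings of equal width.
#' @return The merged cube string, or `NULL`.
#' @examples
#' merge_adjacent("111", "011")  # "-11"
#' @export
merge_adjacent <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) abort("cube widths differ")
  if (!identical(ca == "-", cb == "-")) return(NULL)
  diff <- which(ca != cb)
  if (length(diff) != 1L) return(NULL)
  ca[diff] <- "-"
  paste(ca, collapse = "")
}

# ---- truth functions --------------------------------------------------------

#' A partially-specified boolean function
#'
#' Represents the on-set / off-set / don't-care partition of `{0,1}^n`.
#' Minterm indices are 0-based, reading the variables left to right as a
#' binary number with the first variable most significant. One of `off_set`
#' and `dc_set` may be `NULL`, meaning it is the complement of the other
#' two sets; with both given, any unlisted minterm is a don't-care. This
#' mirrors the usual practice of listing only the observed patterns and
#' treating every unseen pattern as unspecified.
#'
#' @param n_vars Number of input variables.
#' @param on_set Integer vector of minterms with output 1.
#' @param off_set Integer vector of minterms with output 0, or `NULL`.
#' @param dc_set Integer vector of unspecified minterms, or `NULL`.
#' @return An object of class `truth_function`.
#' @examples
#' truth_function(3, on_set = c(3, 7), off_set = setdiff(0:7, c(3, 7)))
#' @export
truth_function <- function(n_vars, on_set, off_set = NULL, dc_set = NULL) {
  n_vars <- as.integer(n_vars)
  stopifnot(n_vars >= 1L)
  norm <- function(x) if (is.null(x)) NULL else sort(unique(as.integer(x)))
  on_set <- norm(on_set); off_set <- norm(off_set); dc_set <- norm(dc_set)
  lim <- 2^n_vars
  for (s in list(on_set, off_set, dc_set)) {
    if (!is.null(s) && length(s) && (min(s) < 0 || max(s) >= lim)) {
      abort(sprintf("minterm indices must lie in 0..%d", lim - 1))
    }
  }
  if (!is.null(off_set) && length(intersect(on_set, off_set))) {
    abort("on_set and off_set overlap")
  }
  if (!is.null(dc_set) && length(intersect(on_set, dc_set))) {
    abort("on_set and dc_set overlap")
  }
  if (!is.null(dc_set) && !is.null(off_set) && length(intersect(dc_set, off_set))) {
    abort("off_set and dc_set overlap")
  }
  structure(list(n_vars = n_vars, on_set = on_set %||% integer(0),
                 off_set = off_set, dc_set = dc_set),
            class = "truth_function")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.truth_function <- function(x, ...) {
  fmt <- function(s) if (is.null(s)) "implicit" else length(s)
  cat(sprintf("<truth_function> %d variables: |on| = %d, |off| = %s, |dc| = %s\n",
              x$n_vars, length(x$on_set), fmt(x$off_set), fmt(x$dc_set)))
  invisible(x)
}

materialize_guard <- function(n, what) {
  if (n > 20L) {
    abort(sprintf(
      "cannot materialize the %s for %d variables (2^%d minterms); supply it explicitly",
      what, n, n))
  }
}

tf_dc <- function(f) {
  if (!is.null(f$dc_set)) return(f$dc_set)
  materialize_guard(f$n_vars, "don't-care set")
  setdiff(0:(2^f$n_vars - 1), c(f$on_set, f$off_set))
}

tf_off <- function(f) {
  if (!is.null(f$off_set)) return(f$off_set)
  materialize_guard(f$n_vars, "off-set")
  setdiff(0:(2^f$n_vars - 1), c(f$on_set, f$dc_set))
}

# ---- covers -----------------------------------------------------------------

new_cover <- function(cubes, n_vars, method = "manual") {
  structure(list(cubes = as.character(cubes), n_vars = as.integer(n_vars),
                 method = method),
            class = "logic_cover")
}

#' Construct a cover (set of rules) from cube strings
#'
#' @param cubes Character vector of cubes over `{0,1,-}`.
#' @param n_vars Cube width.
#' @return An object of class `logic_cover`.
#' @export
logic_cover <- function(cubes, n_vars) {
  if (length(cubes) && any(nchar(cubes) != n_vars)) {
    abort("all cubes must have width n_vars")
  }
  new_cover(cubes, n_vars)
}

#' @export
print.logic_cover <- function(x, ...) {
  cat(sprintf("<logic_cover> %d cube(s) over %d variables [%s]\n",
              length(x$cubes), x$n_vars, x$method))
  for (cb in x$cubes) cat(" ", cb, "\n")
  invisible(x)
}

#' @method tidy logic_cover
#' @export
tidy.logic_cover <- function(x, ...) {
  tibble(cube = x$cubes,
         n_literals = nchar(gsub("-", "", x$cubes)))
}

#' @export
length.logic_cover <- function(x) length(x$cubes)

# ---- prime implicants (Quine-McCluskey tabulation) --------------------------

qm_prime_vm <- function(minterms, n) {
  if (!length(minterms)) return(list(value = integer(0), dcmask = integer(0)))
  cur_v <- sort(unique(as.integer(minterms)))
  cur_d <- rep(0L, length(cur_v))
  pr_v <- integer(0); pr_d <- integer(0)
  bits <- bit_weights(n)
  repeat {
    marked <- logical(length(cur_v))
    new_v <- integer(0); new_d <- integer(0)
    for (dm in unique(cur_d)) {
      sel <- which(cur_d == dm)
      v <- cur_v[sel]
      for (b in bits[bitwAnd(dm, bits) == 0L]) {
        lo <- which(bitwAnd(v, b) == 0L)
        if (!length(lo)) next
        j <- match(v[lo] + b, v)
        ok <- which(!is.na(j))
        if (length(ok)) {
          marked[sel[lo[ok]]] <- TRUE
          marked[sel[j[ok]]] <- TRUE
          new_v <- c(new_v, v[lo[ok]])
          new_d <- c(new_d, rep(dm + b, length(ok)))
        }
      }
    }
    pr_v <- c(pr_v, cur_v[!marked]); pr_d <- c(pr_d, cur_d[!marked])
    if (!length(new_v)) break
    key <- new_v + as.numeric(new_d) * 2^n
    keep <- !duplicated(key)
    cur_v <- new_v[keep]; cur_d <- new_d[keep]
  }
  key <- pr_v + as.numeric(pr_d) * 2^n
  keep <- !duplicated(key)
  list(value = pr_v[keep], dcmask = pr_d[keep])
}

#' Prime implicants of a partially-specified function
#'
#' Tabulates all maximal cubes that cover only on-set and don't-care
#' minterms, by iteratively merging cubes that differ in a single position
#' (the Quine-McCluskey tabulation). Maximal cubes covering only
#' don't-cares are discarded: they can never contribute to a cover of the
#' on-set.
#'
#' @param f A [truth_function()].
#' @return Character vector of prime-implicant cubes, sorted.
#' @export
prime_implicants <- function(f) {
  stopifnot(inherits(f, "truth_function"))
  pr <- qm_on_primes(f)
  sort(vm_to_cube(pr$value, pr$dcmask, f$n_vars), method = "radix")
}

qm_on_primes <- function(f) {
  pr <- qm_prime_vm(c(f$on_set, tf_dc(f)), f$n_vars)
  useful <- vapply(seq_along(pr$value), function(i) {
    any(vm_covers(pr$value[i], pr$dcmask[i], f$on_set, f$n_vars))
  }, logical(1))
  list(value = pr$value[useful], dcmask = pr$dcmask[useful])
}

# lexicographic comparison of two sorted cube lists ('-' < '0' < '1' in C order)
cube_list_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Exact two-level minimization (Quine-McCluskey + minimum cover)
#'
#' Computes all prime implicants, extracts essential primes, and solves the
#' remaining minimum set-cover problem exactly by branch-and-bound, so the
#' result is a minimum-cardinality cover of the on-set. Don't-care minterms
#' may be used to widen cubes but never need to be covered. Ties between
#' equal-size covers are broken by the lexicographically smallest sorted
#' cube list, making the output unique.
#'
#' @param f A [truth_function()].
#' @param exact_limit Refuse inputs with more variables than this (default
#'   16); use [espresso_minimize()] beyond it.
#' @return A `logic_cover` with `method = "quine-mccluskey"`.
#' @examples
#' f <- truth_function(3, on_set = c(3, 7), off_set = setdiff(0:7, c(3, 7)))
#' qm_minimize(f)$cubes  # "-11"
#' @export
qm_minimize <- function(f, exact_limit = 16L) {
  stopifnot(inherits(f, "truth_function"))
  if (f$n_vars > exact_limit) {
    abort(sprintf(
      "%d variables exceed the exact limit (%d); use espresso_minimize()",
      f$n_vars, exact_limit))
  }
  n <- f$n_vars
  on <- f$on_set
  if (!length(on)) return(new_cover(character(0), n, "quine-mccluskey"))
  pr <- qm_on_primes(f)
  cubes <- vm_to_cube(pr$value, pr$dcmask, n)
  ord <- order(cubes, method = "radix")
  pr_v <- pr$value[ord]; pr_d <- pr$dcmask[ord]; cubes <- cubes[ord]

  # coverage matrix: primes x on-set minterms
  cov <- matrix(FALSE, length(cubes), length(on))
  for (i in seq_along(cubes)) cov[i, ] <- vm_covers(pr_v[i], pr_d[i], on, n)

  chosen <- integer(0)
  uncovered <- seq_along(on)
  active <- seq_along(cubes)
  # iterate essential extraction with row/column dominance until stable
  repeat {
    changed <- FALSE
    sub <- cov[active, uncovered, drop = FALSE]
    counts <- colSums(sub)
    ess_cols <- which(counts == 1L)
    if (length(ess_cols)) {
      ess <- unique(active[apply(sub[, ess_cols, drop = FALSE], 2, which.max)])
      chosen <- c(chosen, ess)
      covered_now <- uncovered[colSums(cov[ess, uncovered, drop = FALSE]) > 0L]
      uncovered <- setdiff(uncovered, covered_now)
      active <- setdiff(active, ess)
      changed <- TRUE
    }
    if (!length(uncovered) || !length(active)) break
    # drop primes that no longer cover anything uncovered
    gains <- rowSums(cov[active, uncovered, drop = FALSE])
    if (any(gains == 0L)) {
      active <- active[gains > 0L]
      changed <- TRUE
    }
    # column (prime) dominance: drop primes whose residual coverage is a
    # subset of another's; on equal coverage keep the lex-smaller cube
    if (length(active) > 1L) {
      sub <- cov[active, uncovered, drop = FALSE]
      storage.mode(sub) <- "double"
      m <- tcrossprod(sub, 1 - sub)          # m[a,b] = |cov(a) \ cov(b)|
      subset_of <- m == 0                    # a's coverage inside b's
      diag(subset_of) <- FALSE
      strict <- subset_of & t(m) > 0
      lex <- order(order(cubes[active], method = "radix"))  # rank of each cube
      equal_worse <- subset_of & t(subset_of) & outer(lex, lex, ">")
      drop <- rowSums(strict | equal_worse) > 0
      if (any(drop)) {
        active <- active[!drop]
        changed <- TRUE
      }
    }
    # row (minterm) dominance: a minterm whose candidate primes contain
    # another's candidates is satisfied automatically; keep the harder row
    if (length(uncovered) > 1L && length(active)) {
      sub <- cov[active, uncovered, drop = FALSE]
      storage.mode(sub) <- "double"
      m <- crossprod(sub, 1 - sub)           # m[a,b] = |cand(a) \ cand(b)|
      dominated <- m == 0                    # cand(a) inside cand(b): drop b
      diag(dominated) <- FALSE
      strict <- dominated & t(m) > 0         # strictly larger candidate set
      idx <- seq_along(uncovered)
      equal_later <- dominated & t(dominated) & outer(idx, idx, "<")
      drop <- colSums(strict | equal_later) > 0
      if (any(drop)) {
        uncovered <- uncovered[!drop]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(uncovered)) {
    # branch and bound on the residual cyclic core, with a greedy incumbent
    # and a maximal-independent-rows lower bound
    cand <- active
    sub <- cov[cand, uncovered, drop = FALSE]
    lex_rank <- order(order(cubes[cand], method = "radix"))

    greedy_sel <- local({
      unc <- rep(TRUE, ncol(sub))
      sel <- integer(0)
      while (any(unc)) {
        gains <- rowSums(sub[, unc, drop = FALSE])
        i <- which(gains == max(gains))
        i <- i[which.min(lex_rank[i])]
        sel <- c(sel, i)
        unc <- unc & !sub[i, ]
      }
      sel
    })
    best_sel <- greedy_sel
    best_size <- length(greedy_sel)

    mis_bound <- function(unc_mask) {
      cols <- which(unc_mask)
      cnt <- colSums(sub[, cols, drop = FALSE])
      cols <- cols[order(cnt)]
      used <- rep(FALSE, nrow(sub))
      bound <- 0L
      for (cc in cols) {
        if (!any(sub[, cc] & used)) {
          bound <- bound + 1L
          used <- used | sub[, cc]
        }
      }
      bound
    }

    recurse <- function(sel, unc_mask) {
      if (!any(unc_mask)) {
        size <- length(sel)
        cl <- sort(cubes[c(chosen, cand[sel])], method = "radix")
        if (size < best_size ||
            (size == best_size &&
             cube_list_less(cl, sort(cubes[c(chosen, cand[best_sel])],
                                     method = "radix")))) {
          best_size <<- size
          best_sel <<- sel
        }
        return(invisible(NULL))
      }
      if (length(sel) + mis_bound(unc_mask) > best_size) {
        return(invisible(NULL))
      }
      per_m <- colSums(sub[, unc_mask, drop = FALSE])
      m <- which(unc_mask)[which.min(per_m)]
      branches <- which(sub[, m])
      branches <- branches[order(lex_rank[branches])]
      for (i in branches) {
        if (!(i %in% sel)) recurse(c(sel, i), unc_mask & !sub[i, ])
      }
      invisible(NULL)
    }
    recurse(integer(0), rep(TRUE, length(uncovered)))
    chosen <- c(chosen, cand[best_sel])
  }
  new_cover(sort(cubes[chosen], method = "radix"), n, "quine-mccluskey")
}

# ---- ESPRESSO-style heuristic minimization ----------------------------------

esp_expand <- function(cv, cd, on, off, n, keep_order = seq_len(n)) {
  bits <- bit_weights(n)
  # preference rank for keeping each literal position (1 = keep first on ties)
  pref <- integer(n); pref[keep_order] <- seq_len(n)
  counts <- vapply(seq_along(cv), function(i) sum(vm_covers(cv[i], cd[i], on, n)),
                   integer(1))
  ord <- order(-counts, seq_along(cv))
  for (i in ord) {
    fixed <- which(bitwAnd(cd[i], bits) == 0L)
    if (!length(fixed)) next
    vals <- as.integer(bitwAnd(cv[i], bits[fixed]) != 0L)
    # greedy blocking: keep the literal that distinguishes the most off-set
    # patterns still covered, until no off minterm can be covered
    blocked <- rep(FALSE, length(off))
    kept <- integer(0)
    if (length(off)) {
      disagree <- vapply(seq_along(fixed), function(j) {
        as.integer(bitwAnd(off, bits[fixed[j]]) != 0L) != vals[j]
      }, logical(length(off)))
      disagree <- matrix(disagree, nrow = length(off))
      # fraction of the on-set agreeing with each literal: keeping a literal
      # most of the on-set shares preserves the cube's room to grow
      on_frac <- vapply(seq_along(fixed), function(j) {
        mean(as.integer(bitwAnd(on, bits[fixed[j]]) != 0L) == vals[j])
      }, numeric(1))
      while (!all(blocked)) {
        gain <- colSums(disagree & !blocked)
        cand <- setdiff(which(gain > 0L), kept)
        if (!length(cand)) break  # cannot block; keep every remaining literal
        j <- cand[on_frac[cand] == max(on_frac[cand])]
        if (length(j) > 1L) j <- j[gain[j] == max(gain[j])]
        j <- j[which.min(pref[fixed[j]])]
        kept <- c(kept, j)
        blocked <- blocked | disagree[, j]
      }
      if (!all(blocked)) {
        kept <- seq_along(fixed)
      } else if (length(kept) > 1L) {
        # make the kept set irredundant: drop literals (least shared by the
        # on-set first) whose blocking contribution the others already give
        for (j in kept[order(on_frac[kept], -pref[fixed[kept]])]) {
          rest <- setdiff(kept, j)
          if (all(rowSums(disagree[, rest, drop = FALSE]) > 0L)) kept <- rest
        }
      }
    }
    raise <- setdiff(seq_along(fixed), kept)
    if (length(raise)) {
      add <- sum(bits[fixed[raise]])
      cd[i] <- cd[i] + add
      cv[i] <- bitwAnd(cv[i], bitwXor(as.integer(2^n - 1), add))
    }
  }
  key <- cv + as.numeric(cd) * 2^n
  keep <- !duplicated(key)
  list(v = cv[keep], d = cd[keep])
}

esp_irredundant <- function(cv, cd, on, n) {
  cov <- lapply(seq_along(cv), function(i) which(vm_covers(cv[i], cd[i], on, n)))
  counts <- integer(length(on))
  for (co in cov) counts[co] <- counts[co] + 1L
  sizes <- lengths(cov)
  keep <- rep(TRUE, length(cv))
  for (i in order(sizes, seq_along(cv))) {
    if (all(counts[cov[[i]]] >= 2L)) {
      keep[i] <- FALSE
      counts[cov[[i]]] <- counts[cov[[i]]] - 1L
    }
  }
  list(v = cv[keep], d = cd[keep])
}

esp_reduce <- function(cv, cd, on, n) {
  cov <- lapply(seq_along(cv), function(i) which(vm_covers(cv[i], cd[i], on, n)))
  counts <- integer(length(on))
  for (co in cov) counts[co] <- counts[co] + 1L
  keep <- rep(TRUE, length(cv))
  for (i in seq_along(cv)) {
    required <- on[cov[[i]][counts[cov[[i]]] == 1L]]
    if (!length(required)) {
      keep[i] <- FALSE
      counts[cov[[i]]] <- counts[cov[[i]]] - 1L
      next
    }
    # smallest cube containing the minterms only this cube covers
    nd <- Reduce(bitwOr, bitwXor(required, required[1]), 0L)
    nv <- bitwAnd(required[1], bitwXor(as.integer(2^n - 1), nd))
    dropped <- setdiff(cov[[i]], which(vm_covers(nv, nd, on, n)))
    counts[dropped] <- counts[dropped] - 1L
    cv[i] <- nv; cd[i] <- nd
  }
  list(v = cv[keep], d = cd[keep])
}

#' Heuristic two-level minimization (ESPRESSO-style)
#'
#' Iterates the classic EXPAND / IRREDUNDANT / REDUCE loop against an
#' explicit off-set: each cube is greedily widened (literals raised left to
#' right) as long as it hits no off-set minterm, cubes whose on-set
#' contribution is covered by the rest are dropped, and surviving cubes are
#' shrunk to the smallest cube still needed before the next expansion.
#' Unlike [qm_minimize()] the result carries no global-minimality
#' guarantee, but it never enumerates the don't-care set, so it scales to
#' the 20-22 variable functions produced by feature selection.
#'
#' @param f A [truth_function()]; the off-set must be explicit (or cheap to
#'   materialize, n <= 20).
#' @param max_iters Maximum expand/irredundant/reduce iterations.
#' @param heuristic_limit Refuse inputs wider than this (default 22).
#' @param keep_order Permutation of `1..n_vars`: the tie-break preference
#'   used by EXPAND when two literals block equally many off-set patterns
#'   (default left to right; [train_site_model()] passes the RFE ranking so
#'   the more informative literal is preferred).
#' @return A `logic_cover` with `method = "espresso"`.
#' @export
espresso_minimize <- function(f, max_iters = 20L, heuristic_limit = 22L,
                              keep_order = NULL) {
  stopifnot(inherits(f, "truth_function"))
  n <- f$n_vars
  if (n > heuristic_limit) {
    abort(sprintf("%d variables exceed the heuristic limit (%d)", n, heuristic_limit))
  }
  on <- f$on_set
  if (!length(on)) return(new_cover(character(0), n, "espresso"))
  off <- tf_off(f)
  keep_order <- keep_order %||% seq_len(n)
  stopifnot(length(keep_order) == n, all(sort(keep_order) == seq_len(n)))
  cv <- on; cd <- rep(0L, length(on))
  best <- NULL; best_size <- Inf; prev_size <- Inf
  for (iter in seq_len(max_iters)) {
    ex <- esp_expand(cv, cd, on, off, n, keep_order)
    ir <- esp_irredundant(ex$v, ex$d, on, n)
    cv <- ir$v; cd <- ir$d
    size <- length(cv)
    if (size < best_size) {
      best <- list(v = cv, d = cd); best_size <- size
    }
    if (size >= prev_size) break
    prev_size <- size
    rd <- esp_reduce(cv, cd, on, n)
    cv <- rd$v; cd <- rd$d
  }
  new_cover(sort(vm_to_cube(best$v, best$d, n), method = "radix"), n, "espresso")
}

#' Is a cover equivalent to a partially-specified function?
#'
#' True iff the cover contains every on-set minterm and no off-set minterm;
#' don't-cares may fall on either side. Checked exhaustively over the
#' listed sets, so it is exact.
#'
#' @param cover A `logic_cover`.
#' @param f A [truth_function()] of the same width.
#' @return Logical scalar.
#' @export
covers_equivalent <- function(cover, f) {
  stopifnot(inherits(cover, "logic_cover"), inherits(f, "truth_function"))
  if (cover$n_vars != f$n_vars) abort("cover and function widths differ")
  n <- f$n_vars
  if (n > 20L) abort("equivalence check limited to 20 variables")
  off <- tf_off(f)
  vm <- lapply(cover$cubes, cube_to_vm)
  covered <- function(mts) {
    if (!length(mts)) return(logical(0))
    hit <- rep(FALSE, length(mts))
    for (c in vm) hit <- hit | vm_covers(c$value, c$dcmask, mts, n)
    hit
  }
  all(covered(f$on_set)) && !any(covered(off))
}
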