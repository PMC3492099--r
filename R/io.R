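# Berkeley PLA read/write, FASTA, and human-readable rule rendering.

#' Construct a Berkeley PLA document
#'
#' The PLA text format is the standard interchange for two-level logic
#' minimizers: a header (`.i`, `.o`, optional `.ilb`/`.ob` labels, `.p`,
#' `.type`) followed by cube lines whose input part is written over
#' `{0,1,-}` and whose output part gives the function value (`1` on-set,
#' `0` off-set, `-` don't-care). Type `fr` (on-set and off-set listed,
#' everything else don't-care) is the canonical dialect here: it matches
#' the convention of assigning every unseen pattern an unspecified output
#' without materializing all `2^n` rows.
#'
#' @param n_inputs,n_outputs Numbers of input/output columns.
#' @param cubes A data frame with character columns `inputs` and `outputs`.
#' @param ilb,ob Optional input/output labels (unique).
#' @param type PLA type flag (default `"fr"`).
#' @return A `pla_document`.
#' @export
pla_document <- function(n_inputs, n_outputs = 1L, cubes,
                         ilb = NULL, ob = NULL, type = "fr") {
  cubes <- as_tibble(cubes)
  stopifnot(all(c("inputs", "outputs") %in% names(cubes)))
  if (nrow(cubes)) {
    if (any(nchar(cubes$inputs) != n_inputs)) abort("input part width mismatch")
    if (any(nchar(cubes$outputs) != n_outputs)) abort("output part width mismatch")
    bad_in <- grepl("[^01-]", cubes$inputs)
    bad_out <- grepl("[^01-]", cubes$outputs)
    if (any(bad_in | bad_out)) abort("cube lines must use only 0, 1 and -")
  }
  if (!is.null(ilb) && (length(ilb) != n_inputs || anyDuplicated(ilb))) {
    abort(".ilb must give one unique label per input")
  }
  if (!is.null(ob) && (length(ob) != n_outputs || anyDuplicated(ob))) {
    abort(".ob must give one unique label per output")
  }
  structure(list(n_inputs = as.integer(n_inputs),
                 n_outputs = as.integer(n_outputs),
                 ilb = ilb, ob = ob, type = type, cubes = cubes),
            class = "pla_document")
}

#' @export
print.pla_document <- function(x, ...) {
  cat(sprintf("<pla_document> .i %d .o %d, %d cube line(s), type %s\n",
              x$n_inputs, x$n_outputs, nrow(x$cubes), x$type))
  invisible(x)
}

#' Read a PLA document
#'
#' @param x A file path, or a character vector of PLA lines.
#' @return A `pla_document`.
#' @export
read_pla <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n"))
  }
  lines <- sub("#.*$", "", lines)
  n_in <- NULL; n_out <- 1L; ilb <- NULL; ob <- NULL; type <- "fr"
  ins <- character(0); outs <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (startsWith(tok[1], ".")) {
      switch(tok[1],
             ".i" = { n_in <- as.integer(tok[2]) },
             ".o" = { n_out <- as.integer(tok[2]) },
             ".ilb" = { ilb <- tok[-1] },
             ".ob" = { ob <- tok[-1] },
             ".p" = { },
             ".type" = { type <- tok[2] },
             ".e" = { break },
             abort(sprintf("line %d: unknown directive '%s'", ln, tok[1])))
    } else {
      if (is.null(n_in)) abort(sprintf("line %d: cube before .i declaration", ln))
      inp <- paste(tok[-length(tok)], collapse = "")
      outp <- tok[length(tok)]
      if (length(tok) == 1L) {
        # allow "inputs outputs" fused only when widths allow a unique split
        if (nchar(tok) != n_in + n_out) {
          abort(sprintf("line %d: cube line width mismatch", ln))
        }
        inp <- substr(tok, 1L, n_in); outp <- substr(tok, n_in + 1L, n_in + n_out)
      }
      if (nchar(inp) != n_in || nchar(outp) != n_out) {
        abort(sprintf("line %d: cube '%s %s' does not match .i %d / .o %d",
                      ln, inp, outp, n_in, n_out))
      }
      ins <- c(ins, inp); outs <- c(outs, outp)
    }
  }
  if (is.null(n_in)) abort("missing .i declaration")
  pla_document(n_in, n_out, tibble(inputs = ins, outputs = outs),
               ilb = ilb, ob = ob, type = type)
}

#' Write a PLA document
#'
#' @param doc A `pla_document`.
#' @param path Optional file path; with `NULL` the text is returned.
#' @return The PLA text lines, invisibly when written to a file.
#' @export
write_pla <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "pla_document"))
  lines <- c(sprintf(".i %d", doc$n_inputs), sprintf(".o %d", doc$n_outputs))
  if (!is.null(doc$ilb)) lines <- c(lines, paste(c(".ilb", doc$ilb), collapse = " "))
  if (!is.null(doc$ob)) lines <- c(lines, paste(c(".ob", doc$ob), collapse = " "))
  lines <- c(lines, sprintf(".type %s", doc$type), sprintf(".p %d", nrow(doc$cubes)),
             paste(doc$cubes$inputs, doc$cubes$outputs), ".e")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Number of rows of a complete truth table
#'
#' @param n_inputs Number of binary inputs.
#' @return `2^n_inputs` as a double (e.g. 4,194,304 for 22 inputs).
#' @export
pla_table_rows <- function(n_inputs) 2^as.integer(n_inputs)

#' Convert between PLA documents and truth functions / covers
#'
#' `pla_to_truth_function()` reads output symbols `1`, `0`, `-` into the
#' on-, off- and don't-care sets (input cubes with `-` are expanded to
#' their minterms). `truth_function_to_pla()` writes the explicit sets as
#' minterm lines; with `materialize = TRUE` it emits the complete table,
#' which is refused beyond `max_rows` rows (a complete 22-input table has
#' 4,194,304 rows). `cover_to_pla()` writes each rule cube with output 1.
#'
#' @param doc A `pla_document` with one output.
#' @return A [truth_function()], a `pla_document`, as appropriate.
#' @export
pla_to_truth_function <- function(doc) {
  stopifnot(inherits(doc, "pla_document"), doc$n_outputs == 1L)
  n <- doc$n_inputs
  if (n > 20L) abort("PLA-to-truth-function expansion limited to 20 inputs")
  sets <- list(`1` = integer(0), `0` = integer(0), `-` = integer(0))
  for (i in seq_len(nrow(doc$cubes))) {
    mts <- cube_minterms(doc$cubes$inputs[i])
    o <- doc$cubes$outputs[i]
    sets[[o]] <- union(sets[[o]], mts)
  }
  explicit_dc <- length(sets[["-"]]) > 0L
  truth_function(n, on_set = sets[["1"]], off_set = sets[["0"]],
                 dc_set = if (explicit_dc) sets[["-"]] else NULL)
}

#' @rdname pla_to_truth_function
#' @param f A [truth_function()].
#' @param materialize Emit all `2^n` rows instead of only the listed sets.
#' @param max_rows Guard for materialization (default `2^16`).
#' @export
truth_function_to_pla <- function(f, materialize = FALSE, max_rows = 2^16) {
  stopifnot(inherits(f, "truth_function"))
  n <- f$n_vars
  if (materialize) {
    rows <- pla_table_rows(n)
    if (rows > max_rows) {
      abort(sprintf(
        "refusing to materialize %s rows for %d inputs (limit %s); use the fr-type listing",
        format(rows, big.mark = ","), n, format(max_rows, big.mark = ",")))
    }
    m <- 0:(rows - 1)
    out <- rep("-", rows)
    out[m %in% f$on_set] <- "1"
    out[m %in% tf_off(f)] <- "0"
    return(pla_document(n, 1L, tibble(inputs = vm_to_cube(m, rep(0L, rows), n),
                                      outputs = out), type = "fr"))
  }
  on <- f$on_set
  off <- f$off_set %||% tf_off(f)
  dc <- if (!is.null(f$dc_set)) f$dc_set else integer(0)
  pla_document(n, 1L, tibble(
    inputs = vm_to_cube(c(on, off, dc), rep(0L, length(on) + length(off) + length(dc)), n),
    outputs = rep(c("1", "0", "-"), c(length(on), length(off), length(dc)))
  ), type = "fr")
}

#' @rdname pla_to_truth_function
#' @param cover A `logic_cover`.
#' @export
cover_to_pla <- function(cover) {
  stopifnot(inherits(cover, "logic_cover"))
  pla_document(cover$n_vars, 1L,
               tibble(inputs = cover$cubes,
                      outputs = rep("1", length(cover$cubes))),
               type = "f")
}

# ---- FASTA ------------------------------------------------------------------

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings for multi-record FASTA; sequences are
#' uppercased and ids preserved.
#'
#' @param path File path.
#' @return `read_fasta()`: a tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required to read FASTA")
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) warn("empty FASTA file")
  tibble(id = names(set), sequence = unname(toupper(as.character(set))))
}

#' @rdname read_fasta
#' @param data A data frame with columns `id` and `sequence`.
#' @export
write_fasta <- function(data, path) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  writeLines(paste0(">", data$id, "\n", data$sequence), path)
  invisible(path)
}

# ---- rule rendering ---------------------------------------------------------

# conjunction text for each cube; literals ordered by RFE rank when known
render_conditions <- function(cubes, meanings) {
  ord <- if ("rfe_rank" %in% names(meanings)) order(meanings$rfe_rank)
         else seq_len(nrow(meanings))
  vapply(cubes, function(cb) {
    chars <- strsplit(cb, "")[[1]]
    parts <- character(0)
    for (j in ord) {
      ch <- chars[j]
      if (ch == "-") next
      desc <- meanings$description[j]
      parts <- c(parts, if (grepl(" is/is not ", desc, fixed = TRUE)) {
        if (ch == "1") sub(" is/is not ", " is ", desc, fixed = TRUE)
        else sub(" is/is not ", " is not ", desc, fixed = TRUE)
      } else {
        paste0(desc, " = ", ch)
      })
    }
    if (!length(parts)) "always" else paste(parts, collapse = " and ")
  }, character(1), USE.NAMES = FALSE)
}

#' Render scored rules as a readable table
#'
#' One line per rule - cube, score, and the conjunction of its conditions
#' ("Nucleotide 9 is A and Nucleotide 8 is A and ..."), with an optional
#' trailing note for the implicit negative rule ("Everything else is not a
#' TFBS").
#'
#' @param rs A `scored_rules` object.
#' @param negative_note Text of the implicit 0-output rule, or `NULL`.
#' @return Character vector of lines.
#' @export
render_rules <- function(rs, negative_note = NULL) {
  stopifnot(inherits(rs, "scored_rules"))
  lines <- sprintf("%s  score=%g  %s",
                   rs$rules$cube, rs$rules$score,
                   render_conditions(rs$rules$cube, rs$meanings))
  c(lines, negative_note)
}

#' Write rules / rankings / evaluation reports to disk
#'
#' Plain-text sidecar formats: rules as TSV (cube, score, conditions),
#' rankings as TSV (rank, variable, meaning), evaluation reports as JSON.
#'
#' @param rs A `scored_rules`; `ranking` a `feature_ranking`; `report` the
#'   tibble from [evaluate_predictions()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_rules_tsv <- function(rs, path) {
  utils::write.table(tidy(rs), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(tidy(ranking), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
write_eval_json <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
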