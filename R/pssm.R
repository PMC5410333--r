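# Position-specific scoring matrices: container, PSI-BLAST ASCII I/O,
# and the pair-list table format.

#' Construct a PSSM object
#'
#' A PSSM holds the L x 20 matrix of per-position log-odds substitution
#' scores produced by an iterative profile search (PSI-BLAST) for one
#' protein.  Rows are sequence positions, columns the 20 amino acids.
#'
#' @param scores Integer matrix with exactly 20 columns and at least 2 rows.
#'   Typical PSI-BLAST scores lie in roughly \[-16, 13\] but the range is not
#'   enforced.
#' @param protein_id Identifier string for the protein.
#' @param residues Optional character vector of residue letters, one per row
#'   (bookkeeping only).
#'
#' @return An object of class `pssm`: a list with elements `protein_id`,
#'   `scores` and `residues`.
#' @examples
#' p <- pssm(matrix(0L, 4, 20), "toy")
#' nrow(p$scores)
#' @export
pssm <- function(scores, protein_id = "unknown", residues = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) {
    abort(sprintf("PSSM must have exactly 20 columns, got %d", ncol(scores)),
          class = "ppidvm_error_format")
  }
  if (nrow(scores) < 2) {
    abort("PSSM must have at least 2 rows (L >= 2)",
          class = "ppidvm_error_domain")
  }
  if (!all(is.finite(scores))) {
    abort("PSSM scores must all be finite", class = "ppidvm_error_format")
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- NULL
  if (!is.null(residues)) {
    stopifnot(length(residues) == nrow(scores))
  }
  structure(
    list(protein_id = as.character(protein_id), scores = scores,
         residues = residues),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s: %d positions x 20 scores (range %d..%d)\n",
              x$protein_id, nrow(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
dim.pssm <- function(x) dim(x$scores)

# The 20-letter amino acid ordering used by PSI-BLAST ASCII output.
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the checkpoint-style text written by `psiblast -out_ascii_pssm`.
#' Only the first 20 score columns (the log-odds block) are consumed; the
#' percentage block and trailing statistics lines are ignored.  Data rows
#' are recognised by a leading position index followed by a residue letter.
#'
#' @param file Path to the ASCII PSSM file, or a character vector of lines.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension (or "unknown" when `file` is raw lines).
#'
#' @return A [pssm()] object.
#' @seealso [write_pssm()] for the inverse.
#' @export
read_pssm <- function(file, protein_id = NULL) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(protein_id)) {
      protein_id <- sub("\\.[^.]*$", "", basename(file))
    }
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
    if (is.null(protein_id)) protein_id <- "unknown"
  }

  is_data <- grepl("^\\s*[0-9]+\\s+[A-Za-z*]\\s", lines)
  if (!any(is_data)) {
    abort("no PSSM data rows found in input", class = "ppidvm_error_empty")
  }

  rows <- which(is_data)
  scores <- matrix(NA_integer_, length(rows), 20)
  residues <- character(length(rows))
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    # stop at the first non-numeric token after the scores, if any
    if (anyNA(vals)) vals <- vals[seq_len(which(is.na(vals))[1] - 1)]
    if (length(vals) < 20) {
      abort(sprintf("malformed PSSM row at line %d: %d score fields, need 20",
                    rows[i], length(vals)),
            class = "ppidvm_error_format")
    }
    scores[i, ] <- as.integer(round(vals[1:20]))
    residues[i] <- tok[2]
  }
  pssm(scores, protein_id = protein_id, residues = residues)
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the header, column labels and the 20-column log-odds block in the
#' layout of `psiblast -out_ascii_pssm`, so that [read_pssm()] round-trips
#' the score matrix exactly.
#'
#' @param p A [pssm()] object.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_pssm <- function(p, file) {
  stopifnot(inherits(p, "pssm"))
  res <- p$residues
  if (is.null(res)) res <- rep("X", nrow(p$scores))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", PSSM_ALPHABET), collapse = ""))
  ), con)
  for (i in seq_len(nrow(p$scores))) {
    writeLines(sprintf("%5d %s %s", i, res[i],
                       paste(sprintf("%4d", p$scores[i, ]), collapse = "")),
               con)
  }
  writeLines("", con)
  invisible(file)
}

#' Read a protein-pair list
#'
#' Pair lists are tab-separated files with three columns `id_a`, `id_b`,
#' `label` (1 = interacting, 0 = non-interacting); lines starting with `#`
#' are comments.  A header row is optional and detected automatically.
#'
#' @param file Path to the TSV file.
#' @return A tibble with columns `id_a` (chr), `id_b` (chr), `label` (int).
#' @export
read_pair_table <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("pair list contains no records", class = "ppidvm_error_empty")
  }
  if (grepl("^id_a\\b", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(sprintf("pair list row %d does not have 3 tab-separated fields",
                  bad[1]),
          class = "ppidvm_error_format")
  }
  out <- tibble::tibble(
    id_a = vapply(parts, `[[`, "", 1),
    id_b = vapply(parts, `[[`, "", 2),
    label = as.integer(vapply(parts, `[[`, "", 3))
  )
  validate_pair_table(out)
  out
}

#' Write a protein-pair list
#'
#' @param pairs Tibble with columns `id_a`, `id_b`, `label`.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_pair_table <- function(pairs, file) {
  validate_pair_table(pairs)
  writeLines(c("id_a\tid_b\tlabel",
               sprintf("%s\t%s\t%d", pairs$id_a, pairs$id_b, pairs$label)),
             file)
  invisible(file)
}

validate_pair_table <- function(pairs, pssms = NULL) {
  req <- c("id_a", "id_b", "label")
  if (!all(req %in% names(pairs))) {
    abort("pair table needs columns id_a, id_b, label",
          class = "ppidvm_error_format")
  }
  if (!all(pairs$label %in% c(0L, 1L))) {
    abort("pair labels must be 0 (non-interacting) or 1 (interacting)",
          class = "ppidvm_error_format")
  }
  if (!is.null(pssms)) {
    ids <- unique(c(pairs$id_a, pairs$id_b))
    missing <- setdiff(ids, names(pssms))
    if (length(missing) > 0) {
      abort(sprintf("pair table references proteins with no PSSM: %s",
                    paste(head(missing, 5), collapse = ", ")),
            class = "ppidvm_error_format")
    }
  }
  invisible(pairs)
}

#' Read sequence identifiers from a FASTA file
#'
#' Bookkeeping helper only: the pipeline itself consumes PSSMs, not
#' sequences.  Returns the first whitespace-delimited token of each header.
#'
#' @param file Path to a FASTA file.
#' @return Character vector of record identifiers.
#' @export
read_fasta_ids <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta_ids requires the Biostrings package")
  }
  ids <- names(Biostrings::readBStringSet(file))
  sub("\\s.*$", "", ids)
}
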