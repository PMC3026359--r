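## Peptide bookkeeping: protein sequences, peptide placement, sequence
## coverage and exchangeable-amide counting.

#' Protein sequence object
#'
#' @param residues One-letter amino-acid string (standard 20 letters only).
#' @param id Sequence identifier.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(residues, id = "protein") {
  stopifnot(is.character(residues), length(residues) == 1L, nchar(residues) >= 1L)
  residues <- toupper(residues)
  bad <- setdiff(strsplit(residues, "")[[1]], rownames(.AA_COMPOSITION))
  if (length(bad) > 0L) {
    stop("non-standard residue letter(s) in protein '", id, "': ",
         paste(unique(bad), collapse = ", "))
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used unless `id` is given.
#' @param id Optional record name to select.
#' @return A [protein_sequence()].
#' @export
read_protein_fasta <- function(path, id = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  i <- if (is.null(id)) 1L else match(id, nm)
  if (is.na(i)) stop("sequence '", id, "' not found in ", path)
  protein_sequence(as.character(seqs[[i]]), id = nm[i])
}

#' Write a protein sequence to FASTA
#'
#' @param protein A [protein_sequence()].
#' @param path Output file.
#' @export
write_protein_fasta <- function(protein, path) {
  x <- Biostrings::AAStringSet(protein$residues)
  names(x) <- protein$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Locate a peptide on a protein
#'
#' Finds all exact-match occurrences (including overlapping ones).
#'
#' @param peptide_sequence Peptide one-letter string.
#' @param protein A [protein_sequence()] or plain string.
#' @return A data.frame with 1-based inclusive `start`, `end`, sorted by
#'   start; zero rows when absent.
#' @export
locate_peptide <- function(peptide_sequence, protein) {
  stopifnot(nchar(peptide_sequence) >= 1L)
  res <- if (inherits(protein, "protein_sequence")) protein$residues else protein
  m <- gregexpr(paste0("(?=", peptide_sequence, ")"), res, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  data.frame(start = starts, end = starts + nchar(peptide_sequence) - 1L)
}

#' Validate a peptide table against a protein
#'
#' Checks the `start`/`end`/`sequence` consistency invariants for every row.
#'
#' @param peptides data.frame with columns `sequence`, `start`, `end`,
#'   `charge`, `sn_ratio`.
#' @param protein A [protein_sequence()].
#' @return The table, invisibly; errors name the offending peptide.
#' @export
validate_peptides <- function(peptides, protein) {
  needed <- c("sequence", "start", "end", "charge", "sn_ratio")
  missing_cols <- setdiff(needed, names(peptides))
  if (length(missing_cols)) {
    stop("peptide table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    if (p$end - p$start + 1L != nchar(p$sequence)) {
      stop("peptide '", p$sequence, "': range [", p$start, ",", p$end,
           "] does not match its length")
    }
    sub <- substr(protein$residues, p$start, p$end)
    if (sub != toupper(p$sequence)) {
      stop("peptide '", p$sequence, "' does not match protein '",
           protein$id, "' at [", p$start, ",", p$end, "] (found '", sub, "')")
    }
    if (p$charge < 1L) stop("peptide '", p$sequence, "': charge must be >= 1")
  }
  invisible(peptides)
}

#' Sequence coverage of a peptide set
#'
#' @param peptides Peptide table (see [validate_peptides()]), already
#'   validated against `protein`.
#' @param protein A [protein_sequence()].
#' @return A list of class `coverage_mask`: `covered` (per-residue logical)
#'   and `coverage_fraction` (reported to 3 decimals).
#' @export
compute_coverage <- function(peptides, protein) {
  validate_peptides(peptides, protein)
  n <- nchar(protein$residues)
  covered <- logical(n)
  for (i in seq_len(nrow(peptides))) {
    covered[peptides$start[i]:peptides$end[i]] <- TRUE
  }
  structure(list(covered = covered,
                 coverage_fraction = round(sum(covered) / n, 3)),
            class = "coverage_mask")
}

#' @export
print.coverage_mask <- function(x, ...) {
  cat("<coverage_mask> ", sum(x$covered), "/", length(x$covered),
      " residues covered (", 100 * x$coverage_fraction, "%)\n", sep = "")
  invisible(x)
}

#' Count exchangeable backbone amides of a peptide
#'
#' The N-terminal residue's amide back-exchanges too fast to measure and
#' proline has no amide hydrogen; both are excluded.  Setting
#' `exclude_n_term = 2` applies the common alternative of discounting the
#' first two residues.
#'
#' @param peptide_sequence Peptide one-letter string.
#' @param exclude_n_term Number of N-terminal residues excluded (1 or 2).
#' @return Non-negative integer count.
#' @export
count_exchangeable_amides <- function(peptide_sequence, exclude_n_term = 1L) {
  stopifnot(is.character(peptide_sequence), nchar(peptide_sequence) >= 1L,
            exclude_n_term %in% c(1L, 2L))
  aa <- strsplit(toupper(peptide_sequence), "")[[1]]
  idx <- seq_along(aa) > exclude_n_term
  sum(idx & aa != "P")
}

#' Positions of the exchangeable amides within a peptide
#'
#' @inheritParams count_exchangeable_amides
#' @return Integer vector of 1-based positions within the peptide.
#' @keywords internal
exchangeable_positions <- function(peptide_sequence, exclude_n_term = 1L) {
  aa <- strsplit(toupper(peptide_sequence), "")[[1]]
  which(seq_along(aa) > exclude_n_term & aa != "P")
}

#' Read / write the peptide identification table
#'
#' CSV with header `sequence,start,end,charge,sn_ratio`.
#'
#' @param path CSV file.
#' @return data.frame of peptides.
#' @export
read_peptide_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = "sequence", integer = c("start", "end", "charge"),
    numeric = "sn_ratio"))
  needed <- c("sequence", "start", "end", "charge", "sn_ratio")
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols)) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  as.data.frame(dt)
}

#' @rdname read_peptide_table
#' @param peptides Peptide table to write.
#' @export
write_peptide_table <- function(peptides, path) {
  data.table::fwrite(as.data.frame(peptides)[, c("sequence", "start", "end",
                                                 "charge", "sn_ratio")], path)
  invisible(path)
}
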