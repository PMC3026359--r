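## Residue-level projection of peptide differential HDX and PDB B-factor
## recoloring.

#' Project peptide-level differential HDX onto residues
#'
#' Each residue covered by at least one peptide receives the unweighted mean
#' of `delta_hdx_percent` over all covering peptides; residues covered by no
#' peptide are `undetected`.  Peptides that occur more than once in the
#' protein are ambiguous and excluded by default.
#'
#' @param diff A [differential_table()] result.
#' @param protein A [protein_sequence()].
#' @param exclude_ambiguous Drop peptides with multiple exact occurrences
#'   (default `TRUE`).
#' @return List of class `residue_projection`: `value` (per-residue mean
#'   delta, `NA` where undetected), `status` (`"measured"`/`"undetected"`),
#'   `source_peptides` (per-residue character list), `ambiguous` (excluded
#'   peptide sequences).
#' @export
project_to_residues <- function(diff, protein, exclude_ambiguous = TRUE) {
  n <- nchar(protein$residues)
  total <- numeric(n)
  count <- integer(n)
  sources <- vector("list", n)
  ambiguous <- character()
  d <- data.table::as.data.table(diff)
  for (i in seq_len(nrow(d))) {
    if (exclude_ambiguous &&
        nrow(locate_peptide(d$peptide_sequence[i], protein)) > 1L) {
      ambiguous <- c(ambiguous, d$peptide_sequence[i])
      next
    }
    idx <- d$start[i]:d$end[i]
    total[idx] <- total[idx] + d$delta_hdx_percent[i]
    count[idx] <- count[idx] + 1L
    key <- sprintf("%s/+%d", d$peptide_sequence[i], d$charge[i])
    for (r in idx) sources[[r]] <- c(sources[[r]], key)
  }
  value <- ifelse(count > 0L, total / pmax(count, 1L), NA_real_)
  structure(list(value = value,
                 status = ifelse(count > 0L, "measured", "undetected"),
                 source_peptides = sources,
                 ambiguous = unique(ambiguous)),
            class = "residue_projection")
}

#' @export
print.residue_projection <- function(x, ...) {
  cat("<residue_projection> ", sum(x$status == "measured"), "/",
      length(x$value), " residues measured\n", sep = "")
  invisible(x)
}

#' Read a PDB file's ATOM/HETATM records
#'
#' Minimal fixed-column PDB v3.3 reader sufficient for B-factor round trips.
#'
#' @param lines PDB text as a character vector (or a file path).
#' @return data.frame with `line` (index into the text), `record`, `chain`,
#'   `resseq`, `bfactor`.
#' @export
read_pdb_atoms <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(is_atom)
  data.frame(line = idx,
             record = trimws(rec[idx]),
             chain = substr(lines[idx], 22, 22),
             resseq = as.integer(substr(lines[idx], 23, 26)),
             bfactor = as.numeric(substr(lines[idx], 61, 66)))
}

#' Rewrite PDB B-factors from a residue projection
#'
#' Replaces the B-factor column (61-66, fixed width, 2 decimals) of every
#' ATOM/HETATM record of the selected chain with the residue's projected
#' value; undetected residues receive `sentinel`.  All other bytes are
#' preserved.
#'
#' @param lines PDB text (character vector or file path).
#' @param chain Chain identifier.
#' @param projection A [residue_projection()].
#' @param sentinel B-factor written for undetected residues (default 0).
#' @param offset Added to projection residue indices to obtain PDB `resSeq`
#'   numbers (default 0).
#' @return Character vector of PDB lines; attribute `"unmatched"` lists
#'   projected residues absent from the PDB chain (also raised as a
#'   warning).
#' @export
write_bfactor_pdb <- function(lines, chain, projection, sentinel = 0,
                              offset = 0L) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  atoms <- read_pdb_atoms(lines)
  atoms <- atoms[atoms$chain == chain, ]
  if (nrow(atoms) == 0L) stop("chain '", chain, "' not found in PDB")
  res_idx <- seq_along(projection$value)
  pdb_num <- res_idx + offset
  value <- ifelse(projection$status == "measured", projection$value, sentinel)
  measured <- which(projection$status == "measured")
  unmatched <- measured[!(pdb_num[measured] %in% atoms$resseq)]
  if (length(unmatched)) {
    warning("projected residues absent from PDB chain ", chain, ": ",
            paste(unmatched, collapse = ", "))
  }
  m <- match(atoms$resseq, pdb_num)
  newb <- ifelse(is.na(m), sentinel, value[m])
  for (j in seq_len(nrow(atoms))) {
    ln <- lines[atoms$line[j]]
    substr(ln, 61, 66) <- sprintf("%6.2f", newb[j])
    lines[atoms$line[j]] <- ln
  }
  attr(lines, "unmatched") <- unmatched
  lines
}

#' Write the residue projection sidecar CSV
#'
#' Columns `residue,delta,status`; undetected residues have an empty delta.
#'
#' @param projection A [residue_projection()].
#' @param path Output CSV.
#' @export
write_projection_csv <- function(projection, path) {
  data.table::fwrite(data.frame(residue = seq_along(projection$value),
                                delta = projection$value,
                                status = projection$status), path)
  invisible(path)
}
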