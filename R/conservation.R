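## Alignment-column conservation and its relation to HDX protection.

#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Clustal, via Biostrings.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`; guessed from the extension when
#'   missing.
#' @return Named character vector of aligned (gapped) sequences.
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(aln|clustal|clw)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in width")
  seqs
}

#' Column conservation profile of an alignment
#'
#' Per column, the conservation score is the frequency of the modal non-gap
#' symbol among all sequences (all-gap columns score 0); with
#' `method = "entropy"`, 1 minus the normalized Shannon entropy of the
#' non-gap symbols.  Columns gapped in the reference sequence are unmapped.
#'
#' @param alignment Named character vector of aligned sequences
#'   (see [read_alignment()]).
#' @param reference_id Name of the reference sequence.
#' @param method `"modal"` (default) or `"entropy"`.
#' @return List of class `conservation_profile`: `score` (per column),
#'   `column_to_residue` (per column, 1-based residue index in the ungapped
#'   reference, `NA` where the reference is gapped), `residue_score`
#'   (scores indexed by reference residue).
#' @export
column_conservation <- function(alignment, reference_id,
                                method = c("modal", "entropy")) {
  method <- match.arg(method)
  if (!reference_id %in% names(alignment)) {
    stop("reference '", reference_id, "' absent from alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  nseq <- nrow(mat)
  gap <- mat %in% c("-", ".")
  dim(gap) <- dim(mat)
  score <- vapply(seq_len(ncol(mat)), function(j) {
    sym <- mat[!gap[, j], j]
    if (length(sym) == 0L) return(0)
    tab <- table(sym)
    if (method == "modal") {
      max(tab) / nseq
    } else {
      p <- tab / sum(tab)
      h <- -sum(p * log(p))
      hmax <- log(20)
      1 - h / hmax
    }
  }, numeric(1))
  ref <- mat[match(reference_id, names(alignment)), ]
  is_res <- !(ref %in% c("-", "."))
  column_to_residue <- rep(NA_integer_, ncol(mat))
  column_to_residue[is_res] <- seq_len(sum(is_res))
  residue_score <- score[is_res]
  structure(list(score = score, column_to_residue = column_to_residue,
                 residue_score = residue_score),
            class = "conservation_profile")
}

#' Conservation versus protection report
#'
#' Spearman rank correlation between per-residue conservation and projected
#' differential HDX over residues that are both measured and mapped, plus a
#' per-peptide table of mean conservation against delta HDX.
#'
#' @param projection A [residue_projection()].
#' @param profile A [column_conservation()] profile for the same protein.
#' @param diff Optional [differential_table()] for the per-peptide table.
#' @param min_overlap Minimum number of usable residues (default 5).
#' @return List of class `conservation_report`: `rho`, `p_value`,
#'   `n_residues`, `flag` (`"ok"`, `"untestable"`), `per_peptide`
#'   (data.frame or `NULL`).
#' @export
conservation_protection_report <- function(projection, profile, diff = NULL,
                                           min_overlap = 5L) {
  n <- min(length(projection$value), length(profile$residue_score))
  delta <- projection$value[seq_len(n)]
  cons <- profile$residue_score[seq_len(n)]
  use <- projection$status[seq_len(n)] == "measured" & !is.na(cons)
  per_peptide <- NULL
  if (!is.null(diff)) {
    d <- data.table::as.data.table(diff)
    per_peptide <- data.frame(
      peptide = d$peptide_sequence, start = d$start, end = d$end,
      mean_conservation = vapply(seq_len(nrow(d)), function(i) {
        idx <- d$start[i]:d$end[i]
        idx <- idx[idx <= length(profile$residue_score)]
        mean(profile$residue_score[idx])
      }, numeric(1)),
      delta_hdx_percent = d$delta_hdx_percent)
  }
  if (sum(use) < min_overlap || stats::sd(cons[use]) == 0 ||
      stats::sd(delta[use]) == 0) {
    return(structure(list(rho = NA_real_, p_value = NA_real_,
                          n_residues = sum(use), flag = "untestable",
                          per_peptide = per_peptide),
                     class = "conservation_report"))
  }
  ct <- suppressWarnings(stats::cor.test(cons[use], delta[use],
                                         method = "spearman"))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_residues = sum(use), flag = "ok",
                 per_peptide = per_peptide),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  if (x$flag == "untestable") {
    cat("<conservation_report> untestable (", x$n_residues,
        " usable residues)\n", sep = "")
  } else {
    cat(sprintf("<conservation_report> Spearman rho = %.3f (p = %.3g, n = %d)\n",
                x$rho, x$p_value, x$n_residues))
  }
  invisible(x)
}
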