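## One-command orchestration: validation, uptake, differential statistics,
## structure overlay and conservation report, driven by a single config.

#' Default experiment design / pipeline configuration
#'
#' @param timepoints Exchange times in seconds, strictly increasing, first 0.
#' @param conditions Condition labels; the first is the apo reference.
#' @param sn_threshold Retain peptides with S/N strictly above this.
#' @param last_k Late timepoints entering the differential test.
#' @param alpha Significance level.
#' @param correction A [correction_params()] (or plain list of its fields).
#' @param shared_reference Share the time-0 centroid across conditions.
#' @param exclude_n_term Exchangeable-amide rule (1 or 2).
#' @param basis Differential test basis, `"centroid"` or `"uptake"`.
#' @param chain PDB chain for the overlay.
#' @param pdb_offset Residue-number offset between analysis numbering and
#'   the PDB `resSeq` column.
#' @param sentinel B-factor written for undetected residues.
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(timepoints = c(0, 60, 240, 960, 1920, 3840),
                              conditions = c("apo", "xylohexaose", "xylan"),
                              sn_threshold = 3, last_k = 3L, alpha = 0.05,
                              correction = correction_params(),
                              shared_reference = TRUE, exclude_n_term = 1L,
                              basis = "centroid", chain = "A",
                              pdb_offset = 0L, sentinel = 0) {
  stopifnot(length(timepoints) >= 2L, timepoints[1] == 0,
            all(diff(timepoints) > 0),
            last_k <= sum(timepoints > 0), last_k >= 2L,
            alpha > 0, alpha < 1, length(conditions) >= 2L)
  if (!inherits(correction, "correction_params")) {
    correction <- do.call(correction_params, as.list(correction))
  }
  structure(list(timepoints = timepoints, conditions = conditions,
                 sn_threshold = sn_threshold, last_k = as.integer(last_k),
                 alpha = alpha, correction = correction,
                 shared_reference = shared_reference,
                 exclude_n_term = as.integer(exclude_n_term), basis = basis,
                 chain = chain, pdb_offset = as.integer(pdb_offset),
                 sentinel = sentinel),
            class = "experiment_design")
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys take [experiment_design()]
#' defaults.
#'
#' @param path Config file (`.json`, `.yaml`/`.yml`).
#' @return An [experiment_design()].
#' @export
read_design <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(experiment_design))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(experiment_design, cfg)
}

#' Validate a pipeline input directory
#'
#' Expects `peaks.csv`, `peptides.csv` and `protein.fasta` under `input_dir`
#' and reports (never throws on content problems): missing design cells,
#' malformed peak rows, and peptides inconsistent with the FASTA.
#'
#' @param input_dir Input directory.
#' @param design An [experiment_design()].
#' @return List of class `validation_report`: `findings` (data.frame of
#'   `severity`, `where`, `message`) and `status` (0 clean, 1 warnings,
#'   2 errors).
#' @export
validate_inputs <- function(input_dir, design = experiment_design()) {
  findings <- list()
  note <- function(severity, where, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, where = where, message = message)
  }
  paths <- file.path(input_dir, c("peaks.csv", "peptides.csv", "protein.fasta"))
  names(paths) <- basename(paths)
  for (p in names(paths)) {
    if (!file.exists(paths[p])) note("error", p, "file missing")
  }
  if (!file.exists(paths["protein.fasta"]) ||
      !file.exists(paths["peptides.csv"]) ||
      !file.exists(paths["peaks.csv"])) {
    f <- data.table::rbindlist(findings)
    return(structure(list(findings = f, status = 2L),
                     class = "validation_report"))
  }
  protein <- read_protein_fasta(paths["protein.fasta"])
  peptides <- read_peptide_table(paths["peptides.csv"])
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    hit <- substr(protein$residues, p$start, p$end)
    if (p$end - p$start + 1L != nchar(p$sequence) ||
        hit != toupper(p$sequence)) {
      note("error", sprintf("peptides.csv row %d", i),
           sprintf("peptide '%s' does not match FASTA at [%d,%d]",
                   p$sequence, p$start, p$end))
    }
  }
  peaks <- read_peaks(paths["peaks.csv"])
  bad_int <- which(!is.finite(peaks$intensity) | peaks$intensity < 0)
  for (i in bad_int) {
    note("error", sprintf("peaks.csv row %d", i),
         sprintf("negative or non-finite intensity %g", peaks$intensity[i]))
  }
  bad_mz <- which(!is.finite(peaks$mz) | peaks$mz <= 0)
  for (i in bad_mz) {
    note("error", sprintf("peaks.csv row %d", i),
         sprintf("invalid m/z %g", peaks$mz[i]))
  }
  # completeness of the design grid
  have <- unique(peaks[, c("peptide_sequence", "charge", "condition",
                           "time_s", "replicate")])
  reps <- sort(unique(peaks$replicate))
  want <- expand.grid(i = seq_len(nrow(peptides)),
                      condition = design$conditions,
                      time_s = design$timepoints, replicate = reps,
                      stringsAsFactors = FALSE)
  key <- function(seq, z, cond, t, r) paste(seq, z, cond, t, r, sep = "|")
  have_keys <- key(have$peptide_sequence, have$charge, have$condition,
                   have$time_s, have$replicate)
  want_keys <- key(peptides$sequence[want$i], peptides$charge[want$i],
                   want$condition, want$time_s, want$replicate)
  missing_cells <- setdiff(want_keys, have_keys)
  for (k in missing_cells) {
    note("warning", "peaks.csv", paste("missing cluster for cell", k))
  }
  f <- if (length(findings)) data.table::rbindlist(findings) else
    data.frame(severity = character(), where = character(),
               message = character())
  status <- if (any(f$severity == "error")) 2L else
    if (nrow(f) > 0L) 1L else 0L
  structure(list(findings = as.data.frame(f), status = status),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> status ", x$status, ", ", nrow(x$findings),
      " finding(s)\n", sep = "")
  invisible(x)
}

#' Run the full HDX analysis pipeline
#'
#' Chains validation, centroiding/uptake, differential statistics per holo
#' condition, residue projection, optional PDB overlay (if
#' `structure.pdb` exists under `input_dir`) and optional conservation
#' report (if `alignment.fasta` exists).  All outputs are written under
#' `output_dir` together with the resolved configuration and a JSON run
#' manifest; the run is deterministic given inputs and design.
#'
#' @param input_dir Directory with `peaks.csv`, `peptides.csv`,
#'   `protein.fasta` and optionally `structure.pdb`, `alignment.fasta`.
#' @param output_dir Output directory (created; partial outputs are removed
#'   on failure).
#' @param design An [experiment_design()] or a path to a config file.
#' @return List of class `hdx_report`: `summary`, `uptake`, `differential`
#'   (per holo condition), `projection` (per holo condition),
#'   `conservation` (or `NULL`), `validation`.
#' @export
run_pipeline <- function(input_dir, output_dir, design = experiment_design()) {
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(design, "experiment_design"))
  val <- validate_inputs(input_dir, design)
  if (val$status == 2L) {
    stop("input validation failed:\n",
         paste(utils::head(val$findings$message, 10), collapse = "\n"))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(output_dir, recursive = TRUE), add = TRUE)

  protein <- read_protein_fasta(file.path(input_dir, "protein.fasta"))
  peptides <- read_peptide_table(file.path(input_dir, "peptides.csv"))
  peaks <- read_peaks(file.path(input_dir, "peaks.csv"))

  uptake <- build_uptake_curves(peaks, peptides, design$correction,
                                sn_threshold = design$sn_threshold,
                                shared_reference = design$shared_reference,
                                exclude_n_term = design$exclude_n_term)
  write_uptake_csv(uptake, file.path(output_dir, "uptake.csv"))

  apo <- design$conditions[1]
  holo_conditions <- setdiff(design$conditions, apo)
  differential <- list()
  projection <- list()
  for (holo in holo_conditions) {
    d <- differential_table(uptake, apo = apo, holo = holo,
                            alpha = design$alpha, last_k = design$last_k,
                            basis = design$basis)
    differential[[holo]] <- d
    write_differential_csv(d, file.path(output_dir,
                                        sprintf("differential_%s.csv", holo)))
    pr <- project_to_residues(d, protein)
    projection[[holo]] <- pr
    write_projection_csv(pr, file.path(output_dir,
                                       sprintf("projection_%s.csv", holo)))
    pdb_path <- file.path(input_dir, "structure.pdb")
    if (file.exists(pdb_path)) {
      recolored <- write_bfactor_pdb(pdb_path, design$chain, pr,
                                     sentinel = design$sentinel,
                                     offset = design$pdb_offset)
      writeLines(recolored, file.path(output_dir,
                                      sprintf("overlay_%s.pdb", holo)))
    }
  }

  conservation <- NULL
  aln_path <- file.path(input_dir, "alignment.fasta")
  if (file.exists(aln_path) && length(holo_conditions) > 0L) {
    aln <- read_alignment(aln_path)
    profile <- column_conservation(aln, protein$id)
    conservation <- conservation_protection_report(
      projection[[holo_conditions[1]]], profile,
      diff = differential[[holo_conditions[1]]])
    data.table::fwrite(data.frame(residue = seq_along(profile$residue_score),
                                  conservation = profile$residue_score),
                       file.path(output_dir, "conservation.csv"))
  }

  coverage <- compute_coverage(peptides, protein)
  retained <- unique(uptake$points[, c("peptide_sequence", "charge")])
  summary <- list(
    n_peptides_input = nrow(peptides),
    n_peptide_ions_retained = nrow(retained),
    n_excluded = nrow(uptake$excluded),
    coverage_fraction_all = coverage$coverage_fraction,
    coverage_fraction_retained = compute_coverage(
      peptides[peptides$sequence %in% retained$peptide_sequence, , drop = FALSE],
      protein)$coverage_fraction,
    grand_mean_uptake_apo = summarize_hdx(uptake, conditions = apo)$grand_mean)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hdxprodyn")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_dir = normalizePath(input_dir),
    design = .design_as_list(design),
    summary = summary,
    validation_findings = nrow(val$findings))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.design_as_list(design),
                       file.path(output_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- c(
    sprintf("[%s] hdxprodyn pipeline", manifest$timestamp),
    sprintf("input: %s", manifest$input_dir),
    sprintf("peptides: %d in, %d ion(s) retained, %d excluded",
            summary$n_peptides_input, summary$n_peptide_ions_retained,
            summary$n_excluded),
    sprintf("coverage: %.1f%% (all), %.1f%% (retained)",
            100 * summary$coverage_fraction_all,
            100 * summary$coverage_fraction_retained),
    sprintf("grand mean apo uptake: %.1f%%", summary$grand_mean_uptake_apo))
  writeLines(log_lines, file.path(output_dir, "run.log"))
  ok <- TRUE
  structure(list(summary = summary, uptake = uptake,
                 differential = differential, projection = projection,
                 conservation = conservation, validation = val),
            class = "hdx_report")
}

.design_as_list <- function(design) {
  d <- unclass(design)
  d$correction <- unclass(d$correction)
  d
}

#' @export
print.hdx_report <- function(x, ...) {
  s <- x$summary
  cat("<hdx_report>\n",
      sprintf("  peptides: %d in, %d ion(s) retained, %d excluded\n",
              s$n_peptides_input, s$n_peptide_ions_retained, s$n_excluded),
      sprintf("  coverage: %.1f%% (all) / %.1f%% (retained)\n",
              100 * s$coverage_fraction_all,
              100 * s$coverage_fraction_retained),
      sprintf("  grand mean apo uptake: %.1f%%\n", s$grand_mean_uptake_apo),
      sep = "")
  for (holo in names(x$differential)) {
    d <- x$differential[[holo]]
    cat(sprintf("  %s: %d protected, %d destabilized, %d not significant\n",
                holo, sum(d$classification == "protected"),
                sum(d$classification == "destabilized"),
                sum(d$classification == "not_significant")))
  }
  invisible(x)
}
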