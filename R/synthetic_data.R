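## Simulator for complete HDX experiments with known ground truth.
##
## Generative model: every exchangeable backbone amide exchanges with
## first-order kinetics at its intrinsic rate divided by a regional
## protection factor, up to the buffer D2O fraction.  Back-exchange is an
## independent per-deuteron retention event with probability `recovery`.
## The observed isotopic cluster is the natural envelope (exact elemental
## composition) convolved with the Poisson-binomial deuterium-count
## distribution, with multiplicative lognormal intensity noise.

#' Ground truth for a simulated HDX experiment
#'
#' @param protein A [protein_sequence()].
#' @param regions data.frame with 1-based inclusive `start`, `end` columns
#'   tiling the sequence without overlap, plus one protection-factor column
#'   `pf_<condition>` (>= 1) per condition.
#' @param residue_rates Per-residue intrinsic rates (per second), length
#'   equal to the protein; if `NULL`, sampled log-uniformly over
#'   `model$intrinsic_rate_range` using `seed`.
#' @param model An [exchange_model()].
#' @param seed Integer seed used when sampling rates.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(protein, regions, residue_rates = NULL,
                            model = exchange_model(), seed = 1L) {
  n <- nchar(protein$residues)
  regions <- as.data.frame(regions)
  stopifnot(all(c("start", "end") %in% names(regions)))
  regions <- regions[order(regions$start), , drop = FALSE]
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != n ||
      (nrow(regions) > 1L &&
       any(regions$start[-1] != regions$end[-nrow(regions)] + 1L))) {
    stop("regions must tile residues 1..", n, " without gaps or overlap")
  }
  pf_cols <- grep("^pf_", names(regions), value = TRUE)
  if (length(pf_cols) == 0L) stop("regions need at least one pf_<condition> column")
  if (any(as.matrix(regions[pf_cols]) < 1)) stop("protection factors must be >= 1")
  if (is.null(residue_rates)) {
    set.seed(seed)
    lo <- log(model$intrinsic_rate_range[1])
    hi <- log(model$intrinsic_rate_range[2])
    residue_rates <- exp(stats::runif(n, lo, hi))
  }
  stopifnot(length(residue_rates) == n, all(residue_rates > 0))
  structure(list(protein_id = protein$id, sequence = protein$residues,
                 regions = regions, residue_rates = residue_rates,
                 conditions = sub("^pf_", "", pf_cols), seed = seed),
            class = "synthetic_truth")
}

#' Per-residue protection factors for a condition
#'
#' @param truth A [synthetic_truth()].
#' @param condition Condition label; must have a `pf_<condition>` column.
#' @return Numeric vector, one protection factor per residue.
#' @export
residue_protection <- function(truth, condition) {
  col <- paste0("pf_", condition)
  if (!col %in% names(truth$regions)) {
    stop("no protection factors defined for condition '", condition, "'")
  }
  n <- nchar(truth$sequence)
  pf <- numeric(n)
  for (i in seq_len(nrow(truth$regions))) {
    pf[truth$regions$start[i]:truth$regions$end[i]] <- truth$regions[[col]][i]
  }
  pf
}

#' Ground-truth mean fractional deuteration of a peptide
#'
#' The quantity the corrected uptake percentage estimates: the mean over the
#' peptide's exchangeable amides of 1 - exp(-(k_i / P_i) t), i.e. fractional
#' exchange relative to full saturation (the buffer-fraction and recovery
#' losses cancel under the analysis correction).
#'
#' @param peptide One row of a peptide table (`sequence`, `start`, `end`).
#' @param truth A [synthetic_truth()].
#' @param condition Condition label.
#' @param time Labeling time, seconds.
#' @param exclude_n_term Passed to [exchangeable_positions()].
#' @return Fraction in \[0, 1\] (multiply by 100 for percent).
#' @export
truth_mean_deuteration <- function(peptide, truth, condition, time,
                                   exclude_n_term = 1L) {
  pos <- exchangeable_positions(peptide$sequence, exclude_n_term)
  if (length(pos) == 0L) return(0)
  gpos <- peptide$start + pos - 1L
  k <- truth$residue_rates[gpos]
  pf <- residue_protection(truth, condition)[gpos]
  mean(1 - exp(-(k / pf) * time))
}

#' Simulate one isotopic cluster
#'
#' @param peptide One row of a peptide table (`sequence`, `start`, `end`,
#'   `charge`, `sn_ratio`); `start`/`end` must match the truth's sequence.
#' @param truth A [synthetic_truth()].
#' @param time Labeling time, seconds.
#' @param condition Condition label (needs protection factors in the truth).
#' @param model An [exchange_model()].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   intensity noise; 0 disables noise.
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @param base_intensity Intensity of the tallest peak before noise.
#' @param exclude_n_term Exchangeable-amide rule (see
#'   [count_exchangeable_amides()]).
#' @param tol Relative abundance threshold below which peaks are dropped.
#' @return data.frame of peaks: `mz` (strictly increasing), `intensity`.
#' @export
simulate_peptide_cluster <- function(peptide, truth, time, condition,
                                     model = exchange_model(), noise_cv = 0.05,
                                     seed = NULL, base_intensity = 1e6,
                                     exclude_n_term = 1L, tol = 1e-10) {
  seq <- toupper(peptide$sequence)
  sub <- substr(truth$sequence, peptide$start, peptide$end)
  if (sub != seq) {
    stop("peptide '", seq, "' not found at [", peptide$start, ",",
         peptide$end, "] of protein '", truth$protein_id, "'")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- peptide$charge
  nat <- natural_envelope(peptide_composition(seq))
  pos <- exchangeable_positions(seq, exclude_n_term)
  if (length(pos) > 0L && time > 0) {
    gpos <- peptide$start + pos - 1L
    p <- simulate_residue_deuteration(truth$residue_rates[gpos],
                                      residue_protection(truth, condition)[gpos],
                                      time, model) * model$recovery
    ddist <- poisson_binomial(p)
  } else {
    ddist <- 1
  }
  # convolve natural envelope with the deuterium-count distribution,
  # aggregating by total nominal shift (unit-resolution instrument)
  nmax <- max(nat$shift) + length(ddist) - 1L
  prob <- numeric(nmax + 1L)
  pmass <- numeric(nmax + 1L)
  for (d in seq_along(ddist) - 1L) {
    if (ddist[d + 1L] <= 0) next
    idx <- nat$shift + d + 1L
    w <- nat$prob * ddist[d + 1L]
    prob[idx] <- prob[idx] + w
    pmass[idx] <- pmass[idx] + w * (nat$mass_shift + d * model$deuterium_mass_shift)
  }
  keep <- prob > tol * max(prob)
  shift_mass <- pmass[keep] / prob[keep]
  mono <- molecular_mass(seq, "monoisotopic")
  mz <- (mono + shift_mass) / z + .PROTON_MASS
  intensity <- prob[keep] / max(prob[keep]) * base_intensity
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    intensity <- intensity * stats::rlnorm(length(intensity),
                                           meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(mz = mz, intensity = intensity)
}

#' Random protein sequence
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @param id Sequence identifier.
#' @return A [protein_sequence()].
#' @export
synthetic_protein <- function(length = 190L, seed = 1L, id = "synthetic_xyn") {
  set.seed(seed)
  protein_sequence(paste(sample(rownames(.AA_COMPOSITION), length,
                                replace = TRUE), collapse = ""), id = id)
}

#' Random pepsin-style peptide map
#'
#' Draws overlapping peptides of realistic lengths along the protein,
#' emulating a nonspecific pepsin digest, with lognormal signal-to-noise
#' ratios so that a fraction of peptides falls below a typical S/N filter.
#'
#' @param protein A [protein_sequence()].
#' @param n_peptides Number of peptides.
#' @param length_range Min/max peptide length.
#' @param charge_range Min/max charge state.
#' @param sn_meanlog,sn_sdlog Lognormal S/N parameters.
#' @param seed Integer seed.
#' @return Peptide table (`sequence,start,end,charge,sn_ratio`).
#' @export
synthetic_peptide_map <- function(protein, n_peptides = 57L,
                                  length_range = c(8L, 20L),
                                  charge_range = c(1L, 3L),
                                  sn_meanlog = log(6), sn_sdlog = 0.8,
                                  seed = 1L) {
  set.seed(seed)
  n <- nchar(protein$residues)
  len <- sample(length_range[1]:length_range[2], n_peptides, replace = TRUE)
  start <- vapply(len, function(l) sample.int(n - l + 1L, 1L), integer(1))
  end <- start + len - 1L
  peptides <- data.frame(
    sequence = substring(protein$residues, start, end),
    start = start, end = end,
    charge = sample(charge_range[1]:charge_range[2], n_peptides, replace = TRUE),
    sn_ratio = round(stats::rlnorm(n_peptides, sn_meanlog, sn_sdlog), 2))
  peptides <- peptides[order(peptides$start, peptides$end), ]
  rownames(peptides) <- NULL
  peptides
}

#' Default ground-truth regions
#'
#' Tiles the sequence into `n_regions` equal blocks.  The apo state is
#' unprotected everywhere; a soluble-ligand condition strongly protects two
#' blocks (the binding groove and an adjacent loop in the emulated system)
#' and a polymeric-ligand condition weakly protects one, mirroring a
#' soluble-oligosaccharide versus insoluble-polymer binding contrast.
#'
#' @param n_residues Protein length.
#' @param n_regions Number of equal regions.
#' @param conditions Condition labels; the first is taken as apo (all 1).
#' @return Regions data.frame suitable for [synthetic_truth()].
#' @export
default_truth_regions <- function(n_residues, n_regions = 6L,
                                  conditions = c("apo", "xylohexaose", "xylan")) {
  bounds <- floor(seq(0L, n_residues, length.out = n_regions + 1L))
  regions <- data.frame(start = bounds[-length(bounds)] + 1L,
                        end = bounds[-1L])
  for (cond in conditions) regions[[paste0("pf_", cond)]] <- 1
  if (length(conditions) >= 2L) {
    regions[[paste0("pf_", conditions[2])]][c(2L, 4L)] <- c(8, 5)
  }
  if (length(conditions) >= 3L) {
    regions[[paste0("pf_", conditions[3])]][2L] <- 2.5
  }
  regions
}

#' Generate a complete synthetic HDX experiment
#'
#' @param protein A [protein_sequence()]; default is a random 190-residue
#'   sequence from `seed`.
#' @param peptides Peptide table; default from [synthetic_peptide_map()].
#' @param regions Ground-truth regions; default [default_truth_regions()].
#' @param residue_rates Optional fixed per-residue intrinsic rates; by
#'   default sampled from `seed`.  Pass explicit rates to replicate an
#'   experiment (new measurement noise, same underlying kinetics).
#' @param conditions Condition labels (first = apo reference).
#' @param timepoints Exchange times in seconds; must start at 0.
#' @param replicates Replicate measurements per cell.
#' @param model An [exchange_model()].
#' @param noise_cv Intensity noise CV.
#' @param seed Integer seed governing all randomness.
#' @param exclude_n_term Exchangeable-amide rule.
#' @return An object of class `simulated_experiment`: `clusters` (long peak
#'   table), `peptides`, `protein`, `truth`, `design`.
#' @export
generate_experiment <- function(protein = NULL, peptides = NULL,
                                regions = NULL, residue_rates = NULL,
                                conditions = c("apo", "xylohexaose", "xylan"),
                                timepoints = c(0, 60, 240, 960, 1920, 3840),
                                replicates = 1L,
                                model = exchange_model(), noise_cv = 0.05,
                                seed = 1L, exclude_n_term = 1L) {
  stopifnot(length(timepoints) >= 2L, timepoints[1] == 0,
            all(diff(timepoints) > 0), replicates >= 1L)
  if (is.null(protein)) protein <- synthetic_protein(seed = seed)
  if (is.null(regions)) {
    regions <- default_truth_regions(nchar(protein$residues),
                                     conditions = conditions)
  }
  missing_pf <- setdiff(paste0("pf_", conditions), names(regions))
  if (length(missing_pf)) {
    stop("regions lack protection columns: ", paste(missing_pf, collapse = ", "))
  }
  truth <- synthetic_truth(protein, regions, residue_rates = residue_rates,
                           model = model, seed = seed)
  if (is.null(peptides)) peptides <- synthetic_peptide_map(protein, seed = seed)
  validate_peptides(peptides, protein)
  set.seed(seed)
  cells <- expand.grid(pep = seq_len(nrow(peptides)), condition = conditions,
                       time_s = timepoints, replicate = seq_len(replicates),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$pep, cells$condition, cells$time_s,
                       cells$replicate), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- peptides[cells$pep[i], ]
    peaks <- simulate_peptide_cluster(p, truth, cells$time_s[i],
                                      cells$condition[i], model = model,
                                      noise_cv = noise_cv, seed = NULL,
                                      exclude_n_term = exclude_n_term)
    out[[i]] <- data.table::data.table(
      peptide_sequence = p$sequence, charge = p$charge,
      condition = cells$condition[i], time_s = cells$time_s[i],
      replicate = cells$replicate[i], mz = peaks$mz,
      intensity = peaks$intensity, sn_ratio = p$sn_ratio)
  }
  clusters <- data.table::rbindlist(out)
  design <- list(conditions = conditions, timepoints = timepoints,
                 replicates = replicates, noise_cv = noise_cv, seed = seed,
                 exclude_n_term = exclude_n_term,
                 model = unclass(model))
  structure(list(clusters = clusters, peptides = peptides, protein = protein,
                 truth = truth, design = design),
            class = "simulated_experiment")
}

#' @export
print.simulated_experiment <- function(x, ...) {
  cat("<simulated_experiment> ", nrow(x$peptides), " peptides x ",
      length(x$design$conditions), " conditions x ",
      length(x$design$timepoints), " timepoints x ",
      x$design$replicates, " replicate(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Emits `peaks.csv` (one row per peak), `peptides.csv`, `protein.fasta`,
#' `truth.json` and `design.json` under `dir`.
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(experiment$clusters, file.path(dir, "peaks.csv"))
  write_peptide_table(experiment$peptides, file.path(dir, "peptides.csv"))
  write_protein_fasta(experiment$protein, file.path(dir, "protein.fasta"))
  tr <- experiment$truth
  jsonlite::write_json(
    list(protein_id = tr$protein_id, regions = tr$regions,
         residue_rates = tr$residue_rates, seed = tr$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(experiment$design, file.path(dir, "design.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

#' Synthetic C-alpha-trace PDB text
#'
#' Builds a minimal PDB v3.3 file (one CA atom per residue on a spiral) for
#' a protein sequence.  This is a synthetic stand-in for a crystal
#' structure, for exercising B-factor projection; it has no structural
#' meaning.
#'
#' @param protein A [protein_sequence()].
#' @param chain Chain identifier.
#' @param bfactor Initial B-factor for every atom.
#' @return Character vector of PDB lines.
#' @export
synthetic_pdb <- function(protein, chain = "A", bfactor = 20) {
  aa <- strsplit(protein$residues, "")[[1]]
  n <- length(aa)
  i <- seq_len(n)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, .AA3[aa], chain, i,
    5 * cos(i / 3), 5 * sin(i / 3), 1.5 * i, 1.00, bfactor)
  c(sprintf("HEADER    SYNTHETIC CA TRACE (%s)", protein$id), lines, "END")
}
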