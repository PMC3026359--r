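## Centroiding and back-exchange-corrected deuterium uptake.
##
## The deuteration level of a peptide ion is
##   D% = 100 * (m/z(P) - m/z(N)) / (m/z(F) - m/z(N)) / (recovery * f_D2O)
## where m/z(P), m/z(N) and m/z(F) are the centroids of the partially
## deuterated, nondeuterated and fully deuterated peptide.  m/z(F) is
## computed from the theoretical full-exchange shift unless a measured
## fully-deuterated control is supplied, in which case only the
## buffer-fraction part of the correction applies.

#' Correction parameters for deuterium uptake
#'
#' @param recovery Deuterium recovery after back-exchange (default 0.70).
#' @param buffer_d_fraction D2O fraction of the labeling buffer (default
#'   0.80).
#' @param deuterium_mass_shift Da per deuterium (default 1.00628).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(recovery = 0.70, buffer_d_fraction = 0.80,
                              deuterium_mass_shift = 1.00628) {
  stopifnot(recovery > 0, recovery <= 1, buffer_d_fraction > 0,
            buffer_d_fraction <= 1, deuterium_mass_shift > 0)
  structure(list(recovery = recovery, buffer_d_fraction = buffer_d_fraction,
                 deuterium_mass_shift = deuterium_mass_shift),
            class = "correction_params")
}

#' Intensity-weighted centroid of an isotopic cluster
#'
#' @param mz Peak m/z values (Th).
#' @param intensity Non-negative peak intensities; at least one must be
#'   positive.
#' @return The weighted mean m/z.
#' @export
centroid <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L)
  if (any(intensity < 0)) stop("negative peak intensity")
  s <- sum(intensity)
  if (s <= 0) stop("cluster has no positive-intensity peak")
  sum(mz * intensity) / s
}

#' Theoretical fully-deuterated centroid
#'
#' The 100%-exchange reference: the nondeuterated centroid shifted by one
#' deuterium mass per exchangeable amide, divided by charge.
#'
#' @param c_N Nondeuterated centroid (Th).
#' @param n_exch Number of exchangeable amides (>= 0).
#' @param charge Charge state (>= 1).
#' @param params A [correction_params()].
#' @return m/z(F) in Th.
#' @export
fully_deuterated_centroid <- function(c_N, n_exch, charge,
                                      params = correction_params()) {
  stopifnot(n_exch >= 0, charge >= 1)
  c_N + n_exch * params$deuterium_mass_shift / charge
}

#' Back-exchange-corrected deuteration level
#'
#' Raw fractional shift r = (c_P - c_N)/(c_F - c_N), corrected for deuterium
#' recovery and buffer D2O content.  Corrected values in (100, 105] are
#' clamped to 100 and flagged; values above 105 indicate a broken reference
#' and raise an error; negative values are floored at 0 and flagged.
#'
#' @param c_P Partially deuterated centroid (Th).
#' @param c_N Nondeuterated centroid (Th).
#' @param c_F Fully deuterated centroid (Th); must exceed `c_N`.
#' @param params A [correction_params()].
#' @param measured_full Set `TRUE` when `c_F` comes from a measured
#'   fully-deuterated control, which already embodies the back-exchange
#'   loss: only the buffer-fraction correction is then applied.
#' @return Named list: `percent` (0-100) and `flag` (`"ok"`, `"clamped"`,
#'   `"floored"`).
#' @export
deuteration_level <- function(c_P, c_N, c_F, params = correction_params(),
                              measured_full = FALSE) {
  if (c_F <= c_N) stop("degenerate reference: c_F must exceed c_N")
  divisor <- if (measured_full) params$buffer_d_fraction else
    params$recovery * params$buffer_d_fraction
  pct <- 100 * (c_P - c_N) / (c_F - c_N) / divisor
  flag <- "ok"
  if (pct > 100 && pct <= 100 + 1e-7) pct <- 100  # floating-point guard
  if (pct > 105) {
    stop(sprintf("corrected deuteration %.1f%% exceeds 105%%: broken reference",
                 pct))
  } else if (pct > 100) {
    pct <- 100; flag <- "clamped"
  } else if (pct < 0) {
    pct <- 0; flag <- "floored"
  }
  list(percent = pct, flag = flag)
}

#' Read the peak-list CSV
#'
#' One row per peak: `peptide_sequence,charge,condition,time_s,replicate,
#' mz,intensity,sn_ratio`.
#'
#' @param path CSV file.
#' @return data.table of peaks.
#' @export
read_peaks <- function(path) {
  dt <- data.table::fread(path)
  needed <- c("peptide_sequence", "charge", "condition", "time_s",
              "replicate", "mz", "intensity", "sn_ratio")
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols)) {
    stop(path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dt
}

#' Per-cluster centroid table
#'
#' Collapses a long peak table to one centroid per peptide ion x condition
#' x timepoint x replicate.
#'
#' @param clusters Long peak table (see [read_peaks()]).
#' @return data.table with `peptide_sequence`, `charge`, `condition`,
#'   `time_s`, `replicate`, `sn_ratio`, `centroid_mz`.
#' @export
cluster_centroids <- function(clusters) {
  clusters <- data.table::as.data.table(clusters)
  mz <- intensity <- sn_ratio <- NULL  # NSE
  clusters[, list(centroid_mz = centroid(mz, intensity),
                  sn_ratio = sn_ratio[1]),
           by = c("peptide_sequence", "charge", "condition", "time_s",
                  "replicate")]
}

#' Build uptake curves from clusters
#'
#' Computes the corrected deuteration percentage for every peptide ion x
#' condition x nonzero timepoint x replicate.  The nondeuterated reference
#' (time 0) is shared across conditions by default (mean of all time-0
#' centroids of the ion); peptides whose S/N does not exceed `sn_threshold`
#' are dropped and listed.
#'
#' @param clusters Long peak table.
#' @param peptides Peptide table (gives residue ranges and the amide count).
#' @param params A [correction_params()].
#' @param sn_threshold Retain peptides with S/N strictly greater than this
#'   (default 3); `-Inf` retains everything.
#' @param shared_reference Share the time-0 centroid across conditions
#'   (default `TRUE`); otherwise a per-condition reference is required.
#' @param exclude_n_term Exchangeable-amide rule.
#' @return List of class `uptake_result`:
#'   `points` — per-replicate table (`peptide_sequence`, `start`, `end`,
#'     `charge`, `condition`, `time_s`, `replicate`, `centroid_mz`,
#'     `uptake_percent`, `flag`);
#'   `curves` — replicate-aggregated table with `uptake_mean`, `uptake_sd`,
#'     `centroid_mean`;
#'   `excluded` — data.frame of dropped peptides and reasons.
#' @export
build_uptake_curves <- function(clusters, peptides,
                                params = correction_params(),
                                sn_threshold = 3, shared_reference = TRUE,
                                exclude_n_term = 1L) {
  cent <- cluster_centroids(clusters)
  peptide_sequence <- charge <- condition <- time_s <- sn_ratio <- NULL
  centroid_mz <- uptake_percent <- NULL
  pep <- data.table::as.data.table(peptides)
  excluded <- list()

  # S/N filter: every required point must pass
  sn <- cent[, list(min_sn = min(sn_ratio)), by = c("peptide_sequence", "charge")]
  drop <- sn[sn$min_sn <= sn_threshold]
  if (nrow(drop)) {
    excluded$sn <- data.frame(peptide_sequence = drop$peptide_sequence,
                              charge = drop$charge,
                              reason = sprintf("S/N %.3g <= threshold %g",
                                               drop$min_sn, sn_threshold))
    cent <- cent[!drop, on = c("peptide_sequence", "charge")]
  }
  if (nrow(cent) == 0L) {
    return(structure(list(points = cent[0], curves = cent[0],
                          excluded = data.table::rbindlist(excluded)),
                     class = "uptake_result"))
  }

  # nondeuterated reference
  refgrp <- if (shared_reference) c("peptide_sequence", "charge") else
    c("peptide_sequence", "charge", "condition")
  refs <- cent[time_s == 0, list(c_N = mean(centroid_mz)), by = refgrp]
  work <- merge(cent[time_s > 0], refs, by = refgrp, all.x = TRUE)
  if (anyNA(work$c_N)) {
    miss <- unique(work[is.na(work$c_N),
                        c("peptide_sequence", "charge", "condition")])
    stop("missing nondeuterated (time 0) reference for: ",
         paste(sprintf("%s/+%d/%s", miss$peptide_sequence, miss$charge,
                       miss$condition), collapse = "; "))
  }

  work <- merge(work, pep[, c("sequence", "start", "end", "charge")],
                by.x = c("peptide_sequence", "charge"),
                by.y = c("sequence", "charge"))
  work$n_exch <- vapply(work$peptide_sequence, count_exchangeable_amides,
                        integer(1), exclude_n_term = exclude_n_term)
  zero_exch <- unique(work[work$n_exch == 0L,
                           c("peptide_sequence", "charge")])
  if (nrow(zero_exch)) {
    excluded$no_amide <- data.frame(peptide_sequence = zero_exch$peptide_sequence,
                                    charge = zero_exch$charge,
                                    reason = "no exchangeable amides")
    work <- work[work$n_exch > 0L]
  }
  lev <- mapply(function(cp, cn, cf) deuteration_level(cp, cn, cf, params),
                work$centroid_mz, work$c_N,
                fully_deuterated_centroid(work$c_N, work$n_exch, work$charge,
                                          params),
                SIMPLIFY = FALSE)
  work$uptake_percent <- vapply(lev, `[[`, numeric(1), "percent")
  work$flag <- vapply(lev, `[[`, character(1), "flag")
  points <- work[, c("peptide_sequence", "start", "end", "charge",
                     "condition", "time_s", "replicate", "centroid_mz",
                     "uptake_percent", "flag")]
  data.table::setorderv(points, c("peptide_sequence", "charge", "condition",
                                  "time_s", "replicate"))
  curves <- points[, list(centroid_mean = mean(centroid_mz),
                          uptake_mean = mean(uptake_percent),
                          uptake_sd = stats::sd(uptake_percent)),
                   by = c("peptide_sequence", "start", "end", "charge",
                          "condition", "time_s")]
  structure(list(points = points, curves = curves,
                 excluded = if (length(excluded))
                   data.table::rbindlist(excluded) else
                     data.frame(peptide_sequence = character(),
                                charge = integer(), reason = character())),
            class = "uptake_result")
}

#' @export
print.uptake_result <- function(x, ...) {
  cat("<uptake_result> ",
      data.table::uniqueN(x$curves[, c("peptide_sequence", "charge")]),
      " peptide ions retained, ", nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Summarize uptake curves
#'
#' @param uptake An [build_uptake_curves()] result (or its `curves` table).
#' @param conditions Optional subset of condition labels.
#' @return List: `per_peptide` (mean and max corrected uptake over
#'   timepoints, per peptide ion and condition) and `grand_mean` (mean over
#'   all peptides and timepoints).
#' @export
summarize_hdx <- function(uptake, conditions = NULL) {
  curves <- if (inherits(uptake, "uptake_result")) uptake$curves else
    data.table::as.data.table(uptake)
  if (nrow(curves) == 0L) stop("no uptake curves to summarize")
  if (!is.null(conditions)) curves <- curves[curves$condition %in% conditions]
  uptake_mean <- NULL
  per_peptide <- curves[, list(mean_uptake = mean(uptake_mean),
                               max_uptake = max(uptake_mean)),
                        by = c("peptide_sequence", "charge", "condition")]
  list(per_peptide = per_peptide, grand_mean = mean(curves$uptake_mean))
}

#' Write the uptake output CSV
#'
#' Columns: `peptide,start,end,condition,time_s,centroid_mz,uptake_percent,
#' flag` (one row per replicate point).
#'
#' @param uptake An [build_uptake_curves()] result.
#' @param path Output CSV.
#' @export
write_uptake_csv <- function(uptake, path) {
  out <- data.table::copy(uptake$points)
  data.table::setnames(out, "peptide_sequence", "peptide")
  data.table::fwrite(out[, c("peptide", "start", "end", "condition",
                             "time_s", "centroid_mz", "uptake_percent",
                             "flag")], path)
  invisible(path)
}
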