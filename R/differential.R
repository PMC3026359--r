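## Differential HDX: apo-versus-holo comparison per peptide ion, using a
## paired t-test over the late exchange timepoints.

#' Paired Student's t-test
#'
#' Two-sided paired t on `apo - holo` differences: t = mean(d)/(sd(d)/sqrt(n))
#' with n - 1 degrees of freedom.
#'
#' @param apo_values,holo_values Equal-length series (>= 2), paired by
#'   position.
#' @return List: `t`, `p`, `df`, `flag` (`"ok"`, `"zero_variance"` when the
#'   differences are constant but nonzero — t is +/-Inf, p = 0 — or
#'   `"untestable"` when all differences are zero).
#' @export
paired_t_test <- function(apo_values, holo_values) {
  stopifnot(length(apo_values) == length(holo_values), length(apo_values) >= 2L)
  d <- apo_values - holo_values
  n <- length(d)
  df <- n - 1L
  if (all(d == 0)) {
    return(list(t = NA_real_, p = NA_real_, df = df, flag = "untestable"))
  }
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = sign(mean(d)) * Inf, p = 0, df = df,
                flag = "zero_variance"))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, flag = "ok")
}

#' Select the last k timepoints of a series
#'
#' @param values Values ordered like `times`.
#' @param times Timepoints in seconds (any order).
#' @param k Number of latest timepoints to keep (default 3).
#' @return List `times`, `values` for the k largest times, time-ascending.
#' @export
select_last_timepoints <- function(values, times, k = 3L) {
  stopifnot(length(values) == length(times))
  ut <- sort(unique(times))
  if (length(ut) < k) {
    stop("series has ", length(ut), " timepoints; need at least ", k)
  }
  keep_t <- utils::tail(ut, k)
  ord <- order(times)
  sel <- ord[times[ord] %in% keep_t]
  list(times = times[sel], values = values[sel])
}

#' Differential HDX table
#'
#' One row per peptide ion shared between the apo and holo condition.
#' Pairs are (timepoint x replicate) over the `last_k` latest timepoints;
#' the test statistic is computed on centroids (default) or on corrected
#' uptake — the two are affinely related per peptide ion, so t and p agree
#' (up to sign: a lower holo centroid and a lower holo uptake both mean
#' protection).  `delta_hdx_percent` is always apo - holo mean corrected
#' uptake over the selected timepoints; positive = protected.
#'
#' @param uptake An [build_uptake_curves()] result (or its `points` table).
#' @param apo,holo Condition labels to compare.
#' @param alpha Significance level for classification (default 0.05).
#' @param last_k Number of late timepoints entering the test (default 3).
#' @param basis `"centroid"` or `"uptake"`.
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of p-values before classification.
#' @return data.table of class `differential_table`: `peptide_sequence`,
#'   `start`, `end`, `charge`, `apo`, `holo`, `delta_hdx_percent`,
#'   `t_statistic`, `df`, `p_value`, `classification`; attribute
#'   `"excluded"` lists peptides present in only one condition.
#' @export
differential_table <- function(uptake, apo = "apo", holo, alpha = 0.05,
                               last_k = 3L, basis = c("centroid", "uptake"),
                               adjust = c("none", "BH")) {
  basis <- match.arg(basis)
  adjust <- match.arg(adjust)
  points <- if (inherits(uptake, "uptake_result")) uptake$points else
    data.table::as.data.table(uptake)
  pts <- points[points$condition %in% c(apo, holo)]
  if (nrow(pts) == 0L) stop("no points for conditions '", apo, "'/'", holo, "'")

  key <- c("peptide_sequence", "start", "end", "charge")
  both <- split(pts, by = key, drop = TRUE)
  rows <- list()
  excluded <- character()
  for (grp in both) {
    id <- grp[1, key, with = FALSE]
    a <- grp[grp$condition == apo]
    h <- grp[grp$condition == holo]
    if (nrow(a) == 0L || nrow(h) == 0L) {
      excluded <- c(excluded, sprintf("%s/+%d", id$peptide_sequence, id$charge))
      next
    }
    data.table::setorderv(a, c("time_s", "replicate"))
    data.table::setorderv(h, c("time_s", "replicate"))
    stopifnot(identical(a$time_s, h$time_s), identical(a$replicate, h$replicate))
    sel_a <- select_last_timepoints(seq_len(nrow(a)), a$time_s, last_k)$values
    a <- a[sel_a]; h <- h[sel_a]
    # sign convention: protection shows as lower holo uptake, i.e. lower
    # holo centroid; use apo - holo on the chosen basis
    tt <- if (basis == "centroid") {
      paired_t_test(a$centroid_mz, h$centroid_mz)
    } else {
      paired_t_test(a$uptake_percent, h$uptake_percent)
    }
    rows[[length(rows) + 1L]] <- data.table::data.table(
      id, apo = apo, holo = holo,
      delta_hdx_percent = mean(a$uptake_percent) - mean(h$uptake_percent),
      t_statistic = tt$t, df = tt$df, p_value = tt$p, test_flag = tt$flag)
  }
  if (length(rows) == 0L) stop("no peptide present in both conditions")
  res <- data.table::rbindlist(rows)
  data.table::setorderv(res, c("start", "end", "peptide_sequence", "charge"))
  p_cls <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else
    res$p_value
  res$classification <- ifelse(
    res$test_flag == "untestable", "untestable",
    ifelse(!is.na(p_cls) & p_cls < alpha,
           ifelse(res$delta_hdx_percent > 0, "protected", "destabilized"),
           "not_significant"))
  data.table::setattr(res, "excluded", excluded)
  data.table::setattr(res, "class",
                      c("differential_table", class(res)))
  res
}

#' Write the differential output CSV
#'
#' Columns: `peptide,start,end,holo_condition,delta_hdx_percent,t,df,p,
#' classification`.
#'
#' @param diff A [differential_table()] result.
#' @param path Output CSV.
#' @export
write_differential_csv <- function(diff, path) {
  out <- data.table::as.data.table(diff)
  data.table::fwrite(
    data.table::data.table(peptide = out$peptide_sequence, start = out$start,
                           end = out$end, holo_condition = out$holo,
                           delta_hdx_percent = out$delta_hdx_percent,
                           t = out$t_statistic, df = out$df, p = out$p_value,
                           classification = out$classification),
    path)
  invisible(path)
}
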