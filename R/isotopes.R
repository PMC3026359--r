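## Elemental composition arithmetic, exact masses and natural isotopic
## envelopes.  Everything downstream (simulator, fully-deuterated reference,
## ligand masses) is built on these primitives.

# Isotope tables: mass in Da, abundance as a fraction.  First row of each
# element is the principal (lightest, most abundant) isotope.
.ISOTOPES <- list(
  C = data.frame(mass = c(12.0000000, 13.0033548),
                 abundance = c(0.9893, 0.0107)),
  H = data.frame(mass = c(1.0078250319, 2.0141017780),
                 abundance = c(0.999885, 0.000115)),
  N = data.frame(mass = c(14.0030740052, 15.0001088984),
                 abundance = c(0.99636, 0.00364)),
  O = data.frame(mass = c(15.9949146221, 16.9991315, 17.9991604),
                 abundance = c(0.99757, 0.00038, 0.00205)),
  S = data.frame(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
                 abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

# IUPAC 2021 standard atomic weights (conventional values).
.ATOMIC_WEIGHTS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, S = 32.06)

.PROTON_MASS <- 1.007276466

# Residue (not free amino acid) elemental compositions: columns C,H,N,O,S.
.AA_COMPOSITION <- rbind(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0)
)
colnames(.AA_COMPOSITION) <- c("C", "H", "N", "O", "S")

.WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# Small ligands referenced by name.  Xylohexaose: six beta-1,4-linked xylose
# units (C5H10O5 each) minus five waters of condensation.
.NAMED_LIGANDS <- list(
  xylohexaose = c(C = 30, H = 50, N = 0, O = 25, S = 0),
  xylose      = c(C = 5, H = 10, N = 0, O = 5, S = 0),
  water       = c(C = 0, H = 2, N = 0, O = 1, S = 0)
)

#' Elemental composition of a peptide
#'
#' Sums residue compositions and adds one water for the termini.
#'
#' @param sequence One-letter amino-acid string (standard 20 letters).
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
peptide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, rownames(.AA_COMPOSITION))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  comp <- colSums(.AA_COMPOSITION[aa, , drop = FALSE]) + .WATER
  storage.mode(comp) <- "integer"
  comp
}

#' Parse a chemical formula string
#'
#' Accepts formulas such as `"C4H8N2O3"` over the elements C, H, N, O, S.
#'
#' @param formula Formula string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: ", formula)
  }
  comp <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (tok in toks) {
    el <- gsub("[0-9]+", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(comp)) stop("unknown element: ", el)
    comp[el] <- comp[el] + n
  }
  comp
}

.resolve_composition <- function(x) {
  if (is.numeric(x)) {
    comp <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
    bad <- setdiff(names(x), names(comp))
    if (length(bad)) stop("unknown element: ", paste(bad, collapse = ", "))
    comp[names(x)] <- as.integer(x)
    return(comp)
  }
  stopifnot(is.character(x), length(x) == 1L)
  lig <- tolower(x)
  if (lig %in% names(.NAMED_LIGANDS)) return(.NAMED_LIGANDS[[lig]])
  if (grepl("^[A-Z][A-Za-z0-9]*$", x) && grepl("[0-9]", x)) {
    return(parse_formula(x))
  }
  peptide_composition(x)
}

#' Molecular mass from composition, peptide sequence or named ligand
#'
#' @param x An elemental formula string (e.g. `"C4H8N2O3"`), a named element
#'   count vector, a peptide sequence, or a named ligand (`"xylohexaose"`,
#'   `"water"`).
#' @param kind `"average"` (standard atomic weights) or `"monoisotopic"`
#'   (principal isotopes).
#' @return Mass in Da (g/mol).
#' @examples
#' molecular_mass("xylohexaose")          # 810.70
#' molecular_mass("GG", "monoisotopic")   # glycylglycine
#' @export
molecular_mass <- function(x, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  comp <- .resolve_composition(x)
  if (kind == "average") {
    sum(comp * .ATOMIC_WEIGHTS[names(comp)])
  } else {
    mono <- vapply(names(comp), function(el) .ISOTOPES[[el]]$mass[1L], numeric(1))
    sum(comp * mono)
  }
}

## ---- aggregated isotopic envelopes ---------------------------------------
## A distribution over integer nominal mass shifts n >= 0 relative to the
## monoisotopic species, carrying for every n its probability and the
## probability-weighted mean exact mass shift.  Convolution is exact; peaks
## that a unit-resolution instrument cannot separate are aggregated.

.dist_new <- function(shift, prob, mass_shift) {
  list(shift = as.integer(shift), prob = prob, mass = mass_shift)
}

.dist_delta <- function() .dist_new(0L, 1, 0)

.dist_convolve <- function(a, b, tol = 1e-12) {
  nmax <- max(a$shift) + max(b$shift)
  p <- numeric(nmax + 1L)
  pm <- numeric(nmax + 1L)
  for (i in seq_along(a$shift)) {
    idx <- a$shift[i] + b$shift + 1L
    w <- a$prob[i] * b$prob
    p[idx] <- p[idx] + w
    pm[idx] <- pm[idx] + w * (a$mass[i] + b$mass)
  }
  keep <- p > tol * max(p)
  .dist_new(which(keep) - 1L, p[keep], pm[keep] / p[keep])
}

.dist_power <- function(d, n) {
  out <- .dist_delta()
  base <- d
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .dist_convolve(out, base)
    n <- n %/% 2L
    if (n > 0L) base <- .dist_convolve(base, base)
  }
  out
}

.element_dist <- function(el) {
  iso <- .ISOTOPES[[el]]
  shifts <- round(iso$mass - iso$mass[1L])
  .dist_new(shifts, iso$abundance, iso$mass - iso$mass[1L])
}

#' Natural isotopic envelope of a molecule
#'
#' Computes the aggregated isotopic distribution from the exact elemental
#' composition: peaks grouped by nominal neutron count, each carrying its
#' abundance and abundance-weighted exact mass shift from the monoisotopic
#' species.
#'
#' @param x Composition input as for [molecular_mass()].
#' @param tol Relative abundance below which peaks are dropped.
#' @return A data.frame with columns `shift` (integer nominal shift),
#'   `prob` (relative abundance, summing to ~1) and `mass_shift`
#'   (exact Da above the monoisotopic mass).
#' @export
natural_envelope <- function(x, tol = 1e-9) {
  comp <- .resolve_composition(x)
  d <- .dist_delta()
  for (el in names(comp)) {
    if (comp[el] > 0L) {
      d <- .dist_convolve(d, .dist_power(.element_dist(el), comp[el]))
    }
  }
  keep <- d$prob > tol * max(d$prob)
  data.frame(shift = d$shift[keep], prob = d$prob[keep] / sum(d$prob[keep]),
             mass_shift = d$mass[keep])
}

#' Poisson-binomial distribution
#'
#' Distribution of the number of successes among independent Bernoulli trials
#' with per-trial probabilities `p`, computed by exact sequential convolution.
#'
#' @param p Vector of success probabilities in \[0, 1\].
#' @return Numeric vector of length `length(p) + 1`; element `k + 1` is
#'   P(exactly k successes).
#' @export
poisson_binomial <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  f
}
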