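# Shared fixtures, built in code at test time.

# A protein that contains the groove peptide once at residues 102-120,
# mimicking the pepsin fragment used as the worked example in the field.
GROOVE_PEPTIDE <- "YTIWENTRVNEPSIQGTAT"

fixture_protein_with_groove <- function(total = 190L, seed = 11L) {
  set.seed(seed)
  aa <- setdiff(rownames(hdxprodyn:::.AA_COMPOSITION), "Y")
  pre <- paste(sample(aa, 101L, replace = TRUE), collapse = "")
  post <- paste(sample(aa, total - 101L - nchar(GROOVE_PEPTIDE),
                       replace = TRUE), collapse = "")
  protein_sequence(paste0(pre, GROOVE_PEPTIDE, post), id = "xyn_synthetic")
}

# Small two-condition experiment with a single protected region in holo.
fixture_regions <- function(n, pf_holo_mid = 5) {
  third <- floor(n / 3)
  data.frame(start = c(1L, third + 1L, 2L * third + 1L),
             end = c(third, 2L * third, n),
             pf_apo = 1, pf_holo = c(1, pf_holo_mid, 1))
}

# Peptides lying fully inside or fully outside [start,end]; none straddle.
fixture_tiled_peptides <- function(protein, region_start, region_end,
                                   len = 10L, charge = 2L) {
  n <- nchar(protein$residues)
  starts <- c(seq(1L, region_start - len, by = len),
              seq(region_start, region_end - len + 1L, by = len),
              seq(region_end + 1L, n - len + 1L, by = len))
  starts <- unique(starts[starts >= 1L & starts + len - 1L <= n])
  data.frame(sequence = substring(protein$residues, starts, starts + len - 1L),
             start = starts, end = starts + len - 1L,
             charge = charge, sn_ratio = 10)
}

# Brute-force deuterium-count distribution: enumerate all 2^n outcomes.
enumerate_deuterium_distribution <- function(p) {
  n <- length(p)
  out <- numeric(n + 1L)
  for (mask in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(mask)[seq_len(n)])
    prob <- prod(ifelse(bits == 1L, p, 1 - p))
    out[sum(bits) + 1L] <- out[sum(bits) + 1L] + prob
  }
  out
}

# Null (no protection difference) experiment used by size/power tests.
fixture_null_experiment <- function(seed, n_res = 60L, n_pep = 10L,
                                    noise_cv = 0.05) {
  prot <- synthetic_protein(n_res, seed = 104729L)
  peps <- synthetic_peptide_map(prot, n_peptides = n_pep, seed = 104729L)
  regions <- data.frame(start = c(1L, n_res %/% 2 + 1L),
                        end = c(n_res %/% 2, n_res),
                        pf_apo = 1, pf_holo = 1)
  generate_experiment(protein = prot, peptides = peps, regions = regions,
                      conditions = c("apo", "holo"), seed = seed,
                      noise_cv = noise_cv)
}
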