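# Simulator: exchange kinetics, isotopic envelopes, experiment generation.

test_that("per-residue deuteration follows first-order kinetics", {
  m <- exchange_model()
  # no labeling at time zero
  expect_equal(simulate_residue_deuteration(0.05, 3, 0, m), 0)
  # saturation at the buffer D fraction
  expect_equal(simulate_residue_deuteration(1e6, 1, 3840, m), 0.80,
               tolerance = 1e-9)
  # closed form, cross-checked against a discrete-time stochastic
  # simulation of 1e6 residues (geometric waiting time + Bernoulli
  # retention; frozen value 0.304742, MC standard error ~5e-4)
  d <- simulate_residue_deuteration(0.001, 2, 960, m)
  expect_equal(d, 0.3049733, tolerance = 1e-6)
  expect_equal(d, 0.304742, tolerance = 2e-3)
  expect_error(simulate_residue_deuteration(0.001, 2, -1, m), "non-negative")
  expect_error(exchange_model(buffer_d_fraction = 0))
  expect_error(exchange_model(recovery = 1.2))
})

test_that("Poisson-binomial construction agrees with exhaustive enumeration", {
  set.seed(21)
  for (n in c(1L, 2L, 5L, 12L)) {
    p <- runif(n)
    pb <- poisson_binomial(p)
    expect_equal(sum(pb), 1, tolerance = 1e-12)
    expect_equal(pb, enumerate_deuterium_distribution(p), tolerance = 1e-12)
  }
  expect_equal(poisson_binomial(numeric(0)), 1)
})

test_that("simulated cluster reproduces the analytic envelope", {
  prot <- protein_sequence("GASTAVGAST", id = "p10")
  pep <- data.frame(sequence = "GASTA", start = 1L, end = 5L, charge = 2L,
                    sn_ratio = 10)
  regions <- data.frame(start = 1L, end = 10L, pf_apo = 1)
  truth <- synthetic_truth(prot, regions, seed = 2)
  m <- exchange_model()

  # t = 0, no noise: centroid equals the natural-envelope centroid
  peaks0 <- simulate_peptide_cluster(pep, truth, 0, "apo", m, noise_cv = 0)
  nat <- natural_envelope(peptide_composition("GASTA"))
  nat_centroid <- (molecular_mass("GASTA", "monoisotopic") +
                     sum(nat$prob * nat$mass_shift)) / 2 + 1.007276466
  expect_equal(centroid(peaks0$mz, peaks0$intensity), nat_centroid,
               tolerance = 1e-9)
  expect_true(all(diff(peaks0$mz) > 0))

  # saturating time, protection 1: centroid shift is
  # n_exch * recovery * f * dD / z
  sat <- simulate_peptide_cluster(pep, truth, 1e9, "apo", m, noise_cv = 0)
  n_exch <- count_exchangeable_amides("GASTA")
  expect_equal(centroid(sat$mz, sat$intensity) - nat_centroid,
               n_exch * 0.70 * 0.80 * 1.00628 / 2, tolerance = 1e-6)

  # envelope against brute-force enumeration over deuteration outcomes
  t <- 240
  pos <- hdxprodyn:::exchangeable_positions("GASTA")
  p <- simulate_residue_deuteration(truth$residue_rates[pos], 1, t, m) * 0.70
  ddist <- enumerate_deuterium_distribution(p)
  peaks <- simulate_peptide_cluster(pep, truth, t, "apo", m, noise_cv = 0,
                                    tol = 1e-12)
  # reconstruct expected aggregated intensities
  want <- numeric(max(nat$shift) + length(ddist))
  for (d in seq_along(ddist) - 1L) {
    idx <- nat$shift + d + 1L
    want[idx] <- want[idx] + nat$prob * ddist[d + 1L]
  }
  got <- peaks$intensity / sum(peaks$intensity)
  want <- want[want > 1e-12 * max(want)]
  want <- want / sum(want)
  expect_equal(length(got), length(want))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("noise-free centroids increase monotonically with time", {
  prot <- synthetic_protein(40, seed = 8)
  peps <- synthetic_peptide_map(prot, n_peptides = 6, seed = 8)
  regions <- data.frame(start = 1L, end = 40L, pf_apo = 2)
  truth <- synthetic_truth(prot, regions, seed = 8)
  times <- c(0, 60, 240, 960, 1920, 3840)
  for (i in seq_len(nrow(peps))) {
    cents <- vapply(times, function(t) {
      pk <- simulate_peptide_cluster(peps[i, ], truth, t, "apo",
                                     noise_cv = 0)
      centroid(pk$mz, pk$intensity)
    }, numeric(1))
    expect_true(all(diff(cents) >= -1e-12))
  }
})

test_that("analytic mean deuteration matches the envelope-recovered mean", {
  prot <- synthetic_protein(30, seed = 13)
  pep <- data.frame(sequence = substr(prot$residues, 5, 16), start = 5L,
                    end = 16L, charge = 1L, sn_ratio = 10)
  regions <- data.frame(start = 1L, end = 30L, pf_apo = 1)
  truth <- synthetic_truth(prot, regions, seed = 13)
  m <- exchange_model()
  pos <- hdxprodyn:::exchangeable_positions(pep$sequence)
  gpos <- pep$start + pos - 1L
  for (t in c(60, 960, 3840)) {
    p <- simulate_residue_deuteration(truth$residue_rates[gpos], 1, t, m)
    pb <- poisson_binomial(p * m$recovery)
    mean_from_envelope <- sum((seq_along(pb) - 1L) * pb)
    expect_equal(mean_from_envelope, sum(p) * m$recovery, tolerance = 1e-9)
  }
})

test_that("generate_experiment has the right cardinality and determinism", {
  prot <- synthetic_protein(50, seed = 6)
  peps <- synthetic_peptide_map(prot, n_peptides = 10, seed = 6)
  exp1 <- generate_experiment(protein = prot, peptides = peps, seed = 6)
  # 10 peptides x 3 conditions x 6 timepoints x 1 replicate = 180 clusters
  cells <- unique(exp1$clusters[, c("peptide_sequence", "charge", "condition",
                                    "time_s", "replicate")])
  expect_equal(nrow(cells), 180L)
  # every design cell exactly once
  expect_equal(nrow(cells), 10L * 3L * 6L)

  # same seed twice -> byte-identical files
  exp2 <- generate_experiment(protein = prot, peptides = peps, seed = 6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_experiment(exp1, d1); write_experiment(exp2, d2)
  for (f in c("peaks.csv", "peptides.csv", "protein.fasta", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  exp3 <- generate_experiment(protein = prot, peptides = peps, seed = 7)
  expect_false(identical(exp1$clusters$intensity, exp3$clusters$intensity))
})

test_that("truth construction enforces its invariants", {
  prot <- synthetic_protein(30, seed = 1)
  expect_error(synthetic_truth(prot, data.frame(start = c(1, 10),
                                                end = c(10, 30),
                                                pf_apo = 1)),
               "tile")
  expect_error(synthetic_truth(prot, data.frame(start = c(1, 11),
                                                end = c(10, 30),
                                                pf_apo = c(0.5, 1))),
               ">= 1")
  tr <- synthetic_truth(prot, data.frame(start = c(1, 11), end = c(10, 30),
                                         pf_apo = c(1, 2)))
  expect_equal(residue_protection(tr, "apo"), rep(c(1, 2), c(10, 20)))
  expect_error(residue_protection(tr, "holo"), "holo")
  pep <- data.frame(sequence = "WWWW", start = 1L, end = 4L, charge = 1L,
                    sn_ratio = 5)
  expect_error(simulate_peptide_cluster(pep, tr, 60, "apo"), "not found")
})
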