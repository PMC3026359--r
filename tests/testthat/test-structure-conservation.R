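# Residue projection, PDB B-factor recoloring and conservation.

fake_diff <- function(peptides, deltas) {
  data.table::data.table(
    peptide_sequence = peptides$sequence, start = peptides$start,
    end = peptides$end, charge = peptides$charge, apo = "apo", holo = "holo",
    delta_hdx_percent = deltas, t_statistic = 1, df = 2L, p_value = 0.5,
    test_flag = "ok", classification = "not_significant")
}

test_that("project_to_residues averages covering peptides", {
  prot <- protein_sequence(strrep("A", 20), id = "p20")
  peps1 <- data.frame(sequence = strrep("A", 6), start = 5L, end = 10L,
                      charge = 1L, sn_ratio = 10)
  pr <- project_to_residues(fake_diff(peps1, 20), prot,
                            exclude_ambiguous = FALSE)
  expect_equal(pr$value[5:10], rep(20, 6))
  expect_true(all(pr$status[-(5:10)] == "undetected"))
  expect_true(all(is.na(pr$value[pr$status == "undetected"])))
  expect_true(all(lengths(pr$source_peptides[pr$status == "undetected"]) == 0))

  # overlap: unweighted mean of the covering peptides
  peps2 <- data.frame(sequence = c(strrep("A", 10), strrep("A", 10)),
                      start = c(1L, 6L), end = c(10L, 15L), charge = 1L,
                      sn_ratio = 10)
  pr2 <- project_to_residues(fake_diff(peps2, c(10, 30)), prot,
                             exclude_ambiguous = FALSE)
  expect_equal(pr2$value[6:10], rep(20, 5))
  expect_equal(pr2$value[1:5], rep(10, 5))
  expect_equal(pr2$value[11:15], rep(30, 5))

  # empty results: everything undetected
  pr3 <- project_to_residues(fake_diff(peps2[0, ], numeric(0)), prot)
  expect_true(all(pr3$status == "undetected"))

  # permutation invariance in peptide order
  d <- fake_diff(peps2, c(10, 30))
  pr4 <- project_to_residues(d[2:1], prot, exclude_ambiguous = FALSE)
  expect_equal(pr4$value, pr2$value)

  # ambiguous peptides (poly-A matches everywhere) are excluded by default
  pr5 <- project_to_residues(fake_diff(peps1, 20), prot)
  expect_true(peps1$sequence %in% pr5$ambiguous)
  expect_true(all(pr5$status == "undetected"))
})

test_that("write_bfactor_pdb touches only B-factor columns of the chain", {
  prot <- synthetic_protein(30, seed = 61, id = "ca_trace")
  pdb <- synthetic_pdb(prot, chain = "A", bfactor = 20)
  values <- round(runif(30, -40, 40), 2)
  status <- rep(c("measured", "undetected"), 15)
  proj <- structure(list(value = ifelse(status == "measured", values, NA),
                         status = status,
                         source_peptides = vector("list", 30),
                         ambiguous = character()),
                    class = "residue_projection")
  out <- write_bfactor_pdb(pdb, "A", proj, sentinel = 0)
  expect_equal(length(out), length(pdb))
  atoms_in <- grepl("^(ATOM  |HETATM)", pdb)
  # non-atom lines byte-identical; atom lines differ only in columns 61-66
  expect_identical(out[!atoms_in], pdb[!atoms_in])
  for (i in which(atoms_in)) {
    expect_identical(substr(out[i], 1, 60), substr(pdb[i], 1, 60))
    expect_identical(substr(out[i], 67, nchar(pdb[i])),
                     substr(pdb[i], 67, nchar(pdb[i])))
  }
  # single-residue format check
  one <- structure(list(value = c(rep(NA, 4), 12.3, rep(NA, 25)),
                        status = c(rep("undetected", 4), "measured",
                                   rep("undetected", 25)),
                        source_peptides = vector("list", 30),
                        ambiguous = character()),
                   class = "residue_projection")
  out1 <- write_bfactor_pdb(pdb, "A", one, sentinel = 0)
  atoms <- read_pdb_atoms(out1)
  expect_identical(substr(out1[atoms$line[atoms$resseq == 5]], 61, 66),
                   " 12.30")
  # round trip recovers the projected values exactly (2-decimal values)
  back <- read_pdb_atoms(out)
  expect_equal(back$bfactor, ifelse(status == "measured", values, 0))
  # all-sentinel projection
  allna <- structure(list(value = rep(NA_real_, 30),
                          status = rep("undetected", 30),
                          source_peptides = vector("list", 30),
                          ambiguous = character()),
                     class = "residue_projection")
  outs <- write_bfactor_pdb(pdb, "A", allna, sentinel = -7.5)
  expect_true(all(read_pdb_atoms(outs)$bfactor == -7.5))
  expect_error(write_bfactor_pdb(pdb, "B", proj), "chain 'B'")
})

test_that("column conservation counts modal symbols and maps columns", {
  aln <- c(ref  = "AC-DEF",
           hom1 = "ACGDEF",
           hom2 = "ACGD-F",
           hom3 = "TCGDEW")
  prof <- column_conservation(aln, "ref")
  # hand count: col 5 has E,E,-,E -> 3 of 4; col 6 has F,F,F,W -> 3 of 4
  expect_equal(prof$score, c(3/4, 4/4, 3/4, 4/4, 3/4, 3/4))
  # column 3 is gapped in the reference -> unmapped
  expect_equal(prof$column_to_residue, c(1L, 2L, NA, 3L, 4L, 5L))
  expect_equal(prof$residue_score, c(3/4, 1, 1, 3/4, 3/4))
  # invariant to sequence order
  prof2 <- column_conservation(aln[c(3, 1, 4, 2)], "ref")
  expect_equal(prof2$score, prof$score)
  # all-gap column scores 0
  aln2 <- c(ref = "A-C", hom = "A-C")
  expect_equal(column_conservation(aln2, "ref")$score[2], 0)
  expect_error(column_conservation(aln, "nope"), "absent")
  # direct-count oracle on random alignments
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "G", "S", "-"), 13 * 8, replace = TRUE), 13, 8)
    m[1, ] <- sample(c("A", "G", "S"), 8, replace = TRUE)  # ungapped ref
    rows <- apply(m, 1, paste, collapse = "")
    names(rows) <- c("ref", paste0("h", 1:12))
    prof3 <- column_conservation(rows, "ref")
    for (j in 1:8) {
      sym <- m[m[, j] != "-", j]
      expect_equal(prof3$score[j],
                   if (length(sym)) max(table(sym)) / 13 else 0)
    }
  }
})

test_that("conservation-protection report flags degenerate inputs", {
  n <- 40L
  status <- rep("measured", n)
  proj <- structure(list(value = rnorm(n), status = status,
                         source_peptides = vector("list", n),
                         ambiguous = character()),
                    class = "residue_projection")
  flat <- structure(list(score = rep(0.5, n),
                         column_to_residue = seq_len(n),
                         residue_score = rep(0.5, n)),
                    class = "conservation_profile")
  rep1 <- conservation_protection_report(proj, flat)
  expect_equal(rep1$flag, "untestable")

  # constructed truth: protected residues are also the conserved ones
  delta <- c(rep(25, 20), rep(0, 20)) + rnorm(n, sd = 1)
  cons <- c(rep(0.95, 20), rep(0.30, 20)) + runif(n, 0, 0.04)
  proj2 <- proj; proj2$value <- delta
  prof2 <- flat; prof2$residue_score <- cons
  rep2 <- conservation_protection_report(proj2, prof2)
  expect_equal(rep2$flag, "ok")
  expect_gt(rep2$rho, 0)

  # permutation null: mean correlation over label permutations ~ 0
  set.seed(17)
  rhos <- replicate(400, {
    pp <- proj2; pp$value <- sample(delta)
    conservation_protection_report(pp, prof2)$rho
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)) + 0.02)
})
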