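---
title: "Peptide-level differential HDX-MS: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-level differential HDX-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxprodyn)
```

## The measurement and the model

Hydrogen/deuterium exchange MS measures protein backbone dynamics through
the exchange of amide hydrogens with solvent deuterium. After labeling in
D2O for a series of times, the reaction is quenched, the protein digested
with pepsin, and each peptide ion's isotopic cluster recorded. The
observable per cluster is the intensity-weighted centroid

$$c = \frac{\sum_i (m/z)_i \, I_i}{\sum_i I_i},$$

whose shift relative to the nondeuterated reference measures deuterium
incorporation. The corrected deuteration percentage is

$$D\% \;=\; 100\cdot
  \frac{c_P - c_N}{c_F - c_N}\cdot\frac{1}{R\,f},$$

with $c_P$, $c_N$, $c_F$ the partially deuterated, nondeuterated and
fully deuterated centroids, $R$ the deuterium recovery surviving
back-exchange and $f$ the buffer D2O fraction. Two assumptions matter:

* **Computed full-deuteration reference.** $c_F$ is computed as
  $c_N + N_\mathrm{ex}\,\Delta m_D/z$ rather than measured, where
  $N_\mathrm{ex}$ counts exchangeable amides and
  $\Delta m_D = 1.00628$ Da. A measured fully-deuterated control, when
  available, can be supplied instead; it already embodies the
  back-exchange loss, so only the buffer-fraction part of the correction
  is then applied (`measured_full = TRUE`).
* **EX2 kinetics.** Uptake is treated as a gradual centroid shift of a
  unimodal envelope. Bimodal (EX1) exchange, co-eluting overlapped
  envelopes and retention-time drift are out of scope; peptides affected
  by such artifacts should be excluded upstream, mirroring the common
  practice of discarding co-eluting peptides.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `recovery` | 0.70 | fraction of incorporated deuterium surviving quench/digestion/LC |
| `buffer_d_fraction` | 0.80 | D2O fraction of the labeling buffer; uptake plateau |
| `deuterium_mass_shift` | 1.00628 Da | mass(2H) − mass(1H); not an instrument constant to tune |
| `timepoints` | 0, 60, 240, 960, 1920, 3840 s | log-spaced exchange course |
| `sn_threshold` | 3 | peptides must exceed this S/N at every point |
| `last_k` | 3 | late timepoints entering the paired t-test |
| `alpha` | 0.05 | classification threshold |
| `exclude_n_term` | 1 | amide rule: exclude N-terminal residue (and prolines); 2 excludes the first two residues |

The exchangeable-amide rule (`length − 1 − internal prolines`) feeds the
computed $c_F$, so changing `exclude_n_term` rescales all percentages;
the default (exclude one N-terminal residue) is the most common
convention, and the two-residue alternative is provided because both are
in routine use and the underlying experiments cannot distinguish them.

## Differential statistics

Protection by a ligand is tested per peptide ion with a two-sided paired
Student t-test on the **last `last_k` timepoints** (pairs are
timepoint × replicate; df = 2 in the single-series design). The test
basis is the raw centroid by default: corrected uptake is an increasing
affine transform of the centroid per ion (shared reference, fixed scale),
so t and p are identical on either basis except where clamping breaks
the affinity — a property the test suite asserts rather than assumes.
ΔHDX% is reported as apo − holo mean corrected uptake over the selected
timepoints; positive differences mean protection. No multiple-testing
correction is applied by default, matching common single-study practice;
Benjamini–Hochberg is available via `adjust = "BH"`.

Two degenerate cases are flagged rather than silently propagated: all
differences exactly zero (`untestable`) and constant nonzero differences
(t = ±∞, p = 0, `zero_variance`).

A structural caveat the simulator makes visible: when the apo−holo
centroid difference still *trends* over the last three timepoints, the
trend inflates sd(d) and caps the attainable t regardless of noise
(a linearly growing difference cannot exceed |t| = 2√3 ≈ 3.46 at df = 2).
Late-timepoint pairing therefore favors differences that have stabilized —
a genuine property of this design, not an implementation artifact.

## Residue projection, structure and conservation

Peptide ΔHDX is projected onto residues as the **unweighted mean over all
covering peptides**. Alternatives (shortest-peptide-wins, formal
back-calculation) exist, but with typical 8–20-residue pepsin fragments
the unweighted mean is the transparent default and the overlap rule is
isolated in one function should a different policy be needed. Peptides
that match the protein at more than one position are ambiguous and
excluded from projection by default. Undetected residues carry `NA`
internally; in the recolored PDB they receive a sentinel B-factor
(default 0.00) and are listed in a sidecar CSV — coloring them
distinctly (e.g. green) is a viewer concern. The B-factor writer touches
only columns 61–66 of ATOM/HETATM records of the selected chain,
byte-for-byte, and a residue-number `offset` reconciles mature-protein
numbering with crystal numbering.

Conservation per alignment column is the modal non-gap symbol frequency
over all sequences (entropy-based scoring behind `method = "entropy"`);
columns gapped in the reference are unmapped. The report is a Spearman
rank correlation between residue conservation and residue ΔHDX — a sign
and rank statement only, which is all the qualitative
conservation-vs-protection comparison supports.

## The synthetic-data generator

The simulator emulates the stated experiment: a ~190-residue protein,
57 overlapping pepsin-style peptides (8–20 residues, lognormal S/N with
roughly a fifth failing S/N > 3), three conditions (apo plus a soluble
hexasaccharide and a polymeric substrate), the six-point time course,
$f = 0.80$, $R = 0.70$, and 5% multiplicative intensity noise.

* **Kinetics.** Each exchangeable amide exchanges first-order at $k_i/P$,
  with intrinsic rates $k_i$ sampled log-uniformly over
  $10^{-4}$–$10^{-1}\,\mathrm{s^{-1}}$ and a regional protection factor
  $P \ge 1$. Sequence-dependent (Bai–Englander) intrinsic rates are
  deliberately not used: truth-recovery tests need simple, known rates.
  The rates are sampled once per ground truth; *replicating* an
  experiment (`residue_rates =` a fixed vector) redraws measurement noise
  only, which is what replicate experiments on one protein do.
* **Default truth.** The chain is tiled into six regions; apo is
  unprotected ($P = 1$), the soluble ligand strongly protects two regions
  ($P$ = 8 and 5; a binding groove and an adjacent loop in the emulated
  system), the polymeric ligand weakly protects one ($P$ = 2.5),
  reflecting a soluble-oligosaccharide versus insoluble-polymer binding
  contrast. Under this world the apo grand-mean uptake is ≈65–70%, higher
  than the ≈50% a real xylanase shows — the log-uniform rate window is
  fast relative to a real protein's tail of very slow amides; the stated
  default was kept rather than tuned.
* **Spectra.** The natural isotopic envelope comes from the peptide's
  exact elemental composition (exact convolution over C/H/N/O/S isotopes,
  aggregated by nominal mass at unit resolution — no averagine); the
  deuterium count is Poisson-binomial over per-residue probabilities,
  each multiplied by $R$ to emulate independent per-deuteron retention;
  intensities get multiplicative lognormal noise (mean 1, CV
  `noise_cv`). Deterministic under a seed, byte-identical outputs.

**What a green test establishes — and what it does not.** The simulator
shares the analysis pipeline's definitions of amide counting and the
deuterium mass scale, so round-trip tests validate the *algebra and code*,
not those conventions themselves. It does not emulate chromatographic
co-elution, EX1 bimodality, peak-detection errors, m/z calibration drift,
or intensity-dependent (shot-noise) variance; conclusions about the
pipeline's robustness to those effects cannot be drawn from these tests.

## Numerical choices

* Envelope peaks below $10^{-10}$ relative abundance are dropped; the
  threshold is set so a noise-free t = 0 centroid matches the analytic
  natural-envelope centroid to $10^{-9}$ Th.
* Corrected uptake in (100, 105] clamps to 100 with a `clamped` flag
  (a tiny $10^{-7}$ guard absorbs pure floating-point overshoot); values
  above 105 raise an error, since with a realistic maximum near 96% a
  large overshoot means a broken reference. Negative values floor at 0
  with a `floored` flag.
* Replicates are aggregated as the arithmetic mean of centroids with the
  standard deviation retained; the nondeuterated reference is shared
  across conditions by default (one time-0 measurement per ion) and can
  be made per-condition.
* The time-0 reference uses the mean of all available time-0 centroids;
  a missing reference is an error naming the peptide/condition rather
  than an NA that would silently drop curves.

## Known limitations

Single-factor back-exchange correction (no per-peptide recovery);
no deconvolution of overlapping envelopes; no kinetic-model fitting or
mixed-effects testing (the paired t on late timepoints is the method
under study, including its trend-related power cap); no in-silico
digestion — the peptide table is authoritative; conservation scoring
ignores substitution similarity; the CA-trace `synthetic_pdb()` is a
synthetic stand-in for exercising the B-factor path, not a structure.
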