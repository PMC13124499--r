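---
title: "Identifying and quantifying somatic mutant peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and quantifying somatic mutant peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteomut)
```

# The problem

A patient's tumor carries somatic mutations; a subset is translated and some
of the resulting mutant proteins are packaged into extracellular vesicles
(EVs) that reach body fluids. A mutant peptide observed in urine is, by
construction, tumor-derived, which makes it a highly specific liquid-biopsy
analyte. `proteomut` implements the full desk-scale workflow: filter somatic
variant calls, build a patient-specific mutant protein database, identify
mutant peptides by database search with false-discovery control and
mutation-site validation, and quantify them absolutely by parallel reaction
monitoring (PRM) against stable-isotope-labeled standards.

This vignette records the model, the parameters that matter, the design
choices made where the design was genuinely open, and what the tests do and
do not establish. Nothing claimed here is asserted beyond what the test
suite and `scripts/acceptance.R` themselves compute.

# Somatic variant filtering

A variant passes when **all four** hold, with strict comparisons:

* tumor variant reads > 3;
* normal variant reads < 3;
* tumor VAF (= alt reads / total reads, 0 at zero depth, flagged) > 0.05;
* not in a simple repeat.

Boundary values (3 tumor reads, 3 normal reads, VAF exactly 0.05) therefore
*fail*. VAF is always recomputed from the table's read counts rather than
trusted from an annotation, and simple-repeat membership is an input flag:
repeat annotation is an upstream responsibility. The thresholds are
configurable in `pipeline_config()`, the strictness is not.

# Mutant database construction

* **Missense** entries: the substituted residue with up to 25 reference
  residues on each side. Near a terminus the window truncates (no padding);
  an interior mutation gives a 51-residue entry with the substitution at
  offset 26. Substitutions to a stop (e.g. selenoprotein readthrough
  artifacts) are rejected — the database alphabet is the 20 canonical
  residues.
* **Frameshift** entries: the last 24 unaffected reference residues followed
  by the shifted-frame ("neo-frame") translation up to but excluding the
  first stop codon. An immediate stop leaves the 24-residue lead alone; a
  missing downstream stop lets the entry run to the transcript end and sets
  a flag.
* Variants may be given at protein level (position + alternate residue) or
  CDS level; CDS-level missense calls are re-translated and must agree with
  the stated alternate residue, which catches coordinate bookkeeping bugs.
* Duplicate mutant sequences are collapsed with all provenance kept, entry
  order is deterministic (reference order, then accession/position), and
  each target gets one full-sequence-reversed decoy (`rev_` prefix;
  palindromic sequences are flagged, not dropped).
* Entries are built per variant independently. Co-occurring variants on one
  transcript (haplotypes) are not combined — with the shallow per-gene
  mutation counts this workflow targets, overlapping 51-residue windows are
  rare, and per-variant entries keep provenance unambiguous.

# Identification

**Digestion.** Trypsin/LysC: cleave after every K (LysC cleaves K-P) and
after every R not followed by P; up to 2 missed cleavages; peptide length
6–30. The length bounds are applied uniformly to every search.

**Fragment theory.** Monoisotopic residue masses; fixed carbamidomethyl-C
(+57.02146 Da); variable Met oxidation (+15.99491 Da, at most 4 per
peptide); water 18.0105646 Da, proton 1.007276 Da. b and y ions satisfy the
complementarity identity `b_i + y_{n-i} = M + 2·1.007276` (singly charged),
which the suite asserts property-style. Only singly-charged fragments are
generated by default (configurable to 1–2): the scorer's closed forms and
the simulator are defined on that ladder, and the original ion-trap charge
usage is not something this package can settle.

**Scoring and FDR.** The score is deliberately simple and fully
deterministic: matched-ion count plus the cosine between square-root
intensities of the matched theoretical ladder and the observed peaks. It
stands in for commercial engines whose behavior is out of scope; the FDR
contract is what matters. q-values come from classic target-decoy
competition: FDR(s) = #decoys(≥s) / max(1, #targets(≥s)), q = running
minimum over descending score, filtered at q ≤ 0.01. Score ties break
deterministically (target before decoy, fewer modifications, lexicographic).

**Site validation.** For a mutant peptide of length n with the mutation at
offset m, the site-determining ions are `{b_i : i ≥ m} ∪ {y_j : j ≥ n−m+1}`,
both series capped at the maximal fragment index n−1 (a "y_n" ion is the
precursor, not a fragment; for m = 1 only b ions can localize the site). A
mutant PSM supports its mutation when at least one matched fragment is
site-determining; a strict mode additionally demands full b/y ladder
coverage of the sequence. A peptide that also occurs in any reference entry
is never mutant evidence, whatever it matches.

**Detection rule.** A mutant protein is "detected" in a sample only with at
least one PSM passing *both* the q ≤ 0.01 filter and site support. The
landscape report never flags a mutation on weaker evidence.

# PRM quantification

The heavy (spiked) standard defines the retention time, so the heavy channel
is detected first and the light peak is anchored to the heavy apex — with
two peaks in the window, the light channel takes the one nearer the anchor,
the heavy channel the larger. Peak detection subtracts the window median,
smooths with a 3-point moving median, requires apex signal-to-noise ≥ 3, and
places boundaries where the smoothed signal falls below 5% of the apex.
Integration is trapezoidal with a linear baseline between the boundary
intensities, floored at zero. Then

`amount (fmol) = spike (fmol) × AUC(light) / AUC(heavy)`

which is scale-invariant and exact for co-eluting peaks of the same shape
(both channels lose the same boundary fraction, so the ratio cancels — the
noiseless recovery tests exploit this). An undetected heavy standard yields
a quantification-failure flag, not a number. Co-elution requires apex
agreement within 0.2 min, inclusive at the boundary. Per-analyte/timepoint
summaries are the mean ± SE over detected transitions (SE = sd/√n, n = 3 by
default); the pre/post-surgery comparison is a classical two-sided paired
Student's t test on per-analyte raw amounts (pre vs first post timepoint),
with a degenerate flag when all differences are zero. A log-scale mode
exists but is not the default: the raw-scale test is the conventional
report, and with fold changes near 0.05 the conclusion is insensitive to the
choice. No multiple-testing adjustment is applied across analytes; reports
say so.

# The synthetic-data generator

The generator is first-class, tested code that emulates the statistical
structure the analysis assumes:

* **Reference set** — uniform protein lengths on [60, 400] (60 guarantees
  room for full missense windows in most placements), uniform residue usage,
  CDS assembled from synonymous codons plus a stop; translation round-trips
  exactly, by construction.
* **Variants** — true somatics draw tumor alt reads binomially at a true VAF
  ~ U(0.15, 0.6) with Poisson(100) depth and a 0.001 normal error rate;
  negatives are planted in four flavors, one per filter clause, so each
  clause is exercised. Draws that would contradict a planted label are
  clamped (e.g. a "somatic" draw landing at 3 alt reads is raised): the
  stated world of the recovery tests is *well-separated* truth, and the
  clamp realizes exactly that. Consequently, a green "filter = truth" test
  establishes correct clause logic, not filter performance on borderline
  real-world variants. Default depth and VAF ranges are choices (the
  upstream study does not state purity or depth); both are configurable.
* **Spectra** — peaks at the theoretical singly-charged b/y m/z with
  per-fragment dropout (default 0.1), multiplicative lognormal intensity
  noise (sdlog 0.3) around an exponential-decay intensity ladder
  (`exp(-0.05·(index−1))` — no intensity model is published for these data,
  so the simulator and scorer share one simple ladder), m/z jitter
  (SD 0.05 Da) hard-bounded at 0.3 Da so jittered peaks stay inside the
  0.6 Da match tolerance, and uniform random noise peaks. Real spectra are
  uglier: chimeras, isotope envelopes, charge-reduced species and retention
  time are all out of scope, so planted-recovery results bound bookkeeping
  correctness, not real-instrument sensitivity.
* **Chromatograms** — Gaussian peaks (σ = 0.05 min, sampled at σ/10, window
  ±10σ) whose analytic area is amount × response factor, plus non-negative
  clipped additive Gaussian baseline noise; light and heavy co-elute by
  construction. At σ/10 sampling, trapezoidal integration is accurate to
  well under 0.1%, which is what the linearity tolerance tests assume.
* **Longitudinal series** — per-timepoint true amount = pre-amount (first
  point) or pre-amount × fold-change (later points), with mean-preserving
  lognormal transition noise at the configured CV.

Random streams are partitioned per generator (sequences, variants, spectra,
chromatograms) from the master seed, so adding one stage never perturbs
another and fixtures stay stable.

# Numerical choices and degenerate inputs

* Zero tumor depth ⇒ VAF 0, clause iii fails, row flagged — never a
  division error.
* Fragment matching is greedy nearest-peak within ±0.6 Da; each observed
  peak is used at most once; ties break toward smaller absolute error, then
  larger intensity.
* Precursor tolerance is 10 ppm on m/z at the spectrum's charge.
* Empty spectra score 0; spectra with no candidate in tolerance are reported
  unidentified, not errors.
* `spectral_similarity` bins at the fragment tolerance and square-root
  transforms intensities; an empty spectrum returns 0 with a flag.
* The peak-boundary design (5% of apex after smoothing) deliberately trades
  a small fixed area fraction for robustness; absolute amounts are immune
  because the light/heavy ratio cancels the fraction.

# Known limitations

* The scorer is not a drop-in for Mascot/Sequest/percolator; q-values are
  classic target-decoy without rescoring.
* No retention-time or isotope-envelope modeling; no FAIMS behavior; no
  DIA quantification; no fusion/splice-level variants; no HLA-binding
  logic.
* Heavy-label compositions are validated against residue atom content
  (C6/N2 for Lys, C6/N4 for Arg) and the mass shift is always computed from
  the configured counts; the package takes no position on any particular
  reagent's composition.
* The landscape and association statistics are per-sample descriptive
  outputs; with a handful of analytes the paired test has only n−1 degrees
  of freedom and should be read accordingly.
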