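---
title: "Methods: plastome structure, codon usage bias, and selection in plastocub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structure, codon usage bias, and selection in plastocub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastocub)
```

plastocub implements the comparative analyses routinely applied to annotated
plastid (chloroplast) genomes: the quadripartite LSC/IRb/SSC/IRa architecture
and its junction geometry, per-gene codon-usage-bias statistics with three
inferential diagnostics, sliding-window nucleotide diversity, and pairwise
Ka/Ks selection scans. This vignette explains each model, its assumptions,
the tunable parameters, and the design choices that were genuinely open.

## The quadripartite partition

Most plastomes carry two exact (or nearly exact) reverse-complementary
repeat copies (IRb, IRa) separating a large and a small single-copy region
(LSC, SSC). `detect_inverted_repeats()` finds the maximal-length pair of
disjoint, exactly reverse-complementary substrings of the circular sequence
with length at least `min_len` (default 1000 bp), by seed-and-extend on
24-mers shared between the doubled sequence and its reverse complement.
Seeds on a common diagonal merge into maximal runs, so detection is exact at
single-base resolution.

Choices worth stating:

* **Mismatch tolerance is 0.** Annotated IR pairs in the liverwort plastomes
  this package targets are identical-length exact copies, and exactness gives
  a testable contract (the planted-repeat recovery property). Sequences whose
  two IR copies differ are reported as "no quadripartite structure" rather
  than approximated; a mismatch-tolerant mode was deliberately left out
  because junction placement under mismatches has no ground truth to validate
  against.
* **Canonical orientation.** The genome is reported as LSC → IRb → SSC → IRa
  with LSC the longer single-copy arc and LSC base 1 as the origin. The
  partition carries an `offset` mapping input coordinates onto this frame,
  which makes partitioning rotation-invariant: any rotation of the circular
  sequence yields the same canonical linearization byte for byte.
* **Junction convention.** A junction belongs to the last base of its
  upstream region (JLB = end of LSC, JSB = end of IRb, JSA = end of SSC,
  JLA = genome end). A gene "spans" a junction when it covers that base and
  the next one; its `overlap_bp` counts bases strictly inside the IR-side
  region, which reproduces border-gene figures of the form "64 bp located
  within IRb".
* **Ties.** Multiple maximal repeat candidates of equal length are broken
  deterministically at the smallest start, with a warning.

`extract_lsc_irb_ssc()` drops the IRa copy, the standard redundancy-removal
step before whole-plastome phylogenetics; appending the reverse complement of
the IRb segment reconstructs the genome exactly.

## Codon usage statistics

CDS are assembled on the coding strand (minus-strand and multi-segment
locations resolved in extraction order), deduplicated when the IR duplicates
a gene, and filtered: at least 300 bp, length a multiple of 3, a valid start
codon, a terminal stop, no internal stop. The start-codon policy defaults to
the plastid table-11 set {ATG, GTG, TTG}; `atg_only` is available because
published CDS counts sometimes reflect the stricter rule, and every rejection
carries a machine-readable reason so the two policies can be reconciled.
Trans-spliced genes (rps12-style) are rejected from codon-usage work: their
assembled reading frame depends on annotation conventions that differ between
depositors.

Each statistic is computed over its own codon exclusion set, all under
translation table 11 (whose residue assignments equal the standard code, so
the familiar synonymous-family structure applies):

| statistic | excluded codons | scale |
|---|---|---|
| GC1, GC2, GC3 | stops | percent |
| P1, P2, P3, P12 | ATG, ATA, TGG, stops | fraction |
| A3s, T3s, C3s, G3s | ATG, ATT, ATC, ATA, TGG, stops | fraction |
| GC3s | ATG, TGG, stops | fraction |

The terminal stop codon is removed before counting; `codon_counts()` itself
counts every triplet (callers apply exclusions), and codons containing N are
skipped and tallied separately.

RSCU is the codon count divided by its synonymous family's mean count;
family sums equal the family size exactly whenever the family is observed,
Met and Trp are reported as 1.0 by convention, and unobserved families are NA
rather than 0 to keep "absent" distinct from "maximally avoided".

ENC follows Wright's estimator: per amino-acid family with n observed codons
and frequencies p, F = (n·Σp² − 1)/(n − 1); class means over degeneracy
classes give ENC = 2 + 9/F̄2 + 1/F̄3 + 5/F̄4 + 3/F̄6, using only families with
n ≥ 2 and F > 0. A missing 3-fold class (Ile unobserved) is imputed as the
mean of the 2- and 4-fold means; a missing 2-, 4- or 6-fold class makes ENC
undefined (NA) rather than extrapolated. Values cap at 61. The estimator is
validated at both analytic anchors: single-codon usage per family gives
exactly 20, and the all-families-(3,1) construction gives exactly 38.

## The three diagnostics

**ENC–GC3s.** The mutation-only reference curve is
ENC = 2 + s + 29/(s² + (1−s)²) for third-position synonymous GC content s.
Genes near the curve are compatible with purely compositional codon choice;
genes below it indicate selection among synonymous codons. The per-gene
relative deviation (expected − observed)/expected is reported instead of
confidence bands, whose published constructions vary and are rarely stated.

**PR2.** Each gene is placed at x = G3s/(G3s+C3s), y = A3s/(A3s+T3s);
(0.5, 0.5) is the strand-symmetric point where A=T and G=C. One property of
the conventional axes deserves emphasis: because the exclusion set removes
TGG (and the stops TAA/TAG/TGA), G- and A-ending codons are depleted
asymmetrically, and even a geneset generated under perfectly symmetric
mutation plots below-left of center. Simulation makes this concrete: 200
genes sampled with equal base probabilities at every position reject quadrant
uniformity on the default axes (chi-square p below 10⁻¹⁰, lower-left the
modal quadrant), but are uniform on fourfold-degenerate-site axes
(`pr2_analysis(..., fourfold_only = TRUE)`), which are free of the artifact.
Lower-left clustering on the default axes therefore overstates T/C
preference slightly; the fourfold switch is the control for that.

**Neutrality plot.** Ordinary least squares of P12 on P3 (via `lm()`), with
Pearson's r and its exact t-transform p-value (n − 2 degrees of freedom, via
`cor.test()`). A slope near 1 means positions 1–2 track the same
compositional pressure as position 3 (mutation dominates); a slope near 0
means positions 1–2 are held by selection on the protein. The slope × 100 is
reported as the percent contribution of mutation pressure. The regression
requires at least 3 genes and non-degenerate var(P3), and errors name the
violated condition.

## Nucleotide diversity

π is the mean pairwise per-site difference: over alignment columns with no
gap or N in any sequence, π = 2/(n(n−1)) Σ d_ij with d_ij the fraction of
usable sites at which sequences i and j differ. Gap/N columns leave both
numerator and denominator (complete exclusion), matching common practice in
sliding-window diversity tools. Windows are 600 bp with a 200 bp step by
default — the conventional parameterization for plastome hypervariable-region
scans — defined on alignment coordinates, starting at 1 while they fit; a
window longer than the alignment degenerates to one truncated window. Window
labels come from the reference genome's annotation at the mapped midpoint
(gene name, "upstream~downstream" for intergenic, "unaligned" at reference
gaps). The summary reports the mean over windows; a per-site average over all
usable columns can be had from a single whole-alignment window.

## Ka/Ks by Nei–Gojobori counting

`ng86()` implements the counting estimator in full:

* **Sites.** At each codon position the synonymous fraction is the number of
  synonymous single-base changes divided by the number of changes not
  creating a stop; a position whose every change creates a stop carries no
  site mass (this never triggers under the standard stop set but the
  normalization matters — it is what makes a TTA second position contribute
  zero synonymous sites over one non-stop change). S averages the two
  sequences' site sums; N is the remaining mass.
* **Differences.** Codon pairs differing at 2–3 positions average their
  synonymous/nonsynonymous step counts over all orderings of the
  substitutions, excluding pathways that pass through a stop codon; pairs
  whose every pathway is blocked are flagged and excluded rather than
  guessed. All 61×61 pair decompositions are precomputed once, so the scan
  is a table lookup.
* **Correction.** Jukes–Cantor, d = −(3/4)ln(1 − 4p/3), with explicit
  sentinels instead of numeric surprises: `undefined_Ks0` when no synonymous
  divergence exists, `saturated` when p ≥ 3/4, `undefined_sites` when a site
  class is empty.

Codon alignments are protein-guided: translate, globally align the proteins
(BLOSUM62, gap open 10, gap extend 0.5, via Biostrings), transfer gaps back
to codons, drop gapped columns and terminal stops. Site averaging makes the
estimator exactly symmetric in its two inputs.

Counting estimators and ML codon models disagree numerically on fast-evolving
genes; the deliverable claims here are the selection *classes* (default
neutral band 0.95–1.05), which are robust for clearly purifying genes. Per
simulation, the median estimated ω is within 20% of truth at ω ∈
{0.1, 0.5, 1.0} and expected Ks ≈ 0.3 over 500 codons.

## The synthetic-data generator

The generator exists so every stage can be validated against planted truth
without downloads. Its defaults are the study conditions used throughout the
tests and the analysis scripts:

* **Genome scale.** LSC 12 kb, IR 1.5 kb, SSC 4 kb (19 kb total) — a
  six-fold scale-down of a typical 118 kb liverwort plastome that preserves
  the length ordering LSC > SSC > IR and keeps the full suite inside desk
  timescales. Ten CDS (six LSC, three SSC, one IR-resident and therefore
  duplicated) with 150–600 codons each.
* **Composition.** Positional base weights give GC ≈ 0.43/0.37/0.18 at codon
  positions 1/2/3, mimicking AT-rich organellar coding sequence, so synthetic
  RSCU tables show the familiar U/A-ending preference; single-copy intergenic
  filler at GC 0.30 and IR filler at GC 0.46 reproduce the compositional
  contrast between IR and single-copy regions.
* **Planted maximality.** After assembly the generator breaks accidental
  single-base extensions of the repeat at both flanks, so the planted IR is
  exactly the maximal repeat and the detector's output can be required to
  equal it with tolerance 0. Junction-spanning genes are planted by
  coordinate arithmetic; a JSB-spanning and a JSA-spanning gene cannot
  coexist in one synthetic genome because the repeat mirror would force
  their sequences to overlap (real genomes satisfy that constraint
  automatically; the generator raises an error instead of corrupting a CDS).
* **Divergence.** Substitution-only (no indels, so derived genomes stay
  column-aligned): noncoding sites i.i.d. at the noncoding rate, coding sites
  proposed at the coding rate and accepted if synonymous, with probability ω
  if nonsynonymous, never if a stop would appear; start and terminal stop
  codons are frozen; the substituted base is G/C with probability `beta`.
  IRa is re-mirrored after mutation, so repeat copies co-mutate and stay
  exact reverse complements.
* **Codon pairs for ω recovery.** An ancestor is sampled from the codon
  model; one lineage accumulates accepted substitutions until the expected
  synonymous divergence (through the Jukes–Cantor map) reaches `target_ks`.
  Multiple hits arise naturally, which is what makes the correction step
  testable.
* **Neutrality genesets.** Each gene draws its own GC pressure uniformly in
  `beta ± 0.2` (default beta 0.45 — wide enough compositional spread for a
  stable regression); position-3 composition always follows it, positions
  1–2 follow it with weight (1 − constraint) and the fixed global value with
  weight `constraint`. The regression slope therefore has expectation close
  to 1 − constraint, mildly attenuated by finite-gene sampling noise (400
  codons per gene keeps the attenuation within the asserted 0.8–1.2 band at
  constraint 0).

Everything is a pure function of (spec, seed), with RNG state scoped to the
call.

What the generator does **not** emulate: indels and rearrangements, tRNA/rRNA
sequence realism, context-dependent mutation, among-gene rate heterogeneity
beyond the planted ω map, IR expansion/contraction, and annotation errors.
Passing tests therefore demonstrate correctness of the computations under a
clean substitution-only model, not robustness to messy real annotations —
the GenBank parser's warnings-and-reasons design is the mitigation for the
latter.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive everywhere (GenBank convention);
  origin-wrapping segments are supported on circular records only.
* Ambiguity codes other than N normalize to N with a warning; codons
  containing N are skipped and counted.
* Statistics whose eligible codon set is empty are NA, never 0; π over zero
  usable sites is NA with `usable_sites = 0`; ENC with a missing mandatory
  degeneracy class is NA.
* Report writing rounds GC percents to 1 decimal, π to 4 decimals, ENC and
  Ka/Ks to 2–4 decimals, with fixed row ordering (genome, then gene), so
  identical inputs produce byte-identical TSVs.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` run at desk scale: 19 kb genomes
(6–12 kb LSC, 1.2–1.5 kb IR), 50 generator seeds for repeat recovery, star
trees of 4 × 4 kb for diversity calibration, 50 replicates × 3 ω values of
500-codon pairs for Ka/Ks recovery, and 200-gene × 400-codon genesets for the
neutrality slope. These sizes were chosen so each property is measured with
comfortable statistical margin while the whole suite stays in the
half-minute range.

## Known limitations

* IR detection is exact-match only; genomes whose repeat copies differ by
  even one base are reported as lacking quadripartite structure.
* The NG86 estimator saturates near p = 3/4 and is reported as a sentinel
  there; no ML codon model is provided.
* The neutrality regression treats genes as independent observations, as the
  convention requires; shared mutational history is not modeled.
* `label_windows()` labels by the window midpoint only; a window straddling
  a gene boundary carries the midpoint's label.
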