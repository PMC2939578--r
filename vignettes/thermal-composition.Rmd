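---
title: "Temperature-associated amino-acid composition bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-associated amino-acid composition bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaa)
```

## The scientific question

Proteins of organisms living at high temperature tend to carry more of the
residues that stabilise surface electrostatics (E, R, K) and fewer of the
residues that destabilise structure (D, N, Q, T, S, H, A). Two summary
statistics quantify this on plain sequence data:

* **ERK** = E + R + K − D − N − Q − T − S − H − A,
* **CvP-bias** = D + E + R + K − N − Q − T − S,

where each letter is the fraction of that amino acid among all residues of a
protein (or of a concatenated proteome). Both are reported here in
percentage points, so whole-proteome values land around −16 to −18 for
vertebrates and shift by fractions of a point with temperature. The two
measures differ only in how D, H and A are treated; algebraically,

CvP − ERK = 100 · (2·D + H + A),

an identity the test suite asserts on random sequences.

Two statistical traps surround the question:

1. **Phylogenetic pseudo-replication.** Related species resemble each other
   in both habitat temperature and composition by descent alone, so naive
   cross-species correlations overstate significance. The package
   implements Felsenstein's independent contrasts and a permutation null
   for the contrast correlation to address this.
2. **Nucleotide-level confounding.** Genome GC content and purine loading
   drive amino-acid composition. The codon-matched controls recompute ERK
   on exactly those aligned codon pairs whose G+C (or A+G) counts agree
   between two species, so any residual ERK difference cannot be a GC
   (purine) artifact.

## Composition statistics

`aminoAcidFrequencies()` counts only the 20 standard letters; ambiguity
codes (X, B, Z, U) and stops are excluded from numerator *and* denominator,
so fragmentary assemblies do not dilute the composition. Proteome-level
values (`proteomeBias()`) come from pooled residue counts — equivalent to
concatenating all proteins — never from averaging per-protein values, which
would weight a dipeptide like a titin.

Codon-class usage (`codonClassFractions()`) reports the percentage of
codons encoding the AT-rich amino-acid set (F, Y, M, I, N, K) and the
GC-rich set (G, A, R, P). The FYMINK/GARP dichotomy is the field's standard
coarse classification and is the default because it produces class
percentages on the ~23–25% scale observed for vertebrate ortholog sets; an
alternative scheme classifying codons by their own bases (all three A/T vs
all three G/C) is available and recorded in the output, since the coarse
classification of "AT-rich codon" is a modelling choice, not a fact of the
genetic code.

## Independent contrasts and the permutation null

`independentContrasts()` implements the pruning recursion directly: at an
internal node with child values x1, x2 on (extended) branches v1, v2, the
standardized contrast is (x1 − x2)/√(v1 + v2); the node receives the
precision-weighted mean and its parent branch grows by v1·v2/(v1 + v2).
Child order — hence contrast sign — follows the newick string, making runs
reproducible; all downstream statistics are invariant to sign flips. The
implementation is cross-checked in the tests against `ape::pic` and against
hand-executed recursions on trees of up to five leaves.

Because contrast signs are arbitrary, the correlation of two contrast sets
is computed **through the origin**: R = Σxy / √(Σx²·Σy²), with p from the t
distribution on n_contrasts − 1 degrees of freedom (no intercept is
estimated). Positivization — flipping pairs so one trait's contrast is
non-negative — is offered for diagnostics but cannot change R.

`randomizationPvalue()` permutes one contrast vector N times (default
9999) with a seeded generator and counts permutations whose correlation is
at least as extreme as the observed one, *in the direction of the observed
R*. With the observed data treated as one extra randomization,
p = (k + 1)/(N + 1), bounded below by 1/(N + 1). Two consequences worth
knowing:

* An exceedance count of 498 at N = 9999 gives exactly p = 499/10000.
* Because the direction is chosen by the data, the null distribution of p
  is approximately uniform on (0, 1/2] rather than (0, 1]; the calibration
  test asserts P(p ≤ a) ≈ 2a under independence. A sign-flip null is
  available behind `nullModel = "signflip"` but permutation is the default,
  matching the idea of "randomising the association" between the two
  contrast sets.

**Zero branches.** Contrasts divide by branch lengths, so zero-length
branches (common in published trees after rounding) are replaced by half
the shortest positive branch (`adjustZeroBranches()`); a fixed replacement
value is available. Polytomies are rejected by default; an opt-in policy
resolves them arbitrarily into zero-length branches and then applies the
same rule.

## Orthology

`reciprocalBestHits()` uses bit score as the ranking criterion (it is
independent of database size), with a deterministic tie ladder: bit score,
then e-value, then lexicographically smallest subject id. Hit tables are
reduced to their best HSP per (query, subject) pair on reading, by the same
ladder. `lifestyleFilteredSet()` retains proteins with at least one
ortholog outside their life-style group, controlling for repertoire
differences between thermophiles and mesophiles; `coOrthologGroups()`
builds reference-anchored groups that are complete across a panel.

`alignPair()` provides a global Needleman–Wunsch alignment (BLOSUM62, gap
open 11, extend 1 — BLAST's protein defaults) for desk-scale segment
comparisons. Externally produced alignments are accepted as aligned
sequences everywhere alignments are consumed; the built-in aligner exists
so the whole pipeline can run without external tools, not to replace a
production aligner.

## Codon-matched controls

`backmapCodons()` replaces each aligned residue with its encoding codon
after verifying that the CDS translates exactly to the (ungapped) aligned
protein; gap columns and codons with ambiguous bases are dropped and
counted. "Same GC content" is interpreted per aligned codon pair as an
equal integer G+C count (0–3) — the coarsest faithful reading of matching
aligned codons on GC — and analogously A+G for the purine control.
`matchedErk()` then recomputes ERK from the retained codons on each side.

Downstream, the per-gene (ERK_A, ERK_B) pairs are the unit of testing
(paired Wilcoxon across genes), not a single pooled codon set: pooling
would let a few long genes dominate, and per-gene testing matches how
ortholog-set comparisons are normally reported. Pooled computation remains
possible by concatenating `CodonPairAlignment` objects, and the filters
provably commute with concatenation.

## Hypothesis tests

`wilcoxonRankSum()` fronts `stats::wilcox.test`: the default normal
approximation uses the tie-corrected variance and a 0.5 continuity
correction; the exact method enumerates the rank-sum distribution and
refuses ties instead of silently falling back. On the published vertebrate
species table shipped in `inst/extdata`, the endotherm/ectotherm tests on
genomic-average ERK and on representative temperature give p = 0.0075 and
p = 0.0080 respectively under this convention.

A numerical note: the one-sided continuity-corrected normal approximation
agrees with exact enumeration to within 0.01 for tie-free groups of 5–8
(verified exhaustively over all rank configurations), but the two-sided p
doubles the tail and with it the approximation error — the exhaustive
worst case is 0.0155 at 6+6 and 0.0375 at 3+3. The agreement tests
therefore assert 0.01 one-sided and 0.02 two-sided; no tighter claim is
true at these sample sizes.

Temperature cells in trait tables may carry a representative value and a
range ("26 (24− 28)"); the leading value is authoritative, and a bare range
falls back to its midpoint. Prokaryote life-style classes derive from
optimal growth temperature: hyperthermophile ≥ 80 °C, thermophile
50–80 °C, mesophile ≤ 50 °C.

## The synthetic generator: what it emulates, what it does not

`generatorConfig()` fixes the study conditions; all generators are seeded
and reproducible.

| parameter | default | meaning |
|---|---|---|
| `nSpecies` | 50 | panel size |
| `birthRate` | 1 | Yule speciation rate (per unit branch) |
| `rootTemperature` | 50 °C | BM root value |
| `sigma2` | 100 °C²/branch | BM rate for the temperature trait |
| `clamp` | 0–103 °C | biological range; composition responds ~linearly to temperature over it |
| `beta` | 0.05 pp/°C | imposed ERK-vs-temperature slope |
| `proteinsPerSpecies` | 300 | proteome size |
| `lengthRange` | 100–300 aa | protein lengths (uniform) |
| `gc3` | 0.5 | third-position G/C probability |
| `substitutionRate` | 0.1 /site/branch | ortholog divergence |

Proteomes are drawn i.i.d. from the baseline (Swiss-Prot-like) frequency
vector tilted so the expected ERK equals baseline + β·(T − T_root): mass
β·ΔT/200 moves from the depleted to the enriched set, proportionally to
baseline frequencies within each set. Because ERK is a pure composition
statistic, i.i.d. sampling without site heterogeneity or ordering
structure is adequate for everything the pipeline measures. The proteome
size matters statistically: at 300 proteins of 100–300 residues the
per-species ERK counting noise is ≈ 0.3 pp, safely below the ≈ 1 pp
temperature signal — mimicking real complete proteomes, whose counting
noise is negligible. Much smaller proteomes would bury the contrast
correlation in amplified tip noise and misrepresent the conditions being
emulated.

Coding sequences choose synonymous codons with third-position G/C
probability `gc3`, so the codon controls have a real GC structure to
neutralise; translation round-trips exactly. Ortholog panels evolve each
gene family from a single ancestor along the tree (per-site substitution
probability 1 − exp(−rate·length), replacements from the baseline), and
emit hit tables whose bit scores are a deterministic, monotone function of
ungapped identity — sufficient for testing RBH recovery against known
truth, but *not* a model of BLAST statistics: e-values are synthetic
monotone transforms, there are no indels, no paralogs by default, no
domain structure, and no rate variation across sites or lineages. Passing
tests on these panels therefore demonstrate the correctness of the
pipeline's logic under its own assumptions, not robustness to the many
ways real genome data violate them.

The confounding scenario used in the tests places two clades of ten
species on either side of a deep split and gives one clade both a
temperature offset and an independent E-frequency drift. The naive
correlation, treating 20 species as independent, is strongly significant;
the contrasts reduce the coincidence to a single deeply-discounted data
point and stay non-significant. The depth of the split is essential — a
recent split is barely discounted — which is itself an instructive
property of the comparative method.

## Numerical choices and degenerate inputs

* Underflowing p-values are clamped to the smallest positive double so the
  invariant 0 < p ≤ 1 survives perfect correlations.
* All-zero contrast vectors make the through-origin correlation undefined
  and raise an error rather than returning NaN.
* Sequences with no countable residues (all X/stops), empty proteomes,
  internal stop codons, CDS/protein translation mismatches, unlabeled
  species and tree/panel mismatches all fail fast with the offending
  identifier or index in the message.
* Problem sizes in the test suite: panels of 20–50 species with 20–300
  proteins each, 200-leaf trees for Brownian-motion calibration, 500-gene
  sets for the codon-control power checks, and permutation counts of
  199–9999; the full suite runs in about a minute.

## Known limitations

* The comparative analysis assumes the supplied tree (topology and branch
  lengths) is correct; tree inference is out of scope.
* Only the standard nuclear genetic code is supported.
* The built-in aligner is global and desk-scale; e-values are never
  computed, only read from input.
* Many-to-many orthology (inparalog clustering) is not modelled; RBH
  yields one-to-one pairs only.
* No multiple-testing correction is applied anywhere, mirroring how such
  per-amino-acid tables are conventionally reported; users scanning the
  20-row profile should apply their own adjustment.
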