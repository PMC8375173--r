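---
title: "Methods: classifying plant C2H2 zinc-finger families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying plant C2H2 zinc-finger families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfsurvey)
```

## The biological model

A C2H2 zinc finger is a ~30-residue module in which two cysteines and two
histidines coordinate a single Zn²⁺ ion; the general consensus is
C-X(2–4)-C-X3-F-X5-L-X2-H-X(3–5)-H. Plant fingers additionally carry an
invariant hexapeptide, **QALGGH**, whose final histidine *is* the first
zinc-ligand histidine. Family-wide surveys in wheat, soybean, rice and
*Brassica* classify each finger by how intact this hexapeptide is and how
far apart the metal ligands sit, and each protein by how its fingers are
arranged. `zfsurvey` implements that scheme as an explicit, testable
procedure.

### Finger detection and typing

`scan_domains()` runs a two-pass scan with 1-based inclusive coordinates
(the R and GFF3 convention; outputs are directly reportable).

**Pass 1** enumerates complete C..C..H..H units subject to the
`scan_params()` bounds: 2–4 residues between the cysteines, 7–30 residues
between Cys2 and the first histidine (`spacing`), 3–5 between the
histidines. Two deliberate design rules:

* *The first ligand histidine is the first histidine after Cys2.* An
  earlier histidine would itself be the first ligand, so candidates with
  an intervening histidine are not admitted. This also prevents a
  truncated D-type finger from being absorbed into a spurious unit that
  borrows the histidines of the next finger downstream.
* *Overlaps resolve greedily leftmost-first* (candidates ordered by Cys1,
  then Cys2, H1, H2; accepted fingers never share residues). Greedy
  leftmost selection is deterministic and matches the exhaustive
  enumeration oracle used in the tests.

**Pass 2** revisits only the sequence not covered by pass-1 fingers and
emits **D-type** candidates: a cysteine pair whose first following
histidine falls in the spacing bounds but which lacks the second ligand
histidine (no further histidine within the H–H gap window inside the
uncovered segment). Restricting the search to uncovered segments means a
D finger packed tightly against a complete finger is still found.

Typing is a fixed cascade on the 6-residue window ending at the first
histidine:

1. no second histidine → **D**;
2. window `QALGGH` and spacing exactly 12 → **Q**;
3. 1–4 substitutions among the first five window residues → **M1–M4**
   (the subclass index *is* the substitution count — the published
   M-subclasses are never defined operationally, so the package declares
   this rule and makes the ceiling configurable via `m_max_mismatch`);
4. otherwise **Z**, split by spacing: ≥ 12 → **Z1**, < 12 → **Z2**.

Boundary decisions worth noting: an intact QALGGH at spacing ≠ 12 is Z
(the Q definition pins spacing at 12); a window with five substitutions
is fully degenerate and routes to Z rather than an "M5"; the Z1/Z2
boundary at exactly 12 goes to Z1, keeping the published ">12 / <12"
split total while leaving 12 distinct from Q only via the window. The F
and L of the general consensus are *not* required by default — the
Q-type definition X2-C-X2-C-X7-QALGGH-X3-H omits them — but
`scan_params(require_FL = TRUE)` provides the strict mode. `X` never
matches a ligand or window position: ligand identity must be certain.

### Tandem vs isolated, and the ten subsets

Adjacent fingers connected by **fewer than 12 residues** (gap ≤ 11) are
linked; maximal linked runs form tandem arrays. A protein is *tandem*
when any array has ≥ 2 fingers, *isolated* otherwise. The subset label
follows the field's naming: `Ta-t1-SF` for a single array covering every
finger, `Ta-t2-SF` for several arrays or an array plus dispersed fingers
(the published material never defines the t1/t2 split operationally;
this is the declared rule). Isolated proteins split by finger count and
collapsed type (M1–M4 → M, Z1/Z2 → Z): `Ta-1i-{Q,M,Z,D}-SF`,
`Ta-2i-{Q,M,Z}-SF` or `Ta-2i-Mix-SF` for unequal pairs, `Ta-3i-SF`,
`Ta-4i-SF`; proteins with five or more dispersed fingers (the family
reaches nine) are binned into `Ta-4i-SF` since no 5i+ subset is named.

Summary tables report protein-level percentages against classified
proteins and gene-level percentages against genes with a parseable
locus. Chromosome and arrangement percentages print at one decimal,
sub-genome and arm percentages at two — mirroring the mixed precision of
the source tables — with exact fractions carried alongside; rounding is
half-up.

### Accessory boxes

The EAR repression motif has concrete degenerate forms (`DLNxxP`,
`LxLxL`) and EAR-like variants (`LDLNL`, `LDLSL`, `FDLNI`); these ship
as matchable patterns. The subset-specific boxes (NPL-, SFP1-, DL-, R-,
PL-, L-, EK-box) are known only as sequence logos, so the library ships
them pattern-less with their expected location relative to the fingers,
and accepts user patterns via `read_motif_library()` — the package
refuses to invent consensus strings. Matching is leftmost
non-overlapping per pattern (different patterns may overlap); "N-/C-
terminal of a finger" means strictly outside its span, a 0-residue gap
included.

### Ka/Ks and divergence time

Substitution rates use the Nei–Gojobori (1986) counting method with
Jukes–Cantor correction: fractional synonymous site counts per codon
(changes to stop codons count as nonsynonymous), pathway-averaged
difference counts (orderings through stop codons are excluded; if every
ordering is blocked the differences count as nonsynonymous), proportions
against site counts averaged over the two sequences, and
`K = -(3/4) ln(1 - (4/3) p)`. Proportions at or beyond 3/4 are flagged
saturated rather than raising an error. NG86 was chosen over the
maximum-likelihood model-averaging estimators because it is fully
specified and oracle-checkable: the test suite verifies it against
explicit pathway enumeration over the entire 61 × 61 sense-codon grid.

Selection is called from ω = Ka/Ks with a configurable neutrality band
(|ω − 1| ≤ 0.05 by default; exact equality is measure-zero). Divergence
time uses the grass molecular clock `T = Ks / (2λ × 10⁻⁶)` Mya with
λ = 6.5 × 10⁻⁹ synonymous substitutions per site per year, so Ks = 0.013
corresponds to 1 Mya.

### Expression

TPM matrices are transformed as log2(TPM + 1) — the pseudocount pins
zero TPM at zero. A gene is *expressed* with TPM ≥ 0.5 in ≥ 1 sample
(the published 198-of-204 count is not accompanied by a stated
threshold; these are the declared defaults). Expressed genes cluster by
average-linkage hierarchical clustering on Euclidean distances between
log2 profiles, cut at k = 5 and relabelled 1..k by ascending mean (ties
broken by first gene id), making group 1 the lowest-expressed cluster
deterministically. Organ-level calls average log2 values within the five
organs (root, stem, leaf, spike, grain — mapped from the 15 canonical
stage codes) and call low ≤ 1.0, high ≥ 5.0, moderate between; the
cutoffs are declared defaults for qualitative published labels.
Linkage and distance are configurable design choices; average linkage +
Euclidean is the common heatmap default.

qPCR quantification follows the comparative 2^−ΔΔCT method:
`ddct = (CT_target − CT_ref)_treated − (CT_target − CT_ref)_control`,
fold change `2^−ddct`.

## The synthetic-data generators

`simulate_protein()` emits sequences whose scan output equals the
requested architecture *by construction*: template fingers per type,
filler residues drawn from an alphabet free of C and H (no spurious
ligands) and of F and L (no spurious EAR matches). `simulate_codon_pair()`
draws a stop-free CDS and applies Poisson-distributed synonymous and
nonsynonymous single-base changes — one per affected codon — with
expected counts set by inverting the Jukes–Cantor correction, so the
NG86 estimate centres on the target; multiple hits per codon are
excluded, which keeps the estimator unbiased at the simulated
divergences (Ks ≤ 0.6). `simulate_expression()` adds Gaussian noise
(σ = 0.3 by default) to group mean profiles on the log2 scale.

### The planted-counts fixture

`survey_fixture()` builds a 457-protein / 204-gene family whose pipeline
summary reproduces the published wheat tallies exactly: 253 splice
variants, 214/243 tandem/isolated proteins, 54 genes on chromosome 5, 85
on sub-genome B, 115 on long arms, chromosome counts 38/27/33/13 for
2/3/4/7, 104 intronless genes, 198 expressed genes, and expression
groups of 44/35/8/43/74 genes. Unprinted margins (chromosomes 1 and 6,
subset composition within the tandem class, variant-count distribution)
are fixed design choices honouring all printed constraints; the manifest
is the single source of truth for tests. Seeds vary only filler residues
and expression noise, never the tallies.

Design notes on the expression side, where the published numbers are
internally inconsistent:

* Group sizes sum to 204 but the printed percentages match a denominator
  of 198 (the expressed genes). The fixture plants the six unexpressed
  genes inside group IV, the only placement that keeps groups I (44),
  II (35) and V (74) intact after filtering and hence consistent with
  the printed 22.2%, 37.4% and 25.7%.
* The five planted mean profiles are ordered so that ascending-mean
  relabelling reproduces the published group indices, which requires the
  small "high" group III to be high in one organ (grain) rather than
  all — the published roman numerals follow dendrogram order, not mean
  order, and both cannot hold at once for a group that is high
  everywhere.
* The fixture uses σ = 0.15 (vs the 0.3 generator default): every
  level-call and filter margin then sits ≥ 5 standard errors from its
  cutoff and the between-group profile distances exceed within-group
  spread several-fold, so the clustering and the organ calls recover the
  planted truth for every seed — the fixture invariant the tests rely
  on. Unexpressed genes are capped just below the detection threshold
  for the same reason.

## What the tests do and do not show

The scanner is proved equal to exhaustive ligand-quadruple enumeration
on short sequences over a C/H-rich alphabet and recovers 100% of planted
architectures over 1000 random specifications; the NG86 implementation
is proved equal to pathway enumeration on all sense-codon pairs and
recovers simulated Ks with median absolute error well under 0.05. These
establish correctness of the *procedures*. The fixture establishes that
the pipeline reproduces the published family composition when the
inputs have that composition — it cannot establish that the original
protein set would be re-derived from the live databases, which involved
HMMER/SMART searches and CD-HIT redundancy removal with unstated
parameters. Real proteomes also contain features the generators omit:
compositional bias, histidines inside linkers (handled by the first-His
rule but not exercised at scale), fingers at spacing > 30, and noisy
expression structure without clean group separation.

## Problem sizes and numerical choices

The shipped tests scan the full 457-protein fixture, enumerate the
oracle on 400 random short sequences, verify 1000 planted architectures,
cover the complete 61 × 61 codon grid and 200 simulated codon pairs of
300 codons — small enough to run in about a minute while exercising
every code path. Percentages round half-up (base R's half-to-even would
print 46.85 → 46.8); Jukes–Cantor saturation returns `NA` with a flag;
identical sequences give Ks = Ka = 0 with selection undefined rather
than a division error; and all randomness flows through explicit seeds
with the global RNG state restored afterwards.
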