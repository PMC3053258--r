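---
title: "Scoring plant miRNA hairpins: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring plant miRNA hairpins: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantpin)
```

## The scoring model and its assumptions

`plantpin` scores a candidate precursor — a genomic window excised around a
small-RNA read cluster and folded into a secondary structure — as a Bayesian
log-odds of being a real plant miRNA precursor rather than background. The
score factorizes over five features assumed conditionally independent given
the class: the absolute minimum free energy (through its length-normalized
form), shuffling stability of the structure, the read-mapping signature,
nucleus conservation of the putative mature, and star-read presence. The
total is the exact sum of six components (the five features plus a prior
log-ratio), which makes every reported score decomposable and auditable
(`plot_score_components()`).

The central plant-specific difficulty is precursor length heterogeneity:
hairpin free energy grows roughly linearly with length, so raw MFE
distributions differ by length class and cannot be pooled. Dividing MFE by
precursor length (kcal/mol per nt) collapses these into a single distribution,
and the MFE feature is therefore scored on normalized MFE through a modified
sigmoid `f(x) = a/(b + e^{c·x})` fitted to binned empirical log-odds
(bin width 0.01). For monocots the fitted curve is nearly flat over the range
where most candidates fall — normalized MFE is a weak discriminator there,
saturating at `a/b ≈ 4.82` only for extremely stable folds — while the dicot
curve is steeper. The original animal model instead scored |MFE| through a
pair of Gumbel-minimum cumulative curves; that parameterization ships as a
comparison mode (`default_parameter_set("animal_original")`), with the tail
log-odds `log((1-F_real)/(1-F_bgr))` evaluated at |MFE|. The Gumbel family is
kept in its two-parameter location/scale form; the location-free one-parameter
variant is its special case and is under-determined for fitting real data.

## Parameters

`default_parameter_set()` documents every constant. The ones that matter most:

* **Sigmoid a, b, c** (unitless, per clade): only meaningful jointly;
  see the identifiability note below.
* **Stability log-odds** (`+1.37 / −3.624` monocot, `+0.63 / −3.17` dicot):
  natural logs of the stable-frequency ratios (about 0.98 for real precursors
  vs. about 0.25 for 300-nt monocot backgrounds, with dicot backgrounds
  substantially more often stable, hence the weaker dicot constant).
* **Nucleus log-odds** (`+7.63 / −1.17`): the conserved case is dominated by
  the background pseudo-count 1/3000 — a background mature essentially never
  matches a known nucleus exactly, so a match is worth a lot.
* **Duplex constraints** (paired ≥ 15 nt, unpaired ≤ 5, consecutive unpaired
  ≤ 3, bulge ≤ 2): hard filters, not score components. The two source tables
  of constraints disagree on the bulge cap (2 vs 1); the declared parameter
  table wins and the default is 2, configurable via `max_bulge_total`.
* **Excision length 300 nt**: the window cap around a read cluster. The
  selection operation (`select_excision_length()`) is generic — smallest
  length reaching a target coverage of known precursor lengths while keeping
  an estimation sample of ≥ 30 precursors within ±30 nt — but the shipped
  default is the declared 300.
* **Read filters**: ≤ 1 mapping mismatch, ≤ 20 genomic hits (keeps reads
  mapping across a miRNA family, drops repeats), zero tolerance for CDS/ncRNA
  overlap.
* **Star / signature / prior**: the star presence log-odds (`+1.6 / −0.6`),
  the geometric signature parameter (0.7), the ±2-nt 5′-end tolerance and the
  prior log-ratio (0, uninformative) are inherited configuration of the
  scoring framework, not plant-estimated values; all are exposed as
  parameters and echoed in output provenance headers.

Natural logarithm is used everywhere; back-calculating every discrete
log-odds from its defining frequencies reproduces the declared constants only
in base *e* (e.g. `log(0.98/0.25) = 1.366`, `log(0.02/0.75) = −3.624`), which
the acceptance tests assert. Two sign conventions appear in the source
narrative for the unstable/non-conserved scores; the negative signs are used,
as log-odds of features anti-correlated with real precursors must be.

## Folding: the reference backend

Production folding should use an external Vienna-compatible `RNAfold`
(`fold(x, backend = "vienna")`); a missing executable is a hard error, never a
silent fallback. For hermetic tests the package carries its own reference
folder: an integer nearest-neighbor-lite model over nested structures —
G:C pairs −3.0, A:U −2.0, G:U −1.0 kcal/mol, a stacking bonus (−1.0 when the
stack contains a G:C pair, −0.5 otherwise), a hairpin penalty
`3.0 + 0.1·(L−3)` kcal/mol, minimum loop 3 nt, no dangles, and co-optimal
ties broken by the lexicographically smallest dot-bracket string. Integer
tenths-of-kcal arithmetic makes tie detection exact, and the dynamic program
is verified structure-for-structure against a brute-force enumeration oracle
on random sequences up to 16 nt. The model makes no claim of reproducing
Turner energies; the pipeline only consumes MFE through the fitted score
curve and through shuffle *orderings*, for which any consistent energy scale
suffices. Its absolute values run larger than physical energies, which pushes
the monocot sigmoid to its saturation value on strongly folded synthetic
hairpins — harmless for ranking, worth knowing when reading component values.

## Stability, shuffling and the p-value

`stability_pvalue()` folds the candidate, folds `N` shuffled versions and
counts `R`, the shuffles at least as stable as the original; the p-value is
`max(R, 1)/(N + 1)` (floor 0.001 at N = 999) and `rel = 1` when p ≤ 0.05.
Ties count toward `R` — the conservative reading, yielding the larger
p-value. Mononucleotide shuffling (exact Fisher–Yates histogram preservation)
is the default, matching how the real-precursor stability frequency was
estimated; dinucleotide shuffling is an Euler-path shuffle preserving the full
16-entry dinucleotide table with the terminal bases fixed, for users who want
to control stacking composition. The shuffle ensemble is reproducible from a
seed, and the tests recount `R` by regenerating the ensemble and refolding
each sequence independently.

## Duplex geometry and bookkeeping

The star arm is the interval pairing with the mature, shifted by the
canonical 2-nt Dicer 3′ overhang (`star_overhang`, configurable). Unpaired
mature runs are classified by their opposite arm: contiguous opposite arm →
bulge; gaps on both arms → internal loop, counted as unpaired. Star-side-only
gaps opposite a contiguous mature stretch also count as bulges. A mature
whose positions pair within the mature itself spans the terminal loop and has
no duplex. These conventions keep "unpaired" and "bulge" disjoint, matching
the separation in the constraint tables. The bifurcation filter (more than
one outermost helix) exists but defaults to off, trading a little specificity
for sensitivity on long plant hairpins.

## Signature model

Reads (weighted by collapsed counts) are consistent when their 5′ end falls
within ±2 nt of the mature or star 5′ end or the read sits inside the loop.
The real-precursor likelihood treats the inconsistent count `k` as geometric
(`p(1−p)^k`, p = 0.7); the background likelihood scatters read starts
uniformly, so each read unit is consistent with probability
`q = (consistent positions)/L`, clamped to `[1/L, 1−1/L]`. The component is
the log-likelihood ratio. These internals are deliberately inherited rather
than re-estimated: read-stack geometry over mature/star/loop is expected to
be conserved between plants and animals, though the longer plant loop means a
minor deviation cannot be excluded.

## Estimation procedures

* **Sigmoid fitting.** `f(x) = a/(b + e^{cx})` is identifiable but
  ill-conditioned when `b ≪ e^{cx}` across all observed bins (the curve then
  degenerates to `a·e^{−cx}`). The solver multi-starts over
  `c ∈ {5, 15, 30, 45, 60}`, solves `a, b` per start by the linearization
  `a − b·y = y·e^{cx}` (ordinary least squares), refines each triple with
  Levenberg–Marquardt (`minpack.lm`), and keeps the best residual sum of
  squares. Recovery of a planted `(a, b, c) = (1, 0.5, 10)` within 10%
  relative error, with and without σ = 0.01 Gaussian noise on the bins, is a
  standing test.
* **Gumbel-minimum MLE** via BFGS from a method-of-moments start, with a
  sum-of-absolute-CDF-errors diagnostic; recovery of (32, 5.5) at n = 10,000
  within ±0.3 / ±0.2 is asserted.
* **Conservation profiling**: within a family (≥ 2 aligned members) a
  position is conserved when the modal non-gap residue reaches 0.9 of the
  members — gaps count as mismatches since the metric is otherwise undefined —
  and across-family blocks are maximal runs at ≥ 0.75 of families. A simple
  center-star aligner (+1/−1/−2, pairwise steps via Biostrings) is provided
  for unaligned input; it is explicitly not a CLUSTAL reimplementation, and
  pre-aligned families bypass it.
* **Nucleus frequency** by 10-fold cross-validation: one shuffle, ten disjoint
  test folds, exact 2–12 match of each held-out nucleus against the training
  fold, mean of the ten frequencies. The exact-match rule (0 mismatches)
  follows from choosing the window at which match specificity within a family
  is maximal; a mismatch allowance would need a re-estimated background
  frequency to stay calibrated.
* **Two-sample KS** through `stats::ks.test` (asymptotic p), cross-checked
  against a brute-force ECDF supremum.

## The synthetic generator

`make_dataset()` emulates the ingredients the pipeline needs: planted
stem-loops (default 65-nt arms + 15-nt loop ≈ 145 nt, near the plant mean
precursor length) embedded on both strands of a codon-sampled toy genome
(coding-like background composition, echoing the use of protein-coding
sequence as the negative class), Dicer-like read stacks (mature ×50, star ×2,
loop ×1, a ×3 read with 1-nt 5′ jitter to exercise the signature tolerance),
uniform noise reads, CDS annotations covering designated decoy hairpins, and
a known-mature library of families sharing exact 2–12 nuclei. Everything is a
pure function of the spec (seed included); identical specs give identical
datasets.

What it does **not** emulate: sequencing errors and quality, expression
heterogeneity across loci, multi-locus families, repeat-derived siRNA
clusters, length-heterogeneous precursor populations, or genomic base
composition beyond codon sampling. Passing the planted-recovery tests
therefore demonstrates the machinery is correct end to end — filters route
reads properly, excision windows contain the hairpin, the duplex and features
recover planted geometry, scores separate planted loci from silence — not
that field performance on real genomes matches any published benchmark. The
reference validation on a real maize chromosome requires the maize genome and
an external sequencing run and is out of scope here; the synthetic recovery
standard (100% of duplex-passing planted loci, zero CDS decoys) is the
package's substitute.

## Numerical and design choices in the open corners

* Flank split at excision: 20 nt on the mature-proximal side, the remainder
  of the 300-nt cap on the distal side, two windows per cluster (mature on
  either arm). The source method states only the cap; the split is
  configuration with these defaults.
* Read-cluster gap: 30 nt single-linkage. Stacks further apart (e.g. mature
  and star of a long hairpin) form separate clusters, whose windows re-excise
  the same locus — redundant but harmless, and duplicate windows are
  deduplicated by coordinates.
* p-value floor `max(R, 1)/(N + 1)`: the plain ratio is 0 when no shuffle
  wins, but an empirical p-value of 0 from a finite ensemble is not
  meaningful; the floor is the smallest resolvable value.
* Degenerate inputs: empty alignment files yield an empty, well-formed report
  (exit 0); clusters longer than the excision cap are skipped with a notice;
  matures shorter than the nucleus range score `nuc = 0` with a notice;
  constant samples make the Gumbel fit error out rather than return a
  zero-scale curve.
* Tie-breaks are deterministic everywhere: lexicographic dot-bracket in the
  folder, id-lexicographic ordering of equal scores, earliest-start/read-id
  for equal-count cluster matures.

## Problem sizes in the shipped tests

The test and acceptance runs are sized for a single CPU: the folding oracle
runs 200 random sequences of 10–16 nt against full enumeration; shuffle
conservation runs 100 random sequences of 20–200 nt; stability tests use
N = 99 shuffles on 60-nt hairpins and a dozen 300-nt backgrounds; the
end-to-end recovery dataset plants 5 true hairpins and 2 CDS decoys in a
20-kb genome with the full N = 999 stability check; Gumbel recovery uses
n = 10,000 draws. These sizes are the package's test design; the same code
paths run unchanged at larger scale.

## Known limitations

Multi-functional stem-loops (one precursor, several matures) are not modeled;
a locus yields one putative mature per read cluster. The signature and star
constants are inherited, not plant-estimated. The monocot MFE component is
nearly uninformative by construction (the fitted curve is flat where real
candidates live), so rankings are dominated by conservation, stability and
signature — consistent with the estimation finding that normalized-MFE
distributions of real and background monocot precursors largely overlap.
Candidates are excised from read clusters only: a transcribed precursor with
no mapped reads is invisible by design.
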