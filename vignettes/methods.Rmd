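---
title: "Models and methods behind ncldvtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ncldvtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncldvtools)
```

ncldvtools packages the comparative-genomic computations used to
characterise a newly isolated giant virus and its relationship with its
amoeba host. This vignette explains each method, its assumptions, the
tunable parameters, and the design choices made where the methodology was
genuinely open.

## Reciprocal best hits and transfer direction

The LGT detector consumes two homology hit tables in the standard
12-column tabular format: virus genes searched against host + reference
background, and host genes against virus + background — in both cases with
the query's own genome excluded, which the code enforces as a
precondition. Rows are retained at `evalue < 1e-5`; the inequality is
strict because that is the stated annotation threshold, and threshold
filtering is idempotent.

A *best hit* is the maximal-bitscore hit, with ties broken by minimal
E-value and then by lexicographically smallest subject id. No tie-break
convention is standard across search tools, so the chain was chosen to
make every downstream result deterministic and invariant to the row order
of the input file; the property is tested by shuffling rows.

A candidate is a reciprocal best-hit pair. Direction is inferred from two
"closest genes": the virus query's best hit after excluding host subjects
and the host query's best hit after excluding virus subjects. The rule is

* at least one closest gene viral → virus-to-amoeba (VtoA);
* otherwise at least one eukaryotic → amoeba-to-virus (AtoV);
* otherwise (prokaryotic, unclassified, or absent) → undetermined.

One configuration the prose rule does not resolve is a *conflict*: one
closest gene viral and the other eukaryotic, which satisfies both clauses.
The default policy `conservative` classifies it undetermined with a
warning, on the view that contradictory evidence should not pick a
direction; `vtoa_precedence` gives the viral clause priority, mirroring
the clause order, and is provided for sensitivity analysis. The full 5×5
decision table over closest-gene classes (including absence) is verified
in the tests against an independently written oracle.

## Expression activity and the silencing comparison

Activity is RPKM, `counts × 1e9 / (length × library size)`, with library
sizes defaulting to column sums. The study aggregated 14 RNA-seq runs
without stating how; the package defaults to the mean RPKM across runs,
with the median available — with balanced runs from a common protocol the
mean preserves more information, and the choice is exposed rather than
hidden.

Two comparisons are reported: all LGT candidates versus genes conserved
among Amoebozoa ("AC_conserved", an input label — the package does not
re-derive that orthology), and the pooled VtoA + undetermined classes
versus AtoV. The Mann–Whitney U test is exact by full enumeration of rank
assignments when `n·m ≤ 64` (at most `choose(16, 8) = 12870` assignments)
and otherwise uses the normal approximation with tie correction and a
0.5 continuity correction. Two-sided p-values are reported, as the
sidedness of the published test is unstated, and both routes agree exactly
with `stats::wilcox.test`, which serves as an independent cross-check in
the tests, never as the implementation. P-values are reported raw across
the two planned tests, matching the published analysis. The approximation
tracks the exact p to within a few percent at moderate p but degrades in
relative terms in the deep tail, as any normal approximation does; the
crossover default of 64 keeps the exact route for every group size where
enumeration is instantaneous.

## Genome composition

G+C content excludes ambiguity codes from numerator and denominator — the
convention used when a sequenced genome's G+C is reported. The windowed
track tiles the genome with non-overlapping 2.5-kb windows; a trailing
partial window is kept when at least half a window long. The
length-weighted mean of window values equals the global G+C of the covered
span to 1e-12, a tested invariant. Coding density is the fraction of the
genome covered by the union of ORF intervals (both strands projected to
one axis, overlaps counted once, via interval reduction); a
sum-of-lengths variant is available for sensitivity since "theoretical
coding density" does not pin down the overlap convention. Basic-residue
proportion defaults to the set {K, R, H} — histidine is only partially
protonated at physiological pH, so {K, R} is offered as the stricter
option. Group G+C summaries use the sample (n−1) standard deviation: the
published pandoravirus row (values 63.66, 61.72, 60.66; SD 1.52) is
consistent with n−1 and not with the population formula (1.24).

## Gene-content cladistics

Gene clusters are consumed as a binary taxa × cluster membership matrix;
orthology clustering itself is out of scope and the synthetic generator
emits membership matrices directly. The default similarity is the Dice
coefficient `2|A∩B|/(|A|+|B|)`, with Jaccard and the min-normalised ratio
`|A∩B|/min(|A|,|B|)` as alternatives; the published analysis cites a
similarity score whose formula is not reproduced in the text, so the
choice is surfaced in the function signature rather than fixed silently.
Distance is `1 − s`.

Trees are Saitou–Nei neighbor joining via `ape::nj()`. Negative branch
lengths, which NJ produces on non-additive input, are clamped to zero
with a warning. On additive matrices NJ is consistent, and the tests
verify exact topology recovery on random trees up to eight taxa.
Bootstrap support resamples *columns* (gene clusters) with replacement —
the only exchangeable unit of a gene-content matrix — rebuilding the tree
100 times by default and reporting, for each internal bipartition of the
full-data tree, the percentage of replicates containing it. A replicate
that leaves a taxon with an empty gene set would violate the matrix
invariant and is redrawn (at most ten times, then an error).

The newick writer quotes labels containing metacharacters (spaces,
brackets, quotes) with single quotes, doubling embedded quotes; the
bundled `ape` serialiser substitutes underscores for spaces instead, which
is lossy, so serialisation is done in-package while parsing delegates to
`ape::read.tree()`.

## Virion proteomics

emPAI is `10^(N_observed / N_observable) − 1`. The observable count comes
from an in-silico tryptic digest — cleave after K or R except before P —
filtered to a closed monoisotopic mass window of 500–5000 Da with zero
missed cleavages by default, reflecting common LC-MS/MS practice; window
and missed cleavages are configurable because the published pipeline
delegates these details to its search engine. `n_observed > n_observable`
warns but computes as-is: real spectra can identify peptides the digest
model misses. Molecular weights use average residue masses plus one
water, in kDa. Relative abundances are percentages of the maximum emPAI
(the major capsid protein in the shipped table) with display rounding to
the nearest integer at ≥ 10% and one decimal below — the convention
recovered from the published values 28%, 21%, 9% and 2.7%.

## Capsid geometry

`T = h² + hk + k²`; the brute-force inverse search runs over `h ≤ k ≤ 50`
in well under a second. A closed icosahedral lattice always has 12
pentamers and `10(T−1)` hexamers. Capsomer spacing uses the icosahedron
edge `a = 4R/√(10+2√5)` for the vertex-circumscribed diameter `2R`,
divided by `√T` spacings along a pentamer-to-pentamer lattice path; at
T = 277 and a 232-nm capsid this gives 7.33 nm, within 3% of the
published 7.55 nm estimate whose geometric model is unstated — the model
name is recorded in the output so alternative conventions can be compared.
The capsomer total `10T + 2 = 2772` differs from the published spike
count of 2,660; the report carries both numbers side by side rather than
silently adopting either.

## The synthetic-data generator

`generate_universe()` plants each transfer as a triple descended from one
random ancestor: lightly mutated virus and host copies
(`mutation_rate = 0.02` per residue by default) and a more heavily
mutated background relative (rate `4×mutation_rate + 0.08`) whose
taxonomy label encodes the intended direction — viral for VtoA,
eukaryotic for AtoV, prokaryotic/unclassified or absent (alternating) for
undetermined. All other proteins are independent random sequences over
the 20 canonical residues.

Homology scores are shared distinct k-mer counts (k = 4) rather than
alignments: the inference consumes ranked hits, and k-mer counts are
fast, deterministic, and strictly order divergence at these rates —
identical sequences attain the maximal score for a query, planted
partners outscore the relative, and unrelated random proteins share
essentially no 4-mers, so a reporting floor of 10 shared k-mers keeps
chance matches out of the tables entirely. Emitted E-values are
`10^-score`, far below the 1e-5 retention threshold for any reported row.

Expression counts are negative binomial (`var = μ + φμ²`, default mean
200, dispersion φ = 0.3 — mid-range for bulk RNA-seq) over 14 runs,
matching the number of public runs the study aggregated. Silencing
multiplies the expected count of VtoA and undetermined planted genes by
0.1 by default, mirroring the observation that those classes sit lowest;
the silenced set and multiplier are configurable. Unplanted host genes
stand in for the conserved Amoebozoa reference set. The synthetic genome
draws i.i.d. bases at the observed G+C of 0.617 over 381,277 bp.

What the generator does *not* emulate: realistic substitution processes
(no rate heterogeneity or indels), read-level RNA-seq (counts only),
correlated expression between runs, homology between unplanted genes, or
compositional structure along the genome. Passing tests therefore
demonstrate that the algorithms implement their contracts — full recovery
of planted transfers, exact tallies, correct statistics — not that the
pipeline is robust to every artefact of real survey data.

## Problem sizes and determinism

Every stochastic function is a pure function of its seed: RNG state is
saved and restored around each generator, so calls do not perturb the
caller's stream and equal seeds give byte-identical outputs. The test
suite and the acceptance script use deliberately small universes (15–25
genes per genome, 30–40 background proteins, 20 seeds for the recovery
sweeps, 100-seed Monte-Carlo checks for the power and type-I properties,
10,000 replicates for the exact-test calibration at n = m = 4) — sizes at
which the planting guarantees are airtight and the full suite runs in
well under a minute.

## Known limitations

* Direction inference sees only the single closest gene per side; a
  phylogenetic confirmation step (as performed for selected genes in the
  study) is out of scope.
* The conflict policy affects only the rare viral-vs-eukaryotic case and
  defaults to the conservative reading; published tallies may have used
  an undocumented precedence.
* emPAI values in the shipped proteome table are inputs transcribed from
  the publication, not recomputations — the spectra-level pipeline behind
  them (search engine, peptide FDR) is not reproducible from sequence
  alone.
* The gene-content similarity score of the cited prior work is not
  reproduced in the source text; Dice is a defensible default, not a
  confirmed match.
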