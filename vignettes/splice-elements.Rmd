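---
title: "Methods: comparative splice-element analysis with orthosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative splice-element analysis with orthosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosplice)
```

`orthosplice` tests whether orthologous exons that are alternatively
spliced in exactly one of two species carry weaker core splicing
elements — branch point (BP), 3′ splice site, 5′ splice site — than
their constitutively spliced orthologs. This vignette documents the
models, the parameter choices and their rationale, what the synthetic
data generator does and does not emulate, and the numerical decisions a
maintainer would want to know about.

## Coordinate model

All internal coordinates are 0-based half-open on the forward genomic
strand; GFF3 input/output converts to and from 1-based inclusive at the
boundary, and BED output stays 0-based half-open. Transcripts store
exons in transcription order, so "the intron upstream of exon *k*"
always means upstream in the direction of transcription, and extracted
intron sequences always read 5′→3′ and end with the 3′ splice-site AG.
A single convention everywhere removes the usual off-by-one drift
between modules.

## Branch-point model

A BP candidate is an intronic adenine presented as a 9-nt window with
the adenine at position 6 (five nt upstream, three downstream). This
registration is the only one consistent with the conserved CCTAA core
at window positions 2–6 seen across vertebrate BP sequences, including
all five bundled *CAMK2B* intron calls (`camk2b_branchpoints()`).

**Distance.** `distance = L − 1 − p`, the number of intron nucleotides
strictly 3′ of the BP adenine (`p` its 0-based index, `L` the intron
length). Endpoint conventions differ between published BP tools and
cannot be re-derived from printed tables without the underlying genome
sequence, so the convention is documented here and used consistently;
all planted and recovered distances in the tests use it.

**Search window.** Candidates are enumerated for distances in
[`min_dist` = 10, `max_dist` = 100] nt. Functional BPs overwhelmingly
sit within 100 nt of the 3′ splice site; the printed *CAMK2B* distances
are 20–26 nt, and 10 leaves margin below them. Both bounds are
arguments everywhere.

**AGEZ.** `compute_agez()` returns the length of the maximal region
immediately upstream of the terminal AG containing no other AG
dinucleotide. The scanning-model rationale: the spliceosome selects the
first AG downstream of the BP, so functional BPs usually lie inside
this zone. A candidate is flagged `in_agez` when
`distance ≤ agez + 1` — the adenine-position rule that reproduces the
observed pattern for the bundled calls (rodent BP at distance 26 inside
an AGEZ of 44; the human BP at distance 26 just outside its AGEZ of
22).

**Scoring.** The default model is a position weight matrix trained on
the five bundled nonamers with pseudocount 0.5 against a uniform
background; the score is `Σ_j log2(p_j(base)/bg(base))`, in log-odds
units (dimensionless). This desk-scale model preserves the structure
the analysis needs (strong consensus-like BPs score high, degraded ones
lower, differences are additive per position) but is *not* the
published scaled-vector classifier: reproducing published decision
values (e.g. 1.77 for the rodent *Camk2b* BP) requires that tool's
model files, which can be supplied as a score table via
`bp_model_table()`. The **motif score** used in the ortholog comparison
augments the sequence score with a distance term:
`bp_motif = bp_seq + log2(prior(d)/uniform)`, with a gamma(shape 4,
scale 7) distance prior (mode 21 nt) over the search window. This is
the package's own distance-aware construction, chosen so that two
candidates with equal sequence scores rank by their plausibility as BP
positions; it is monotone in the sequence score, so planted score
differences survive it unchanged.

**Ties and floors.** `best_branchpoint()` breaks score ties toward the
smaller distance (closer to the 3′ splice site), and accepts every
candidate under the PWM model (floor −∞); score-table models default to
a floor of 0, the usual SVM decision-value cutoff, so introns without
an acceptable BP return nothing rather than a meaningless best.

## Splice-site models

Donor windows are the last 3 exonic plus first 6 intronic nt; acceptor
windows the last 20 intronic plus first 3 exonic nt — the published
maximum-entropy convention, with GT/AG consensus checks that warn by
default and can be made strict or disabled (synthetic data may violate
consensus). Scores are `log2(P_model/P_background)`, base 2 to match
the published tools' scale.

A full 23-mer joint table is intractable, so models are factorized into
components over position subsets whose probabilities multiply; the
published tools' factorization fits this representation. The bundled
trainer `train_maxent()` performs iterative proportional fitting from
the uniform distribution on full tables up to window 6 — desk scale by
design. Against what is it checked? For overlapping pairwise
constraints on positions (1,2) and (2,3), the maximum-entropy joint has
the closed Markov form `p12(x1,x2)·p23(x2,x3)/p2(x2)`; the tests
compare the trainer to this independent oracle to 10⁻⁶ and verify
entropy dominance over a feasible reference distribution. Convergence
is declared when all constrained marginals match within `tol` (default
10⁻⁸); inconsistent constraints surface as required mass on impossible
cells or non-convergence after `max_iter` sweeps.

## PSI and event filters

PSI is computed from junction counts only:
`psi = (I/len_I) / (I/len_I + S/len_S)` with effective lengths (2, 1):
an included cassette exon offers two supporting junctions, a skipped
one a single junction. Junction-count PSI is read-length independent
and reproducible from count tables alone. Both counts zero leaves PSI
undefined rather than 0 or 1.

Event summaries use the n−1 sample SD (0 for a single sample) and the
mean of `I + S` as the junction-read depth. Filters follow the
thresholds stated with their boundary semantics taken literally:
support **at least** 3 datasets (inclusive), SD of PSI **below** 0.2
(strict), mean junction reads of **at least** 10 (inclusive).
Classification uses two strict inequalities — alternative below 0.9,
constitutive above 0.9 — so a PSI of exactly 0.9 is *unclassified*
rather than forced into either class; the threshold is an argument.
Support is counted in samples (datasets and samples are not
distinguished in the count tables; callers aggregating studies should
pre-aggregate).

Total exclusion of an exon skipped by several distinct events is the
sum of the per-event exclusion fractions, as percentages capped at 100.

## Ortholog mapping and species-exclusive sets

Intervals are projected through the single highest-scoring chain
overlapping them (no chain stitching — deterministic and adequate at
the scales this package targets), keeping the target-side hull of
mapped bases when at least `min_ratio` = 0.9 of the interval's bases
fall in aligned blocks. A pair is emitted when the mapped exon
reciprocally overlaps an annotated exon of the other species at the
same ratio. The same exon appearing in several transcript contexts
(different flanking exons) is deduplicated keeping the first entry in
input order.

Species-exclusive exons are alternative in one species, constitutive
in the other, with `|ΔPSI| ≥ delta_psi_min`; 0.2 is the default and
0.15 a supported softer choice — both appear in comparative practice,
and neither is privileged: the threshold is an explicit argument.
Exclusive-pattern pairs failing the ΔPSI threshold, and pairs with
missing PSI, are labeled `unclassified`, keeping the partition
exhaustive and mutually exclusive.

Element-score comparisons between species are paired Wilcoxon
signed-rank tests per metric and exclusivity class, two-sided (the
direction is not assumed), with Holm adjustment across the family of
tests performed.

## Statistical machinery

The signed-rank test drops zero differences, uses the exact
distribution of the rank sum for up to 25 non-zero pairs (dynamic
programming over doubled midranks, equivalent to enumerating all 2ⁿ
sign assignments), and a normal approximation with tie and continuity
corrections beyond. The null-calibration test uses n = 20 pairs: the
exact test is discrete, and at n = 20 its attainable size is close to
the nominal 5% level, which smaller n undershoot by discreteness.

The two-sample comparison of pooled plateau activities gates Student
vs Welch on an F test of variances at α = 0.05. A Shapiro–Wilk
normality report is available but does not drive the selection by
default, mirroring workflows in which normality is additionally judged
by Q-Q inspection; both behaviours are explicit arguments. Missing
phosphosite intensities are treated as truly missing (mass-spectrometry
semantics), never as zeros, for correlations and replicate merging;
each replicate table is min–max normalized over its own intensity range
before merging, averages are taken where several replicates measured a
site, and single-replicate values are kept as-is.

## Hill kinetics

The activation model is the three-parameter Hill equation
`V = Vmax·xʰ/(EC50ʰ + xʰ)` with no basal-activity offset — V(0) = 0,
the "allosteric sigmoidal" form matching the three reported parameters
(Vmax, h, EC₅₀; concentrations in nM calmodulin, activities on the
V/Vmax(reference) scale). Fitting is unweighted least squares (no
weighting scheme is reported for the underlying assays) by
Levenberg–Marquardt with data-driven starts (`Vmax₀ = max v`,
`EC50₀ = x` nearest half-max, `h₀ = 1`), positive lower bounds, tight
convergence tolerances, and a small set of perturbed restarts before
giving up; standard errors come from the Jacobian at the optimum.
Replicate-level observations are fitted directly (not replicate means),
which is what the generator produces. Plateau pooling takes
concentrations in [100, 1000] nM inclusive at both ends.

## What the synthetic generator emulates — and what it does not

`gen_species_pair()` builds paired single-chromosome genomes of
three-exon genes whose middle exon is the cassette exon. Planted
structure: canonical GT…AG introns; an AG-depleted 3′ intron region
with one planted AG setting the AGEZ (default 44 nt); a BP nonamer
planted at distance 26 nt whose PWM score is driven to within 0.5
log-odds units of its target by greedy substitution search; a
configurable fraction of genes (defaults 30% A-exclusive, 10%
B-exclusive) whose BP is weakened by `bp_delta` = 1.5 log-odds units in
one species. The orthologous intron is the same sequence with only the
nonamer window swapped. Species B additionally differs by neutral
substitutions (rate 0.02, drawn to avoid creating AG/GT motifs) and
spacer insertions that give the chain real gaps. True inclusion comes
from a logistic link `π = 1/(1+exp(−(β₀+β₁·bp)))` with β₁ = 2 and β₀
anchored so the strong BP score maps to π = 0.97; the weakened score
then lands near π ≈ 0.6, comfortably alternative and separated by more
than the ΔPSI threshold. Junction reads are binomial at depth 2000 over
9 samples per species, with inclusion probability `w = 2π/(1+π)` — the
junction-opportunity weighting under which the (2, 1) effective-length
PSI estimator is unbiased. Heterozygotes are equal mixtures of two
allele inclusion fractions.

Deliberately *not* emulated: sequencing error and read-level
simulation, alignment artifacts, multiple transcripts per gene,
expression variation between samples, splice-site strength variation
coupled to PSI (the link slopes for splice-site scores default to 0),
and realistic genome-scale sequence composition. Passing tests
therefore demonstrate that the pipeline's logic — PSI estimation,
filtering, mapping, classification, paired testing — is correct under
its own assumptions, not that those assumptions hold in any particular
real dataset.

Phosphosite tables plant exact isoform-overlap group sizes; missingness
is applied to at most one replicate per cell so that merging provably
restores the planted structure, and low-localization sites are added on
top as filter fodder. Lognormal intensities with replicate-level
jitter mimic the scale but not the dependence structure of real
intensity data.

## Problem sizes and determinism

Test and simulation sizes are chosen to be desk scale: 200-gene
genomes (~150 kb), depth 2000, 9 samples per species for the
comparative power checks (20 replicate simulations); depth 10⁴ for the
estimator-bias check; 10⁴ simulations for the null calibration of the
signed-rank test. Every stochastic operation takes an explicit integer
seed; composite operations derive per-step sub-seeds deterministically
from the master seed, so a fixed seed yields byte-identical genomes,
counts, tables and result files. Model scoring and fitting are
deterministic; rerunning a pipeline on the same inputs reproduces the
output files exactly.

## Known limitations

* The bundled PWM is trained on five nonamers; its absolute scores are
  not comparable to published scaled-vector decision values, and its
  ranking of closely related nonamers can differ from the published
  classifier's. Published scores should be supplied via
  `bp_model_table()` where exactness matters.
* The maximum-entropy trainer is full-table and limited to windows of
  length ≤ 6; full-size acceptor models must be loaded, not trained.
* Ortholog mapping uses one chain per interval; genuinely split
  mappings (exon spanning two chains) are reported unmapped.
* `in_agez` and the distance convention are documented choices;
  printed tables from other tools may use different endpoint
  conventions and disagree by ±1 nt.
* The heterozygote model assumes equal allelic expression; allelic
  imbalance would shift the expected 50% inclusion accordingly.
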