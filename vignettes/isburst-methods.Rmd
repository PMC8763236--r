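---
title: "Methods: detecting and analyzing an IS transposition burst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analyzing an IS transposition burst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isburst)
```

# Scope

`isburst` analyzes laboratory-evolution experiments in which
insertion-sequence (IS) transposition dominates the mutational input: a
strain whose genome already carries many element copies is propagated
under serial dilution, populations are sequenced at intervals, and new
insertions are detected, tracked and related to fitness. The package
couples each analysis stage to a synthetic-data generator with known
truth, so the whole pipeline is testable at desk scale. This vignette
states the models, estimators, defaults and limitations; nothing here
reports a number that the test suite or `scripts/acceptance.R` does not
itself compute.

# The transposase census

`assembly_stats()` computes contig count, total length, N50 (the length
of the shortest contig in the smallest set of longest contigs reaching
half the assembly), and GC over unambiguous bases, split into coding and
noncoding once gene intervals are supplied (overlaps are merged before
splitting).

`cluster_paralogs()` reconstructs families of duplicated genes. Two
proteins are linked when an ends-free pairwise alignment (BLOSUM62, gap
open 10, extend 0.5) reaches 50% identity over the shorter sequence and
covers 50% of the target; clusters are the connected components of this
relation (single linkage), which matches the transitive "cluster of
homologous genes" notion. Whether coverage should be mutual or
target-only was genuinely open; we test the criterion with either
sequence as target, which is the more permissive and the more common
behavior of k-mer prefilter clusterers. Membership is independent of
input order; ids and representatives (longest member) are deterministic
with lexicographic tie-breaks.

`annotate_is_families()` assigns each transposase to the family of its
best local-alignment hit in a user-supplied reference set, at E ≤ 1e-9.
An E-value threshold is only meaningful under a declared model, so the
score-to-E map is fixed: Karlin–Altschul `E = K·m·n·exp(−λS)` with
gapped BLOSUM62 parameters λ = 0.267, K = 0.041 (gap open 11, extend 1).
A query absent from the reference — the situation of a recently invaded,
unclassified element — stays `"unclassified"`.

`flag_pseudogenes()` calls a CDS intact iff its length is divisible by
three, it starts with a bacterial start codon (ATG/GTG/TTG), and it has
exactly one stop, at the terminus. Frameshifts (length not divisible by
three) are reported together with the premature stop they induce in the
shifted frame.

`scan_element_copies()` finds "nearly identical" element copies by
seed-and-extend: exact 18-mers sampled every 5 bp along the query (both
strands) anchor candidate loci, which are then aligned globally against
the element; hits need 95% identity over the element length and 90%
aligned length by default. The paper-scale notion of "nearly identical"
is not defined anywhere; 95%/90% are our defaults and both are exposed
as arguments. With substitution-only divergence up to 5%, the chance
that a copy retains no exact 18-mer seed is below 1e-40, so recall on
planted copies is effectively 1.

# Dating duplicates: Nei–Gojobori dN/dS

Divergence between duplicated coding sequences uses the NG86 counting
method rather than a maximum-likelihood codon model: it is closed-form,
deterministic, and the natural reading of "rates of synonymous and
nonsynonymous divergence between pairs". Results are therefore
comparable, not identical, to codeml estimates.

Per codon, each of the three positions contributes the fraction of its
three possible changes that preserve the amino acid; changes creating a
stop count as nonsynonymous, which keeps S + N = 3 × (codons) exactly.
Observed differences in multi-difference codons are averaged over all
orderings of single-base steps, excluding paths through stop codons (if
every path is blocked, all paths are used). Proportions pS = Sd/S and
pN = Nd/N are corrected by the Jukes–Cantor map
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is outside the correction's domain and
sets the corresponding rate to `NA` with a saturation flag. The
implementation is checked against an independent recursive
path-enumeration oracle on 1,000 random codon pairs in the test suite.

# Multicopy expression

Reads are recruited to paralog clusters by end-to-end matching with at
most 3 substitutions and no indels. This is a deliberate simplification
of a two-stage mapper-plus-exact-match pipeline: the disambiguation step
requires 100% identity and coverage anyway, and substitution-only
matching makes `classify_ambiguity()` exact — a read is attributed to an
individual gene iff it is a perfect full-length substring of exactly one
cluster member. Reads tied between clusters are dropped and counted
rather than fractionally assigned. Strandedness: member sequences are
transcript-oriented, so under the FR convention a `+`-orientation match
is sense; RF (dUTP) inverts this; unstranded counts everything as sense.
TPM is computed per replicate (`rate = count/(length/1000)`,
`TPM = 1e6·rate/Σrate`) and sums to 1e6 whenever any count is positive;
cluster-level TPM uses the longest member as effective length, a choice
the underlying study leaves open.

# The insertion caller

## Junction evidence

A read supports a junction iff it splits into a reference-matching
segment and an element-terminus-matching segment, each at least
m = 12 bases with at most one mismatch per segment. Reads are anchored
by exact 12-mers at either end and extended; a mismatch is tolerated
during extension only when followed by at least four matching bases, so
a sequencing error inside a segment does not masquerade as a breakpoint.
When the element's first bases coincide with the reference continuation
at the insertion point (microhomology), the maximal reference extension
overshoots; the caller scans a small offset (up to 16 bp) between the
reference boundary and the element terminus and restores the true
coordinate, which is what makes boundary recovery exact rather than
approximately right. m = 12 with one mismatch per segment keeps the
chance of a random 150-bp read faking a junction negligible while
leaving a wide detectable window.

## Calls, TSDs and frequency

Left and right junction groups are paired when the implied target-site
duplication length k = a − b + 1 (a = left boundary, b = right flank
resumption) lies within ±20; k > 0 recovers the duplicated sequence
`reference[b..a]`, k = 0 is a blunt insertion, k < 0 flags a target
deletion. The reported site is the first TSD base, 1-based, on the
forward strand.

Frequency is the mean over sides of J/(J+S). With paired reads, J and S
are counted in fragment units: a fragment supports the insertion when a
read crosses the junction or when its near mate points at the boundary
while its far mate is discordant (it multi-maps back to a resident
element copy); a fragment supports the reference when both mates align
concordantly (insert size within 25% of the library median) across the
boundary with 12 bp margins. Fragment counting uses the unsequenced
inner gap as evidence and roughly doubles the informative count per
site. Single-end input falls back to read-level counting.

Calls below the 2% frequency cutoff, with fewer than 2 supporting
junction fragments, or with only one side observed are emitted with
explanatory statuses (`LOW_FREQ`, `LOW_SUPPORT`, `ONE_SIDED`), never
silently dropped.

## Bias tests

Each two-sided call carries a two-sided Fisher exact p for strand
balance of junction versus reference reads, and a one-sided two-sample
Kolmogorov–Smirnov p for whether junction-supporting base qualities are
stochastically lower than reference-supporting ones (exact when both
samples have ≤ 25 observations; fewer than 3 observations per class
yields `NA` with `INSUFFICIENT_DATA`). Both annotate rather than
reject — mirroring a manual-inspection workflow — unless
`strict = TRUE`, which rejects at p < 0.01. Both implementations are
checked against exhaustive enumeration oracles in the tests.

## Accuracy and its noise floor

On 20-replicate simulations (10 kb genome, one resident element copy,
one planted insertion at a uniform frequency in [0.05, 0.95], 250×
paired 150-bp reads, 0.2% error), the caller attains recall 1.0 and
precision 1.0 with exact site and TSD recovery, and a mean absolute
frequency error of about 0.02 (`caller_benchmark()`). A per-insertion
error bound of 0.05 is not attainable at these coverages by any counting
estimator: the frequency is a binomial proportion over the few hundred
fragments that overlap one site, so individual errors have SD ≈ 0.02–0.03
— an estimator given the simulator's own truth labels shows the same
scatter. Accuracy claims are therefore stated on the mean.

Insertions into or immediately beside a resident element copy are
unresolvable by short-read junction evidence (reads from the new copy
multi-map to the resident one); the transposition simulator therefore
excludes target windows within 500 bp of a resident copy by default
(`avoid_existing`), and real-data users should treat calls inside
repeats with the same suspicion.

# Trajectories

`build_trajectories()` merges per-timepoint calls into alleles when
family, contig and orientation match and sites agree within 5 bp (the
cross-timepoint matching tolerance is not observable from published
tables; 5 bp is our default). Undetected timepoints are `NA`, not 0 —
population sequencing cannot distinguish absence from sub-cutoff
presence, and the distinction is preserved end to end. Classification is
a pure function of the frequency vector: fixed iff the final frequency
is ≥ 0.95 (encoding "fixed or near fixation"), lost iff previously
detected at ≥ 2% and absent or below 2% at the end, segregating
otherwise, transient if never detected. `fixation_rate()` is
1000 × fixed / total generations. `detect_clonal_interference()` reports
every locus–timepoint pair where two or more derived alleles are
simultaneously at or above the detection threshold.
`muller_export()` nests lineages by a containment heuristic (child never
exceeds parent at shared timepoints and appears no earlier); exact
genealogy would require clone sequencing, so the nesting is declared
best-effort and unresolved lineages attach to the root.

# Growth models

Batch growth is modeled as exponential then linear:
OD(t) = a·e^{rt} for t ≤ t*, continuing linearly with slope m. The
exponential phase is fit by OLS on log OD — a deterministic,
initialization-free realization of the two-parameter model that can
differ from nonlinear least squares under heteroscedastic noise, which
we accept for reproducibility. `segment_phases()` grid-searches t* over
observed timepoints (≥ 4 points per side) minimizing the summed SSE of
the two fits on the OD scale, ties to the earliest; on noiseless curves
this recovers the generating breakpoint and both rates exactly.
`compare_to_ancestor()` defaults to a one-sample one-tailed t of the
per-population means against the ancestor's point estimate (the
alternative "evolved > ancestor"); because the published degrees of
freedom are not stated, a Welch two-sample mode is also provided and the
mode is recorded in the output. `regress_rate_on_fixed()` reports
Pearson R with F = R²(n−2)/(1−R²) on (1, n−2) df; note that an F
computed from a rounded R of 0.78 at n = 8 is 9.32, slightly above a
value computed from the unrounded correlation.

# Synthetic data: what it emulates, and what not

The generators reproduce the features the pipeline's claims rest on: a
genome with coding/noncoding GC contrast (defaults 47.5%/41.5%) and IS
families at configurable copy number, divergence and intactness (the
ancestral configuration of interest being nine nearly identical copies
with a single intact transposase and a 14-bp terminal inverted repeat);
copy-and-paste transposition that never excises the donor, duplicates
the k-bp target window (default k = 8 — the element's true TSD length is
only implied, never stated, so this is a configurable placeholder), and
samples sites with weight exp(β·AT); `calibrate_target_bias()` solves
for the β whose expected target GC matches an observed value such as
27%. Serial transfer runs `round(log2(D))` discrete Wright–Fisher
generations per cycle with the population doubling from the bottleneck
(defaults D = 150, hence ≈ 7 generations/cycle; bottleneck 1e4 for
desk-scale runs, with the experimental 4.5e5 available), new mutants at
rate u per genome per generation, and a multinomial bottleneck. Because
within-cycle demography is unobserved, selection enters as a per-cycle
fitness w = (1+s_e)^{g_e}(1+s_l)^{g_l} applied per generation as
w^{1/g}, with the whole cycle treated as exponential phase by default.
Read simulation draws fragments proportional to weight × genome length
with i.i.d. substitution errors and flat Phred+33 qualities.

Not emulated: realistic base-quality profiles, PCR duplicates, indel
sequencing errors, cut-and-paste (excising) transposition, and ectopic
recombination between copies. Passing tests therefore demonstrate
correctness of the algorithms under substitution-only noise and tidy
library geometry, not robustness to every artifact of real libraries;
the quality-bias KS test, in particular, only becomes informative on
data with genuine quality variation.

# Numerical conventions

Coordinates are 1-based inclusive everywhere, including all TSV/GFF3
output. Stochastic functions take an explicit `seed` and restore the
caller's RNG state. Frequencies are conserved to 1e-12 per cycle in the
simulator; TPM sums to 1e6 within 1e-6; JC correction returns exact 0 at
p = 0. Test problem sizes (10–60 kb genomes, 60–250× coverage, 2,000
Wright–Fisher replicates, 10,000 t-test replicates) were chosen so the
full suite exercises every stated property in a few minutes on one CPU.

# Known limitations

* The caller reports insertions of known elements via their termini; it
  is not a general structural-variant caller (no deletions, inversions
  or amplifications) and does not call SNPs — externally derived allele
  frequencies can be appended to trajectory tables instead.
* Family annotation E-values rest on fixed Karlin–Altschul parameters;
  they order hits correctly but are not BLAST-identical.
* Cluster-level TPM uses the longest member as the effective length;
  with length-heterogeneous clusters this choice matters and is
  documented rather than hidden.
* The Muller nesting heuristic can misplace lineages whose frequencies
  track their parent within noise; it guarantees only containment
  consistency, with violations clipped and warned.
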