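---
title: "Models and methods: KRAB zinc-finger evolution and ERV silencing"
author: "kznfevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: KRAB zinc-finger evolution and ERV silencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Endogenous retroviruses (ERVs) enter mammalian germ lines recurrently, and
the host must evolve sequence-specific repressors to silence each new
family. In humans the dominant system couples KRAB-domain C2H2 zinc-finger
transcription factors, many of them clustered on chromosome 19, to the
corepressor KAP1 (TRIM28), which nucleates heterochromatin on the bound
locus. `kznfevo` implements, as a tested and fully seeded pipeline, the
computational analyses that support this picture:

1. **Peak enrichment** — base-pair accounting of repressor ChIP peaks over
   repeat classes against an accessible-chromatin null, and the retention
   of binding in a mutant lacking the KRAB-binding RBCC domain.
2. **Motif scanning** — six-frame translation of genomic DNA, exhaustive
   C2H2 motif matching, overlap resolution, and tandem grouping.
3. **Duplication dating** — pairwise divergence of motif DNA, Jukes–Cantor
   correction, UPGMA trees whose first-merge heights are duplication ages,
   count-scaled age densities, divergence-based spatial clustering, and
   the distance–divergence correlation expected under local unequal
   crossover.
4. **Deletion-rate estimation** — the Watterson estimator and a
   frequency-spectrum refinement applied to polymorphic deletions, with
   region-vs-background folds and bootstrap intervals.
5. **Binding prediction** — a pluggable recognition-code model mapping
   tandem finger specificity residues to position weight matrices, ERV
   family-specific k-mer discovery, and repressor-candidate calling.
6. **Coevolution statistics** — parsimony dating of family invasions and
   tandem affinity gains on a primate tree, the contemporaneous-pair
   filter, and the chromosome-19 enrichment test (Fisher's exact test,
   with a noisy-classifier bootstrap correction).

A synthetic-data module generates every input with ground truth, so each
analysis stage is validated end to end by recovery tests.

# Conventions

All genomic coordinates are 0-based, half-open (the BED convention), on
every tibble in and out of the package; `end - start` is always a length
in base pairs. One-based coordinates appear only in display strings.
Divergence and duplication ages are expressed as fractions of nucleotide
substitutions per site (f.n.s.).

# Models and estimators

## C2H2 motif model

The C2H2 motif is matched as `C-x(2,4)-C-x(12)-H-x(3,5)-H` (21–25 amino
acids), the PROSITE-style consensus whose length range matches the
published description of the motif. Matching is exhaustive over start
positions and spacer lengths, so overlapping alternative parses are all
enumerated; `X` (unknown residue) never matches an anchor and a stop
breaks a match. Overlaps are resolved greedily from the left (ascending
genomic start, then longer match, then `+` strand), a deterministic rule
chosen because only the non-overlapping property itself is prescribed.
Tandems are maximal same-strand runs of two or more motifs with every
consecutive gap strictly below 200 bp.

Motif DNA is compared in a fixed pattern-anchored alignment: one codon
per anchor, spacers right-padded with gap codons to their maximal
lengths (75 nt total). Gap and `N` positions are ignored pairwise, which
makes the mismatch fraction `p` well defined without a multiple sequence
alignment dependency. This is adequate because C2H2 spacer length
variation is confined to two short blocks; it would misalign motifs that
had internal indels, which the package does not model.

## Duplication ages

Raw mismatch fractions are corrected with Jukes–Cantor,
`d = -(3/4) log(1 - 4p/3)`. The correction diverges at `p = 0.75`, so
distances are censored at `d_max = 1.5` f.n.s. — applied as a cap on the
corrected value, keeping the map monotone — rather than dropping
saturated pairs, so tree building stays total. UPGMA (average linkage,
size-weighted update, merge height `D/2`) is implemented in the package
because the duplication-age bookkeeping (the height of each leaf's first
merge = the time of its most recent duplication) and a deterministic
lexicographic tie-break are part of the method's definition; tests check
it against an independent naive agglomeration that recomputes cluster
distances as plain means over leaf pairs. Age-density curves are Gaussian
kernel densities (Silverman bandwidth by default) scaled so the area
under each group's curve equals the group's motif count.

## Deletion rates

For a region with `S` segregating deletions among `n` haplotypes,
`theta_W = S / a_n`, `a_n = sum_{i<n} 1/i`. The frequency-spectrum
refinement fits the observed class counts to the neutral expectation
`E[xi_i] = theta / i` with Poisson weights, computed class-wise:
`theta_hat = sum_i xi_i / sum_i 1/i` over unmasked classes. With no
masking this is exactly Watterson; masking singletons trades variance for
robustness to deletion-call errors, which concentrate in the singleton
class. The published refinement's exact derivation is not public, so this
estimator is a declared, reproducible stand-in with the same inputs and
the same no-masking limit. Rates are converted to deletions per
generation per Gb as `mu = theta / (4 N_e L) * 1e9` with `N_e = 10,000`
by default; the conversion constants are explicit arguments and reported
`theta` values should always accompany `mu`. Sample size is exposed
explicitly everywhere (the 45 diploid individuals of the reference data
contribute `n = 90` haplotypes by default). Region-vs-background folds
bootstrap the pooled record set (1000 replicates, seeded), because
resampling within a region would leave its count statistic unchanged;
regions with fewer than 5 segregating deletions (background: 20) are
reported as having insufficient data rather than a fold.

## Binding model

The trained support-vector predictor used in the original analysis is not
redistributable, so binding prediction is factored behind a pluggable
interface: any table mapping (helix position, residue) to a base
probability vector can drive it. The default table is a deliberately
simple linear code — helix 6, 3 and −1 determine the 5′, middle and 3′
subsite base; N/D/R/Q specify A/C/G/T near-deterministically; unknown
residues give uniform columns; helix 2 (a cross-strand contact) is
carried in the interface but unused. Finger PWMs are concatenated in
reverse finger order, following the antiparallel binding convention
(N-terminal finger contacts the 3′ subsite). A site qualifies as strongly
bound when its log-odds score reaches 80% of the PWM's maximum — an
explicit configurable convention, not a reconstruction of the original
cutoff; a PWM with no positive information content has an unreachable
threshold. Family-specific motifs are k-mers (canonicalised over strand)
present in one family's consensus and at most `max_other` others.

## Coevolution dating and the chromosome-19 test

Family invasions are dated by single-gain parsimony: the invasion branch
is the branch above the MRCA of all carriers; absences inside the clade
are tolerated as losses and logged. Tandem affinity gains are dated the
same way on the species set whose predicted motif repertoire contains the
focal tandem's target motif. A repressor pair is contemporaneous when the
two branches coincide (strict mode) or are parent/child (relaxed mode).
Branches are named by their clade's sorted leaf set, which makes epoch
labels stable and comparable.

The contingency table counts repressor tandems by location against
inclusive column totals (the published fraction arithmetic,
32/2492 = 1.3%, implies the totals include the repressors, and the
package adopts that convention). Fractions are reported to two
significant figures. Fisher's exact test sums hypergeometric point
probabilities over the support; the one-sided "greater" alternative is
the default because the hypothesis (chromosome-19 excess) is directional.
The noisy-classifier correction re-draws each tandem's true label from
the posterior implied by its observed label under false-positive rate
`alpha` and false-negative rate `beta` (precision for observed positives,
the complementary leak rate for observed negatives, both derived from the
column's label prevalence), rebuilds the table per replicate and averages
the Fisher p-values. It reduces exactly to the plain test at
`alpha = beta = 0`; at `alpha + beta = 1` the labels carry no information
and true labels are re-drawn at the pooled rate, saturating the adjusted
p-value near 0.5. The published adjusted P-value is treated as context,
not a target, because the original correction's exact form is not public.

# The synthetic-data generators

The generators' defaults are the study conditions the package is
validated under; they are fixed once and shared by tests and the
acceptance script.

**Zinc-finger clusters.** Each of 8 clusters is one sequence family: a
seed gene carrying 4–12 copies of a founder C2H2 finger joined by coding
linkers, grown by 5 tandem segmental duplications; after each duplication
every copy accumulates 0.06 substitutions per site, so planted ages span
0.06–0.30 f.n.s., the recent-burst regime in which most chromosome-19
duplications fall. Three generator choices emulate purifying selection on
a functional zinc-finger array and are what make the planted truth
recoverable: (i) substitutions spare the anchor C/H codons, (ii) codons
that would become stops or stray C/H codons are reverted, and (iii)
construction and mutation draws that would create spurious off-frame or
antisense C2H2 parses are rejected. Each finger copy is pre-diverged from
the founder by 0.05 substitutions per site so that a motif's closest
relative is its counterpart in another gene copy, not its within-gene
paralog — as in real arrays, whose fingers bind different subsites. What
passing recovery tests therefore show is that the scan/dating/clustering
pipeline is correct on clean tandem arrays; they do not certify
robustness to antisense motif artifacts, pseudogenised fingers, or
indels, none of which the generator produces.

**Deletion polymorphisms.** Per region of scaled rate `theta`, the number
of segregating deletions is Poisson(`theta * a_n`) and derived counts
follow the neutral `1/i` spectrum, with `n = 90` haplotypes and lengths
exceeding 50 bp (the published filter). Defaults
`theta_background = 50`, `theta_hotspot = 100` put the planted twofold
hotspot in a regime with hundreds of segregating deletions — a pooled
cluster-region scale at which fold recovery is statistically stable. No
demography, linkage, or call-error model is included (a configurable
singleton inflation is used in tests to probe the masking estimator).

**ChIP peaks.** Open chromatin is placed uniformly; peak centers land on
class `c` with probability proportional to `enrichment_factors[c]` times
the class's genome share, and lengths are Normal(474, 74) truncated at
50 bp, matching the published peak statistics. Because placement weights
renormalise across the genome, the realised fold over a uniform
background is `factor / norm` with `norm` the factor-weighted share sum;
the generator reports this expected fold as ground truth. Mutant peaks
are a per-class Bernoulli retention of wild-type peaks (LTR 3.5%, other
TE classes 4%, matching the published depletion regime). Measured
retention runs slightly above the planted value because mutant peaks
centered on neighbouring DNA spill class base pairs across element
edges — the same boundary effect a real bp-level analysis has.

**Coevolution.** ERV family consensi share one retroviral backbone with a
family-specific 9-mer planted in a fixed window, so every family-specific
k-mer is attributable to the planted difference; each family is assigned
an invasion branch on a fixed 7-leaf primate tree (human plus six
non-human primates). Planted repressor tandems receive finger residues
that decode to their target family's k-mer under the default code, and
per-species motif sets whose gain clade equals the invasion clade;
anachronistic decoys gain affinity on a different branch and must be
removed by the contemporaneous filter. Tandem totals (2492 on
chromosome 19, 1898 elsewhere) and planted repressor counts (32/9)
default to the published chromosome-19 census, so the simulated
contingency table reproduces it exactly when the pipeline is correct.

# Numerical choices and degenerate inputs

* Jukes–Cantor censoring at `d_max = 1.5` f.n.s. (monotone cap).
* UPGMA ties broken by lexicographic leaf-set order; tolerance for tie
  detection is relative `1e-12`.
* `fisher_exact` two-sided mode includes outcomes with probability at
  most `(1 + 1e-7)` times the observed table's, the standard guard
  against floating-point exclusion of the observed outcome itself;
  degenerate margins give `p = 1` with a flag.
* PWM columns receive a 0.01 pseudocount before the log-odds transform.
* Empty deletion regions give `S = 0` spectra; heterogeneous sample sizes
  are an error rather than silently pooled.
* Permutation p-values use the `(1 + exceedances) / (1 + reps)` add-one
  rule.

# Validation design and problem sizes

The test suite validates every operation against an independent oracle
(per-base overlap counting, exhaustive PWM scoring, hypergeometric
enumeration, naive UPGMA agglomeration; 100 random instances each) and
every pipeline against simulation ground truth at these scales: 500
regions per rate for estimator calibration; one 8-cluster genome
(~300–400 motifs) for scan recall, age rank-correlation and family
recovery; 20 seeded end-to-end coevolution runs for enrichment detection
plus 200 seeded null tables for p-value uniformity. These sizes give
stable recovery statistics while keeping the full suite fast enough to
run routinely.

# Known limitations

* The recognition code is a toy stand-in; predictions are only as good as
  the supplied table, and the package deliberately reports no claim about
  real binding affinities.
* Motif alignment is pattern-anchored; motifs with internal indels would
  be misaligned.
* Parsimony dating ignores incomplete lineage sorting and horizontal
  reinvasion; losses are logged, not modelled.
* The deletion-rate conversion to per-generation units depends linearly
  on the assumed `N_e`; only scaled rates are comparable across studies
  without that assumption.
* Simulated ERV consensi share a backbone by construction; real family
  consensi differ throughout their length, which makes real
  family-specific motif discovery harder than the simulated task.
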