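---
title: "Methods: family-based sex-linkage discovery and homeolog filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based sex-linkage discovery and homeolog filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
```

This vignette documents the statistical reasoning, the tunable parameters,
and the deliberate design choices behind the package, in the spirit of a
methods section. Nothing here is asserted that the test suite or the
acceptance script does not itself compute.

## 1. The genotype model

All genotypes are unordered, unphased diploid allele pairs (`"A/T"`,
with `{A,T} == {T,A}`); missing calls are `NA`. Phase is deliberately
discarded: every operation in the pipeline depends only on zygosity and
allele content. VCF half-calls (`./1`) are demoted to missing, because the
dropout-correction logic is defined on full diploid calls. Records with
more than two alleles are loaded and flagged rather than dropped, so the
accounting invariant "input loci = retained + reported" always holds.

## 2. Family QC

**Mendelian plausibility.** An offspring call is plausible iff it can be
formed by one allele from each parent. With parents A/T × A/A an offspring
T/T is implausible; because parents are sequenced at roughly ten-fold the
offspring coverage, such a call is best explained by allele dropout of a
true A/T heterozygote. `mendel_check()` is property-tested against
brute-force enumeration of the four gamete combinations for *all* pairs of
parental genotypes over a four-letter alphabet.

**The 10% rule.** Per locus, with `f` = implausible / called offspring:
`f < max_implausible_frac` (default 0.10) sets the implausible cells to
missing and keeps the locus; otherwise the locus is discarded. Two
boundary conventions were open and are resolved as follows:

* *The boundary itself.* The rule's verbal form ("below 10% correct,
  above 10% discard") leaves `f = 0.10` unassigned; this package discards
  at `f >= max_implausible_frac`. That is the conservative reading, and the
  threshold is a visible config field, so the alternative is a one-line
  change.
* *The denominator.* Offspring with missing calls carry no plausibility
  evidence, so `f` is computed over *called* offspring only.

**Call-rate trim.** Loci genotyped in at least `min_call_rate` (default
0.90) of individuals are retained. "Individuals" defaults to parents plus
offspring — the literal reading of a 90%-of-individuals rule — with a
toggle (`call_rate_includes_parents = FALSE`) for the offspring-only
convention. The pipeline order is call-rate trim first, then undercall
correction, matching how a raw GBS table is normally reduced.

Loci where either parent is missing cannot be assessed and pass through
flagged, untouched: correcting or discarding them would apply the rule
outside its definition.

## 3. The sex-linkage scan

A locus is *completely sex-biased* when, among non-missing offspring calls,
every daughter is heterozygous and every son homozygous, or vice versa.
Completeness is evaluated over non-missing calls by default, guarded by
`min_informative_per_sex` (default 5) so that sparsely genotyped loci
cannot slip through on a handful of calls; a strict mode
(`require_all_offspring = TRUE`) disqualifies any locus with a missing
offspring call. With `n` informative offspring and one heterozygous
parent, a fully autosomal locus is completely sex-biased by chance with
probability `2^-(n-1)`; at 47 offspring that is ~1.4e-14, so any hit in a
realistic dataset is either true linkage or systematic error. The test
suite verifies zero chance hits over 100,000 simulated autosomal loci.

Classification then reads the parents (mother-het/father-hom with
heterozygous daughters = W pattern, and so on; see the README table).
Three guard rails apply:

* loci where both parents are heterozygous or both homozygous are
  classified `inconsistent` rather than silently dropped — a double-het
  cross cannot produce complete sex bias without error;
* any Mendelian-implausible offspring call among those used demotes the
  call to `inconsistent`, preventing dropout artifacts from being counted;
* a missing parental genotype yields `unassessable`, distinct from
  `inconsistent`.

X and Y patterns are implemented by exact mirror symmetry (swap
mother↔father and F↔M); the symmetry is property-tested by programmatic
relabeling: the W/Z calls of a ZW dataset map tip-for-tip onto the Y/X
calls of its relabeled twin.

`infer_system()` is deliberately conservative: *all* informative calls
must agree with one heterogamety before a verdict is issued; any mixture
is `CONFLICTING` with full tallies.

## 4. The family simulator

`simulate_family()` emulates the study conditions the pipeline is meant
for: 24 daughters and 23 sons by default; biallelic tags; a fully
sex-linked, non-recombining marker class under ZW or XY; dropout
concentrated in offspring; missingness applied after dropout.

* *Founder genotypes.* Autosomal parent pairs are drawn uniformly from the
  seven ordered genotype configurations that leave the locus polymorphic
  in the family (3×3 minus the two monomorphic crosses), because
  reference-free SNP callers only report polymorphic tags.
* *Dropout model.* A heterozygote becomes either homozygote with equal
  probability, at rate `undercall_rate` for offspring and
  `undercall_rate × parent_error_scale` (default scale 0.1) for parents,
  mirroring the ten-fold coverage asymmetry without modeling reads. Under
  an A/T × A/A cross this predicts an implausible-call fraction of `u/4`
  (P(het) = 1/2 × P(dropout) = u × P(implausible homozygote) = 1/2), which
  the Monte-Carlo test confirms within three binomial standard errors on
  >10,000 offspring-calls.
* *Sex linkage.* Simulated with zero recombination and a homozygous
  co-parent, the configuration the pattern classifier is defined on;
  pseudoautosomal behavior is out of scope.
* The dropout and missingness rates are not estimates of any real
  dataset's rates — the source experiment did not quantify its own — they
  are knobs for sensitivity analysis. Defaults of 0 keep the generator's
  null clean.

What the simulator does **not** emulate: read-level noise, coverage
heterogeneity across tags, linked autosomal markers, de-novo mutations,
and genotyping errors that respect Mendelian plausibility (e.g. a
plausible wrong homozygote at a monomorphic-parent locus). Passing tests
therefore demonstrate correctness of the *logic* under the stated error
model, not robustness to every real-data pathology. One consequence is
visible in the README example: dropout events that produce *plausible*
homozygotes destroy the completely-sex-biased signature of true sex-linked
loci and are unrecoverable by design — precision is protected, recall is
coverage-limited.

## 5. Gene families: simulation and filtering

**Simulator.** Families evolve on a gene tree built by duplicating an
ultrametric five-species ingroup tree at a WGD node that predates all
speciation (stem 0.05 subs/site per copy; ingroup depth 0.06; outgroup at
0.15), under Jukes–Cantor with `seq_length` 500 bp by default. These
depths give ingroup sister species ~0.06 expected substitutions/site
between them and a long (0.10) internal edge at the WGD — deep enough that
a 500 bp alignment recovers the homeolog split essentially always, which
is the regime the real transcriptome data occupy (homeolog divergence far
exceeds species divergence). Optional per-branch clade loss (`loss_prob`)
and splice-variant injection (a ≥99% identical copy of a random tip)
reproduce the two artifacts the filter must survive. A
`lineage_specific` mode generates the null case: no WGD, one
within-species duplication at 0.015 subs/site depth — distant enough not
to look like a splice variant, recent enough to be sisters.

**Alignment QC.** Ungapped length is the number of columns with no gap in
*any* sequence (the stricter of the two readings of "ungapped length";
a per-sequence mode would keep more data but weaken the shared-signal
guarantee). The default threshold of 300 means "above 299 bp". At least
three ingroup species, and at least one ingroup species with two
sequences, are required — without the latter, orthology and homeology are
indistinguishable in principle.

**Trees.** Provided gene trees are used when present; otherwise
neighbor-joining on p-distances with pairwise deletion. Sequences are
sorted by name before distance computation so ties break deterministically;
negative NJ branch lengths are clamped to zero. A sequence pair with no
comparable columns is an error naming the pair, not a silent NaN.

**The homeolog criterion.** After rooting (outgroup if present, midpoint
otherwise), internal nodes are searched in post-order for a node whose two
child clades satisfy: (a) at most one sequence per species per clade,
(b) at least one species present in both clades, (c) at least one clade
with three or more sequences. Requiring both ortholog sets to be *clades*
is the load-bearing choice: a bipartition-style search (one clade versus
everything else) would accept a lineage-specific duplication, because the
edge above one duplicate always separates it from its twin while
satisfying (a)–(c). Two same-species sisters can never satisfy the
two-clade form, which is exactly the biology — under a pre-speciation WGD
each copy must cluster with other species' orthologs, not with its twin.
The first valid node in post-order wins (determinism); the acceptance
decision itself is order-independent and is property-tested against
exhaustive enumeration of all child-clade pairs on random trees of up to
eight tips.

**Prune-and-rebuild.** When no valid node exists but a species carries
near-identical copies (p-distance ≤ `prune_pdist`, default 0.01 — an
arbitrary but visible threshold), the shorter copies are pruned, QC re-run,
the tree rebuilt, and the assessment repeated, up to `max_rounds`
(default 3) cycles. The original multi-round procedure this emulates was
never specified at byte level; the realization here (longest-tip
retention, ≤3 cycles, machine-readable rejection reasons) is this
package's own and is isolated behind `assess_homeology()` so it can be
revised independently.

**Coalescent selection.** From an accepted family whose complete lineage
covers all required species, the other lineage contributes exactly one
sequence: the longest by ungapped length, ties broken by a seeded draw.
Homeologs are equidistant from the whole ortholog set, so the choice of
donor species is irrelevant — only reproducibility matters, hence the
seed.

## 6. Tag homology

E-value thresholding is strict (`< 1e-5`). A "region" is a distinct
subject scaffold — multiple HSPs on one scaffold count once. Two-scaffold
tags (a short query matching both homeologs of an allotetraploid
reference) retain one scaffold by a seeded draw; the original analysis
used an unseeded choice, and seeding is the only deviation, made for
reproducibility. Scaffold placement calls a split only for exactly two
chromosomes, each with at least `min_span` (default 1 kb) of aligned
segment; three or more substantial chromosomes is `unplaced` rather than
a guess. Split detection is at scaffold level; whether the tag's own hit
falls inside the split portion is not examined (the finer tag-level
convention was never specified).

## 7. Phylogenetic utilities

The harmonic-mean marginal log-likelihood is computed stably in log space,
`lnML = log n − logsumexp(−ℓ)`, and comparisons are reported as 2·lnBF
(the Kass–Raftery scale). The harmonic-mean estimator's well-known high
variance is inherited deliberately — this utility reproduces a standard
comparison, it does not improve on it; stepping-stone or path sampling are
out of scope. Closed forms anchor the tests: identical traces give exactly
0, and constant traces at −10 and −12 give exactly 4.

Chronogram rescaling multiplies all branch lengths by `r / (current root
age)` with `r ~ Normal(65, 4.62)` MY truncated at zero by rejection
(negligible at these parameters: ~7e-45 of the mass is negative).
Topology and relative node depths are preserved exactly; the function also
accepts an explicit `root_age`, which is how the closed-form tests avoid
seed hunting. Ultrametricity is checked within a relative tolerance and
violations warn rather than fail, since posterior tree samples routinely
carry last-digit noise.

## 8. Problem sizes and runtime

The shipped validation uses 5,000 autosomal loci for recovery runs,
100,000 loci for the false-positive null, ~14,000 offspring-calls for the
dropout Monte-Carlo, 200 WGD families (plus 60 lineage-specific null
families) for the filter, 150 random trees of ≤8 tips for the
enumeration oracle, and 2,000–10,000 draws for the root-age distribution
checks. These sizes put every binomial/Poisson tolerance at three standard
errors while keeping the full suite under a minute on one core; they are
statements about statistical resolution, not about the limits of the
implementation, which is vectorized across loci and comfortably handles
the ~10^5-tag scale of a real GBS experiment.

## 9. Known limitations

* Verdicts come from one family; populations segregating multiple systems
  need multi-family designs the package does not model.
* The scan targets *complete* sex bias only; partial association
  (GWAS-style) statistics, recombination distances and pseudoautosomal
  markers are out of scope.
* The homeolog filter assumes the duplication predates speciation; nested
  or repeated duplications are rejected, not resolved.
* The NJ tree builder is a default, not a claim that NJ is optimal;
  externally estimated trees plug in through the `tree` slot.
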