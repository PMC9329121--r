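---
title: "Measuring de novo APOBEC3 mutagenesis in clone lineages: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring de novo APOBEC3 mutagenesis in clone lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental design this package analyses

APOBEC3 cytidine deaminases leave a characteristic imprint on cancer
genomes: C>T and C>G substitutions at TpC dinucleotides (COSMIC signatures
SBS2 and SBS13), enriched at TCA trinucleotides and — depending on which
family member is active — at YTCA (APOBEC3A-preferred) or RTCA
(APOBEC3B-preferred) tetranucleotides, together with clustered mutation
showers (kataegis) and smaller diffuse clusters (omikli). A clean way to
measure *ongoing* APOBEC3 mutagenesis in cultured cancer cells is a
mutation-accumulation design: expand a single-cell-derived **parent**
clone, re-clone it into single-cell-derived **daughter** clones, sequence
everything, and read off the mutations private to each daughter — exactly
the mutations acquired in the propagation interval bounded by the two
cloning events.

`apomut` implements the computational arm of that design as a reusable,
fully tested pipeline: lineage-aware somatic-call filtering, sequence-
context classification, motif-enrichment statistics, simulation-calibrated
clustered-mutation detection, penalized signature refitting, and the
non-parametric group comparisons used to contrast genotypes (for example
wild-type against deaminase-knockout lineages). A synthetic study
generator with recorded ground truth makes every stage testable without
access to any sequencing data.

## Mutation identification: two steps, six filters

Caller output (PASS-flagged single-base substitutions with read-level
quality annotations) passes through two stages.

**Locus quality (filters 0–4).** Non-PASS calls are dropped first. Then,
in order: ASMD (median alignment score of mutation-reporting reads) ≤ 130;
clipping index CLPM > 0; fewer than 16 reads covering the locus in the
comparison reference sample; and lack of mutant support on both sequencing
directions. Attribution is to the first failing filter, but the retained
set is provably order-independent (each rule is a per-record predicate),
and the tests assert exact conservation: input = retained + Σ removals.

**Lineage provenance (filters 5–6).** Candidate loci are re-genotyped
across every clone of the cell line. A mutation is removed from a clone's
catalogue if (5) any mutant read supports it in the clone's reference
sample (its parent, for daughters), or (6) it is present in strictly more
than 50% of clones from *other* parental lineages — the fingerprint of
germline or pre-existing somatic variation. "Present" means ≥ 1 mutant
read, a deliberately literal reading of "presented in any reads". The
denominator of filter 6 counts all genotyped clones of other lineages,
parents included. Everything removed in this second stage is pooled into a
bulk-proxy catalogue approximating the pre-cloning mutational state of the
cell line; the package pools all stage-two removals and records
per-record provenance, since the narrower alternative (only variants
shared between ≥ 2 parents) is a subset that can be reconstructed from the
report.

Daughters sharing > 30% of their de novo mutations with a sibling (an
asymmetric fraction, measured against each daughter's own catalogue size
so that a small catalogue nested in a large one is caught) are flagged as
descendants of an undeclared subclone and excluded from burden statistics.

A kernel-density diagnostic (bandwidth 0.05 on the VAF axis, modes = local
maxima above 10% of the global peak) labels each clone `clonal` or
`possible_subclonality`; below 50 mutations it reports `underpowered`
rather than guessing. The original assessment of this property was visual,
so the bandwidth is a package choice, fixed and documented here.

## Sequence-context classification

Every substitution is expressed with the mutated base as the pyrimidine of
its base pair and assigned simultaneously to the 6, 96 (± 1 bp flanks),
1536 (± 2 bp flanks) and 288 channel systems. Records stated on the minus
strand (reference allele equal to the complement of the genome base) are
re-expressed automatically; this makes classification idempotent under
strand re-statement, which the tests assert exactly.

The 288 system is 96 × 3: transcribed (pyrimidine on the template strand
of a gene), untranscribed (coding strand), and nontranscribed. The third
category is a design necessity — 96 × 2 = 192 ≠ 288 — and absorbs
intergenic positions, records without any annotation, and loci covered by
genes on both strands (tie-break, logged here rather than silently
chosen). Channel order is fixed (alphabetical flanks within
C>A…T>G blocks) so matrices are bit-comparable across runs.

## Motif enrichment

Fold enrichment at motif M is
`E_M = (Mut_M / Con_M) / (Mut_C / Con_C)`,
with `Mut` counting pyrimidine-strand C>T and C>G mutations (C>A at TCN is
excluded: that class is confounded by culture-associated processes) and
`Con` counting genome-wide availability from the context inventory. The
inventory stores 32 pyrimidine-centred trinucleotide and 512
pentanucleotide keys; availability is per target *site*, not per mutation
outcome, which is why 32 (not 96) keys suffice — either convention gives
identical E values because the collapsing is strand-symmetric. YTCA/RTCA
availability is marginalized from the pentanucleotide inventory over the
3'-most base; counting 4-mers directly would give identical numbers.
Degenerate inputs never divide by zero: a zero denominator yields an
explicit `insufficient_data` status.

Autosome restriction (or any region restriction) is expressed through the
chromosome filter and an optional BED-style include mask, not hard-coded
chromosome names — synthetic genomes have arbitrary names.

## Clustered mutations

Whether an intermutation distance (IMD) is "short" depends on the
sample's burden and spectrum, so the cutoff is calibrated per sample
against a context-preserving background: each catalogue is re-scattered
100 times, preserving per-chromosome counts and each mutation's ± 1 bp
pyrimidine-strand context (and therefore the exact 96-channel catalogue,
asserted replicate by replicate in the tests). The cutoff is the largest
threshold at which (i) at least 90% of sub-threshold mutations are
unexplained by the simulated model and (ii) the replicate-count
exceedance probability is below 0.01 after Benjamini–Hochberg correction
across candidate thresholds. Two numerical choices deserve note. First,
the exceedance p is the raw fraction of replicates reaching the observed
count: with 100 replicates, any additive smoothing puts the floor at
1/101 ≈ 0.0099, which BH correction then pushes past the q < 0.01
contract, so no cutoff could ever be reported; the source method's
"q < 0.01 from 100 simulations" is only satisfiable with the raw
estimator. Second, candidate thresholds are one past each distinct
observed IMD (thinned to ≤ 2000 quantile-spaced values on very large
samples).

Mutation-rich 10-Mb windows (observed count above the 99th percentile of
simulated window counts) get a window-specific cutoff re-derived from
within-window IMDs and capped at the global cutoff. Runs of consecutive
mutations under the applicable cutoff become events; VAF consistency
(successive pairs differing by < 0.10 — successive-pair, not max–min,
matching the definition of consistency between *subsequent* mutations)
gates classification into doublet (2 adjacent), multibase (≥ 3 adjacent),
omikli (2–3, some gap > 1 bp) and kataegis (≥ 4, some gap > 1 bp);
VAF-inconsistent runs are `other`. Clustered SBSs at cytosines in TCN
context are partitioned as APOBEC3, everything else non-APOBEC3, and
burdens are reported per megabase both as mutations and as events.

## Signature attribution

Catalogues are refit onto a fixed reference signature set by sparse
forward–backward selection with non-negative least squares on the selected
support. The penalties are cosine-improvement thresholds: a signature
enters only if it raises the reconstruction cosine by more than
`add_penalty`, and a selected signature is dropped whenever removing it
costs less than `remove_penalty`. The tool this mirrors names its options
(`nnls_add_penalty`, `nnls_remove_penalty`) but not their semantics, so
the threshold interpretation is this package's design choice; it
reproduces the properties that matter — determinism, penalty
monotonicity of the support, and the sensitivity ordering between the
"lowered" (0.005/0.001, the default here, used for per-sample calls) and
"default" (0.05/0.01) pairs. Externally extracted signatures can be
decomposed into reference mixtures with the standard cosine grading:
> 0.97 decomposed, < 0.95 novel, ambiguous in between. Flat profiles
(SBS5-like) are genuinely harder to refit than peaked ones; the tests
assert that ordering rather than a fabricated constant.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once:

* **Lineages**: 2 parents × 4 daughters of one cell line, an unrelated
  normal as parent reference; optional genotype labels per parent.
* **Burdens**: a flat SBS5-like background (800 SBS per daughter) plus
  episodic APOBEC3-like bursts — each burst-capable daughter draws a
  log-normal SBS2/13-like burden (meanlog log 800, sdlog 0.6, 60/40 C>T
  to C>G), present with probability 0.6. This reproduces the episodic,
  heavy-tailed per-daughter variation the design is meant to detect.
* **Placement** is channel-first: the 96-channel is drawn from the
  mixture, then a uniformly random genomic site matching that channel's
  context — so the generating mixture *is* the sampling distribution of
  the emitted catalogue, and attribution recovery is well-posed.
* **Reads**: clonal VAF 0.5 with binomial sampling at ~30× depth
  (optional subclone mixing at half VAF exercises the clonality
  diagnostic); non-artifact records are guaranteed locus-filter-clean.
* **Pre-existing variation**: 400 germline and 250 parent-private
  variants, genotypable in every carrier; a leak fraction appears in call
  tables so filters 5/6 have real work to do. De novo sites never collide
  with these loci (collisions would be correctly, but confusingly,
  filtered as inherited).
* **Artifacts**: a configurable fraction (default 5%) of records is
  degraded into exactly one locus-filter failure mode (low ASMD, CLPM > 0,
  thin reference coverage, or unidirectional support).
* **Clusters**: injected kataegis carry 8–20 members, omikli 2–3, with
  member IMDs uniform on 2–20 bp. The short range is a deliberate scale
  compression, not a tuning knob: a real sample has ~10³–10⁴ mutations on
  a 3-Gb genome while the synthetic world keeps desk-scale mutation
  counts on a 10⁸-bp genome, i.e. a ~60-fold higher density. Chance
  sub-threshold IMD counts grow linearly with density, so preserving the
  clustered-versus-chance contrast of real kataegis (tens to hundreds of
  bp between members) requires compressing cluster IMDs by the same
  factor. With uncompressed IMDs no 90%-purity cutoff exists at synthetic
  density — a property of the compressed world, not of the method.

What a green test does **not** establish: the generator draws i.i.d. bases
(no repeats, no chromatin or replication-timing covariates of mutation
rate), produces no indels or rearrangements, no copy-number variation
(VAFs sit at 0.5, not the polyploid spread of real lines), and its
artifact model is one-failure-per-record. Conclusions about real data
still depend on the upstream caller and the representativeness of its
quality annotations.

## Open choices made and their rationale

* The "96 contexts" of availability are stored as 32 pyrimidine-centred
  keys (availability is per site); the E statistic is invariant to this
  choice.
* The bulk-proxy catalogue pools all stage-two removals (with provenance)
  rather than only multi-parent-shared variants.
* YTCA/RTCA availability comes from marginalized 5-mer counts (identical
  to 4-mer counting, recorded for reproducibility).
* The exceedance statistic for the IMD cutoff is the replicate-count
  exceedance with raw empirical p (see above); the upstream method's
  exact statistic is unpublished, so the contract (90% purity, q < 0.01)
  is what this module guarantees.
* Mann–Whitney p values are exact (full enumeration) for tie-free groups
  with min(n, m) ≤ 8 and tie-corrected normal with continuity correction
  otherwise. Exhaustively, the one-sided approximation stays within 0.02
  of exact for all sizes ≤ 8; the doubled two-sided tail reaches 0.0375
  at n = m = 3, so that is the bound the tests assert for two-sided.
* FDR families are declared by the caller per report — the figures this
  mirrors do not enumerate their correction families, so guessing them is
  the caller's scientific decision, not a package default.

## Limitations

IMD-cutoff calibration needs ≥ 2 mutations per chromosome and loses power
below a few hundred mutations per sample (the cutoff collapses to 0 and
no clusters are called — conservative by construction). The refitting
optimizer is greedy; with near-collinear reference sets it can settle on
an equivalent-cosine support differing from the generating one, which is
why acceptance measures activity recovery rather than support identity.
Transcription-strand categories rely on a user-supplied annotation and
default to `nontranscribed` without one.
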