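---
title: "Classifying Rab GTPases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying Rab GTPases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rabclass)
```

## The problem

Rab GTPases are the largest family of small Ras-superfamily GTPases and the
central organisers of vesicular trafficking. Because Rab orthologs keep their
subfamily-specific function across very distant taxa, assigning a protein to a
Rab subfamily (Rab1, Rab5, ...) is a strong functional prediction — but doing
it by hand does not scale to hundreds of proteomes, and doing it naively is
hard: generic GTPase motifs produce strong non-specific signal, the family is
large, and subfamilies are mutually very similar.

rabclass implements an automated two-phase classifier for this problem,
together with the clustering machinery for proposing *hypothetical* new
subfamilies from sequences that match no known one, and the ROC machinery used
to calibrate its confidence cutoff.

## Phase 1 — is it a Rab?

Three stages are applied strictly in order; the first failure rejects the
sequence and is recorded:

1. **G-domain filter.** The query is scored against a pooled profile (PSSM)
   built from *all* reference GTPases, Rab and non-Rab. The pass threshold is
   calibrated, not guessed: it is the minimum bit score of any reference
   GTPase against the profile minus 1 bit of slack, which encodes the
   requirement that the filter must never exclude a genuine GTPase. Candidate
   reduction comes at stage 2-3, not here.
2. **Best-hit triage.** A Smith–Waterman search (BLOSUM62, affine gaps
   11/1) against the curated reference set, with Karlin–Altschul E-values
   (`E = K m n e^{-λS}`, gapped parameters λ = 0.267, K = 0.041) gated at
   1e-10. If the query has no hit at the gate, or its best hit (BH) is a
   non-Rab GTPase (Ras, Rho, Ran, Arf, RabL2/3/5, ...), it is discarded:
   a protein most similar to a non-Rab is not a Rab.
3. **RabF motif scan.** Five short diagnostic motifs (consensus seeds
   `igvdf`, `klqiw`, `rfxxxt`, `yyrga`, `lvydit`) distinguish Rabs from other
   small GTPases. Position weight matrices trained on reference instances are
   slid over the query; a window is a hit when its *exact* position p-value
   is at most 0.0005. A sequence with no motif at all cannot be a Rab.

Survivors are Rabs, with a family confidence in [0, 1]:

```
confidence = e_bh * (0.5 + 0.5 * min(1, distinct_motifs / 2))
e_bh       = s_rab / (s_rab + s_nonrab)      (bit scores; 1 if no non-Rab hit)
```

This fusion is a **documented reconstruction**: the original pipeline combined
its stage statistics by an unpublished procedure. The formula above was chosen
to be bounded, monotone in each evidence channel (the Rab/non-Rab bit-score
margin and the count of distinct motifs), and to attain 1 for unambiguous
evidence; wrong calls concentrate at low values on synthetic benchmarks. It is
not claimed to be the original formula, and the CLI says so at startup.

## Phase 2 — which subfamily?

A 40% identity gate is applied first: if the query's identity to its best hit
(measured over the aligned columns of the best local alignment) is below 0.40,
the sequence is too disparate to be assigned to any known subfamily and is
called **RabX**. Otherwise a likelihood score is distributed over the
subfamilies: for each subfamily *k*,

```
b_k = best pairwise bit score against members of k   (0 unless E <= 1e-10)
r_k = profile bit score against the subfamily PSSM   (0 unless E <= 1e-5)
score_k = 0.5 * (b_k / Σb + r_k / Σr)
```

If exactly one channel is empty its weight shifts to the other; if both are
empty the vector is empty and the call is RabX. Non-empty vectors sum to 1, so
the winning score doubles as the call confidence on a probability simplex, and
the full vector is retained as a record of relative uncertainty. Exact ties
break to the lexicographically smallest name and set an ambiguity flag.

In **high-confidence mode** a named call whose confidence falls below the
cutoff (default 0.4) is demoted to RabX. The mode can only demote, never
introduce, named calls. The 0.4 default is the operating point chosen by ROC
analysis of call confidences on validation data; `roc_auc()` reproduces that
analysis for any labelled call set (AUC = probability that a random correct
call outscores a random incorrect one, ties at half credit, computed both as
trapezoidal area and verified against the concordance statistic in the tests).

The evaluation module reports accuracy under both published conventions — the
overall fraction of correct decisions and the unweighted mean of per-organism
fractions — separately at family and subfamily level, because the two levels
answer different questions (is it a Rab? / which Rab?).

## Hypothetical subfamilies from RabX sequences

RabX sequences are structured into candidate new subfamilies in two steps,
following the published procedure:

1. **Within each genome**, sequences with pairwise identity ≥ 70% (matches
   over the shorter sequence, the deduplication-heuristic convention) are
   joined into an identity-weighted graph, partitioned by Markov clustering
   (MCL) at inflation 2.0. The MCL iteration: self-loops at the maximum
   incident weight, column normalisation, then alternately expansion (matrix
   squaring) and inflation (entrywise power, renormalise), pruning entries
   below 1e-8, until the maximum change is below 1e-6 or 100 iterations.
   Attractor overlap is resolved to the lexicographically smallest attractor,
   so the output is always a clean partition.
2. **Across genomes**, clusters merge by single linkage whenever at least one
   cross-cluster pair exceeds 70% identity.

Clusters are named `Novel1, Novel2, ...` by decreasing size and categorized by
breadth with strict precedence: spanning more than one taxon, more than one
genome, several members in one genome, or a singleton.

Note the package deliberately carries **two identity conventions**: the 40%
subfamily gate uses aligned-column identity (what a BLAST hit table reports),
while deduplication (90%) and RabX clustering (70%) use matches over the
shorter sequence (the convention of the clustering heuristics those thresholds
come from). Both are implemented in one place and documented; conflating them
shifts both boundaries.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `evalue_family` | 1e-10 | E-value gate for the family-level best-hit search |
| `evalue_profile` | 1e-5 | E-value gate for subfamily profile hits |
| `motif_pvalue` | 0.0005 | position p-value gate for a RabF motif hit |
| `identity_subfamily_gate` | 0.40 | minimum BH identity for a named call |
| `identity_cluster` | 0.70 | RabX clustering / merging threshold |
| `identity_dedupe` | 0.90 | reference redundancy ceiling |
| `mcl_inflation` | 2.0 | Markov clustering granularity |
| `confidence_cutoff` | 0.4 | high-confidence demotion threshold |
| `gap_open`, `gap_extend` | 11, 1 | affine gap costs (gap of length k costs 11 + k) |
| `ka_lambda`, `ka_K` | 0.267, 0.041 | gapped Karlin–Altschul parameters for BLOSUM62(11,1) |
| `background` | uniform 1/20 | amino-acid background for motifs and profiles |

## Numerical and design choices

* **Alignment.** Pairwise Smith–Waterman goes through
  `Biostrings::pairwiseAlignment()`; the test suite holds it against an
  independent brute-force Gotoh implementation, exactly, on hundreds of random
  pairs. No compositional soft masking is applied (the original search stage
  used it); this is logged once per CLI run. Profile alignment uses the same
  affine-gap recurrence against PSSM columns, in compiled code.
* **Exact motif p-values.** Log-odds scores are discretized to a 1/100-bit
  grid and the null score distribution of a background window is built by
  exact convolution of per-column distributions, so `position_pvalue()` is
  exact on the grid (error bounded by the grid spacing); the tests verify it
  against exhaustive enumeration. Wildcard (`x`) positions are modelled as
  background columns with log-odds ≈ 0. With an exact per-window p-value gate
  at 0.0005, a fraction of up to 0.0005 of background windows per motif is
  called *by construction* — on a 500-residue random sequence that is about
  one window call in expectation across the five motifs. This is the
  calibration the threshold defines, it is tested as such, and it is why the
  pipeline never relies on the motif stage alone: random sequences die at
  stages 1–2.
* **Profiles.** One transparent construction replaces the external
  profile-tool black boxes for both the subfamily PSSMs and the G-domain
  filter: members anchored to the first member by global alignment (input
  order is the guide order; profile quality, not alignment optimality, is the
  contract), columns with more than 50% gaps dropped, duplicate sequences
  collapsed, Henikoff position-based weights, background pseudocounts
  (weight 5 per column), log-odds against background. An adapter seam
  (`rab_pssm` objects with a serialized TSV form) allows plugging an external
  domain caller later.
* **Motif training.** Models are trained from labelled instances when the
  reference database provides them (the benchmark generator does), otherwise
  by a two-pass scheme: consensus-seeded models harvest each reference Rab's
  best-scoring window, and the models are retrained on those windows.
  De-novo motif discovery is out of scope; the five motifs are fixed a priori.
* **Determinism.** Every source of randomness flows from an explicit seed;
  every writer produces byte-identical files for identical inputs (fixed
  number formats, no wall-clock fields — the run manifest records the
  command, package version, input digests and flags instead).

## The synthetic benchmark

`simulate_benchmark()` generates the complete study fixture: 12 Rab
subfamilies (one random ancestor each, members evolved at 85–95% identity to
their ancestor), four non-Rab classes, 120 queries evolved from reference
members inside a 0.55–0.85 identity band with motifs preserved, and 80 decoys
split between stage-3 decoys (Rab-derived scaffolds whose motif windows are
randomized and audited to scan motif-free) and stage-2 decoys (evolved from
non-Rab members). All sequences share a G-domain-like core so the pooled
profile filter is meaningful; ancestors are rejection-sampled below 40%
cross-subfamily identity; motifs are implanted as noisy consensus instances.
Evolution is by substitution-matrix-conditioned point mutation, steered until
the realized aligned-column identity is within ±0.03 of target.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: indel evolution and domain rearrangements, realistic
amino-acid composition (background is uniform), phylogenetic correlation
among subfamilies, fragmentary gene models, and the real ratio of Rabs to
the rest of a proteome. The synthetic subfamilies are well separated by
construction, so benchmark accuracies are upper bounds; the published
validation on real, adversarially chosen proteomes is the reference point for
real-world performance, not these fixtures.

Problem sizes used by the test suite and the acceptance script: the full
fixture above (200 query sequences against a 108-entry reference set) for the
end-to-end properties, a 4×3 fixture for unit tests, 100–300 random cases for
each oracle comparison.

## Known limitations

* The G-domain filter is a pooled full-length profile, not a true
  profile-HMM of the fold; very divergent genuine GTPases could in principle
  fall below a calibration set by a narrow reference collection. Enriching the
  reference set is the remedy, as in the original curation loop.
* The confidence fusion is a reconstruction (above); absolute confidence
  values are comparable within this implementation only.
* Subfamily evidence uses the best hit per subfamily, not summed evidence —
  a documented choice where the original is ambiguous.
* Whether the original 40% gate used local-alignment or full-length identity
  is unstated; local-alignment identity is used here and recorded as an
  assumption.
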