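---
title: "OrthoCover: model, parameters and design decisions"
author: "OrthoCover authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoCover: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoCover)
```

## The problem and the model

Given per-species protein catalogs (predicted ORFs from genomes or MAGs)
and a user-defined set of reactions of interest, OrthoCover answers two
questions: *which species can carry each reaction*, and *which combinations
of species jointly carry a whole pathway*. The model has three layers.

**Gene-protein-reaction (GPR) rules.** A reaction is available to a species
when the species encodes a sufficient gene set. Sufficiency is expressed as
a monotone boolean formula over KEGG Orthology (KO) identifiers: `AND` for
subunits of one complex, `OR` for isoenzymes or alternative complexes.
Because rules contain no negation, possession of extra KOs can never revoke
a capability, and every rule is false on the empty KO set. The species ×
reaction capability table is defined cell-wise as the rule value on the
species' annotated KO repertoire; `reactionCapabilities()` materializes it
with lexicographic row/column order so downstream outputs are reproducible.
A reaction lacking an explicit rule defaults to `OR` over its KO set — the
single-protein case — and the default is flagged in the database's load
report rather than silently applied.

**Two-stage annotation.** Annotating every sequence against every reference
is wasteful when only a small pathway-focused database is of interest, and
orthogroups let cluster members share evidence. The *relaxed* stage aligns
a uniform random sample (default half, at least one sequence) of each
cluster against all reference sequences; a KO whose references are hit at
E ≤ `relaxedEvalue` becomes a *candidate* for that cluster, and clusters
with no candidates are dropped (with the reason recorded in the annotation
report). The *restrictive* stage aligns **all** sequences of each surviving
cluster against the full reference sets of its candidate KOs and confirms
annotation of sequence *s* with KO *k* only when the best hit satisfies
E ≤ `restrictiveEvalue` **and** bit score strictly greater than
`minBitScore`. A sequence may carry several KOs (shared domains across
isoenzymes are real); there is no best-KO-only collapse.

**Pathway set-cover.** With the capability table in hand, a pathway is an
ordered set of reactions and a *combination* is a set of ≥ 2 species whose
united rows cover at least a fraction `completenessFraction` of them.
Species that cover the pathway alone ("complete" species) are always
reported separately; a flag controls whether they may also appear inside
combinations, because both readings of "excluded when calculating
interactions, but also included for comparison" are useful. Constraints
restrict the search space: each *single-species subset* is a reaction group
that one member must carry entirely (modeling non-exchanged intermediates);
transporter requirements demand transporter-associated reactions in at
least one or in every member; a size cap bounds combinations. Enumeration
is depth-first over species in lexicographic order, abandoning a branch
when even the union of the current set with all remaining species cannot
reach the coverage target (coverage is monotone in set inclusion, so
failure of the maximal extension kills the whole branch). All covering
subsets are emitted, not only minimal ones — community data report
non-minimal consortia — with `minimalOnly` available when the minimal
covers are wanted. Output order is by size then lexicographic members,
making result files byte-stable.

## Alignment and its statistics

The built-in aligner is Smith–Waterman with affine gaps (Gotoh's
algorithm, implemented in C++), default BLOSUM62 with gap open 11 / extend
1; a gap of length *L* costs `gapOpen + gapExt * L`. The unknown residue
`X` scores 0 against everything, a neutral choice that neither rewards nor
punishes masked positions. Raw scores are normalized to bit scores with the
Karlin–Altschul parameters λ = 0.267, K = 0.041 (the standard values for
this matrix/gap setting): *S′ = (λS − ln K)/ln 2*, and E-values are
*E = m·n·2^(−S′)* with *m* the query length and *n* the total residue
count of the reference set. Two deliberate simplifications, both
documented divergences from BLAST: no effective-length (edge) correction,
and one hit per query–subject pair (the single maximal-scoring local
alignment, no HSP tiling). The pipeline's decisions are threshold
comparisons, which these simplifications preserve. The restrictive stage
keeps the relaxed stage's search-space size (the whole database) so both
stages share one E-value scale; restricting which alignments are computed
does not change the statistical reference. Traceback ties prefer diagonal
over a gap in the subject over a gap in the query, fixing percent identity
and alignment length deterministically; E-value thresholds are inclusive
(≤) while the bit-score floor is strict (>), so a best hit at exactly the
floor is rejected. Pre-computed hits in the 12-column BLAST tabular dialect
can replace the internal aligner wholesale.

## Clustering and its evaluation

The built-in clusterer connects two sequences when their local alignments
in both directions reach `minBit` bits (default 50) and takes connected
components of size ≥ 2 as clusters; singletons are reported unassigned.
This is intentionally the simplest defensible orthogrouping — no score
normalization by length, no MCL — because production use is expected to
import OrthoFinder tables; the internal engine exists so the whole pipeline
is testable without external binaries, and its component structure is
order-invariant (cluster ids are assigned by smallest member id).

Clustering quality uses pair semantics: precision is the fraction of
co-clustered unordered pairs that share a function label; recall is the
fraction of same-label pairs that are co-clustered. Unassigned sequences
participate in no co-clustered pair (so they cannot hurt precision) but
their same-label pairs still count in recall's denominator — failing to
cluster a true pair is a recall miss. Zero denominators raise errors
instead of returning 0: an all-singleton clustering has *undefined*
precision, and silently reporting 0 would be misleading.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `relaxedEvalue` | 0.001 | expected chance hits | permissive pre-filter: capture candidates while skipping most alignments |
| `restrictiveEvalue` | 1e-9 | expected chance hits | confirmation threshold; stricter cutoffs mainly shrink the cluster flow without changing annotations |
| `minBitScore` | 50 (strict >) | bits | floor below which short/spurious local matches pass E-value filters on small databases |
| `sampleFraction` | 0.5 | fraction of cluster | relaxed-stage sample; ceiling with a floor of one so singleton clusters are represented |
| `seed` | 42 | — | sampling stream; combined per cluster with a hash of the cluster id so cluster order is irrelevant |
| `minBit` (clusterer) | 50 | bits | reciprocal-edge threshold of the internal clusterer |
| `completenessFraction` | 1.0 | fraction of pathway | full cover by default; lower values model partial-pathway questions |
| `transporterMode` | off | — | transporter semantics differ across datasets; off unless the user states them |

Sampling rounds up (`ceiling(fraction × size)`, minimum 1): a one-sequence
cluster must still be able to enter the relaxed stage.

## The synthetic-data generators

Fixtures are generated, never stored. `generateFamily()` draws a random
ancestor (background amino-acid composition) and derives members at an
exact Hamming distance `round(divergence × length)` — divergence is a
controlled substitution fraction, not an evolutionary model.
`generateOradbFixture()` builds databases whose reactions have
reaction-private KO sets, so each capability depends only on its own
families. `generateCommunity()` realizes a planted species × reaction
table: one satisfying KO branch chosen per reaction (shared across
species, so a reaction carried by *k* species yields a *k*-member family
rather than cross-species singletons), one diverged member per needed
family per species, plus decoy proteins resampled until aligned identity
to every family ancestor stays below 30%. The realized table is re-derived
from the planted KO sets and validated against the input — an inconsistent
planting is an error, not a silent fixup.

The mutation simulator follows the in-silico protocol for point mutations:
substitutions only, `max(1, round(rate × length))` bases drawn without
replacement from interior codons (first and last codon never touched), each
base replaced by one of the three alternatives. Translation enumerates
in-frame candidate proteins — from the first codon to the first stop, and
from every in-frame ATG to the next stop — and keeps the longest (earliest
start on ties). Only the original frame is considered, since substitutions
cannot shift frames. A consequence worth knowing: at high rates an early
stop can leave the longest ATG-initiated product short, so an occasional
variant can legitimately fall below the clustering floor; the fixed-seed
mutation-grid check in the test suite uses genes of ~400 residues, the
scale of the dehydrogenase/reductase-subunit genes this kind of mutation
study targets.

What the generators do *not* emulate about real data: gene length and
composition heterogeneity, domain architecture (decoys are compositionally
random, not reshuffled domains), paralogy and gene families within one
genome, indels, and any phylogenetic structure among species. Passing the
planted-recovery tests therefore demonstrates the machinery is correct and
the thresholds coherent — not that real-genome annotation accuracy equals
the fixtures' 100%.

## Numerical and degenerate-input choices

Scores are integers; bit scores and E-values are double precision with
inclusive comparisons, and coverage fractions are compared with a 1e-12
slack to absorb float division. An empty local alignment (raw score 0) has
identity 0 over length 0. Empty sequences, unknown residues (with
position), duplicate sequence ids, headerless hit files with wrong column
counts, pathways referencing unknown reactions, and unmapped annotated
sequences are all hard errors naming the offending item. Enumeration
refuses more than 30 species (the subset space outgrows the method; the
error advises tightening constraints). The species-KO table uses set
semantics; all CSV/TSV outputs are written sorted.

## Scale of the validation runs

The test suite and the acceptance script run entirely on generated data:
100 random enumeration instances of up to 12 species × 8 reactions checked
against full 2ⁿ subset scans; a 3-cluster/4-KO annotation fixture checked
against brute-force all-vs-all filtering; a 6-species / 8-reaction /
14-KO community at 8% divergence recovered exactly end to end; and an
18-variant mutation grid over rates 0.01–0.25. These sizes keep each
property check exhaustive where exhaustiveness is the point (subset scans,
truth tables over ≤ 6 KOs, all partitions of ≤ 6 labelled elements) while
the whole validation completes in minutes on one core.

## Known limitations

No HMM/profile methods, no translated searches, no composition-based score
adjustment; annotation transfers by pairwise similarity alone. The internal
clusterer is single-linkage and will chain through promiscuous sequences
where MCL-based tools would split. E-values are comparable within this
package but not numerically identical to BLAST's. Interaction predictions
are genomic-potential statements — they say a consortium *could* cover a
pathway, not that it will express, exchange intermediates, or grow; no
flux or thermodynamic modeling is attempted.
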