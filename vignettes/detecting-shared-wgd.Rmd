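---
title: "Detecting a shared ancient whole-genome duplication from macrosynteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a shared ancient whole-genome duplication from macrosynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the three lines of evidence

An ancient whole-genome duplication (WGD) shared by a clade leaves three
genome-scale signatures that survive hundreds of millions of years of
turnover:

1. **A discrete peak in the paralog Ks distribution.** All duplicate pairs
   created by one WGD are the same age, so their synonymous distances pile up
   at one value; small-scale duplications arise continuously and smear across
   the range. A duplicated genome therefore shows two peaks (an L-shaped or
   broad young-duplicate component plus the WGD spike) where an unduplicated
   relative shows one.
2. **2:1 macrosynteny against ancestral chromosomes.** If an unduplicated
   outgroup retains the ancestral karyotype, each ancestral chromosome (AC)
   should correspond to two chromosome segments in every descendant of the
   WGD, and one in lineages that never duplicated.
3. **Duplicate gene-tree topology.** For genes with both WGD copies retained
   in two species X and Y, the unrooted quartet {X1, X2, Y1, Y2} resolves as
   (X1,Y1)|(X2,Y2) when the duplication predates the speciation (the copies
   group by subgenome) and as (X1,X2)|(Y1,Y2) when each lineage duplicated
   independently.

`paleoploid` implements all three readouts behind one pipeline and ships a
forward simulator of chromosome-scale genome evolution so the whole chain is
testable, deterministically, without external data.

## Homology: reciprocal best hits

All homology decisions are score-based best hits over a BLAST-tabular-style
hit table, with an e-value ceiling of 1e-3 (the conventional threshold for
this kind of screen; configurable via `evalue_max`). Ties on score break by
lower e-value, then lexicographically smallest subject id — the choice is
arbitrary but makes every result invariant to row order. Self-hits are
removed before any best-hit computation. Within-species paralog pairs are
reciprocal best hits (RBH) of a species against itself, canonicalized to
lexicographic order.

## Ks estimation and the same-chromosome exclusion

Synonymous distance is estimated by Nei–Gojobori (1986) counting with the
Jukes–Cantor correction `d = -(3/4) ln(1 - (4/3) p)`. Published NG86
variants differ in small conventions, so ours are explicit:

* every codon position contributes exactly one site, split between
  synonymous and nonsynonymous in proportion to the non-stop single-step
  mutations at that position (hence S + N = 3 × compared codons);
* codons differing at several positions are averaged over all minimal
  mutation pathways, excluding pathways through stop codons (if all are
  blocked, all pathways are used with the stop as an ordinary state);
* codon pairs containing ambiguity characters or stops are skipped pairwise;
* when p ≥ 3/4 the correction is undefined: `ks` is `NA` and the raw
  proportion is kept.

The estimator is deliberately substitutable: any Ks source can be supplied
as a precomputed pair table, and the simulator emits one directly.

Before peak counting, paralog pairs on the **same chromosome are excluded**.
Tandem duplicates — the bulk of small-scale duplication — sit beside their
parent and would dominate the low-Ks range, while WGD pairs start out on
distinct chromosome copies, so the filter enriches exactly the signal of
interest.

## Counting Ks peaks

`fit_ks_modes()` fits Gaussian mixtures with 1..`k_max` (default 4)
components to ln(Ks) by EM (10 seeded restarts per k; quantile-based
initialisation, which makes the selected component count invariant to
rescaling all Ks by a constant) and selects k by minimal BIC. Components
lighter than `weight_floor` (default 0.05) are merged into their nearest
neighbour: a peak carrying under 5% of pairs is not a "prominent" peak.
Numerical guards: component standard deviations are floored at 0.05 on the
log scale (well below any realistic Ks noise; prevents spike-collapse), and
the analysis window is Ks in [0.05, 5] — below 0.05 Ks is dominated by
alleles and assembly artifacts in real data, above ~5 the Jukes–Cantor
correction is saturated and unreliable. At least 50 usable values are
required; fewer is reported as an error rather than a meaningless fit.

## Calibrating ancestral chromosomes and cutting segments

The AC coordinate system is supplied as a proxy map: outgroup genes labelled
with the AC they represent. Each proxy gene probes the ingroup genome with a
**unidirectional best hit**; an ingroup gene claimed by probes of several
ACs takes the AC of the highest-scoring probe. Because the outgroup is
unduplicated while the ingroup is (putatively) doubled, each probe can mark
only one of the two copies — so both copy chromosomes end up about half
labelled, which is why segment calling must tolerate unlabeled interlopers.

A segment is a maximal run of genes with one AC label, tolerating up to
`max_gap` consecutive interlopers, keeping runs with at least `min_run`
assigned genes. The defaults `min_run = 3`, `max_gap = 2` operationalize
"several genes in succession": three assigned genes is the smallest count
that is not a coincidence under random labelling, and two interlopers match
the expected gap structure at ~50% label density. Both are configurable and
the calling rule is tested against an independently coded scan oracle on
enumerated label strings. Where candidate runs of different ACs overlap
(possible only with `max_gap > 0`), runs with more assigned genes win;
segments on a chromosome therefore never overlap and no gene is in two
segments. Coordinates are gene-ordinal, 0-based, half-open throughout:
synteny at this scale is an ordering statement, not a base-pair one.

Segments of one AC form a cluster; `reassemble_chromosomes()` concatenates
each cluster's segments in a seeded random order into one AC-coordinate
chromosome. The random order is deliberate: nothing downstream may depend on
intra-cluster order, and the tests permute it. `dotplot_table()` emits the
Oxford-grid table (reorganized position versus proxy position within the AC)
used to validate the reconstruction visually.

## Selecting two-copy homolog sets and calling topologies

For each species and each AC cluster, every segment is searched for RBH
partners of the AC's proxy genes — per segment, so that at most one homolog
per proxy per segment is found and within-segment tandem duplicates cannot
interfere. An ancestral gene is accepted for a species when its homologs
fall on **exactly two segments** (both kept); on more than two, the homologs
from the **two longest segments** are kept (ties: earlier chromosome id,
then smaller start — determinism again); on fewer than two it is rejected.
Only ancestral genes accepted in every ingroup species enter the analysis.

Per AC, a distance matrix over taxa species × copy is the mean pairwise
distance across that AC's homolog sets. Copy indices are species-local and
follow segment identity: within a species' cluster, chromosomes are ranked
by the total assigned length they carry, segments within chromosomes by
length; in each homolog set the homolog on the lower-ranked segment is copy
1. Before rearrangement this makes copy 1 one subgenome and copy 2 the
other; after a fission it remains consistent because both fragments of a
broken copy still rank behind the intact partner chromosome. Copy indices
are *not* harmonized across species — the quartet test does not need them to
be, since both cross-species pairings read as "shared". Taxon pairs with no
observed distance are imputed with the mean observed entry, with a warning.

Trees are neighbor-joining (`ape::nj`, negative branches clamped to zero).
The published analysis this design follows used maximum-likelihood trees on
concatenated alignments; NJ on mean Ks distances is the desk-scale
substitute, and since the classification consumes topology only, any
correct tree method can be swapped in behind `nj_tree()`'s contract.

Classification enumerates every unordered species pair, restricts the tree
to the four copies, and reads the induced quartet: cross-species cherries
vote "shared", within-species cherries "independent", stars and zero-length
internal edges "ambiguous". The per-AC label is the majority of shared
versus independent votes; ambiguous votes are evidence for neither side and
ties are ambiguous. The overall verdict is positive when the shared fraction
of per-AC calls exceeds 0.5 **and** the ingroup Ks distributions show at
least 2 peaks (modal count across ingroup species, ties resolved
downwards). ACs with fewer than `min_sets_per_ac = 3` homolog sets are not
called — the analogue of the minimum-alignment-length requirement a
sequence-based analysis would impose.

## The simulated world

The generator evolves an ancestral karyotype (default 10 chromosomes × 100
genes) along a species tree, by default
`((A:0.8,(B:0.5,C:0.5):0.3):0.6,OUT:1.4)` with a WGD halfway along the
ingroup stem. Divergence is `2 × ks_rate × time`; observed Ks adds
lognormal noise (log-sd 0.25). The stated scenario has retention 0.4,
background duplication rate 0.1 per gene per unit time, loss rate 0.02,
fission/fusion rates 0.3/0.2 per genome per unit time. Defaults chosen where
no value was stated:

* `ks_rate = 0.4`, putting the WGD peak at Ks = 0.88 and root-level
  orthologs at 1.12. The similarity-score model (`score = 200 e^{-Ks}`,
  `e-value = 10^{-score/10}`) maps distances above ~1.9 over the 1e-3
  e-value threshold; real BLASTP hits between genomes at these distances
  pass that threshold comfortably, so the divergence scale is set to keep
  ortholog hits well inside it.
* `dup_dispersed_frac = 0.5`: half of small-scale duplications insert at a
  random genomic position rather than in tandem. Dispersed (e.g.
  retro-)duplication is common in real genomes, and it is what leaves the
  broad inter-chromosomal background component that the same-chromosome
  filter cannot remove — the component that makes the unduplicated outgroup
  unimodal rather than empty.
* hit scores are computed from the *noisy* Ks, not the true divergence:
  with exact scores, every probe's hits to the two WGD copies would tie and
  deterministic tie-breaking would label only one subgenome, which no real
  aligner does.

Fractionation is instantaneous: each WGD duplicate pair survives with
probability `retention` at the event itself, so two-copy families are
Binomial(n, retention) and shared across descendants. Real fractionation is
gradual and lineage-specific; the simplification preserves everything the
pipeline consumes (copy numbers, divergences, placements) at the cost of
underdispersing retention differences between species. Other deliberate
omissions: no selection or rate variation across branches, no sequence
alignment or alignment error (hits are generated from divergence directly),
no sex chromosomes, no gene order noise beyond the modelled events. Optional
codon sequences evolve under a crude two-rate scheme (third positions at the
synonymous rate, others at 20% of it, stop codons rejected) — enough to
exercise the NG86 code path end to end, but not a codon model; green
sequence-mode tests establish plumbing, not estimator realism.

All randomness flows from one integer seed; every stage derives a substream
from the seed and its stage name, so identical (config, seed) gives
byte-identical output files and re-running one stage from its predecessor's
files reproduces the in-pipeline result exactly.

## What a green test establishes, and what it does not

The simulator realizes the *assumed* generating model of the method: clean
orthology within families, no cross-family similarity, an outgroup that
genuinely retains the ancestral karyotype. Passing tests demonstrate that
the pipeline recovers a shared WGD under its own assumptions and rejects one
under independent duplications — they do not demonstrate robustness to
assembly error, annotation noise, cross-family homology, outgroup
rearrangement, or strongly biased fractionation, none of which the
generator emulates.

## Small contract decisions

* A single homolog set is accepted by `build_distance_matrix()` (its matrix
  is that set's pairwise distances); the error is reserved for zero sets or
  fewer than two species, where no tree is possible.
* Pipeline configs are JSON; the environment provides no YAML parser for R,
  and the config is a flat structured-text file either way.
* The CLI (`inst/cli/wgdpipe.R`) is a thin dispatcher over `run_stage()`;
  the package functions are the real interface.
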