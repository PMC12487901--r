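---
title: "Methods behind viroscape: host typing, confidence triage and TA-pattern mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind viroscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroscape)
```

viroscape implements the analysis layer downstream of a viral protein
structure catalogue: clustering files, structure-search hit tables,
predicted models and genomic-context tables come in; host-type labels,
confidence tiers, oligomeric-state calls, filtered defense/antidefense
hits and toxin–antitoxin (TA) pattern candidates come out. This vignette
explains each model and the choices behind the tunable parameters.

## Host typing and the minority-count rule

Each protein inherits host domains from its source virus through a
virus→host mapping table (one lineage string per recorded host,
superkingdom first). Three situations yield *host undefined*: the taxid
is missing or absent from the mapping, the recorded host is itself a
virus (virophages and phage satellites would otherwise create spurious
cross-domain links), or a curation override forces it. Overrides are
matched on the exact virus lineage name, case-insensitively, because
curation lists name lineages rather than taxids.

A cluster of `N` members (undefined-host members included in `N`) is
labelled from its per-domain member counts. The qualification threshold

\[ T = \max(3,\; \lceil 0.01\,N \rceil) \]

is a whole-protein count — proteins are discrete, so the 1% term is
rounded up. The modal defined domain always qualifies; every other
defined domain qualifies only with at least `T` members. Two or more
qualifying domains give a **heterohost** label, exactly one a
**monohost** label, none (no defined-host member at all) *host
undefined*. Two consequences worth knowing:

* a modal tie (two domains with equal maximal counts) makes both qualify,
  deterministically yielding a heterohost label;
* a protein whose virus has recorded hosts in several domains counts once
  toward each domain. The upstream mapping can legitimately list multiple
  hosts and collapsing them to a "primary" host would discard evidence;
  `species_support`-style double counting is bounded by the small number
  of multi-host viruses.

The rule is deliberately conservative: below `N = 300` the 1% term never
exceeds 3, so a heterohost label always needs at least three
independently annotated minority proteins.

## Comparing sequence- and structure-level clusterings

Cluster-to-cluster relationships are counted as *unordered pairs of
distinct clusters* linked by at least one hit; hits are undirected for
this purpose, and self- or within-cluster hits carry no information. No
score threshold is applied while counting — thresholds belong to the hit
generation or to the filtering module, keeping the counting pure. The
relationship gain is the ratio of structure-level to sequence-level pair
counts on the same cluster universe; an empty sequence-level set is
reported as infinite with an explicit flag rather than an error, since it
is a legitimate outcome on small inputs.

Transition tables cross-tabulate, per protein, the host type of its
sequence cluster against that of its structure cluster. Proteins present
at only one level are kept in an `"unpaired"` margin (with a warning)
so that margins always conserve protein counts.

## Model confidence

Predicted models store per-residue pLDDT (0–100) in the B-factor column;
means are taken over Cα atoms so that each residue contributes once, with
an all-atom fallback for files without Cα records. Homodimer confidence
tiers follow ipTM with inclusive boundaries — *confident* at ipTM ≥ 0.5,
*good* at ≥ 0.8 — since stated cutoffs are conventionally attained;
boundary behaviour is configurable. The dimer-over-monomer gain is the
maximum of the two dimer chain means minus the monomer mean, flagged when
strictly above 5 units; the maximum makes the gain invariant to chain
order. For matched-pair database comparisons the inputs are assumed
matched upstream (near-identical proteins, >90% identity and coverage);
the module reports the fraction of pairs scoring higher and the fraction
scoring more than 5 units higher, the latter never exceeding the former
when differences are positive.

## Oligomeric-state inference

PDB chains carry two assembly counts: copies of the chain in its
biological assembly and distinct chain types in that assembly. These
induce the state vocabulary: `monomer` (1, 1), `homodimer`…`homooctamer`
then `homoN-mer` (k, 1), and `hetero-N-mer` (·, N > 1). Hits below
TM-score 0.5 — the conventional same-fold boundary — are discarded; the
remaining hits vote for their chain's state with weight equal to their
TM-score, and the heaviest state wins. Ties are broken by supporting hit
count and then lexicographically, keeping calls deterministic. Weighted
voting is scale-invariant (multiplying all TM-scores by a constant never
changes the argmax) and raising the threshold can only remove states from
the vote. In cluster mode the hits of all cluster members are pooled
before voting, matching the practice of assigning one state per cluster.
Homo- and hetero-oligomer flags are independent unions over hits: a query
can legitimately show both kinds of evidence.

## Defense/antidefense hit filtering

Best-hit selection maximizes identity × query coverage per query (ties:
higher TM, then smaller target id). The two bundled policies apply strict
inequalities throughout, because stated bounds use strict comparison
symbols:

| bound | defense library | antidefense (merged) |
|---|---|---|
| TM-score | > 0.65 | > 0.65 |
| E-value | < 1e-3 | < 1e-3, antidefense-library hits only |
| avg. coverage | > 0.6 | > 0.5 |
| cluster mean TM | > 0.5 | > 0.5 |
| cluster mean aln. length | — | > 100 |

*Average alignment coverage* is `(qcov + tcov) / 2` — the two coverages
are what search tools emit, and their mean is the plain reading of the
phrase. The per-source E-value exemption exists because one antidefense
source provides models without meaningful E-values. Cluster-level bounds
average over **all** hits from members of the query's structural cluster
to the same target; these statistics should be computed once, on the
exhaustive search output (`cluster_hit_stats()`), and passed to
`apply_policy()` — then filtering is idempotent and tightening any bound
can only shrink the surviving set. Recomputing cluster statistics from an
already-filtered table would silently change the criteria.

## TA-pattern mining

Screening starts from dark communities (median functional brightness
below 5%, at least five members) and only considers context sets whose
target protein occurs in at least six species — conservation across a
handful of near-identical genomes is not evidence.

Candidate patterns are contiguous runs of 2–4 gene families, in fixed
order, containing a target gene's family. Contiguity follows from the
order criterion plus the spacing limit: intergenic distances inside a
pattern may not exceed 100 nt (computed as
`start(next) − end(prev) − 1` on 1-based inclusive coordinates), which is
the operonic spacing regime. Pattern genes must share a strand by default
(TA systems are co-transcribed); the requirement is configurable off.

Two measures are kept deliberately distinct:

* **Occurrence frequency** (`freq`) — the fraction of contexts containing
  a valid occurrence (order, gaps, strand). This is the support measure
  and it is *anti-monotone by construction*: any occurrence of an
  extended pattern contains an occurrence of the shorter one, so
  `freq(P) ≥ freq(P + one gene)` always. The candidate score is
  `freq(P) − max(freq over one-gene left/right extensions)`: a true
  bicistron is frequent as-is while no longer variant recurs.
* **Clean-flank support** — a context supports a candidate only if some
  valid occurrence additionally has every *conserved* family outside the
  pattern (present in ≥ 50% of contexts, inclusive) more than 100 nt
  away. This operationalizes the requirement that neighborhood
  conservation be restricted to the pattern itself, and defines the
  supporting contexts and species counts that gate candidacy.

Folding the flank conditions into `freq` itself would be self-defeating:
a conserved gene 50 nt downstream of a pair would make the triple more
frequent than the pair, breaking anti-monotonicity and with it the
apriori-style reasoning the score relies on. With the split, that
situation resolves correctly — the pair loses all clean-flank support and
is dropped, while the triple becomes the ranked candidate.

The denominator of `freq` is contexts, not species (species are exposed
separately as `species_support`); ranking is global across the context
set (score, then frequency, then shorter length, then label order),
keeping the output deterministic and invariant to context input order.

## Synthetic data: what it emulates, and what not

The generators produce every input table with planted truth, under one
master seed with independent per-table substreams — changing one
generator's parameters never perturbs another's draws, and identical
configurations yield byte-identical tables.

* **Cluster tables** follow the observed domain shares of viral protein
  hosts (79.9% bacteria, 15.4% eukaryota, 1.1% archaea, remainder
  undefined). Injected minority domains are sized exactly at the
  threshold `T` or one below it, so both sides of the minority rule are
  exercised. Undefined hosts are realized both as unmapped taxids and as
  virus-infecting lineages.
* **Oligo hit tables** give true-state hits TM ≈ 0.78 and decoys ≈ 0.58
  (Gaussian noise, default sd 0.05, clamped to valid ranges) plus
  sub-threshold noise at ≈ 0.3 — separation large enough that the
  weighted vote recovers essentially all planted states, with ≥ 95%
  asserted to absorb sampling noise.
* **Neighborhoods** plant the bicistron on the plus strand with internal
  gaps in [0, 100] nt, flanked by per-context decoy families (drawn from
  a 30-family pool, hence never conserved) at gaps in [101, 400] nt, 20
  contexts over 8 species. `assert_recoverable = TRUE` errors on gap
  ranges inconsistent with recovery; leave it off to generate the
  adversarial variants (oversized gaps, too few species).

What passing on these inputs does **not** show: real catalogues have
correlated misannotations (a mislabelled virus contributes many proteins,
not one), paralogous expansions inside contexts, unevenly sampled
species, and hit scores whose noise is anything but Gaussian. The
synthetic results validate the *rules*, not the biological effect sizes;
headline fractions from real catalogues (e.g. the jump of heterohost
protein fractions from sequence- to structure-level clustering) require
the full upstream runs, which this package deliberately consumes as
files.

## Problem sizes and numerical choices

The shipped tests run the miner's brute-force cross-check on instances of
up to 8 genes × 12 contexts (100 random instances), the voting
cross-check on 1000 random hit tables, the exhaustive host-rule sweep on
all ~46k composition vectors with ≤ 30 members, and 100 seeded
planted-operon runs; the full suite completes in under two minutes on a
single core. Ties are broken deterministically everywhere (documented per
function); thresholds follow the strictness of their sources (strict for
the filter policies and the 5-unit gain, inclusive for ipTM tiers and the
50% conservation boundary); degenerate inputs (empty clusters, zero-hit
queries, empty pair sets) return typed empty results or flagged values
rather than NA surprises.
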