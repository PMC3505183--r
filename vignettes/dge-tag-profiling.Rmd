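---
title: "Digital gene expression tag profiling with dgetag: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital gene expression tag profiling with dgetag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Digital gene expression (DGE) tag profiling counts short cDNA tags instead of
sequencing whole transcripts. In the NlaIII chemistry emulated here, each
transcript contributes a *tag*: the 21-mer starting at the 3'-most `CATG`
restriction site that has at least 17 bases downstream of the anchor
(`CATG` + 17 = 21 bases). Because tag counts are absolute molecule counts,
two libraries can be compared with an exact count-based test rather than a
variance-modelling framework.

`dgetag` implements the full analysis path for such libraries:

1. **Cleaning** (`extract_clean_tags()`): raw tag tables are filtered by
   removing adaptor-prefixed tags, empty tags, tags flagged low quality,
   malformed tags (length ≠ 21, missing `CATG` anchor, non-ACGT symbols) and,
   last, tags with a library-wide copy number of 1.
2. **Mapping** (`build_tag_index()`, `map_tag()`, `classify_library()`):
   every distinct clean tag is matched against all CATG-anchored windows of
   the transcript set (sense strand) and the genome (both strands), allowing
   at most one mismatch, and classified as unambiguous-gene, ambiguous-gene,
   genome-only, or unknown.
3. **Quantification** (`tpm_normalize()`): gene counts are sums of
   unambiguous tag counts, normalized to transcripts per million clean tags.
4. **Differential expression** (`ac_pvalue()`, `call_de_genes()`): the
   Audic–Claverie exact test with Benjamini–Hochberg FDR control.
5. **Quality control** (`pearson_correlation()`, `saturation_curve()`,
   `abundance_distribution()`).
6. **Enrichment** (`enrich_terms()`): 2×2 term enrichment of the DE set
   against the expressed background.
7. **Phylogenetics** (`p_distance()`, `neighbor_joining()`,
   `bootstrap_support()`, `assign_clade()`): distance trees for gene-family
   classification from prebuilt protein alignments.

## Tag cleaning and its conventions

"Too long or too short" is interpreted as any length other than 21 after
CATG anchoring: with a fixed restriction chemistry there is a single
admissible tag length. Low quality is an input flag per tag (a quality
model is out of scope at the counts level); by default no tags are flagged.
The copy-number-1 filter runs after all other filters, so an adaptor tag
with count 1 is accounted to the adaptor rule, and the filter is applied
per library. Cleaning is idempotent and order-independent, which the test
suite checks as properties.

The abundance report uses copy-number bins `[2,5] [6,10] [11,20] [21,50]
[51,100] >100`. The outer boundaries (5 and 100) are the conventional
"rare" and "abundant" cutoffs for this assay type; the interior boundaries
are a display choice.

## Mapping with one mismatch

The index stores every complete CATG window, not only canonical tags, so a
tag from an upstream NlaIII site still maps to its gene. The 1-mismatch
search enumerates the 51 single-position substitutions at positions 5–21
(positions 1–4 are the anchor shared by tag and window, so a single
mismatch cannot sit there) and resolves them against the same hash index —
a transparent, exactly equivalent alternative to a dedicated aligner for
21-mers.

Two precedence rules are fixed and documented:

* the exact tier beats the 1-mismatch tier even when the exact hit is
  ambiguous and the mismatch hit would be unique — the mismatch allowance
  is an error model, not an arbitrator between genes;
* gene hits beat genome-only hits across tiers, so a tag matching a gene at
  one mismatch and an intergenic site exactly is still counted as
  gene-mapped. Consequently "mapping to genome" in the report means
  genome-*only*.

Gene expression uses unambiguous tags only. Report percentages use the
conventional denominators (distinct clean tags; total clean tags for total
unknown; the reference gene count for tag-mapped genes) and print with one
decimal, halves rounded away from zero (`round_half_up()`); base R's
round-half-even would change printed values.

## TPM and the 0.01 floor

TPM is `count × 10^6 / total clean tags`. The denominator is total clean
tags rather than mapped tags: with a 3.76-million-tag library this makes a
single-copy gene print as 0.27 TPM, the natural detection floor of the
assay. Undetected genes are set to TPM = 0.01 so that ratios against them
are defined; the same floored values enter the log10 scatter used for
between-library Pearson correlation (computed over genes detected in at
least one of the pair). The detection threshold is one unambiguous tag,
consistent with the floor semantics.

Saturation analysis subsamples the clean tag pool without replacement on a
10-step grid using a single shared permutation, so subsamples are nested
and the detected-gene curve is non-decreasing by construction.

## The Audic–Claverie test

For a transcript with `x` tags in a library of `N1` clean tags, the
probability of seeing `y` tags in a library of `N2` is

$$p(y \mid x) = \Big(\tfrac{N_2}{N_1}\Big)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial mass with size `x + 1` and success probability
`N1/(N1+N2)`. The exponent `x + y + 1` matters: variants omitting the `+1`
do not normalize. Evaluation is in log space through `lgamma`; naive
factorials overflow long before realistic counts.

**Sidedness.** The two-sided p-value is defined as

$$p = \min\!\big(1,\; 2\min\{P(Y \ge y \mid x; N_1, N_2),\;
                       P(X \ge x \mid y; N_2, N_1)\}\big),$$

the doubled smaller of the two direction-wise tail significances, each
including the observed count. This form was chosen over doubling the
lower/upper tails of a single conditional because it is exactly symmetric
under exchanging the libraries — `ac_pvalue(x, y, N1, N2) ==
ac_pvalue(y, x, N2, N1)` — which a DE caller needs so that the arbitrary
ordering of conditions cannot change significance. At `(x=0, y=20)` with
equal depths it gives `2^-19`. Tails are computed by direct summation of
the mass with adaptive truncation (complement of the lower head when the
tail is large, so there is no catastrophic cancellation), and the result is
floored at the smallest positive double so p stays in (0, 1].

Significance requires both FDR ≤ 0.001 (Benjamini–Hochberg step-up, via
`stats::p.adjust`) and |log2 ratio| ≥ 1, with the ratio taken as library 2
over library 1 on floored TPM (put the treated/resistant condition
second). Genes undetected in both libraries are excluded: their p-value is
1 and their floored ratio 0 by construction. The test is conservative for
small counts; the suite checks that the null fraction of p ≤ α stays below
α plus sampling noise.

## Term enrichment

Each term yields the 2×2 table (DE ∩ term, DE \ term, non-DE ∩ term,
non-DE \ term) over the background of genes detected in the relevant
libraries — not the whole reference set, since never-detected genes cannot
be called DE and would dilute the margins. The p-value is a 1-df chi-square
without continuity correction unless any expected cell count
(`row·col/total`) is below 5, in which case the two-sided Fisher exact test
(point-probability method: summing all tables with the observed margins
that are no more probable than the observed one) is used; the Yates
correction is unnecessary because the exact test covers the small-count
regime. Benjamini step-up q-values are computed across terms. Terms are
flat labels; ontology structure is out of scope.

## Distance phylogenetics

`p_distance()` uses pairwise deletion: each pair of sequences is compared
over the columns where neither has a gap, and the distance is the mismatch
fraction over those columns. Ambiguity codes (B, Z, X) match only
themselves — a declared convention, since reference tools do not document
theirs. A pair with zero comparable columns is an error naming the pair.

`neighbor_joining()` is the classic agglomerative algorithm. Ties in the Q
criterion are broken by the lowest (row, column) pair, making every tree
reproducible. Additive matrices are recovered exactly (bipartitions and
path lengths), which the tests verify against randomly generated trees and
an independent implementation. Negative branch lengths are kept internally
and clamped to zero only when writing newick.

`bootstrap_support()` resamples columns with replacement, rebuilds the tree
per replicate, and scores each internal edge of the full-data tree by
bipartition identity (robust to rerooting). Replicates containing a pair
with no comparable columns are dropped; if 10% or more drop, the run
errors. Supports print as integers, optionally only above a display
threshold (the usual "> 70%" figure convention). `assign_clade()` gives
each query leaf the clade of its nearest reference by patristic distance,
leaving exact ties unassigned.

## The synthetic-data generator

The generator exists so every stage is testable with known truth and no
downloads. It emulates:

* a transcript set in which every gene carries a canonical CATG tag (one is
  inserted near the 3' end when none arises by chance), concatenated into a
  toy genome with random spacers whose own CATG windows exercise
  genome-only classifications;
* libraries of multinomially drawn canonical tags at a configurable depth
  (the default, 3.5 million, matches the scale this assay is run at), with
  three noise channels: per-base sequencing error (default 0.5%), a fixed
  adaptor sequence (0.5%), and unique random singleton tags (2%). The
  noise defaults are stated knobs, not measured values — the assay's own
  error rates are not published — chosen so that error tags are common
  enough to exercise the 1-mismatch tier and singletons the copy-number
  filter. Singletons are CATG-anchored on purpose: otherwise the format
  filter would remove them before the singleton rule ever ran;
* spiked fold changes between two conditions with randomized direction and
  renormalized profiles (so null genes absorb a small common composition
  shift, as in real libraries);
* flat gene→term annotations with an optional exactly-covered enriched
  term, and protein alignments evolved along an optional guide tree with
  per-site substitution probability proportional to branch length, plus
  i.i.d. gaps.

It does **not** simulate read-level quality strings, restriction-digest
partiality, PCR duplication bias, or alignment uncertainty. Passing tests
therefore demonstrate the correctness of the statistics and bookkeeping on
data satisfying the model's assumptions, not robustness to artifacts the
model omits.

## Problem sizes and numerical choices

The test suite runs the deep-library properties at the scale the assay is
run at — abundance-distribution shape at 3×10^6 tags over 5,000 genes,
replicate correlation at 3×10^6 tags over 2,000 genes, saturation plateau
at 3.5×10^6 tags over 12,000 genes, DE recovery at 10^6 tags over 1,020
genes — and everything else on small fixtures built in code. The bundled
demo (`demo_config()`, seed 42) simulates three libraries of 5×10^5 tags
over 400 genes with 20 spiked genes and runs the whole pipeline
deterministically: re-running the same config rewrites byte-identical
outputs, which is also a tested property.

Other fixed numerical choices: percentages print one decimal, halves away
from zero; expansion percentages round to integers; TPM prints with two
decimals; bootstrap supports print as integers; the Fisher comparison uses
the conventional `1 + 1e-7` relative slack when summing the point
probabilities.

## Known limitations

* Antisense transcript tags are not indexed (sense-strand convention);
  genome windows are indexed on both strands.
* The DE test has no biological-replicate dispersion model — it tests
  counts from one library pair, as the assay's design intends; use it for
  screening, not as a substitute for replicated designs.
* Mapping is exact-window based: no splice awareness and no indel
  tolerance.
* Enrichment treats terms as flat labels; GO DAG propagation is not
  performed.
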