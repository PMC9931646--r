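---
title: "Scoring enhancer–gene interactions and gene-level TF affinities with gabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring enhancer–gene interactions and gene-level TF affinities with gabc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabc)
```

## The model

The Activity-By-Contact principle assumes that an enhancer which is both
active and frequently in physical contact with a gene's promoter is likely
to regulate that gene. For candidate enhancer $r$ and gene $g$,

$$\mathrm{ABC}(r,g) = \frac{A_r\,C_{r,g}}{\sum_{i \in R_g} A_i\,C_{i,g}},$$

where $A_r$ is the enhancer's activity (sequencing read signal), $C_{r,g}$
the normalized chromatin contact between enhancer and TSS, and $R_g$ the
candidate enhancers within a window around the gene's TSS. The score is a
*relative contribution*: per gene it sums to 1 whenever any candidate has a
positive activity–contact product, and interactions are called above a
cutoff.

The generalized score corrects two simplifications of this gene-centric
view. First, the activity of an enhancer conceptually covers *all* of its
regulatory interactions, so a gene should only receive the share of it
that the contact profile supports:

$$A_{r,g} = A_r\,\frac{C_{r,g}}{\sum_{j \in G_r} C_{r,j}},$$

with $G_r$ the genes having a TSS within the window around $r$. This
always satisfies $A_{r,g} \le A_r$, with equality exactly when the
enhancer sees a single gene. Second, genes have several annotated TSSs,
and committing to one of them discards contact information; the gABC score
sums over all of them:

$$\mathrm{gABC}(r,g) =
  \frac{\sum_{t \in \mathrm{TSS}_g} A_{r,t}\,C_{r,t}}
       {\sum_{i \in R_g}\sum_{t \in \mathrm{TSS}_g} A_{i,t}\,C_{i,t}}.$$

Both adaptations leave the per-gene normalization intact, which is the
package's first-class invariant (tested to $10^{-9}$).

### Assumptions worth keeping in mind

* All genes are treated as regulated the same way; the score is a relative
  ranking, not an effect size.
* Contact matrices are taken as already normalized; the package never
  re-balances them.
* Scoring windows never cross chromosomes, and promoter-overlapping
  regions are scored like any other candidate — no enhancer/promoter
  dichotomy is imposed.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 5e6 | bp | total window span; a candidate's midpoint must lie within `window/2` of a TSS |
| `cutoff` | 0.02 | score | inclusive interaction-calling threshold |
| `resolution` | 5000 | bp | contact-map bin size |
| `pseudocount` | 1e-6 | contact units | added to every contact lookup; equals the inverse-distance estimate at 1 Mb |
| `tss_proximal_bp` | 2500 | bp | distance below which a region is "promoter-proximal" in affinity summarization |
| `decay_d0` | 5000 | bp | length scale of the exponential distance decay |
| TRAP `lambda` | 0.7 | energy | mismatch-energy scale |
| TRAP $\ln R_0$ | $0.584\,W - 5.66$ | — | equilibrium factor as a function of motif width $W$ |
| TRAP pseudocount | 1 | counts | PFM regularization |

The 5 Mb window, 0.02 cutoff, 5 kb resolution, 2.5 kb proximal rule and
5 kb decay constant are the field's customary operating point for this
model family; the TRAP numbers are the published defaults of the occupancy
model. The pseudocount guarantees that *every* candidate in a window
contributes to the denominators, which keeps the adapted-activity ratio
defined even where the matrix is empty; its default ties it to the
weakest contact the distance model would predict at megabase range.

## Geometry and numerical choices

* **Coordinates.** BED input is 0-based half-open; GTF is 1-based
  inclusive and converted on read ('+' transcripts contribute their start,
  '−' transcripts their end, as 0-based TSS positions). Exact duplicate
  TSSs are collapsed; distinct TSSs are kept even when they share a
  contact bin, because the all-TSS sum is defined over annotated sites,
  not bins.
* **Bin assignment.** A region is attributed to the bin of its midpoint,
  `floor(mid/resolution)`; a TSS to `floor(tss/resolution)`. Distances are
  midpoint-to-nearest-TSS.
* **Anchors.** The plain ABC score anchors its window on the 5′-most TSS;
  gABC anchors on (and sums over) all TSSs. Both are exposed through
  `use_all_tss`. In the multi-TSS denominator $\sum_j C_{r,j}$ each gene
  is represented by its TSS nearest to the enhancer — one contact per
  gene, mirroring the one-term-per-gene structure of the apportioning sum.
* **Order of operations.** The adapted activity is computed as
  $A_r \cdot (C/D)$, ratio first. Since IEEE division gives $x/x = 1$
  exactly, a locus with one gene and one TSS reduces gABC to plain ABC
  *bit for bit*, which the test suite asserts with `identical()` rather
  than a tolerance.
* **Ties and degenerate input.** Score ties at the cutoff are kept
  (inclusive $\ge$). A gene/condition whose activity–contact products are
  all zero yields scores of 0 — not NaN — plus a classed warning. Energy
  matrices resolve tied consensus counts in A<C<G<T order; non-ACGT bases
  take the worst energy at their position rather than invalidating a site.
  Background base frequencies of zero are floored at $10^{-4}$ before
  normalization to keep energies finite.
* **Batching.** With many activity columns, candidate windows, contact
  lookups, and per-enhancer contact denominators are computed once and
  reused; the per-condition results are bitwise identical to independent
  single-condition runs, which is tested. Gene-level parallelism
  (`n_workers`) chunks genes but always apportions activity against the
  full gene universe, so worker count cannot change any number.

## TF affinity summarization

Per region, TRAP converts a PFM into position-specific mismatch energies
$E(p,b) = \tfrac{1}{\lambda}\ln\!\big(\tfrac{c_{max}}{c_b}\cdot
\tfrac{bg_b}{bg_{b^\*}}\big)$ (consensus base at zero, clamped at zero,
counts regularized by the pseudocount) and sums the occupancy
$R_0 e^{-E}/(1+R_0 e^{-E})$ over every site on both strands — low
affinities are retained rather than thresholded. Gene-level summaries are
$\mathit{af}_{g,tf} = \sum_r \tfrac{\mathit{af}_{r,tf}}{ml_{tf}} m_r$ with
the multiplier $m_r$ depending on how regions were assigned:

* **window**: $A_r e^{-d_{r,g}/d_0}$ for every region in the window;
* **gabc**: proximal regions ($d \le 2500$ bp) keep the decay multiplier
  (their measured "contact" would largely be the bin's self-contact);
  distal regions use the adapted activity $A_{r,g}$;
* **abc**: distal regions use $A_r\,C_{r,g}/C_{max}$, scaling by the
  maximum contact over all region–gene pairs of the run so both
  multipliers live in $[0,1]$. $C_{max}$ is taken genome-wide per run; a
  per-chromosome variant would only rescale chromosomes relative to each
  other, and the genome-wide choice keeps multipliers comparable across
  the whole output.

In abc/gabc mode, the assigned regions are the called interactions of the
gene plus all proximal regions regardless of score, deduplicated. Three
auxiliary features accompany the affinities: region count, mean TSS
distance and mean region length.

## What the synthetic data emulates — and what it does not

`make_toy_locus()` plants the structure the model family cares about:
multi-TSS genes, enhancers shared between genes, an inverse-distance
contact decay ($\mathrm{round}(K/\max(d,\mathrm{res}))$, $K=5\times10^5$,
i.e. a contact of 100 one bin away), a strong planted loop (+250) joining
one enhancer to a distant gene, gamma-distributed activities (shape 2,
rate 0.2), and a consensus motif (TGACGTCA) planted in alternate
enhancers. Every file it writes is byte-identical per seed, and all decay
contacts exceed the default pseudocount so degenerate-denominator paths
only appear when requested.

What it deliberately does **not** emulate: Hi-C statistical noise and
distance-dependent variance, matrix-balancing artefacts, single-cell
sparsity and dropout, realistic motif redundancy, or genome-scale extent.
Passing tests therefore demonstrate the *equations and contracts* are
implemented correctly — oracle equivalence, normalization, invariances —
not that the model's biological accuracy on real screens is reproduced;
benchmarking on real CRISPRi/eQTL data is an application of the
`evaluation` functions to user-supplied tables, not something the test
suite claims.

`make_labeled_benchmark()` draws positives with probability increasing in
the true gABC score (exponential weighting of the standardized score); at
signal 0 the labels are independent of the scores, which pins the expected
AUC at 0.5 and gives the evaluation suite a proper null.

## Problem sizes and tolerances used by the tests

The oracle-equivalence suite runs 100 seeded loci of up to 10 enhancers,
4 genes and 3 TSSs per gene against a literal loop-based transliteration
of the scoring equations, at $10^{-12}$ relative error; normalization is
checked at $10^{-9}$; TRAP and summarization oracles at $10^{-12}$; the
null AUC is averaged over 200 label redraws. These sizes keep the full
suite under half a minute while exercising every code path (multi-TSS,
multi-gene windows, ties, degenerate columns).

## Known limitations

* Inter-chromosomal contacts are ignored by design; windows never span
  chromosomes.
* One contact map covers one chromosome; multi-chromosome runs with
  measured contacts require the inverse-distance model or per-chromosome
  maps supplied through the API.
* The affinity model assumes additive TF contributions and inherits motif
  redundancy from the supplied PFM collection.
* RPKM vs. raw counts for scoring is a user decision (`normalize` flag);
  both are supported and neither is privileged.
* The geometric-mean combination of two assays is applied after any RPKM
  normalization by default; the order is configurable by simply combining
  before loading, but normalizing first keeps the two assays on
  comparable depth-corrected scales.
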