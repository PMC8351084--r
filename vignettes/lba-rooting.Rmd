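---
title: "Diagnosing and mitigating long-branch attraction with ancestral-sequence rooting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and mitigating long-branch attraction with ancestral-sequence rooting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcaroot)
```

## The problem

Deep-split phylogenomic questions — which of a handful of anciently diverged
lineages is sister to which — are often decided by a rooted tree of five or
six OTUs built from a concatenated supermatrix of conserved genes. Two
features of such datasets conspire against the standard recipe of rooting
with a distant outgroup:

* one ingroup lineage may evolve much faster than the rest (in the
  motivating system, an epizoic lineage represented by two near-identical
  strain genomes), and
* any usable outgroup is *very* far away, so its branch is close to
  saturation.

Under these conditions the fast ingroup branch is attracted to the long
outgroup branch — **long-branch attraction (LBA)**. In the unrooted tree the
fast lineage clusters with the outgroup; rooting on the outgroup then places
the fast lineage as the basalmost ingroup branch, which looks like a real
phylogenetic result but is an artifact.

`lcaroot` implements, as reusable and tested components, a protocol for
diagnosing and mitigating this artifact:

1. **A** — full supermatrix, exhaustive ML search, outgroup rooting (the
   naive analysis, where the artifact shows up);
2. **B** — remove *singleton positions* (columns in which at least one
   sequence carries a private character state) together with the outgroup,
   and search the remaining OTUs unrooted;
3. **C** — additionally delete each strain tip in turn and re-prune the
   singletons its removal exposes, yielding 4-OTU analyses in which branch
   lengths are homogenized;
4. **D** — reconstruct the ingroup's last-common-ancestor (LCA) sequence by
   maximum-likelihood marginal ancestral reconstruction **on a star tree**,
   replace the outgroup by this sequence, and root on it (**LCA rooting**).

The star-topology intree is the crux of D: because it encodes no resolved
relationships, the reconstruction cannot presuppose the answer, and the
resulting surrogate outgroup sits *close* to the ingroup root instead of at
the end of a saturated branch — there is nothing left to attract.

## The model layer

Everything runs on a self-contained time-reversible likelihood engine:

* **Models** — `subst_model()` parses `"LG+G4+I+F"`-style strings. LG (with
  phangorn's shipped table) and POISSON (uniform exchangeabilities and
  frequencies) for amino acids; GTR and JC for nucleotides; `+G<k>`
  discrete-gamma rate categories (mean-of-bin discretization over
  equiprobable quantile bins of Gamma(α, α), mean pinned at 1), `+I` a
  proportion of invariant sites (gamma rates rescaled by 1/(1−p_inv) so the
  overall expected rate stays 1), `+F` empirical frequencies counted from
  the data with unobserved states floored at 1e-6.
* **Rate matrix** — Q = S·diag(π) off-diagonal, rows summing to zero,
  rescaled to one expected substitution per site at equilibrium;
  transition probabilities via the π-symmetrized eigendecomposition.
* **Likelihood** — Felsenstein pruning over unique site patterns with
  per-node log-scaling; gaps and ambiguity codes are missing data (partial
  likelihood of one at the tip); the invariant category contributes only at
  sites whose observed states are compatible with a single state. The
  engine accepts rooted, unrooted and star trees; for reversible models the
  likelihood is invariant to the virtual root (the pulley principle), which
  the tests assert to 1e-8.
* **Optimization** — branch lengths by coordinate-wise Brent line search
  (bounds 1e-8 to 20 substitutions/site), sweeping edges from the root down
  with cached bidirectional conditional likelihoods; each edge's likelihood
  profile is projected onto the eigenbasis once per sweep so a line-search
  evaluation is a single small matrix–vector product. Gamma shape
  (α ∈ [0.02, 100], log scale) and p_inv (∈ [0, 0.99]) by interleaved 1-D
  fits; GTR exchangeabilities by L-BFGS-B on the log scale with GT fixed
  at 1. All tolerances are arguments (`tol`, `max_passes`, `brent_tol`);
  the defaults (1e-6 lnL for final fits, 1e-4 inside topology searches)
  are engineering choices, not statements about the data.

`aic_select()` ranks candidate models by AIC = 2k − 2 lnL, where k counts
free model parameters (+G → 1, +I → 1, +F → #states − 1, GTR → 5) plus free
branch lengths, with ties broken toward fewer parameters.

## Tree search, support and rooting

With at most eight OTUs the topology space is tiny ((2n−5)!! ≤ 10,395), so
the search is **exhaustive** rather than heuristic: every unrooted topology
is enumerated, seeded with branch lengths fitted by non-negative least
squares to pairwise ML distances, and scored. For larger sets of candidates
a likelihood prescreen at the NNLS lengths ranks all topologies and only the
top `screen_k` (default 10) receive full branch-length optimization — the
winner is insensitive to this because topology lnL differences at these data
sizes are orders of magnitude larger than optimization slop; `screen_k =
Inf` forces full optimization of every candidate. Ties are broken by
lexicographic canonical Newick, so results are deterministic. Shared model
parameters are estimated once, on the prescreen winner, and held fixed
across topologies.

Branch support is **nonparametric bootstrap** (site resampling with full
exhaustive re-search per replicate) rather than SH-like aLRT: at this scale
the bootstrap is exact, self-contained and seed-reproducible.

`root_with_taxon()` places the root at the midpoint of the chosen tip's
pendant edge — a display convention that does not affect the likelihood.

## LCA rooting

`lca_root()` chains the steps: drop the outgroup → optimize a star tree over
the ingroup (branch lengths and any free model parameters) →
`marginal_asr()` computes, per site and rate category, the posterior over
central-node states ∝ π_s · ∏ tips P(s → x_tip; t_tip·r), mixes categories
by their weights (the invariant category enters at constant-capable sites),
and takes the per-site MAP state, breaking ties by alphabet order and
flagging them → the MAP sequence joins the ingroup alignment as tip `"LCA"`
→ exhaustive search (+ optional bootstrap) → root on the LCA tip. The fitted
pendant length of the LCA tip is reported; on data without systematic error
it is near zero (tested: median < 0.05).

The reconstruction uses the per-site MAP state rather than a posterior
sample or averaged profile, matching the standard marginal-reconstruction
output of ML ancestral-inference tools.

## The synthetic-data generator

`simulate_alignment()` performs site-wise i.i.d. simulation: per site an
invariant flag (probability p_inv), otherwise a fresh discrete-gamma
category; a root state from π; evolution along each branch by the model's
transition probabilities. Output is gapless — the protocol's inputs are
curated (block-filtered) alignments, and indel simulation is out of scope.
The true root sequence is retained for benchmarking ancestral
reconstruction. Identical specs (seed included) give bit-identical output.

`make_lba_scenario()` encodes the study design the package emulates: four
ingroup lineages, of which one ("seison") carries a long branch
(default 1.0) and is represented by a cherry of two strain tips (total
divergence 0.002 — the strain pair is a cherry subtending the fast lineage,
mirroring two strains of one species); the other lineages get short branches
(0.1); a single outgroup attaches at the ingroup root at distance 2.0;
sequences evolve under LG+G4 with α = 1 over 5000 sites. The generating
rooted ingroup topology — fast lineage sister to "acantho", that clade
sister to ("bdelloid", "monogonont") — is returned for scoring. The source
study does not report branch lengths for its tree, so these defaults are the
package's choice of a realistic deep-split regime: an order of magnitude
between ordinary and fast branches, and an outgroup twice as long again,
near saturation; all are configurable.

What the generator does *not* emulate: alignment error and gaps,
compositional heterogeneity across lineages, covarion-style rate drift, and
per-gene model differences. Passing tests therefore show that the protocol
behaves as designed under its own model assumptions — not that it is robust
to every pathology of real data.

## Why the LBA experiment analyzes under a uniform-rate model

With the generator's defaults and a correctly specified LG+G4 analysis,
exhaustive ML is statistically consistent and 5000 sites are ample: the true
topology wins in essentially every replicate and no attraction occurs (we
measured log-likelihood margins of +30 to +46 in the true topology's favor).
That is itself a meaningful negative result, but it exercises nothing.

In practice LBA arises because the analysis model underfits the data —
most classically, because among-site rate variation is underestimated.
The package's Monte-Carlo experiment therefore analyzes the
gamma-heterogeneous alignments under the uniform-rate `POISSON` model. This
reproduces the artifact at realistic strength (the fast lineage becomes the
basalmost ingroup branch under outgroup rooting in ~85–90% of replicates)
while the same misspecified model under LCA rooting places it basally in
~0% — the mitigation is a property of the *rooting strategy*, not of model
quality. The singleton-pruned taxon-deletion analyses (B/C) recover the true
sister relationship under the same misspecified model in essentially all
replicates.

## Numerical choices and degenerate inputs

* Transition-probability entries are clipped at 0 (round-off can produce
  −1e-16); rows sum to 1 within 1e-12.
* Per-pattern log-scale factors are tracked at every internal node, so 21k
  site supermatrices with branch lengths up to 20 do not underflow.
* A tree with all-zero branch lengths and a variable column yields −Inf
  with a warning, as reported.
* Zero-length alignments are allowed (and flagged) after column dropping;
  empirical frequencies refuse all-gap alignments.
* MAP ties in ancestral states are broken by alphabet order and recorded in
  the profile.
* Singleton detection treats gaps and missing symbols as transparent:
  never private themselves, never blocking another state from being
  private. This is deliberately conservative — alignment uncertainty should
  not count as phylogenetic signal.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the experiments at the sizes
stated above: 5000-site scenario alignments (50 paired replicates in the
acceptance tests, 20 in the script), 6-taxon recovery at L = 5000 (20 and
10 replicates), star-tree ASR at L = 2000 (10 and 5 replicates), AIC at
L = 2000 (20 and 10 replicates), and a 21,042-site, 100-gene supermatrix for
the editing operations. These sizes keep a full run in the minutes range on
one core while leaving the per-replicate statistics far from their decision
boundaries.

## Known limitations

* Exhaustive search caps at 8 taxa by design; there is no heuristic mode.
* One model for the whole concatenate — no per-gene (partitioned) models.
* Marginal ASR is computed at the star-tree center only, not at internal
  nodes of resolved trees; no joint reconstruction.
* The simulator emits no indels; gap handling is exercised only on the
  inference side.
* Estimating all 189 amino-acid exchangeabilities (REVaa-style) is out of
  scope; LG or POISSON exchangeabilities are used instead, which matched the
  motivating analysis' tree-inference model.
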