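---
title: "Methods: orthology assessment and ancestral pocket reconstruction after 2R"
author: "rarphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthology assessment and ancestral pocket reconstruction after 2R}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The two rounds of whole-genome duplication (2R WGD) at the base of the
vertebrates turned single ancestral genes into families of up to four
paralogues (the "1-2-4" pattern). For the retinoic acid receptors (RARs)
this produced the gnathostome subtypes RARα, RARβ and RARγ (a fourth,
"RARδ", is assumed lost). Jawless vertebrates — lampreys and hagfish —
also carry three receptors (RAR1, RAR2, RAR3), but because cyclostome
sequences are fast-evolving, which gnathostome subtype each cyclostome
gene is orthologous to cannot be read off a standard gene tree with any
confidence. `rarphylo` implements the two analyses this question calls
for:

1. a **probabilistic orthology assessment**: maximum-likelihood scoring
   of a constrained set of gene-tree topologies, summarized as
   per-hypothesis probabilities by RELL bootstrap;
2. a **marginal ancestral reconstruction** of the ligand-binding domain
   on a fixed reconciled tree, read out at the three pocket positions
   that control ligand specificity (232, 270, 395 in human RARα
   numbering), with substitution/reversion events inferred along the
   tree.

A synthetic 2R gene-family generator with complete ground truth makes
every stage testable without any sequence downloads.

## Topology space and the 1-2-4 constraint

The assessment uses five operational taxonomic units (OTUs): one
cyclostome gene `C`, the three gnathostome subtype groups `A`, `B`, `G`,
and an outgroup `O`. There are $(2\cdot 5-5)!! = 15$ unrooted binary
topologies on five leaf-slots; rooted with `O` they are 15 rooted
four-leaf trees over `{C, A, B, G}`.

The duplication constraint is formalized as a cherry rule: under a
strict 2R history the four paralogue slots form a balanced
`((.,.),(.,.))` tree, so a cyclostome gene that is one-to-one
orthologous to a subtype (or that occupies the lost fourth slot) must be
the immediate sister of a single subtype slot. Topologies whose ingroup
cherry is purely gnathostome would place the cyclostome divergence
*between* the two duplication rounds and are excluded. Exactly nine of
the fifteen topologies survive, three per cherry partner — this count
and the 3/3/3 partition are verified by brute force in the test suite.

Hypothesis aggregation adds up bootstrap probabilities over each
cherry-partner class. In three-subtype mode the classes partition the
mass. In four-subtype mode (fourth paralogue assumed) each *balanced*
topology `((C,X),(Y,Z))` is equally compatible with "C orthologous to X"
and "C orthologous to the lost δ whose slot pairs with X"; such
topologies are dual-counted into both sums and the dual decomposition is
reported explicitly, since nothing in the five-OTU data can separate the
two readings.

## Likelihood machinery

Site likelihoods use Felsenstein pruning under an empirical
exchangeability model. The shipped constants are the LG model (PAML
text dialect, parsed at load time); the construction is
$Q_{ij} = s_{ij}\pi_j$ with the usual normalization
$-\sum_i \pi_i Q_{ii} = 1$, so branch lengths are expected
substitutions per site. Model frequencies are used as-is (no `+F`
re-estimation from the data), the conservative default when nothing
argues for data-derived frequencies. The engine is alphabet-generic, which lets
binary-alphabet closed forms exercise the same code paths as the
20-state model in tests.

Rate heterogeneity is discrete-gamma with equal-probability categories
and the **mean-of-bin** convention (category rate = conditional mean of
its bin, rescaled to mean exactly 1). The two common conventions
(mean vs median of bin) differ numerically; mean-of-bin is the
convention of the classic maximum-likelihood phylogenetics programs. The shape is estimated by
bounded search in $\log\alpha$ on $[0.05, 50]$, alternated with
branch-length optimization (3 cycles). By default one shape is estimated
on the first topology and shared across the topology set
(`shared-estimate`), mirroring a single dataset-level rate model;
per-topology estimation is available but makes per-site log-likelihoods
less comparable across topologies.

Numerical points:

* gaps and `X` enter the pruning as all-ones conditional vectors (`X`
  is total ambiguity); ambiguity codes other than `X` are mapped to `X`
  (or rejected, by flag);
* per-node rescaling prevents underflow at any tree size;
* a site with exactly zero likelihood (possible only with zero-length
  branches and conflicting states) reports a configurable log floor of
  −745 instead of −∞ so RELL resampling stays finite;
* transition matrices come from the symmetric eigendecomposition of the
  reversible $Q$; the per-branch likelihood as a function of the branch
  length is evaluated in the eigenbasis, which reduces every evaluation
  of the one-dimensional search to a matrix–vector product.

Branch lengths are optimized by coordinate ascent: each branch in turn
is maximized with Brent's method on $[10^{-8}, 20]$, with all partial
vectors kept current (one down-pass plus one pre-order sweep per round),
so the total log-likelihood is nondecreasing across rounds — a property
the tests assert. Initialization is 0.1 for unset lengths; any positive
value works under monotone ascent. Convergence is declared when a full
round improves the total by less than `tol` (default $10^{-6}$; the
end-to-end drivers use $10^{-4}$, which changes bootstrap probabilities
by far less than Monte-Carlo noise).

## RELL bootstrap and orthology probabilities

RELL ("resampling of estimated log-likelihoods") resamples site indices
with replacement, sums the per-topology site log-likelihoods, and awards
each replicate to the argmax topology, with **exact ties split equally**
(and counted) rather than broken by seed order. No re-optimization is
performed. The implementation draws the per-replicate counts as a
multinomial over the distinct site-loglik columns, which is exactly the
distribution of iid site resampling. `B` defaults to 10,000, giving a
Monte-Carlo standard error on a bootstrap probability of at most
$\tfrac{1}{2}\sqrt{1/B}\approx 0.005$ at sub-minute cost. Every run is
reproducible from its integer seed, and the seed handling leaves the
caller's RNG stream untouched.

## Marginal ancestral reconstruction

Reconstruction is **marginal** (per node and column, integrating over
all other nodes), matching the "probability of a particular amino acid
at a particular position" read-out; joint reconstruction is out of
scope. For node $v$, column $c$ and category $k$, the posterior is
proportional to the product of the below-partial (down pass) and the
rest-of-tree partial (up pass, with the stationary frequencies folded in
at the root). Categories are mixed with **site-specific weights** — the
posterior probability of each category given the column — a point on
which reconstruction tools differ and which is therefore stated
explicitly.

The "best predicted" (MAP) residue is the per-column argmax with a
deterministic alphabetical tie-break; ties are flagged, and in the
event-inference chain tied positions propagate as `X` and produce
no-calls rather than guessed events. Columns with more than 10% gaps
(strict inequality) are removed before reconstruction; `X` counts as a
residue, not a gap, in that filter. Named ancestors are specified as
most-recent-common-ancestors of leaf sets, so node identity is stable
under any tree rewriting that preserves the clades.

## Pocket signatures and event inference

The three diagnostic pocket patterns are exact triplets — α-like
Ser/Ile/Val, β-like Ala/Ile/Val, γ-like Ala/Met/Ala — and anything else
(including any `X`) is `other`: no nearest-class assignment is
attempted, because no distance between pockets is defined. Event
inference is a deterministic edge-wise diff of parent/child states;
a change is a **reversion** iff the new state equals a state held by a
strict ancestor older than the most recent change at that position, so
multi-step histories (Ser→Ala→Ser) are labelled correctly rather than
only grandparent comparisons.

## The synthetic generator

`scenario_spec()`/`simulate_scenario()` realize a 1-2-4 history: a
balanced four-slot duplication tree (default pairing α with δ and β with
γ, the RAR arrangement), optional paralogue loss (default: δ lost), a
single cyclostome gene grafted as sister to its true orthologue, and
sequences evolved by drawing the root from the stationary frequencies
and sampling states edge-wise through the transition matrices, one
gamma category per column. Defaults are the validation conditions used
throughout: 2,000 columns, all branches 0.1 expected substitutions per
site, shape α = 1, one species per subtype. The three designated pocket
columns are **overwritten deterministically** after simulation so their
states are exactly scenario-determined: signature and event tests are
then exact closures while the remaining columns exercise the stochastic
machinery.

The shipped demonstration fixture (`rar_pocket_scenario()`) is a 19-leaf
vertebrate-RAR-like family (hagfish + lamprey RAR1/2/3;
chondrichthyan, actinopterygian and sarcopterygian representatives per
gnathostome subtype; amphioxus outgroup) with the family's inferred
pocket history planted: Ser→Ala at 232 on the RAR2-β/RAR1-γ stem, its
reversion on the cyclostome RAR1 stem, Ile→Met at 270 and Val→Ala at 395
on the gnathostome RARγ stem, and Ala→Ser reversions at 232 in the
actinopterygian and frog RARγ lineages. Its branch lengths follow the
family's documented rate profile rather than a uniform value: cyclostome
branches long (their sequences are unusually divergent), deep
post-duplication stems long, chondrichthyan and amniote RARγ branches
short. This is a structural requirement, not a tuning knob: a
reversion-rich planted history is only the maximum-likelihood history —
and hence recoverable by *any* correct reconstruction — if the branches
carrying the planted changes are not rate-equivalent to the branches
carrying the alternative, more parsimonious placements. Under uniform
lengths the marginal reconstruction correctly prefers a three-change
history (keeping Ser at the base of RARγ), which is precisely the
tension visible between ancestral-state read-outs and event scenarios
for this family.

What the generator does **not** emulate: insertions/deletions (gaps
only enter via hand-made fixtures), compositional heterogeneity across
lineages, site-specific selective constraints outside the three pocket
columns, and alignment error. Passing tests therefore demonstrate
correctness of the inference machinery under the model's own
assumptions, not robustness to real-data violations of them.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive enumeration over internal-node states for the pruning
likelihood (all instances with ≤ 4 leaves, ≤ 3 states, ≤ 4 sites; 200
random cases), exhaustive Bayes for marginal posteriors on three-leaf
trees, closed forms for binary-alphabet transition probabilities and
two-taxon ML distances, quadrature for the discrete-gamma bin means,
and brute-force recounts for the combinatorial claims. End-to-end
recovery runs use the generator's default conditions — 2,000 columns,
branches 0.1, B = 10,000, twenty seeds per cyclostome placement, with
the aggregated probability of the true hypothesis required to reach
0.95 in at least 18 of 20 — and marginal-ASR accuracy uses 20-leaf
trees with 0.05-length branches and 300 columns, where MAP root
recovery of at least 90% of columns is required. These sizes are the
package's design point for a single-workstation validation; all of them
are plain function arguments.

## Known limitations

* The orthology stage assumes exactly one cyclostome gene per
  assessment (the five-OTU design); multi-gene joint placement is out
  of scope.
* Only RELL bootstrap probabilities are produced; approximately-
  unbiased p-values and other topology-test statistics are not.
* Gap/indel states are never reconstructed; the gap-column filter
  removes them before reconstruction.
* The signature classes are the three printed triplets; receptors with
  derived pockets (e.g. a cysteine in H3) are reported as `other`, by
  construction.
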