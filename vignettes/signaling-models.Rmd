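---
title: "Carving condition-specific signaling models from multi-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carving condition-specific signaling models from multi-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalcarver)
```

## The problem

A kinase inhibitor hits its receptor within minutes, but the phenotype a
cell reaches a day later — death, arrest, or resistant proliferation —
is decided by how the signal rewires the network downstream.  Bulk
differential omics (RNA-seq, proteomics, phosphoproteomics) measure the
*consequences* of that rewiring; curated resources such as SIGNOR or
PhosphoSitePlus record the *possible* causal routes.  `signalcarver`
joins the two: it infers which regulators changed activity, connects
them to the perturbed receptor through the prior network, and carves out
the sign-consistent subnetwork that best explains the data — a
mechanistic, condition-specific model whose nodes carry activation
(+1) or inhibition (−1) states.

The pipeline has four steps.

## Step 1 — regulator activity inference

**Footprint scores.**  A regulator's activity is read from its known
targets rather than its own abundance.  For a regulon with signed
targets $t = 1..n$ (signs $s_t$, differential measurements $x_t$) the
raw statistic is

$$ A = \frac{1}{\sqrt{n}} \sum_t s_t x_t , $$

positive when the regulator's program moved in its activating
direction.  Transcription-factor regulons are transcriptional edges
with their activity signs; kinase and phosphatase regulons are the
phosphosites they write or erase, signed by the *event direction* (+1
phosphorylation, −1 dephosphorylation) because the statistic acts on
site abundance.  These are two distinct sign layers: the knowledge-base
edge sign remains the effect on the target's *activity* and is what the
network optimization consumes.

The null is built by re-drawing target labels from the measurement
table (`n_perm` permutations, fixed seed): `z` standardizes the raw
score against the null and the two-sided p-value is the empirical tail
with the usual $+1$ correction, so p-values are uniform on a discrete
grid under the null and type-I error is controlled by construction.
The statistic is a deliberately simple, calibratable mean-enrichment
form; it is isolated behind `footprint_activity()` so a
likelihood-weighted variant could be swapped in without touching the
rest of the pipeline.

**Regulatory-site scores.**  Phosphoproteomics also measures sites with
annotated functional roles.  `phospho_score()` averages
$\text{effect} \times \log_2\text{FC}$ over a protein's quantified
regulatory sites: hyperphosphorylation of an inhibitory site (the
classic CDK1 Tyr15) therefore yields a *negative* activity change.
Before kinase scoring, phosphosite fold-changes are corrected by
subtracting the host protein's fold-change
(`normalize_phospho_by_protein()`), so abundance-driven site changes do
not masquerade as regulation; sites without a quantified host pass
through flagged.

When both a footprint and a site score exist for a protein they are
combined by averaging the z-scores (and raw scores); a p-value for the
combined estimate is taken as the Stouffer form
$2\Phi(-|z_a + z_b|/\sqrt{2})$.  Opposite-signed pairs are flagged
discordant and excluded from modeling by default.  Proteins that have
quantified regulatory sites but no regulon of their own (substrates)
are scored by the site method alone, which is what lets them act as
anchors in the network stage.  Significance is called at BH FDR < 0.05
across all scored proteins; the differential statistics feeding the
scores use the more permissive FDR < 0.1 conventional for differential
abundance.

Welch's unequal-variance t-test is used per analyte (a moderated test
is a reasonable alternative; plain Welch keeps the per-analyte model
assumption-free).  Zero-variance, equal-mean analytes receive p = 1 so
BH ranks stay defined.

## Step 2 — the naive network

Significant regulators are connected to the perturbed source through
**every causal path of minimal length**: for each ordered pair
(source→regulator, regulator→regulator, regulator→TF) the shortest
directed path length $L$ is computed in the prior network and, if
$L \le$ `max_len` (default 4), *all* paths of exactly length $L$ are
kept.  Per-pair minimality preserves parallel co-minimal routes — the
later optimization, not the path search, should decide between them —
while the length cap bounds the combinatorics.  Unmeasured
intermediates enter with state 0; edges with contradictory sign
annotations never participate.  The default cap of 4 hops reflects how
far curated kinase-substrate chains usefully reach; deeper paths are
almost always assembled from the same 1–4 hop segments.

## Step 3 — sign-consistent optimization

Ternary states $\sigma_v \in \{-1, 0, +1\}$ and a set of active edges
are chosen to maximize

$$ \sum_{v\ \mathrm{measured}} w_v\,[\sigma_v = \hat\sigma_v]\;-\;\lambda\,|E_{\mathrm{active}}| $$

subject to: along every active edge $u \to v$ with sign $s$,
$\sigma_v = s\,\sigma_u$ and $\sigma_u \neq 0$; and every nonzero node
receives signal from the fixed perturbation through active edges.  The
second condition is deliberately stronger than the local "at least one
incoming active edge" support rule, which would admit self-sustaining
loops detached from the perturbation; requiring root reachability is
what makes the model causal.  Weights default to $|z|$, measured nodes
are soft constraints (a mismatch merely forfeits $w_v$), and
$\lambda = 0.1$ sets a mild parsimony pressure — large enough to prune
decorative edges, an order of magnitude below typical $|z|$ weights so
it never buys an extra mismatch.

Three engines share these semantics:

* `exact` — branch-and-bound over node states in BFS order from the
  perturbation, seeded with a deterministic greedy signed-path
  incumbent and pruning any branch that cannot *strictly* beat it.
  Optimal at any size it completes; realistic naive networks
  (~25–40 nodes) solve in well under a second.
* `exhaustive` — enumeration of all $3^k$ assignments (vectorized,
  capped at 12 free nodes to keep the state matrix in memory), kept as
  an independent verification oracle.
* `anneal` — the greedy cover refined by simulated annealing on
  closure-repaired states; feasible and reproducible under a seed, for
  instances beyond exact reach.

Every returned solution is audited by `check_solution()`, a separate
code path that re-verifies the invariants and the objective.
Degenerate inputs: fixing the source to 0 leaves nothing to ground the
signal and is reported as infeasible with a certificate; among
co-optimal solutions the exact engine returns its first
strictly-improving leaf in a canonical value order and the exhaustive
engine prefers fewer active edges, so both are deterministic.

The optimization runs twice, mirroring how signal traverses the two
biological layers: run 1 connects the source to kinases, phosphatases
and substrates; run 2 connects everything run 1 retained to the
transcription factors, with run-1 states as hard constraints (the
retained nodes act as grounded signal entry points).  The merged model
is re-audited globally.

## Step 4 — phenotype readout

As an in-silico validation, marker proteins of a phenotype (e.g.
pro-survival MCL1/BCL2 versus pro-apoptotic BAD/BIM) are scored by the
one-hop signed mean of their upstream model nodes:
$\text{score}(m) = \mathrm{mean}_u\, \sigma_u \cdot s_{u\to m}$, bounded
in $[-1, 1]$; per-phenotype scores sum marker scores times their
association signs.  Markers with no upstream model node are flagged
unpredictable rather than silently scored.  Re-running the optimization
with markers appended would be the heavier alternative; the one-hop
readout keeps validation independent of the fit it validates.  The
shipped marker table is a small synthetic reconstruction of a typical
text-mining panel and is meant to be replaced by the user's own.

## The synthetic benchmark

`generate_truth()` emulates the study design the pipeline targets: one
receptor silenced by an inhibitor (state −1), a spanning arborescence
of kinases/phosphatases, substrates and TFs over which states
telescope, plus extra prior edges of which a configurable fraction
(default 10%) carry corrupted signs and contribute no real signal —
curation noise.  Measurements follow the declared effect model: every
real regulatory event moves its readout by
$\sigma \cdot \text{effect\_size}$ (mean |log2FC| 2.0 by default),
phosphosites additionally ride on state-independent host-protein
abundance shifts (SD 0.5) so the normalization step is genuinely
exercised, replicate noise is Gaussian (SD 0.5, 4 replicates per
group), and unregulated genes and sites pad the tables so permutation
nulls see a realistic background.  Defaults (40 nodes: 10 kinases, 4
phosphatases, 8 TFs with 8 transcript targets each, the rest
substrates) were chosen once as a desk-scale caricature of a deep
(phospho)proteomics study; the validation experiments below use them
unchanged.

What the generator does **not** emulate: heavy-tailed MS noise
(Gaussian is a documented simplification), shared-peptide ambiguity,
batch structure, absolute abundances, or feedback loops that
re-equilibrate after perturbation.  Passing the benchmarks therefore
shows the machinery is correct and calibrated under its own stated
model, not that real data meet that model.

`make_condition_pair()` plants condition differences: listed nodes are
negated and their descendants re-propagated over a shared prior and a
shared noise stream, so the two conditions differ *only* through the
flipped states.  Because a flipped node contradicts every original
route to it, the shared prior is augmented with one depth-matched
alternative route of the opposite sign per flip — exactly the kind of
context-dependent contradictory evidence curated databases contain.
Flips are planted on TFs in the packaged experiments: TFs are leaves of
the protein layer, so the set of truly differing states is exactly the
planted set.  Condition pairs for these experiments use a clean prior
(inconsistent fraction 0) so that discordance detection is measured
against measurement noise alone; prior corruption is stressed by the
recovery benchmark instead.  Extra edges never target TFs, keeping
TF regulation on the curated transcriptional route.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` re-run five experiments,
sized to stay comfortably within a desktop run:

* solver correctness: exact vs exhaustive objectives on 100 random
  instances (4–8 nodes), every solution re-audited independently;
* recovery: 20 independent 40-node truths at the default noise; the
  reported metric is the share of model nodes whose nonzero state
  matches the truth (nodes the prior cannot explain stay at 0 and are
  excluded — the model makes no claim about them).  A clean-prior,
  zero-noise run must recover every node exactly;
* discordance: 3 planted TF flips, 10 seeds, noise SD 0.25 — model
  comparison must report exactly the planted set;
* calibration: empirical type-I error of both permutation tests at
  $\alpha = 0.05$ over 1000 pure-noise regulators, 1000 permutations;
  BH checked against the closed-form rank formula;
* formulas: the 4-target unit fixture ($A = +2$ exactly),
  antisymmetries, combination commutativity.

## Known limitations

Identifier spaces are taken as given symbols (no ortholog or isoform
mapping).  The footprint statistic ignores regulon confidence weights.
The two-run scheme fixes run-1 states, so evidence arriving only
through TFs cannot revise an upstream call.  Marker readout is one-hop.
And all guarantees about recovery are relative to the generator's own
effect model, as discussed above.
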