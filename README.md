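# signalcarver

Condition-specific mechanistic signaling models from multi-omics data
and signed causal priors.

## What problem this solves

When a targeted drug (say, a receptor tyrosine kinase inhibitor) kills
one cell line and not another, the difference usually lives in how the
signal rewires downstream of the receptor — not in the receptor itself.
Differential transcriptomics and (phospho)proteomics observe the
consequences of that rewiring; curated causal resources
(SIGNOR/PhosphoSitePlus-style tables of signed, directed interactions
and regulatory phosphosites) enumerate the possible routes.
`signalcarver` is for systems biologists who want to join the two into
a testable model: a signed network, rooted at the perturbation, in
which every retained node carries an activation (+1) or inhibition
(−1) state consistent with the measurements.

The pipeline, in four steps:

1. **Activity inference.** Transcription-factor activity by footprint
   enrichment over signed regulons, `A = Σ s_t·x_t / √n`, with a
   label-permutation null; kinase/phosphatase activity by the same
   footprint over (protein-normalized) phosphosites **plus** a
   regulatory-site score, `mean(effect · log2FC)` over a protein's own
   annotated sites (hyperphosphorylation of inhibitory CDK1 Tyr15 ⇒
   negative activity), the two z-scores averaged.
2. **Naive network.** All minimal-length causal paths from the
   perturbed source to every significant regulator and TF.
3. **Optimization.** The sign-consistent subnetwork maximizing
   `Σ w_v·[state matches measurement] − λ·|edges|`, with an exact
   branch-and-bound engine, an exhaustive verification oracle and an
   annealing fallback, run in the two-stage scheme
   (source→regulators, then retained nodes→TFs).
4. **Phenotype readout.** One-hop signed propagation onto marker
   proteins (pro-survival vs pro-apoptotic panels) as in-silico
   validation.

A synthetic ground-truth generator emits matched transcriptome /
proteome / phosphoproteome tables over a known signed network so every
stage is benchmarkable without any external download.

## Worked example

```r
library(signalcarver)

params <- generator_params(seed = 42, noise_sd = 0.4)   # 40-node truth
truth  <- generate_truth(params)
truth$kb
#> <causal_kb> 142 edges (0 ambiguous), 51 regulatory sites, 104 proteins

tabs <- lapply(truth$tables, differential_stats)         # Welch + BH
acts <- activity_table(truth$kb, tabs$transcriptome, tabs$proteome,
                       tabs$phospho, seed = 42)
dplyr::arrange(dplyr::filter(tibble::as_tibble(acts), significant),
               dplyr::desc(abs(z)))[1:5, c("protein", "role", "z", "fdr",
                                           "method", "n_evidence")]
#> # A tibble: 5 × 6
#>   protein role      z     fdr method    n_evidence
#>   <chr>   <chr> <dbl>   <dbl> <chr>          <int>
#> 1 TF01    TF    -5.70 0.00229 footprint          8
#> 2 TF02    TF     5.69 0.00229 footprint          8
#> 3 TF08    TF     5.56 0.00229 footprint          8
#> 4 TF06    TF    -5.51 0.00229 footprint          8
#> 5 TF07    TF     5.49 0.00229 footprint          8

model <- two_run_optimize(truth$kb, truth$source, acts, seed = 42)
model
#> <causal_network:optimized> 29 nodes, 28 edges, source=RCPT

state_recovery(model, truth$true_states)
#> $accuracy
#> [1] 1
#> $n
#> [1] 29
```

Reading the output: the five strongest significant calls are TF
activities inferred from their 8-gene transcriptional programs (|z| ≈
5.5–5.7 against the permutation null, BH FDR ≈ 0.002); the optimized
model grounds 29 proteins in the inhibited receptor through 28
sign-consistent edges; and every one of those 29 inferred states equals
the generator's hidden truth.

For file-based runs, `run_pipeline(config, outdir)` executes the same
chain from TSV inputs (see `?read_run_config`) and writes every
intermediate plus a JSON manifest; `write_truth_dir()` emits a
ready-to-run directory, and `inst/cli/signalcarver.R` wraps
simulate/run/compare for shell use.

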