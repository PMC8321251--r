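# stageGRN

Stage-specific disease-gene prioritization for paired tumor/normal
cohorts.

Cancer cohorts annotated with clinical stage (I/II/III) carry signal
that stage-agnostic driver prediction discards. `stageGRN` implements a
stage-aware pipeline that integrates paired differential expression with
DNA-methylation status, builds one transcription-factor (TF) → target
regulatory network per stage, detects co-expression modules, selects the
modules where stage-exclusive genes concentrate, and prioritizes
candidate disease genes per stage — plus the genes shared by all stages.
Because its intended real inputs are controlled-access tumor cohorts,
the package ships a synthetic paired-cohort simulator with planted
ground truth, so that every step is testable by parameter recovery.

## Method

For each stage *s* with paired tumor/normal samples:

1. **DEGs** — paired t-test on per-patient differences of
   log2(FPKM + 1); gene *g* is a DEG when *p* < 0.05 and
   |log2FC| ≥ 0.5.
2. **Methylation status** — CpG β values are averaged per gene; a gene
   is hypermethylated when its mean tumor β > 0.8, hypomethylated when
   < 0.2 (strict). The candidate universe is
   DEG(s) ∩ (hyper ∪ hypo).
3. **Stage network** — TF→target prior pairs with target in the
   universe are kept when the Pearson correlation of the pair over the
   stage's tumor samples satisfies |r| ≥ 0.5.
4. **Modules** — the network's nodes are clustered by UPGMA on
   d = 1 − |cor| and cut adaptively into modules of ≥ 30 genes with
   WGCNA-style color labels; grey (unassigned) genes are discarded.
5. **Specific modules** — DEGs exclusive to one stage are its
   stage-specific genes; modules enriched for them (hypergeometric,
   BH FDR < 0.05) are the stage's specific modules.
6. **Candidates** — within the specific modules, the *correlation core*
   (genes with ≥ 10% of module partners at |r| ≥ 0.8, *p* < 0.05) is
   intersected with the *topology core* (union of the top 5% by degree,
   betweenness and closeness on the module subgraph, with boundary-tie
   expansion). The intersection is the stage's candidate disease-gene
   set; candidates present in every stage are reported as shared.

All thresholds are defaults of `pipeline_config()` and can be changed;
the methods vignette (`vignettes/stage-specific-disease-genes.Rmd`)
documents every rule, the simulator's generative model, and the design
choices made where the procedure was open.

## Worked example

Simulate a three-stage cohort under the default study conditions (2,000
genes, 50 tumor/normal pairs per stage, four planted modules, 10 planted
disease genes per stage of which 3 are pan-stage drivers) and run the
full pipeline:

```r
library(stageGRN)

sim <- simulate_cohort(simulation_config(seed = 1))
sim$cohort
#> paired_cohort: 2000 genes x 300 samples
#>   methylation: 6000 CpG sites
#>   pairs per stage: I=50, II=50, III=50

res <- run_pipeline(sim$cohort, sim$prior, pipeline_config(),
                    truth = sim$truth)
res$report
#> stage I: 10 candidates (corr core 38, topo core 17) in modules [turquoise, blue]
#>    G0001, G0014, G0033, G0034, G0035, G0039, G0043, G0068, G0084, G0087
#> stage II: 9 candidates (corr core 37, topo core 16) in modules [turquoise, blue]
#>    G0021, G0033, G0035, G0054, G0059, G0074, G0082, G0084, G0085
#> stage III: 10 candidates (corr core 39, topo core 15) in modules [turquoise, blue]
#>    G0007, G0020, G0033, G0035, G0037, G0044, G0070, G0083, G0084, G0097
#> shared across stages: G0033, G0035, G0084

res$recovery$per_stage$I
#> $n_predicted [1] 10   $n_planted [1] 10
#> $precision   [1] 1    $recall    [1] 1
#> $module_ari  [1] 1
```

Per stage, `turquoise` is the large pan-stage module and `blue` the
stage's home module; the ten candidates are exactly the ten planted
drivers (7 stage-exclusive, 3 pan-stage), and the three genes shared
across stages are the planted pan-stage drivers. `res$stages` holds
every intermediate: DEG tables, gene status tables, stage networks,
module partitions, specificity tables and per-gene topology scores.

The same analysis runs from files: `write_fixture()` emits the TSV
layout (`expression.tsv`, `beta.tsv`, `cpg_map.tsv`, `tf_targets.tsv`,
`metadata.tsv`), and `run_all(input_dir, out_dir, config)` writes every
artifact (edge lists, GraphML, partitions, candidate report JSON, run
manifest) deterministically.

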