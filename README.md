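# devconnectome

Graph-theoretical analysis of developmental white-matter brain networks in
R. The package is aimed at researchers studying how the large-scale
organization of the structural connectome changes across age groups: it
turns per-subject tractography summaries (streamline counts, mean tract
FA, regional volumes over a 78-region cortical parcellation) into weighted
networks, and carries the full analysis through group backbones, weighted
graph metrics, null-model small-worldness, module detection, hub
classification and adjacent-group statistics. A synthetic cohort generator
with planted modular structure makes every stage testable without any
imaging data.

## The model

Per subject, two cortical regions i and j are connected when at least 10
streamlines join them, with weight

    w_ij = FN_ij · FA_ij / ((V_i + V_j)/2)

(fiber number times mean tract FA, normalized by the mean regional volume);
each network is then scaled to unit mean edge weight. Per age group, a
**backbone network** keeps the edges whose presence across subjects
survives an exact one-tailed sign test (`P(X ≥ k)`, `X ~ Bin(n, ½)`) with
Bonferroni correction over all `N(N−1)/2 = 3003` region pairs; at
`n = 36` subjects that means presence in at least 31 subjects.

On these networks the package computes total strength
`S = (1/N) Σ_{i≠j} w_ij`, Onnela max-scaled weighted clustering `CC`,
harmonic characteristic path length `L = 1/E_glob`, global, local and
nodal efficiency (edge length `1/w`, disconnected pairs contribute 0),
small-worldness `σ = γ/λ` against Maslov–Sneppen degree-preserving null
ensembles in which weights travel with the swapped edges, weighted Newman
modularity `Q = Σ_s [w_s/W − (W_s/2W)²]` maximized by a size-normalized
greedy agglomeration, participation coefficients
`P_i = 1 − Σ_s (w_is/w_i)²`, and hubs by the one-SD rule on nodal
efficiency (global hubs) or PC (connector hubs). Adjacent age groups are
compared with an OLS model `metric ~ group + age + sex`; nodal maps are
FDR-corrected (Benjamini–Hochberg, `q = 0.05`) across the 78 regions per
metric and transition.

## Worked example

```r
library(devconnectome)

cohort <- generate_cohort(cohort_spec(seed = 1))   # 5 groups x 36 subjects
config <- pipeline_config(cohort = cohort, n_null_networks = 100,
                          null_seed = 1)
result <- run_pipeline(config)
print(result)
```

```
Developmental network analysis
  180 subjects, groups: early_childhood -> late_childhood -> adolescence -> young_adult -> adult
  backbone sparsity by group: 0.1142, 0.1209, 0.1279, 0.1322, 0.1365
  small-world sigma by group: 2.68, 2.68, 2.64, 2.59, 2.61
  backbone Q by group: 0.529, 0.532, 0.522, 0.524, 0.507
  significant global transitions: S (early_childhood->late_childhood);
  L (early_childhood->late_childhood); E_glob (early_childhood->late_childhood); ...
```

Reading the output: backbone sparsity rises with age (the generator
programs a ×1.2 span, mirroring denser connectivity in older groups);
every group backbone is strongly small-world (σ ≫ 1: much more clustered
than degree-matched random networks at comparable path length); modularity
sits near 0.52 with the six planted modules recovered in each group; and
the adjacent-group GLM flags the developmental transitions where the
generated fiber counts and sparsity actually change. Per-subject metric
tables, per-group backbones, module assignments and the statistics table
are in `result$global_metrics`, `result$backbones`, `result$partitions`
and `result$group_stats`, and are written as CSV/TSV plus a JSON manifest
when `output_dir` is set.

The programmed-effect machinery is available through
`cohort_spec(effect_map = ...)`, which plants relative changes of global
efficiency, local efficiency or modularity at chosen transitions — see the
vignette (`vignettes/developmental-connectome-analysis.Rmd`) for how the
generator realizes them and for every modeling convention.

## Command-line use

```sh
Rscript inst/cli/connectome.R generate --seed 1 --out cohort_dir
Rscript inst/cli/connectome.R run --in cohort_dir --out results --nulls 1000
Rscript inst/cli/connectome.R metrics --network results/backbone_adult.csv
```

Subcommands `backbone`, `smallworld` and `modules` operate on single
groups or network CSVs; all flags have sensible defaults.
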