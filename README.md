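# pte — participatory theme elicitation from card-sorting data

Participatory theme elicitation (PTE) is a participatory approach to
qualitative analysis in which a group of analysts — typically researchers
with lived experience working alongside academic researchers — each
independently sort a shared set of quote cards into labelled piles. The
combined sorting patterns are then analysed as a network to propose quote
groupings that no single analyst controls, and the groupings seed the
group's theme discussion. This package implements the computational slice
of that workflow for mixed-methods health research teams: ingesting and
validating sorting tables, building the co-occurrence network, detecting
groupings, scoring how well human themes align with the groupings and with
each other, and simulating sorting studies to probe when the method breaks
down.

## The model

Quotes are nodes. Two quotes are connected if at least one analyst placed
them in the same pile, and the edge weight `w_ij` counts the analysts who
did so (for `R` analysts, `0 ≤ w_ij ≤ R`). Groupings are communities that
maximize weighted modularity at resolution `γ`:

    Q = (1/2m) Σ_ij [ w_ij − γ k_i k_j / 2m ] δ(c_i, c_j)

with `k_i` the weighted degree and `2m` the total weight. Optimization
uses the Louvain heuristic (seeded greedy local moving + aggregation,
plus a final refinement pass), implemented in the package; an exhaustive
set-partition oracle is included for validating results on small graphs.

Theme-level statistics mirror how PTE studies report congruence:

* **dominant grouping percentage** — the share of a theme's quotes
  carrying the theme's modal grouping label; undefined (`N/A`) on ties,
  which are reported as a breakdown such as `4 green; 4 pink; 3 blue`;
* **adjusted Rand index** — chance-corrected agreement between two
  groupings of the same quotes;
* **theme overlap matching** — the full Jaccard matrix between two theme
  lists with a transparent greedy best-match pairing.

A seeded generator plants `K` latent themes among `N` quotes and perturbs
each analyst's copy of the planted partition (pile splits, merges, and
per-quote moves) to support recovery experiments.

## Worked example

Simulate a study the size of a typical PTE exercise (89 quotes, 4
analysts, 4 latent themes, 10% sorting noise), then run the pipeline:

```r
library(pte)
dir <- tempfile(); dir.create(dir)
pte_cli(c("simulate", "--out", dir, "--quotes", "89", "--researchers", "4",
          "--themes", "4", "--p-move", "0.1", "--p-split", "0",
          "--p-merge", "0", "--seed", "1"))

study <- read_sorting_table(file.path(dir, "sorting.csv"))
study
#> Sorting study: 4 researcher(s), 89 quote(s)
#>   R1: 4 piles (sizes 26, 22, 22, 19)
#>   R2: 4 piles (sizes 25, 22, 22, 20)
#>   ...

net <- build_cosort_network(study)
net
#> Co-sort network: 89 quotes, 1641 edges (0 isolated), 4 researchers

asg <- louvain_communities(net, seed = 1)
modularity_score(net, asg)
#> [1] 0.5449112
adjusted_rand_index(asg, read_grouping(file.path(dir, "truth.csv")))
#> [1] 0.9393923
```

The detected groupings recover the planted themes almost exactly (ARI
0.94) despite each analyst misfiling ~9 quotes. Scoring a theme list
against a grouping assignment reproduces the familiar table layout:

```r
themes <- read_theme_file(system.file("extdata", "themes_academics.txt",
                                      package = "pte"))
asg2 <- read_grouping(system.file("extdata",
                                  "synthetic_grouping_academics.csv",
                                  package = "pte"))
theme_congruence_table(themes, asg2)[1:4, c("theme", "dominant", "percentage")]
#>                                       theme dominant percentage
#> 1                   1. A social environment     pink      85.7%
#> 2 2. Unique qualities of trainers/programme     blue       100%
#> 3                                 3. Agency     blue       100%
#> 4      4. Physical adjustments to programme     blue       100%
```

The bundled theme files transcribe the two analyst groups' published
theme lists; the per-quote colour assignments are synthetic stand-ins
consistent with those tables (see `inst/extdata/README.txt`).

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/pte` (subcommands `validate`, `run`, `congruence`, `compare`,
`simulate`; results to files/stdout, logs to stderr).

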