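# c4scan

Genome-wide branch-model selection scans over syntenic ortholog groups in
grasses.

C4 photosynthesis arose repeatedly within the grasses; genes recruited
into the pathway are expected to show an elevated dN/dS ratio (ω) on the
branches where the C3→C4 transitions occurred. `c4scan` is an R package
for scientists who want to run — or stress-test — that scan end to end on
the six-taxon pan-grass phylogeny `(((Zm,Sb),(Si,Do)),(Os,Bd))` (maize,
sorghum, *Setaria italica*, *Dichanthelium oligosanthes*, rice,
*Brachypodium distachyon*; the first three are C4):

* **Ortholog groups** — synteny-table parsing, maize whole-genome-
  duplication homeolog merging, best-hit attachment of the
  *Dichanthelium* homolog, and classification into the four testable
  member patterns.
* **Codon-aware alignment** — progressive protein alignment on the
  species-tree guide (BLOSUM62, affine gaps), back-translation,
  Gblocks-style conserved-block trimming, and a 30% coverage filter.
* **Congruence filter** — exhaustive-search ML gene trees under GTR+Γ+I
  (all sites and third codon positions); a group survives if at least one
  tree has quartet distance 0 to the species topology.
* **Selection scan** — the Goldman–Yang branch model
  `q_ij = π_j κ^[ts] ω^[nonsyn]` over the 61 sense codons, fitted by
  Felsenstein pruning (C++ core). For each group and each of nine
  phylogenetic conditions (C4 lineages removed one or two at a time), a
  likelihood-ratio test of H0 (one ω everywhere) against Ha (an
  independent ω on the C4 foreground branches), `2ΔlnL ~ χ²(1)`.
* **Candidates** — per-condition Benjamini–Hochberg q-values; a group is
  a candidate iff some condition has `q < 0.2` *and* `ω_fg > ω_bg`; exact
  hypergeometric enrichment of known genes among the candidates.
* **Simulator** — forward codon evolution with branch-specific ω,
  homeologs, gene losses, and discordant histories, with deterministic
  ground truth; plus calibration/power harnesses.

Results come back as tibbles (with `tidy()`, `glance()` and `autoplot()`
methods), so they drop straight into dplyr/ggplot2 workflows.

## Worked example

Simulate a 20-group cohort in which 4 groups (20%) carry ω_fg = 4 on the
C4 branches, then run the full pipeline:

```r
library(c4scan)

cfg <- cohort_config(n_groups = 20, fraction_selected = 0.2, seed = 7)
coh <- generate_cohort(cfg)

pc  <- pipeline_config(sequences = coh$sequences, synteny = coh$synteny,
                       known_groups = coh$truth$group_id[coh$truth$selected],
                       seed = 1)
res <- run_pipeline(pc)
res
#> <c4_pipeline_result>
#>   input       20
#>   pattern_ok  20
#>   aligned     20
#>   congruent   18
#>   tested      18
#>   candidates  5
res$candidates
#> # A tibble: 5 × 6
#>   group_id best_condition    min_q omega_fg omega_bg n_significant
#>   <chr>             <int>    <dbl>    <dbl>    <dbl>         <int>
#> 1 g0007                 1 3.97e-16     5.32    0.144             8
#> 2 g0010                 1 3.83e-14     5.59    0.163             4
#> 3 g0002                 1 4.80e-12     2.76    0.147             8
#> 4 g0019                 1 3.76e- 9     2.38    0.199             8
#> 5 g0018                 5 2.24e- 4     1.47    0.156             2
res$enrichment
#> # A tibble: 1 × 5
#>   n_tested n_candidates n_known n_detected       p
#>      <int>        <int>   <int>      <int>   <dbl>
#> 1       18            5       4          4 0.00163
```

Reading this: the funnel shows 20 groups in, 2 excluded by the congruence
filter (the simulated discordant histories), 18 tested under the nine
conditions. All four truth-selected groups (g0002, g0007, g0010, g0019)
are recovered with tiny q-values and strongly elevated ω_fg against
ω_bg ≈ 0.15–0.2; g0018 is a false discovery of the kind an FDR-0.2
threshold tolerates. The exact hypergeometric test puts 4/4 known genes
among 5 candidates of 18 at P = 0.0016.

Lower-level entry points (`lrt_branch_model()`, `infer_gene_tree()`,
`congruence_test()`, `trim_blocks()`, `power_experiment()`, …) expose each
stage separately; `inst/cli/c4scan` wraps `simulate` / `run` / `report`
for shell use.

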