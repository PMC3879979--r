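# strandbalance

Why do bacterial genomes keep genes on the lagging strand, where head-on
collisions between DNA and RNA polymerase are mutagenic and costly? This
package implements the quantitative case that no adaptive explanation is
needed: a mutation–selection balance maintains lagging-strand genes, and
the substitution patterns cited as evidence of adaptation ("multihit"
amino acid sites) are what a neutral null already predicts once the
elevated substitution rate of lagging-strand genes is conditioned on.

It is aimed at molecular evolution researchers who want to (i) explore the
strand-orientation balance model and (ii) re-run multihit/parallel/
convergent site analyses on strain alignments — or on fully synthetic data
with known ground truth.

## The models

**Balance model.** With inversion mutation rates `u` (leading→lagging) and
`v` (reverse), and selective disadvantage `s` of lagging encoding, the
equilibrium probability that a gene is lagging-encoded solves
`(1−q)u = q(v+s)`:

    q = u / (u + v + s),   and for u = v:  q = 1 / (2 + s/u)

`equilibrium_q()` gives the analytic value; `iterate_deterministic()` runs
the generation-by-generation map (mutation, then purging of lagging
lineages at rate `s`); `simulate_wright_fisher()` is the stochastic
finite-`n` counterpart.

**Substitution re-analysis.** Per gene: Fitch small parsimony on a rooted
strain tree counts amino acid changes per alignment column
(`fitch_min_changes()`, `map_gene_changes()`), with exhaustive enumeration
of most-parsimonious reconstructions (`enumerate_mprs()`). Sites are
classified as variable / multihit / parallel / convergent
(`classify_site()`, `summarize_genes()`). The conditional null
(`null_distribution()`) redraws each gene's observed change count `C`
uniformly with replacement over its `V` variable sites and builds the
null distributions of the lagging:leading ratios `R_N` (multihit-site
totals) and `R_G` (multihit-gene counts). Fisher's exact test
(`fisher_exact_two_tail()`) handles parallel-change gene enrichment by
strand. A synthetic-data generator (`generate_dataset()`) with recorded
ground truth makes the whole pipeline testable end to end.

## Worked example

```r
library(strandbalance)

# the published strand-by-parallel gene counts: leading 10/303, lagging 3/34
fisher_exact_two_tail(rbind(c(10, 293), c(3, 31)))
#> [1] 0.1329005        # not significant: no parallel-change enrichment

equilibrium_q(1e-4, 1e-4, 2e-4)
#> [1] 0.25             # u = v, s/u = 2: a quarter of genes lagging at balance

# synthetic end-to-end run: 60 leading + 12 lagging genes, lagging genes
# evolving twice as fast, 2,000-replicate conditional nulls
cfg <- list(
  simulate = simulation_config(n_leading = 60, n_lagging = 12, seed = 42),
  resample = list(n_replicates = 2000, seed = 42))
report <- run_pipeline(cfg)
print(report)
#> <pipeline_report> 72/72 genes kept
#>   parallel-change genes: leading 0/60, lagging 0/12; Fisher two-sided P = 1
#>   [observed] R_N obs 0.733 (P = 0.59), R_G obs 0.692 (P = 0.049)
#>   [all] R_N obs 0.733 (P = 0.76), R_G obs 0.692 (P = 0.52)
```

Reading the output: the lagging strand has fewer multihit sites than the
leading strand in absolute terms (`R_N = 0.73`) simply because it has far
fewer genes; what matters is where the observed ratio falls within its
conditional null — here `R_N` sits comfortably inside the central 90%
(`P = 0.59`), i.e. the multihit content of lagging-strand genes is what
their own change counts already predict. `plot(report$nulls$observed)`
draws the null histograms with the observed ratios arrowed.

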