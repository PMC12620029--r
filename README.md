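# pinepop

Haploid-aware population genomics for conifer sequencing panels.

## The problem

Conifer genomes are huge and highly repetitive. Short reads from collapsed
paralogs align on top of each other and produce false heterozygous SNP
calls that inflate diversity estimates and blur population structure.
Conifer seeds, however, contain a haploid maternal tissue — the
megagametophyte — and *any* heterozygous call in a haploid library is by
definition an error. Panels that mix haploid (megagametophyte) and diploid
(needle) samples can therefore screen out paralog-collapse errors far more
aggressively than diploid data alone.

`pinepop` implements the full inference chain for such panels:

* **Variant QC** — four error criteria per SNP: (1) heterozygous in a
  haploid sample, (2) heterozygosity above 60%, (3) read-ratio deviation
  score `D = (A − N/2)/√(N/4)` beyond ±20 (HDplot), (4) exact
  Hardy–Weinberg failure (p < 0.05) in more than 3 of 8 diploid
  populations; error rates aggregated in 250 bp windows, windows above 10%
  excluded; depth/missingness filters, LD pruning (r² > 0.8 in 10 kb),
  random splitting of diploids into pseudo-haploids.
* **Diversity** — π by codon-degeneracy class (π₀, π₄, π₀/π₄), Tajima's D,
  folded site-frequency spectrum with hypergeometric projection to 50% of
  the sample size, Stairway-plot-2 blueprint export.
* **Structure** — Weir–Cockerham F_st (haploid and diploid designs),
  two-level AMOVA on pairwise mismatch distances, smartpca-style PCA, and
  shared-ancestry profiles as convex combinations of source-pool centroids
  in PC space (EIGMIX-style surrogate).
* **Gene flow** — Mantel tests of F_st/(1−F_st) against log geographic
  distance, Rousset's Nm = 1/slope with refugium-conditioned subsets, and
  Ennos pollen/seed flow ratios contrasting nuclear (biparental),
  mitochondrial (maternal, seed-dispersed) and chloroplast (paternal,
  pollen-dispersed in pines) differentiation.
* **Rare-allele sharing (PSRA)** — for individual *i*, source *j* and
  minor-allele count *c* in the pooled sources:
  `PSRA(c)_{i,j} = (1/n) Σ_l f_{l,j} / Σ_s f_{l,s}`
  over the n loci where *i* carries the minor allele; the three source
  shares sum to one by construction and converge to 1/3 for common
  alleles.
* **Organelles** — relaxed-depth filtering, Hamming distances, minimum
  spanning haplotype networks and Louvain communities (resolution 0.2).
* **Synthetic data** — a Balding–Nichols generator with admixture, rare
  alleles private to source pools, forward-simulated organelle
  compartments with separate seed and pollen migration, and paralog-error
  injection in 250 bp windows, all with recorded ground truth, so every
  stage is testable without any external data.

## Worked example

```r
library(pinepop)

cfg <- sim_config(n_pops = 8, samples_per_pop = 10, n_loci = 3000, seed = 7,
                  error_windows = list(n_windows = 10, window_len = 250,
                                       error_prob = 0.5),
                  spacing_bp = 50)
ds <- simulate_dataset(cfg)

fl <- qc_flags(ds$nuclear, ds$sheet)         # four error criteria
ws <- window_screen(fl, ds$nuclear)          # 250 bp windows, >10% excluded
g  <- depth_missing_filter(geno_subset(fl$geno, loci = ws$keep), ds$sheet)

fst  <- fst_matrix(g, ds$sheet)
am_m <- amova_two_level(organelle_filter(ds$mito),   ds$sheet)
am_c <- amova_two_level(organelle_filter(ds$chloro), ds$sheet)
d    <- tajimas_d(g, ds$sheet)
psra_summary(psra(g, ds$sheet,
                  list(southwest = "P01", italy = "P02",
                       carpathian = "P03")))
```

This prints (seed 7):

```
flagged 18 of 3000 loci; 9 of 600 windows excluded
mean pairwise Weir-Cockerham theta: 0.0519
AMOVA among-population %: mito 16.2 vs chloro 11.9
Tajimas D range across populations: [-0.52, -0.34]
   population     source      mean         sd n_cells
22        P08  southwest 0.3302861 0.07496568      80
23        P08      italy 0.3270778 0.06858320      80
24        P08 carpathian 0.3426362 0.08238366      80
```

Reading it: 9 of the 10 injected paralog windows are recovered by the
window screen (the tenth held too few corrupted SNPs to cross the 10%
rate); the multilocus θ ≈ 0.05 matches the simulated `fst_target`;
the maternally dispersed (mitochondrial) compartment is more
differentiated among populations than the pollen-dispersed chloroplast;
Tajima's D is negative everywhere (the generator's rare-allele excess);
and a population unrelated to any source pool shares rare alleles about
equally (≈ 1/3) with each of the three pools.

A command-line interface wraps the same stages
(`inst/cli/pinepop-cli.R`; subcommands `simulate`, `qc`, `diversity`,
`structure`, `geneflow`, `psra`, `organelle`, `sfs-export`, `run-all`).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the statistical
models, the synthetic-data generator's stated world and what it does and
does not emulate, numerical conventions, and known limitations.
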