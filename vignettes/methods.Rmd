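---
title: "Methods: models, conventions and design choices in pinepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in pinepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pinepop` analyses SNP panels from species whose genomes are large,
repetitive and — in conifers — accessible through a naturally haploid
tissue, the seed megagametophyte. This vignette documents the statistical
models the package implements, the conventions and tolerances it fixes
where the methods literature leaves latitude, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open.

## 1. Error model and variant QC

Collapsed paralogs superimpose reads from two loci onto one reference
position. The signature is (i) heterozygous calls in haploid samples,
where no true heterozygote can exist, (ii) excess heterozygosity in
diploids, (iii) allele-specific read ratios at heterozygotes far from 1:2,
and (iv) Hardy–Weinberg departures replicated across populations. The four
per-locus criteria are:

* **Haploid heterozygotes** (`flag_haploid_hets`). Any het call in a
  ploidy-1 sample flags the locus. Samples whose het count exceeds
  `median + 5·MAD` among haploids are treated as contaminated by diploid
  tissue: their het calls are set missing and do not by themselves flag
  loci. The multiplier is a design choice (the phenomenon is a gross
  outlier — contaminated samples carry orders of magnitude more hets); the
  MAD is used instead of the SD because the het-count distribution is
  itself contaminated.
* **Heterozygosity excess** (`het_excess`): observed het fraction among
  non-missing diploid calls strictly above 0.60.
* **Read-ratio deviation** (`read_ratio_D`): reads supporting the
  alternate allele pooled over all diploid heterozygotes at the locus,
  `D = (A − N/2)/√(N/4)`; |D| > 20 flags. The designated allele is the
  alternate; the sign is immaterial under the two-sided threshold.
* **Multi-population HWE** (`hwe_multi_pop`): an exact test (full
  enumeration of heterozygote counts given allele counts, no mid-p —
  robust at per-population n of 6–18). A locus is flagged when p < 0.05 in
  strictly more than 3 populations when ≥ 8 diploid populations exist, and
  proportionally more than `floor(3·n/8)` otherwise. The generalization is
  logged per run; the literal rule is recovered at n = 8.

A SNP is "erroneous" if **any** evaluable criterion flags it (union; a
SNP flagged by several criteria counts once). Criteria that cannot be
evaluated (no haploids, no diploids, no read depths, fewer than two
diploid populations) are explicitly *not evaluable*, never silently
all-false.

**Window screen.** Non-overlapping 250 bp windows are anchored at position
1 of each contig (the anchoring is a convention; nothing in the method
fixes it). A window with SNPs is excluded when its error rate is strictly
above 0.10; windows without SNPs are vacuously retained. The excluded
footprint is returned in bp so that monomorphic accessible length can be
reduced by the same rule when computing per-site diversity.

**Depth/missingness.** Diploid genotypes with depth < 6 become missing;
loci with > 60% overall missingness are dropped; then loci called in
< 50% of samples of any single population are dropped. The filter is
idempotent. The preliminary "≤ 75% missing" screen used when assembling
raw panels is treated as an upstream pre-pass, not re-applied here.

**LD pruning** uses squared dosage correlation on pairwise-complete
genotypes, pairs within 10 kb evaluated in position order; one member of
each r² > 0.8 pair survives, chosen uniformly with a seeded RNG.
Zero-variance loci are skipped. The pipeline prunes haploid and diploid
sample subsets separately and keeps loci surviving both, after which
diploids are split into two pseudo-haploids by assigning the two alleles
uniformly at random, independently across loci (linkage equilibrium
assumed); homozygotes are forced, so pooled allele counts are conserved
exactly.

## 2. Diversity, Tajima's D and the projected folded SFS

Per-site diversity for a degeneracy class is
`π = Σ_l 2 p̂ q̂ n/(n−1) / L_class`, with `n` the non-missing allele
copies at locus *l* and `L_class` the accessible (monomorphic +
polymorphic) length of the class. A 4-fold site is one where all three
substitutions are synonymous; 0-fold, none. Codons with ambiguous bases
are `other`.

Tajima's D uses the 1989 constants. With missing data the per-site terms
use site-specific `n` while the constants use the **median** `n` — the
missing-data convention is not specified by the statistic itself, so it is
fixed here and logged. A `projected` mode computes D from the
hypergeometrically projected spectrum instead; `raw` is the default.

The folded SFS projection distributes each segregating site's
hypergeometric mass `P(j | k, n, n_proj)` over projected counts, discards
mass on the monomorphic classes 0 and `n_proj`, and folds (`j` with
`n_proj − j`, the central class counted once). The default `n_proj` is
50% of the panel's haploid genome copies rounded **down to an even
number**, so folding is symmetric. Sites with fewer than `n_proj`
non-missing copies are skipped and reported; the ledger
`retained + discarded + skipped = segregating sites` holds exactly and is
asserted in the tests. The Stairway-plot-2 blueprint writer serializes the
spectrum with `L`, `mu` (default 15.9e-9 per bp per generation) and a
generation time (default 20 years); no demographic fitting is performed.

## 3. Structure: F_st, AMOVA, PCA, shared ancestry

**Weir–Cockerham θ** is the ratio of summed among-population variance
components to summed totals across loci. All-diploid designs use the full
1984 a/b/c components with the heterozygosity correction; haploid or
mixed designs collapse to a one-level ANOVA on allele frequencies (the b
and c terms vanish). Loci need ≥ 2 copies in every population to enter the
sums. Negative multilocus estimates are reported as computed — truncation
would bias downstream regressions.

**AMOVA** partitions pairwise mismatch counts (haplotypic distance —
the convention matching distance-based AMOVA defaults for multilocus
haploid data) into among- and within-population components; percentages
sum to 100. Diploids must be split first; a single population leaves the
among component undefined rather than zero.

**PCA** standardizes each locus by `√(p(1−p))` after mean-centring,
imputes missing entries to the locus mean, drops monomorphic loci and
eigendecomposes the sample covariance. Scores are eigenvectors scaled by
the square root of their eigenvalues, so Euclidean geometry in score space
reflects genetic covariance.

**Shared ancestry.** Each sample's position in the first 20 PCs is
expressed as the *closest convex combination* of source-pool centroids —
least squares constrained to the probability simplex, solved exactly by
active-subset enumeration. This is an operational surrogate for
eigen-decomposition ancestry estimators (EIGMIX-style): only the use of
the leading PC subspace and reference pools is prescribed, not the exact
estimator, and the surrogate is validated by parameter recovery on
simulated admixture (50/50 mixtures recovered within ±0.05 at 10,000
loci). Plain NNLS followed by renormalization was rejected: for samples
near the PC origin all coefficients shrink to zero and the renormalized
weights are undefined, whereas the simplex fit is stable everywhere.
Collinear centroids are flagged non-identifiable.

## 4. Gene flow

Isolation by distance linearizes differentiation as `F_st/(1−F_st)` and
regresses it on the natural log of great-circle distance (haversine,
Earth radius 6371 km); `Nm = 1/slope` when the slope is positive,
otherwise undefined with a diagnostic. Same-location pairs are excluded
(log 0). Negative pairwise θ values are linearized as computed — dropping
or truncating them would bias the slope. Refugium subsets keep pairs with
exactly one member in a focal source pool. The Mantel test correlates
off-diagonal entries with a two-sided permutation p-value
`(1 + #{|r*| ≥ |r|})/(n_perm + 1)` under seeded joint row/column
permutations; its type-I error is verified by simulation (rejection rate
at α = 0.05 within [0.03, 0.07] over 500 null replicates).

The Ennos ratios contrast marker transmission modes at island-model
equilibrium: with biparental + maternal markers
`r5 = ((1/f_b − 1) − 2(1/f_m − 1))/(1/f_m − 1)`; with paternal + maternal
markers `r6 = (1/f_p − 1)/(1/f_m − 1) − 1` (the paternal marker moves via
both pollen and seed, hence the −1). Inputs must lie strictly in (0,1);
negative ratios are returned with a model-violation warning.

## 5. Rare-allele sharing (PSRA)

The minor-allele count *c* of each locus is computed **once** from the
pooled source samples (ties between the two alleles resolve to the
alternate allele and are flagged; query individuals never alter *c*). For
individual *i* and count class *c*, the statistic averages, over the loci
where *i* carries the minor allele (dosage ≥ 1 — carrier status, not
dosage weighting: the formula counts loci, not copies), each source's
share of the summed source frequencies. The shares sum to one exactly,
which the tests assert at 1e-9. Loci whose minor allele is absent from
every source (possible only for query carriers) would make the share 0/0
and are excluded from *n*. Source members are evaluated against their own
pools without leave-one-out correction, matching the estimator's plain
form; a leave-one-out mode exists but is off by default. Cells with
`n = 0` are reported missing, never zero. Only classes `c` from 1 to 8
are summarized: beyond that the shares converge to 1/3 and carry no
signal.

## 6. Organelle haplotypes

Organellar data is haploid, so the filter marks heterozygous calls
missing, drops loci where any het was observed, then applies the sample
(≤ 25% missing) and locus (≤ 25% missing) rules — in that fixed order;
order matters and is documented rather than configurable. No depth floor
is applied (organelle coverage is low). Hamming distances count
mismatching jointly-called loci; pairs sharing under half the loci are
flagged low-confidence, and the triangle inequality may fail under
missingness (flagged, not repaired).

The haplotype network is a minimum spanning network: at each distance
level, every edge of that length joining components that were distinct
when the level started is kept (the MST plus all ties, deterministically —
no randomized tie handling). Louvain communities are detected at
resolution 0.2. Louvain treats edge weight as affinity, while mutation
counts are distances, so edges are weighted `1/(1 + d)`; feeding raw
mutation counts as weights would invert the community semantics. This
transform is a potential divergence from analyses that passed counts
directly and is flagged as such.

## 7. The synthetic world

The generator's defaults describe the panel the statistics assume:

* 10 populations × 10 samples, haploid by default, 5,000 loci on
  synthetic 10 kb contigs (one SNP per 100 bp unless configured);
* Balding–Nichols differentiation `fst_target = 0.05` around ancestral
  frequencies Uniform(0.05, 0.95) — the bounded support avoids the
  boundary degeneracy of the Beta moments;
* three single-population source pools (`southwest`, `italy`,
  `carpathian`), with 25% of loci overwritten as minor alleles private to
  one pool at frequency ≤ 0.1 — a post-hoc overwrite rather than a
  coalescent simulation, so PSRA ground truth is exact;
* a rare-allele excess: 80% of loci draw their ancestral frequency from
  Uniform(0.01, 0.10). The magnitude of the excess is a free parameter of
  the stated world; 0.8 was fixed once so per-population Tajima's D falls
  in the post-expansion range (−1, 0) and was not revisited. Without this
  layer, Balding–Nichols sampling alone yields slightly positive D;
* organelle compartments simulated **forward in time on haplotype
  frequencies** (100 generations, deme size 200, 8 founder haplotypes on
  a simulated coalescent genealogy so Hamming distances count mutations):
  the maternal compartment migrates at `m_seed = 0.001` per generation,
  the paternal at `m_seed + m_pollen = 0.021`. Forward simulation (not a
  coalescent) was chosen for direct control of the seed/pollen contrast.
  Deme size 200 makes the among-population variance contrast between
  compartments (the qualitative analogue of strong mitochondrial vs weak
  chloroplast structure) hold in ≥ 95% of replicates;
* paralog errors injected in chosen 250 bp windows: haploid samples gain
  het calls (probability 0.5 each), diploid heterozygosity inflates to
  ~0.7, allelic ratios skew to 0.15, at per-locus corruption probability
  0.5;
* Poisson read depth (mean 20), binomial allelic depths, 2% random
  missingness; coordinates on a southwest→northeast diagonal so
  geographic distances are non-degenerate.

Every stochastic choice downstream stages estimate — ancestral and
per-population frequencies, rare-allele assignments, admixture weights,
migration rates, error-window coordinates — is recorded in `truth`.
Identical configs (including seed) give bit-identical output, and the
generators restore the caller's RNG state.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: linkage disequilibrium within contigs (loci are
independent, so LD pruning is exercised only by explicitly duplicated
loci), selection, spatially structured nuclear gene flow (nuclear
populations are exchangeable; isolation by distance arises only in the
organelle stepping-stone mode), sequencing error outside the paralog
model, multi-allelic sites and indels, and reference bias. Equilibrium
site-frequency spectra come from a separate coalescent generator
(`simulate_neutral_pop`), not from the Balding–Nichols layer.

## 8. Numerical conventions

* Strict inequalities at every printed threshold: het fraction > 0.60,
  |D| > 20, window error rate > 0.10, depth < 6, "more than 3"
  populations.
* Exact-test p-values sum outcome probabilities ≤ the observed one with a
  1e-12 slack against floating-point ties.
* PSRA normalization is asserted at 1e-9; oracle equivalences (θ, D, π,
  window screen, hypergeometric masses) at 1e-10 or tighter.
* Coordinates are 1-based in VCF, 0-based half-open in BED, stated in the
  writers.
* All seeds derive from a single master seed through a fixed affine map
  kept below 2^31.
* Degenerate inputs return explicit states: "not evaluable" flag sets,
  `NA` Tajima's D without segregating sites, undefined Nm on non-positive
  slopes, `single-deme` AMOVA, non-identifiable ancestry on collinear
  centroids.

## 9. Known limitations

* The shared-ancestry estimator is a PC-space surrogate, not the exact
  eigen-analysis estimator it stands in for; profiles agree on simulated
  admixture but may differ on real data with strong LD or unbalanced
  pools.
* Mixed haploid/diploid F_st uses the allele-level design, which ignores
  the within-individual component the diploid-only estimator would model.
* The Mantel permutation loop is quadratic in populations; panels of
  hundreds of demes would need a compiled path.
* `hwe_exact_p` enumerates heterozygote counts per locus and population;
  it is exact but not vectorized across loci with shared allele counts.
* The organelle forward model tracks haplotype frequencies only; it
  cannot generate new mutations during the simulated epoch, so haplotype
  richness is bounded by the founder set.
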