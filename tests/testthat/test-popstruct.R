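test_that("Weir-Cockerham theta: fixed differences and identical pools", {
  # two haploid populations fixed for alternative alleles -> theta = 1
  g <- make_geno(rbind(matrix(0L, 5, 4), matrix(2L, 5, 4)),
                 ploidy = rep(1, 10))
  sheet <- sheet_for(g, rep(c("A", "B"), each = 5))
  expect_equal(wc_fst(g, sheet, "A", "B"), 1)
  # identical allele counts in both populations -> theta <= 0 and small
  gt <- rbind(matrix(c(0L, 2L), 5, 4), matrix(c(0L, 2L), 5, 4))
  g2 <- make_geno(gt, ploidy = rep(1, 10))
  th <- wc_fst(g2, sheet_for(g2, rep(c("A", "B"), each = 5)), "A", "B")
  expect_lte(th, 0)
  expect_lt(abs(th), 0.35)
  # no shared informative loci -> undefined
  g3 <- make_geno(matrix(c(NA, NA, 0L, 2L), 4, 1), ploidy = rep(1, 4))
  expect_true(is.na(wc_fst(g3, sheet_for(g3, rep(c("A", "B"), each = 2)),
                           "A", "B")))
})

test_that("theta matches the literal 1984 transcription oracles", {
  set.seed(20)
  # haploid design, 3 random instances
  for (rep in 1:3) {
    n_per <- c(8, 12)
    p <- runif(50, 0.1, 0.9)
    al <- lapply(n_per, function(n)
      matrix(rbinom(n * 50, 1, rbeta(50, p * 9, (1 - p) * 9)[col(matrix(0, n, 50))]), n, 50))
    gt <- do.call(rbind, lapply(al, function(m) 2L * m))
    g <- make_geno(gt, ploidy = rep(1, sum(n_per)))
    sheet <- sheet_for(g, rep(c("A", "B"), n_per))
    expect_equal(wc_fst(g, sheet, "A", "B"), oracle_wc_haploid(al),
                 tolerance = 1e-12)
  }
  # diploid design with heterozygotes and missing data
  for (rep in 1:3) {
    n_per <- c(10, 7)
    gts <- lapply(n_per, function(n) {
      m <- matrix(rbinom(n * 40, 2, runif(40, .2, .8)[col(matrix(0, n, 40))]),
                  n, 40)
      m[sample(length(m), 10)] <- NA
      m
    })
    g <- make_geno(do.call(rbind, gts), ploidy = rep(2, sum(n_per)))
    sheet <- sheet_for(g, rep(c("A", "B"), n_per))
    expect_equal(wc_fst(g, sheet, "A", "B"),
                 oracle_wc_diploid(gts), tolerance = 1e-12)
  }
})

test_that("theta is symmetric and invariant under allele relabeling", {
  set.seed(21)
  gt <- matrix(sample(c(0L, 2L), 200, TRUE), 20, 10)
  g <- make_geno(gt, ploidy = rep(1, 20))
  sheet <- sheet_for(g, rep(c("A", "B"), each = 10))
  expect_equal(wc_fst(g, sheet, "A", "B"), wc_fst(g, sheet, "B", "A"))
  g2 <- make_geno(2L - gt, ploidy = rep(1, 20))
  expect_equal(wc_fst(g2, sheet_for(g2, rep(c("A", "B"), each = 10)),
                      "A", "B"),
               wc_fst(g, sheet, "A", "B"), tolerance = 1e-12)
  fm <- fst_matrix(g, sheet)
  expect_equal(fm, t(fm))
  expect_equal(diag(fm), c(A = 0, B = 0))
})

test_that("AMOVA percentages behave at the extremes and sum to 100", {
  # two populations fixed different -> 100% among
  g <- make_geno(rbind(matrix(0L, 6, 5), matrix(2L, 6, 5)),
                 ploidy = rep(1, 12))
  sheet <- sheet_for(g, rep(c("A", "B"), each = 6))
  am <- amova_two_level(g, sheet)
  expect_equal(unname(am$percent[["among"]]), 100)
  expect_equal(sum(am$percent), 100, tolerance = 1e-9)

  # panmictic simulation -> among ~ 0
  cfg <- sim_config(n_pops = 4, samples_per_pop = 12, n_loci = 5000,
                    fst_target = 0, rare_private_fraction = 0,
                    rare_excess_fraction = 0, miss_rate = 0, seed = 6)
  nuc <- simulate_nuclear(cfg)
  am0 <- amova_two_level(nuc$geno, nuc$sheet)
  expect_lt(abs(am0$percent[["among"]]), 2)
  expect_equal(sum(am0$percent), 100, tolerance = 1e-9)
  # diploids must be split first
  gd <- make_geno(matrix(0L, 2, 2), ploidy = c(2, 2))
  expect_error(amova_two_level(gd, sheet_for(gd, c("A", "B"))),
               "split_diploids")
})

test_that("AMOVA among-% and mean theta rise with fst_target", {
  amp <- c(); tht <- c()
  for (f in c(0.01, 0.05, 0.1, 0.2)) {
    cfg <- sim_config(n_pops = 5, samples_per_pop = 10, n_loci = 1500,
                      fst_target = f, rare_private_fraction = 0,
                      rare_excess_fraction = 0, miss_rate = 0, seed = 30)
    nuc <- simulate_nuclear(cfg)
    am <- amova_two_level(nuc$geno, nuc$sheet)
    fm <- fst_matrix(nuc$geno, nuc$sheet)
    amp <- c(amp, am$percent[["among"]])
    tht <- c(tht, mean(fm[upper.tri(fm)]))
  }
  expect_true(all(diff(amp) > 0))
  expect_true(all(diff(tht) > 0))
})

test_that("PCA separates pools, deduplicates and bounds variance", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 15, n_loci = 800,
                    fst_target = 0.3, rare_private_fraction = 0,
                    rare_excess_fraction = 0, miss_rate = 0, seed = 8,
                    source_pools = NULL)
  nuc <- simulate_nuclear(cfg)
  pc <- pca_genotypes(nuc$geno)
  pop <- nuc$sheet$population
  s1 <- pc$scores[pop == "P01", 1]
  s2 <- pc$scores[pop == "P02", 1]
  expect_true(max(min(s1), min(s2)) > min(max(s1), max(s2)) ||
                min(s1) > max(s2) || min(s2) > max(s1))
  expect_lte(sum(pc$varfrac), 1 + 1e-9)
  # duplicated samples get identical scores
  gt <- nuc$geno$gt[c(1, 1, 5, 9), ]
  rownames(gt) <- paste0("s", 1:4)
  gdup <- make_geno(gt, ploidy = rep(1, 4),
                    pos = nuc$geno$pos, chrom = nuc$geno$chrom)
  pd <- pca_genotypes(gdup, n_pcs = 2)
  expect_equal(pd$scores[1, ], pd$scores[2, ], tolerance = 1e-8)
  # monomorphic-only input fails
  gm <- make_geno(matrix(0L, 4, 3), ploidy = rep(1, 4))
  expect_error(pca_genotypes(gm), "polymorphic")
})

test_that("ancestry profiles: centroid identity, normalization, NNLS", {
  # toy geometry: two pool centroids, an individual sitting on one
  scores <- rbind(c(0, 0), c(0.2, -0.2), c(10, 0), c(9.8, 0.2),
                  c(0.1, -0.1), c(5, 0))
  rownames(scores) <- paste0("s", 1:6)
  colnames(scores) <- c("PC1", "PC2")
  sheet <- data.frame(sample = rownames(scores),
                      population = c("A", "A", "B", "B", "A", "Q"),
                      stringsAsFactors = FALSE)
  prof <- eigmix_ancestry(scores, sheet, list(a = "A", b = "B"), n_pcs = 2)
  expect_equal(unname(rowSums(prof$weights)), rep(1, 6), tolerance = 1e-9)
  expect_gt(prof$weights["s1", "a"], 0.95)
  expect_gt(prof$weights["s3", "b"], 0.95)
  # midpoint individual splits about evenly
  expect_equal(unname(prof$weights["s6", "a"]), 0.5, tolerance = 0.06)
  # pools with < 2 samples rejected
  expect_error(eigmix_ancestry(scores, sheet, list(a = "A", q = "Q")),
               ">= 2 samples")
  # collinear centroids flagged
  sc2 <- cbind(PC1 = c(0, 0, 1, 1, 2, 2), PC2 = 0)
  rownames(sc2) <- paste0("t", 1:6)
  sh2 <- data.frame(sample = rownames(sc2),
                    population = rep(c("A", "B", "C"), each = 2))
  pr2 <- eigmix_ancestry(sc2, sh2, list(a = "A", b = "B", c = "C"),
                         n_pcs = 2)
  expect_true(pr2$non_identifiable)
})
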