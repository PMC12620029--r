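# genotype codes: 0 hom-ref, 1 het, 2 hom-alt, NA missing (diploid-coded)

test_that("haploid heterozygote flagging follows the definition", {
  gt <- rbind(c(1, 0, 2, 0),   # haploid with a het at locus 1
              c(0, 0, 2, NA),  # haploid, clean
              c(1, 1, 0, 0))   # diploid hets are not errors
  g <- make_geno(gt, ploidy = c(1, 1, 2))
  r <- flag_haploid_hets(g)
  expect_true(r$evaluable)
  expect_equal(unname(r$flags), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(r$sample_het), c(1, 0))

  # all-homozygous haploids: zero flags
  g2 <- make_geno(rbind(c(0, 2), c(2, 0)), ploidy = c(1, 1))
  expect_equal(sum(flag_haploid_hets(g2)$flags), 0)

  # no haploid samples: explicit not-evaluable state
  g3 <- make_geno(rbind(c(1, 1), c(0, 2)), ploidy = c(2, 2))
  r3 <- flag_haploid_hets(g3)
  expect_false(r3$evaluable)
  expect_null(r3$flags)
})

test_that("contaminated haploids are masked, not used to flag loci", {
  set.seed(1)
  n <- 200; L <- 400
  gt <- matrix(0L, n, L)
  # 8 contaminated samples with many hets; everyone else clean
  bad <- 1:8
  for (s in bad) gt[s, sample(L, 60)] <- 1L
  g <- make_geno(gt, ploidy = rep(1, n))
  r <- flag_haploid_hets(g)
  expect_length(r$outliers, 8)
  expect_setequal(r$outliers, rownames(g$gt)[bad])
  # loci het only in contaminated samples are not flagged...
  expect_equal(sum(r$flags), 0)
  # ...and their het calls became missing
  expect_true(all(is.na(r$geno$gt[bad, ][gt[bad, ] == 1L])))
})

test_that("heterozygosity excess uses a strict 60% threshold", {
  gt7 <- rbind(matrix(1L, 7, 1), matrix(0L, 3, 1))  # 7 of 10 hets
  g <- make_geno(cbind(gt7, rbind(matrix(1L, 6, 1), matrix(0L, 4, 1)),
                       matrix(0L, 10, 1)),
                 ploidy = rep(2, 10))
  f <- het_excess(g)
  expect_equal(unname(f), c(TRUE, FALSE, FALSE)) # 0.7 > 0.6; 0.6 not > 0.6
  # zero non-missing diploid calls: not evaluable
  g2 <- make_geno(matrix(NA_integer_, 3, 1), ploidy = rep(2, 3))
  expect_true(is.na(het_excess(g2)))
})

test_that("read-ratio deviation matches the binomial z-score", {
  # helper to build one locus with given pooled het depths
  one <- function(A, N) {
    gt <- matrix(1L, 1, 1)
    dp <- matrix(as.integer(N), 1, 1)
    ad <- matrix(as.integer(A), 1, 1)
    make_geno(gt, ploidy = 2, dp = dp, ad_alt = ad)
  }
  expect_equal(unname(read_ratio_D(one(50, 100))$D), 0)
  expect_equal(unname(read_ratio_D(one(80, 100))$D), 6)
  expect_equal(unname(read_ratio_D(one(400, 500))$D), 150 / sqrt(125))
  expect_false(unname(read_ratio_D(one(400, 500))$flags))  # 13.42 < 20
  expect_true(unname(read_ratio_D(one(90, 100))$flags) %in% FALSE) # D = 8
  # no heterozygotes: undefined
  g <- make_geno(matrix(0L, 2, 1), ploidy = c(2, 2),
                 dp = matrix(10L, 2, 1), ad_alt = matrix(0L, 2, 1))
  expect_true(is.na(read_ratio_D(g)$D))
})

test_that("exact HWE p-values match the enumeration oracle", {
  cases <- rbind(c(5, 0, 5), c(3, 4, 3), c(0, 10, 0), c(8, 2, 0),
                 c(2, 5, 9), c(1, 1, 1), c(6, 6, 6), c(0, 1, 7))
  for (i in seq_len(nrow(cases))) {
    expect_equal(pinepop:::hwe_exact_p(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle_hwe_p(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-12,
                 info = paste(cases[i, ], collapse = "/"))
  }
  # monomorphic: p = 1
  expect_equal(pinepop:::hwe_exact_p(10, 0, 0), 1)
})

test_that("multi-population HWE rule counts strictly more than 3 of 8", {
  # build 8 diploid populations of 10; locus 1 grossly out of HWE in 4
  # pops, locus 2 in exactly 3, locus 3 in perfect proportions
  set.seed(2)
  mk_pop <- function(bad1, bad2) {
    l1 <- if (bad1) c(rep(0L, 5), rep(2L, 5)) else c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
    l2 <- if (bad2) c(rep(0L, 5), rep(2L, 5)) else c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
    l3 <- c(rep(0L, 3), rep(1L, 4), rep(2L, 3))
    cbind(l1, l2, l3)
  }
  gts <- do.call(rbind, lapply(1:8, function(k) mk_pop(k <= 4, k <= 3)))
  g <- make_geno(gts, ploidy = rep(2, 80))
  sheet <- sheet_for(g, rep(sprintf("P%02d", 1:8), each = 10))
  r <- hwe_multi_pop(g, sheet)
  expect_true(r$evaluable)
  expect_equal(r$threshold, 3)
  expect_equal(unname(r$flags), c(TRUE, FALSE, FALSE))
  # proportional threshold with fewer diploid populations: floor(3*4/8) = 1
  g4 <- make_geno(gts[1:40, ], ploidy = rep(2, 40))
  sheet4 <- sheet_for(g4, rep(sprintf("P%02d", 1:4), each = 10))
  expect_equal(hwe_multi_pop(g4, sheet4)$threshold, 1)
  # fewer than 2 diploid populations: not evaluable
  g1 <- make_geno(gts[1:10, ], ploidy = rep(2, 10))
  expect_false(hwe_multi_pop(g1, sheet_for(g1, rep("P01", 10)))$evaluable)
})

test_that("window screen boundaries and brute-force equivalence", {
  # 10 SNPs in one window: 2 flagged -> excluded; 1 flagged -> retained
  g <- make_geno(matrix(0L, 2, 20), ploidy = c(1, 1),
                 pos = c(1:10 * 20, 251 + 0:9 * 20))
  flags <- c(rep(FALSE, 8), TRUE, TRUE, TRUE, rep(FALSE, 9))
  ws <- window_screen(flags, g)
  expect_equal(ws$windows$error_rate, c(0.2, 0.1))
  expect_equal(ws$windows$excluded, c(TRUE, FALSE))
  expect_equal(sum(ws$keep), 10)
  expect_equal(ws$excluded_bp, 250)
  expect_equal(ws$windows$start, c(0L, 250L))

  # property: equivalence with a direct per-window recount
  set.seed(42)
  for (rep in 1:5) {
    L <- 500
    chrom <- sprintf("ctg%02d", sample(1:3, L, replace = TRUE))
    pos <- integer(L)
    for (ct in unique(chrom)) {
      k <- sum(chrom == ct)
      pos[chrom == ct] <- sort(sample(1:5000, k))
    }
    o <- order(chrom, pos)
    chrom <- chrom[o]; pos <- pos[o]
    fl <- runif(L) < 0.15
    gg <- make_geno(matrix(0L, 2, L), ploidy = c(1, 1),
                    chrom = chrom, pos = pos)
    ws <- window_screen(fl, gg)
    expect_equal(ws$keep, oracle_window_screen(chrom, pos, fl))
  }
})

test_that("depth/missingness filter boundaries and idempotence", {
  gt <- matrix(2L, 10, 3)
  dp <- matrix(10L, 10, 3)
  dp[1, 1] <- 5L   # below 6: set missing (diploid)
  dp[2, 1] <- 6L   # kept
  g <- make_geno(gt, ploidy = rep(2, 10), dp = dp)
  sheet <- sheet_for(g, rep(c("A", "B"), each = 5))
  f <- depth_missing_filter(g, sheet)
  expect_true(is.na(f$gt[1, 1]))
  expect_equal(f$gt[2, 1], 2L)
  # idempotence
  f2 <- depth_missing_filter(f, sheet)
  expect_identical(f$gt, f2$gt)

  # per-population call-rate rule: locus called in 40% of pop A dropped
  gt2 <- matrix(2L, 10, 2)
  gt2[1:3, 1] <- NA  # pop A call rate 2/5 = 0.4 < 0.5
  g2 <- make_geno(gt2, ploidy = rep(1, 10))
  f3 <- depth_missing_filter(g2, sheet_for(g2, rep(c("A", "B"), each = 5)))
  expect_equal(ncol(f3$gt), 1)

  # overall missingness rule: > 60% missing dropped, 60% retained
  gt3 <- matrix(2L, 10, 2)
  gt3[1:7, 1] <- NA  # 70%
  gt3[1:6, 2] <- NA  # 60%
  g3 <- make_geno(gt3, ploidy = rep(1, 10))
  f4 <- depth_missing_filter(g3, sheet_for(g3, rep("A", 10)), pop_call = 0)
  expect_equal(ncol(f4$gt), 1)

  # an all-complete matrix passes unchanged
  g4 <- make_geno(matrix(0:1 * 2L, 4, 5), ploidy = rep(1, 4))
  expect_identical(depth_missing_filter(g4, sheet_for(g4, rep("A", 4)))$gt,
                   g4$gt)
})

test_that("LD pruning removes exactly one of a duplicated pair", {
  set.seed(3)
  x <- rbinom(40, 1, 0.5) * 2L
  y <- rbinom(40, 1, 0.5) * 2L
  g <- make_geno(cbind(x, x, y), ploidy = rep(1, 40),
                 pos = c(100L, 200L, 300L))
  p <- ld_prune(g, seed = 9)
  expect_equal(ncol(p$gt), 2)            # one duplicate dropped
  expect_true("y" %in% colnames(p$gt))   # independent SNP survives
  # determinism
  p2 <- ld_prune(g, seed = 9)
  expect_identical(colnames(p$gt), colnames(p2$gt))
  # far-apart duplicates (outside the window) both survive
  g2 <- make_geno(cbind(x, x), ploidy = rep(1, 40),
                  pos = c(100L, 20000L))
  expect_equal(ncol(ld_prune(g2, seed = 1)$gt), 2)
})

test_that("diploid splitting conserves allele counts exactly", {
  set.seed(4)
  gt <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  g <- make_geno(gt, ploidy = c(1, 2, 2, 1, 2, 2))
  s <- split_diploids(g, seed = 5)
  expect_true(all(s$ploidy == 1))
  expect_equal(nrow(s$gt), 2 + 2 * 4)
  # forced homozygotes
  hom <- which(gt[2, ] == 2L)
  expect_true(all(s$gt[c("S002__a", "S002__b"), hom] == 2L))
  # per-locus allele count conservation (pooled frequency invariance)
  af_in <- allele_freq(g)
  af_out <- allele_freq(s)
  expect_equal(af_in$alt_count, af_out$alt_count)
  expect_equal(af_in$n, af_out$n)
  # heterozygote alleles split one each way
  het <- which(gt[2, ] == 1L)
  expect_true(all(s$gt["S002__a", het] + s$gt["S002__b", het] == 2L))
  expect_true(all(s$gt["S002__a", het] %in% c(0L, 2L)))
})

test_that("qc_flags union honours not-evaluable criteria", {
  gt <- rbind(c(1, 0), c(0, 2))  # haploid het at locus 1
  g <- make_geno(gt, ploidy = c(1, 1))
  sheet <- sheet_for(g, c("A", "B"))
  fl <- qc_flags(g, sheet)  # no diploids: het/hwe/D not evaluable
  expect_equal(unname(fl$union), c(TRUE, FALSE))
  expect_null(fl$hwe)
})
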