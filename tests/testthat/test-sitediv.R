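test_that("codon degeneracy classification matches the code table", {
  # GGA (Gly): third position 4-fold; ATG (Met): first position 0-fold;
  # TGG (Trp): third position 0-fold
  expect_equal(classify_degeneracy("GGA")[3], "fold4")
  expect_equal(classify_degeneracy("ATG")[1], "fold0")
  expect_equal(classify_degeneracy("TGG")[3], "fold0")
  # ambiguous bases: whole codon -> other
  expect_equal(classify_degeneracy("GGN"), rep("other", 3))
  # frame offset: skipped bases are "other"
  expect_equal(classify_degeneracy("AGGA", frame = 1)[1], "other")
  expect_equal(classify_degeneracy("AGGA", frame = 1)[4], "fold4")
  # minus strand: classify the reverse complement, report input order
  # revcomp of TCC is GGA -> pos 1 of input is codon pos 3 -> fold4
  expect_equal(classify_degeneracy("TCC", strand = "-")[1], "fold4")

  # exhaustive property vs an independent enumeration over all codons
  nts <- c("A", "C", "G", "T")
  code <- Biostrings::GENETIC_CODE
  for (codon in apply(expand.grid(nts, nts, nts), 1, paste, collapse = "")) {
    got <- classify_degeneracy(codon)
    cod <- strsplit(codon, "")[[1]]
    for (w in 1:3) {
      syn <- sum(vapply(setdiff(nts, cod[w]), function(nt) {
        c2 <- cod; c2[w] <- nt
        code[[paste(c2, collapse = "")]] == code[[codon]]
      }, logical(1)))
      want <- if (syn == 3) "fold4" else if (syn == 0) "fold0" else "other"
      expect_equal(got[w], want, info = paste(codon, w))
    }
  }
})

test_that("site_annotation enforces accessible length >= SNP count", {
  expect_error(site_annotation(rep("fold4", 5), c(fold4 = 3)), "below")
  ann <- site_annotation(c("fold4", "fold0"), c(fold4 = 10, fold0 = 50))
  expect_s3_class(ann, "site_annotation")
})

test_that("pi matches the definition and the pairwise oracle", {
  # 2 haploids, 1 difference, L = 10 -> 0.1
  g <- make_geno(rbind(c(0, 0), c(2, 0)), ploidy = c(1, 1))
  ann <- site_annotation(rep("fold4", 2), c(fold4 = 10))
  sheet <- sheet_for(g, rep("A", 2))
  expect_equal(unname(pi_diversity(g, sheet, ann, "fold4")), 0.1)
  # identical sequences -> 0
  g0 <- make_geno(rbind(c(2, 0), c(2, 0)), ploidy = c(1, 1))
  expect_equal(unname(pi_diversity(g0, sheet_for(g0, rep("A", 2)), ann)), 0)

  # random instances vs brute-force pair averaging (with missing data)
  set.seed(10)
  for (rep in 1:4) {
    n <- 8; L <- 30
    gt <- matrix(sample(c(0L, 2L, NA), n * L, replace = TRUE,
                        prob = c(.5, .4, .1)), n, L)
    gg <- make_geno(gt, ploidy = rep(1, n))
    annr <- site_annotation(rep("fold4", L), c(fold4 = 100))
    hap <- gt / 2
    expect_equal(unname(pi_diversity(gg, sheet_for(gg, rep("A", n)), annr)),
                 oracle_pi(hap, 100), tolerance = 1e-12)
  }
  # zero accessible length is an error
  expect_error(pi_diversity(g, sheet, site_annotation(rep("fold4", 2),
                                                      c(fold4 = 0))),
               "accessible")
})

test_that("pi ratio handles degenerate numerators and denominators", {
  L <- 8
  gt <- rbind(rep(0L, L), c(2L, rep(0L, L - 1)))
  g <- make_geno(gt, ploidy = c(1, 1))
  sheet <- sheet_for(g, rep("A", 2))
  # the only SNP is fold4: pi0 = 0 -> ratio 0
  ann <- site_annotation(c("fold4", rep("fold0", L - 1)),
                         c(fold4 = 10, fold0 = 10))
  expect_equal(unname(pi_ratio(g, sheet, ann)), 0)
  # equal diversities -> 1: one fold0 and one fold4 SNP, equal L
  gt2 <- rbind(c(0L, 0L), c(2L, 2L))
  g2 <- make_geno(gt2, ploidy = c(1, 1))
  ann2 <- site_annotation(c("fold4", "fold0"), c(fold4 = 7, fold0 = 7))
  expect_equal(unname(pi_ratio(g2, sheet_for(g2, rep("A", 2)), ann2)), 1)
})

test_that("Tajima's D matches the textbook oracle and sign properties", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 10; L <- 40
    hap <- matrix(rbinom(n * L, 1, runif(1, 0.1, 0.5)), n, L)
    g <- make_geno(2L * hap, ploidy = rep(1, n))
    expect_equal(tajimas_d(g), oracle_tajima(hap), tolerance = 1e-10)
  }
  # singleton-only spectrum is negative
  hap <- matrix(0L, 10, 12)
  hap[cbind(rep(1:6, 2), 1:12)] <- 1L  # two singletons per carrier sample
  hap <- apply(hap, 2, function(col) { col[] <- 0L; col })  # reset
  for (l in 1:12) hap[sample(10, 1), l] <- 1L
  g <- make_geno(2L * hap, ploidy = rep(1, 10))
  expect_lt(tajimas_d(g), 0)
  # no segregating sites: undefined
  g0 <- make_geno(matrix(0L, 5, 4), ploidy = rep(1, 5))
  expect_true(is.na(tajimas_d(g0)))
  # projected mode runs and stays finite
  gp <- simulate_neutral_pop(12, 40, seed = 2)
  expect_true(is.finite(tajimas_d(gp, mode = "projected", n_proj = 6)))
})

test_that("hypergeometric projection matches enumeration exactly", {
  # k=2 of n=4 projected to 2: 4/6 at class 1, 2/6 discarded
  g <- make_geno(matrix(c(0L, 0L, 2L, 2L), 4, 1), ploidy = rep(1, 4))
  sfs <- folded_sfs_project(g, n_proj = 2)
  expect_equal(sfs$counts, 4 / 6)
  expect_equal(sfs$ledger$discarded, 2 / 6)
  expect_equal(sfs$ledger$retained + sfs$ledger$discarded +
                 sfs$ledger$skipped, sfs$ledger$n_seg)

  # identity projection: complete data, n_proj = n
  set.seed(12)
  hap <- matrix(rbinom(8 * 50, 1, 0.3), 8, 50)
  g2 <- make_geno(2L * hap, ploidy = rep(1, 8))
  sfs2 <- folded_sfs_project(g2, n_proj = 8)
  mac <- pmin(colSums(hap), 8 - colSums(hap))
  raw <- tabulate(mac[mac > 0], nbins = 4)
  expect_equal(sfs2$counts, as.numeric(raw))

  # masses match the combinatorial oracle for many (k, n, n_proj)
  for (n in c(6, 11, 20)) for (k in c(1, 3, n %/% 2)) {
    n_proj <- 4
    hapk <- matrix(0L, n, 1); hapk[seq_len(k), 1] <- 1L
    gk <- make_geno(2L * hapk, ploidy = rep(1, n))
    sfsk <- folded_sfs_project(gk, n_proj = n_proj)
    mass <- oracle_project_mass(k, n, n_proj)
    folded <- c(mass[2] + mass[4], mass[3])
    expect_equal(sfsk$counts, folded, tolerance = 1e-12,
                 info = sprintf("k=%d n=%d", k, n))
  }

  # sites with fewer copies than n_proj are skipped and ledgered
  gt <- rbind(c(2L, 2L), c(0L, 0L), c(0L, NA), c(0L, NA))
  g3 <- make_geno(gt, ploidy = rep(1, 4))
  sfs3 <- folded_sfs_project(g3, n_proj = 3)
  expect_equal(sfs3$ledger$skipped, 1)
  expect_error(folded_sfs_project(g3, n_proj = 10), "exceeds")
})

test_that("projection is linear over locus-set concatenation", {
  set.seed(13)
  hap_a <- matrix(rbinom(10 * 30, 1, 0.2), 10, 30)
  hap_b <- matrix(rbinom(10 * 20, 1, 0.4), 10, 20)
  ga <- make_geno(2L * hap_a, ploidy = rep(1, 10))
  gb <- make_geno(2L * hap_b, ploidy = rep(1, 10),
                  pos = 100L * seq_len(20) + 5000L)
  gab <- geno_cbind(ga, gb)
  s_a <- folded_sfs_project(ga, n_proj = 6)
  s_b <- folded_sfs_project(gb, n_proj = 6)
  s_ab <- folded_sfs_project(gab, n_proj = 6)
  expect_equal(s_ab$counts, s_a$counts + s_b$counts, tolerance = 1e-12)
})

test_that("stairway blueprint round-trips and validates", {
  g <- simulate_neutral_pop(16, 60, seed = 3)
  sfs <- folded_sfs_project(g, n_proj = 8)
  path <- tempfile(fileext = ".blueprint")
  export_stairway_input(sfs, L = 487000, popid = "overall", path = path)
  back <- read_stairway_input(path)
  expect_equal(back$sfs, sfs$counts, tolerance = 1e-12)
  expect_equal(back$L, 487000)
  expect_equal(back$mu, 15.9e-9)
  expect_equal(back$gen_time, 20)
  expect_equal(back$nseq, 8)
  expect_error(export_stairway_input(sfs, L = 0, path = path), "positive")
})

test_that("pi is invariant under sample reordering and allele swap", {
  set.seed(14)
  gt <- matrix(sample(c(0L, 2L), 60, TRUE), 6, 10)
  g <- make_geno(gt, ploidy = rep(1, 6))
  ann <- site_annotation(rep("fold4", 10), c(fold4 = 50))
  sheet <- sheet_for(g, rep("A", 6))
  base <- pi_diversity(g, sheet, ann)
  perm <- sample(6)
  g2 <- geno_subset(g, samples = perm)
  expect_equal(pi_diversity(g2, sheet, ann), base)
  g3 <- make_geno(2L - gt, ploidy = rep(1, 6))  # allele-label swap
  expect_equal(pi_diversity(g3, sheet_for(g3, rep("A", 6)), ann), base)
})
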