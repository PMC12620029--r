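#' Flag loci heterozygous in haploid samples
#'
#' In haploid (megagametophyte) tissue every heterozygous call is a
#' genotyping error, typically caused by collapsed paralogs. Samples with a
#' gross excess of heterozygous calls (count above median + `mad_mult` * MAD
#' among haploids) are treated as contaminated by diploid tissue: their
#' heterozygous positions are set missing and do not, by themselves, flag a
#' locus.
#'
#' @param g a [geno] object containing raw diploid-coded calls.
#' @param mad_mult outlier multiplier for the contaminated-sample rule.
#' @return list with `evaluable`, per-locus logical `flags`, per-sample
#'   `sample_het` counts, `outliers` (contaminated sample names) and `geno`
#'   (copy with outlier heterozygous calls set missing).
#' @export
flag_haploid_hets <- function(g, mad_mult = 5) {
  hap <- which(g$ploidy == 1L)
  if (!length(hap))
    return(list(evaluable = FALSE, flags = NULL, sample_het = NULL,
                outliers = character(), geno = g))
  het <- g$gt[hap, , drop = FALSE] == 1L
  het[is.na(het)] <- FALSE
  cnt <- rowSums(het)
  thr <- stats::median(cnt) + mad_mult * stats::mad(cnt)
  out <- cnt > thr
  if (any(out)) {
    rows <- hap[out]
    gt <- g$gt[rows, , drop = FALSE]
    gt[gt == 1L] <- NA_integer_
    g$gt[rows, ] <- gt
  }
  flags <- colSums(het[!out, , drop = FALSE]) > 0L
  list(evaluable = TRUE, flags = flags,
       sample_het = stats::setNames(cnt, rownames(g$gt)[hap]),
       outliers = rownames(g$gt)[hap][out], geno = g)
}

#' Flag loci with excess heterozygosity in diploid samples
#'
#' A locus is flagged when the observed heterozygote fraction among
#' non-missing diploid genotypes strictly exceeds `het_max`.
#'
#' @param g a [geno] object.
#' @param het_max heterozygosity threshold (default 0.60).
#' @return per-locus logical flags; `NA` where no diploid call is available.
#' @export
het_excess <- function(g, het_max = 0.6) {
  dip <- which(g$ploidy == 2L)
  if (!length(dip))
    return(rep(NA, ncol(g$gt)))
  gt <- g$gt[dip, , drop = FALSE]
  n <- colSums(!is.na(gt))
  h <- colSums(gt == 1L, na.rm = TRUE)
  ifelse(n > 0L, h / n > het_max, NA)
}

#' Read-ratio deviation score D (HDplot)
#'
#' Pools, per locus, the reads observed at heterozygous diploid genotypes
#' and scores the deviation of the alternate-allele read count A from the
#' balanced expectation N/2: `D = (A - N/2) / sqrt(N/4)`, a binomial
#' z-score. Collapsed paralogs produce strongly unbalanced ratios and
#' |D| above `d_max`.
#'
#' @param g a [geno] object with `dp` and `ad_alt` fields.
#' @param d_max flag threshold on |D| (default 20).
#' @return list with per-locus `D` (NA where no heterozygote has reads) and
#'   logical `flags` (|D| > d_max).
#' @export
read_ratio_D <- function(g, d_max = 20) {
  if (is.null(g$dp) || is.null(g$ad_alt))
    stop("read_ratio_D requires dp and ad_alt fields", call. = FALSE)
  dip <- g$ploidy == 2L
  het <- g$gt == 1L & matrix(dip, nrow(g$gt), ncol(g$gt))
  het[is.na(het)] <- FALSE
  A <- colSums(g$ad_alt * het, na.rm = TRUE)
  N <- colSums(g$dp * het, na.rm = TRUE)
  D <- ifelse(N > 0, (A - N / 2) / sqrt(N / 4), NA_real_)
  list(D = D, flags = ifelse(is.na(D), NA, abs(D) > d_max))
}

# Exact Hardy-Weinberg test: full enumeration of heterozygote counts
# compatible with the observed allele counts; p = total probability of
# outcomes no more likely than the observed one (no mid-p).
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0L) return(NA_real_)
  na <- 2L * n_aa + n_ab
  if (na == 0L || na == 2L * n) return(1)
  hets <- seq(na %% 2L, min(na, 2L * n - na), by = 2L)
  logp <- vapply(hets, function(h) {
    haa <- (na - h) %/% 2L
    hbb <- n - haa - h
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1) +
      h * log(2) +
      lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Multi-population Hardy-Weinberg screen
#'
#' Runs an exact Hardy-Weinberg test on diploid genotype counts in each
#' population and flags loci out of equilibrium in more than a threshold
#' number of populations: literally "more than 3" when at least 8 diploid
#' populations are present, proportionally more than `floor(3 * n / 8)`
#' otherwise.
#'
#' @param g a [geno] object.
#' @param sheet sample sheet with `sample` and `population` columns.
#' @param alpha per-population significance level (default 0.05).
#' @param pops_max baseline count threshold (default 3, referring to 8
#'   populations).
#' @return list with `evaluable`, per-locus logical `flags`, the matrix of
#'   per-population `p` values and the applied `threshold`.
#' @export
hwe_multi_pop <- function(g, sheet, alpha = 0.05, pops_max = 3) {
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  dip <- g$ploidy == 2L
  dpops <- unique(pop[dip])
  dpops <- dpops[!is.na(dpops)]
  if (length(dpops) < 2L)
    return(list(evaluable = FALSE, flags = NULL, p = NULL, threshold = NA))
  L <- ncol(g$gt)
  pmat <- matrix(NA_real_, length(dpops), L, dimnames = list(dpops, NULL))
  for (k in seq_along(dpops)) {
    rows <- which(dip & pop == dpops[k])
    gt <- g$gt[rows, , drop = FALSE]
    n0 <- colSums(gt == 0L, na.rm = TRUE)
    n1 <- colSums(gt == 1L, na.rm = TRUE)
    n2 <- colSums(gt == 2L, na.rm = TRUE)
    pmat[k, ] <- mapply(hwe_exact_p, n0, n1, n2)
  }
  thr <- if (length(dpops) >= 8L) pops_max else
    floor(pops_max * length(dpops) / 8)
  nsig <- colSums(pmat < alpha, na.rm = TRUE)
  list(evaluable = TRUE, flags = nsig > thr, p = pmat, threshold = thr)
}

#' Compute all four error criteria on a genotype matrix
#'
#' Convenience wrapper running [flag_haploid_hets()], [het_excess()],
#' [read_ratio_D()] and [hwe_multi_pop()] and forming their union (a locus
#' is erroneous if any evaluable criterion flags it).
#'
#' @param g a [geno] object (raw, pre-filter calls).
#' @param sheet sample sheet.
#' @param het_max,d_max,hwe_alpha,hwe_pops thresholds, see the individual
#'   criteria.
#' @return object of class `error_flags`: the four per-locus flag sets, the
#'   read-ratio score `D`, the `union` flag vector, and `geno` (with
#'   contaminated-haploid heterozygotes set missing).
#' @export
qc_flags <- function(g, sheet, het_max = 0.6, d_max = 20,
                     hwe_alpha = 0.05, hwe_pops = 3) {
  hh <- flag_haploid_hets(g)
  g2 <- hh$geno
  he <- het_excess(g2, het_max)
  rr <- if (!is.null(g2$dp) && !is.null(g2$ad_alt))
    read_ratio_D(g2, d_max) else list(D = NULL, flags = NULL)
  hw <- hwe_multi_pop(g2, sheet, hwe_alpha, hwe_pops)
  L <- ncol(g$gt)
  u <- rep(FALSE, L)
  for (f in list(hh$flags, he, rr$flags, hw$flags))
    if (!is.null(f)) u <- u | (!is.na(f) & f)
  structure(list(haploid_het = hh$flags, het_excess = he,
                 read_ratio = rr$flags, D = rr$D, hwe = hw$flags,
                 hwe_p = hw$p, union = u,
                 outlier_samples = hh$outliers, geno = g2),
            class = "error_flags")
}

#' Windowed error-rate screen
#'
#' Tiles each contig with non-overlapping windows anchored at position 1,
#' computes the fraction of SNPs flagged as erroneous per window, and
#' excludes windows whose error rate strictly exceeds `err_max`. Windows
#' without SNPs are not evaluated (vacuously retained).
#'
#' @param flags an `error_flags` object from [qc_flags()], or a plain
#'   per-locus logical vector of error calls.
#' @param g the [geno] object the flags were computed on.
#' @param window_bp window length (default 250).
#' @param err_max exclusion threshold on the error rate (default 0.10,
#'   strict inequality).
#' @return list with `windows` (contig, 0-based half-open start/end,
#'   `n_snps`, `n_flagged`, `error_rate`, `excluded`), `keep` (per-locus
#'   logical: SNP lies outside every excluded window), `excluded_bed`
#'   (the excluded footprint) and `excluded_bp` (its total length, for
#'   genome-size accounting).
#' @export
window_screen <- function(flags, g, window_bp = 250, err_max = 0.10) {
  f <- if (inherits(flags, "error_flags")) flags$union else flags
  f <- !is.na(f) & f
  stopifnot(length(f) == ncol(g$gt))
  start <- ((g$pos - 1L) %/% window_bp) * window_bp
  key <- paste(g$chrom, start, sep = ":")
  n_snps <- tapply(f, key, length)
  n_flag <- tapply(f, key, sum)
  keys <- names(n_snps)
  parts <- strsplit(keys, ":", fixed = TRUE)
  win <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE)
  win$end <- win$start + as.integer(window_bp)
  win$n_snps <- as.integer(n_snps)
  win$n_flagged <- as.integer(n_flag)
  win$error_rate <- win$n_flagged / win$n_snps
  win$excluded <- win$error_rate > err_max
  win <- win[order(win$chrom, win$start), , drop = FALSE]
  rownames(win) <- NULL
  keep <- !(key %in% paste(win$chrom[win$excluded], win$start[win$excluded],
                           sep = ":"))
  bed <- win[win$excluded, c("chrom", "start", "end")]
  rownames(bed) <- NULL
  list(windows = win, keep = keep, excluded_bed = bed,
       excluded_bp = sum(bed$end - bed$start))
}

#' Depth and missingness filters
#'
#' Applies, in order: (1) diploid genotypes with sequencing depth strictly
#' below `min_depth` are set missing; (2) loci with overall missingness
#' strictly above `max_miss` are dropped; (3) loci called in strictly less
#' than `pop_call` of the samples of any single population are dropped.
#' The operation is idempotent.
#'
#' @param g a [geno] object.
#' @param sheet sample sheet (`sample`, `population`).
#' @param min_depth depth threshold for diploid genotypes (default 6).
#' @param max_miss maximum locus missingness (default 0.6).
#' @param pop_call minimum per-population call rate (default 0.5).
#' @return the filtered [geno] object.
#' @export
depth_missing_filter <- function(g, sheet, min_depth = 6, max_miss = 0.6,
                                 pop_call = 0.5) {
  if (!is.null(g$dp)) {
    dip <- matrix(g$ploidy == 2L, nrow(g$gt), ncol(g$gt))
    g$gt[dip & g$dp < min_depth] <- NA_integer_
  }
  miss <- colMeans(is.na(g$gt))
  keep <- miss <= max_miss
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  for (p in unique(pop)) {
    rows <- which(pop == p)
    cr <- colMeans(!is.na(g$gt[rows, , drop = FALSE]))
    keep <- keep & cr >= pop_call
  }
  geno_subset(g, loci = keep)
}

#' LD pruning by dosage correlation
#'
#' Within each contig, every pair of retained loci closer than `window_bp`
#' with squared dosage correlation above `r2_max` loses one member, chosen
#' uniformly at random; pairs are evaluated in position order and loci
#' with zero variance are skipped. Reproducible given `seed`.
#'
#' @param g a [geno] object.
#' @param r2_max squared-correlation threshold (default 0.8).
#' @param window_bp maximum pair distance in bp (default 10000).
#' @param seed integer seed for the random survivor choice.
#' @return the pruned [geno] object.
#' @export
ld_prune <- function(g, r2_max = 0.8, window_bp = 10000, seed = 1) {
  d <- dosage(g)
  keep <- rep(TRUE, ncol(d))
  with_seed(seed, {
    for (ct in unique(g$chrom)) {
      idx <- which(g$chrom == ct)
      if (length(idx) < 2L) next
      for (a in seq_along(idx)[-length(idx)]) {
        i <- idx[a]
        if (!keep[i]) next
        for (b in seq((a + 1L), length(idx))) {
          j <- idx[b]
          if (g$pos[j] - g$pos[i] > window_bp) break
          if (!keep[j]) next
          xi <- d[, i]; xj <- d[, j]
          ok <- !is.na(xi) & !is.na(xj)
          if (sum(ok) < 2L) next
          if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) next
          r2 <- stats::cor(xi[ok], xj[ok])^2
          if (r2 > r2_max) {
            drop <- if (stats::runif(1) < 0.5) i else j
            keep[drop] <- FALSE
            if (drop == i) break
          }
        }
      }
    }
  })
  geno_subset(g, loci = keep)
}

#' Split diploid samples into pseudo-haploids
#'
#' Each diploid sample becomes two pseudo-haploid samples (suffixes `__a`,
#' `__b`). At every locus the two alleles are assigned to the two
#' pseudo-haploids uniformly at random, independently across loci (assuming
#' linkage equilibrium); homozygotes are forced, so pooled allele counts are
#' conserved exactly. Haploid samples pass through unchanged.
#'
#' @param g a [geno] object.
#' @param seed integer seed.
#' @return an all-haploid [geno] object (depth fields are dropped).
#' @export
split_diploids <- function(g, seed = 1) {
  n <- nrow(g$gt)
  out_rows <- list()
  with_seed(seed, {
    for (s in seq_len(n)) {
      nm <- rownames(g$gt)[s]
      if (g$ploidy[s] == 1L) {
        out_rows[[nm]] <- g$gt[s, ]
      } else {
        gt <- g$gt[s, ]
        a <- ifelse(gt == 0L, 0L, ifelse(gt == 2L, 1L, NA_integer_))
        b <- a
        hets <- which(!is.na(gt) & gt == 1L)
        flip <- stats::runif(length(hets)) < 0.5
        a[hets] <- as.integer(flip)
        b[hets] <- as.integer(!flip)
        out_rows[[paste0(nm, "__a")]] <- 2L * a
        out_rows[[paste0(nm, "__b")]] <- 2L * b
      }
    }
  })
  gt <- do.call(rbind, out_rows)
  geno(gt, g$chrom, g$pos, g$ref, g$alt, ploidy = rep(1L, nrow(gt)),
       compartment = g$compartment, contig_len = g$contig_len)
}

#' Expand a sample sheet to match [split_diploids()] output
#' @param sheet sample sheet.
#' @return sheet with diploid rows duplicated as `__a` / `__b`
#'   pseudo-haploids (ploidy 1), population labels inherited.
#' @export
split_sheet <- function(sheet) {
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    r <- sheet[i, , drop = FALSE]
    if (r$ploidy == 2L) {
      r2 <- rbind(r, r)
      r2$sample <- paste0(r$sample, c("__a", "__b"))
      r2$ploidy <- 1L
      r2
    } else r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
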