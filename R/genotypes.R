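#' Genotype matrix for mixed haploid/diploid panels
#'
#' The central container of the package: a samples-by-loci matrix of
#' diploid-coded genotype calls together with locus coordinates, alleles,
#' per-sample ploidy and optional per-genotype read-depth information.
#'
#' Genotype calls are stored diploid-coded regardless of sample ploidy,
#' because variant callers run at ploidy 2 on haploid (megagametophyte)
#' libraries emit diploid genotypes; a heterozygous call in a haploid sample
#' is then a genotyping error that the QC machinery screens for. Codes are
#' 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing). Use [dosage()] to
#' obtain ploidy-aware allele dosages, in which haploid heterozygotes are
#' `NA`.
#'
#' @param gt integer matrix, samples x loci, values 0/1/2/NA. Row names are
#'   sample ids; column names are locus ids (optional, generated if absent).
#' @param chrom character vector of contig names, one per locus.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each contig.
#' @param ref,alt single-character reference / alternate alleles per locus.
#' @param ploidy integer vector (1 or 2) per sample.
#' @param dp optional integer matrix of per-genotype read depths.
#' @param ad_alt optional integer matrix of reads supporting the alternate
#'   allele (allelic depth), used by the read-ratio deviation score.
#' @param compartment one of `"nuclear"`, `"mito"`, `"chloro"`.
#' @param contig_len optional named integer vector of contig lengths (bp);
#'   defaults to the largest observed position per contig rounded up to a
#'   multiple of 10 kb.
#' @return An object of class `geno`.
#' @export
geno <- function(gt, chrom, pos, ref = NULL, alt = NULL, ploidy,
                 dp = NULL, ad_alt = NULL, compartment = "nuclear",
                 contig_len = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  L <- ncol(gt)
  n <- nrow(gt)
  if (is.null(rownames(gt))) rownames(gt) <- sprintf("S%03d", seq_len(n))
  if (is.null(colnames(gt))) colnames(gt) <- sprintf("L%05d", seq_len(L))
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("T", L)
  ploidy <- as.integer(ploidy)
  if (length(ploidy) == 1L) ploidy <- rep(ploidy, n)
  compartment <- match.arg(compartment, c("nuclear", "mito", "chloro"))
  obj <- structure(list(
    gt = gt,
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    ploidy = stats::setNames(ploidy, rownames(gt)),
    dp = dp, ad_alt = ad_alt,
    compartment = compartment,
    contig_len = contig_len
  ), class = "geno")
  if (is.null(obj$contig_len)) {
    mx <- tapply(obj$pos, obj$chrom, max)
    obj$contig_len <- stats::setNames(as.integer(ceiling(mx / 10000) * 10000),
                                      names(mx))
  }
  validate_geno(obj)
  obj
}

validate_geno <- function(g) {
  stopifnot(inherits(g, "geno"))
  L <- ncol(g$gt)
  n <- nrow(g$gt)
  if (length(g$chrom) != L || length(g$pos) != L)
    stop("chrom/pos length must equal number of loci", call. = FALSE)
  if (length(g$ref) != L || length(g$alt) != L)
    stop("ref/alt length must equal number of loci", call. = FALSE)
  if (length(g$ploidy) != n)
    stop("ploidy must have one entry per sample", call. = FALSE)
  if (!all(g$ploidy %in% c(1L, 2L)))
    stop("ploidy must be 1 or 2", call. = FALSE)
  bad <- !(g$gt %in% c(0L, 1L, 2L) | is.na(g$gt))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  # positions strictly increasing within contig (loci sorted by contig block)
  for (ct in unique(g$chrom)) {
    p <- g$pos[g$chrom == ct]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions must be strictly increasing within contig ", ct,
           call. = FALSE)
  }
  for (fld in c("dp", "ad_alt")) {
    m <- g[[fld]]
    if (!is.null(m) && !all(dim(m) == dim(g$gt)))
      stop(fld, " must match genotype matrix dimensions", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d samples x %d loci [%s]\n",
              nrow(x$gt), ncol(x$gt), x$compartment))
  cat(sprintf("  ploidy: %d haploid, %d diploid; %d contigs; %.1f%% missing\n",
              sum(x$ploidy == 1L), sum(x$ploidy == 2L),
              length(unique(x$chrom)),
              100 * mean(is.na(x$gt))))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$gt)

#' Ploidy-aware allele dosage matrix
#'
#' Converts diploid-coded genotype calls to allele dosages: diploid samples
#' keep codes 0/1/2; haploid samples map 0 -> 0 and 2 -> 1, while
#' heterozygous calls in haploid samples (genotyping errors) become `NA`.
#'
#' @param g a [geno] object.
#' @return integer matrix, samples x loci; entries in `0..ploidy` or `NA`.
#' @export
dosage <- function(g) {
  d <- g$gt
  hap <- g$ploidy == 1L
  if (any(hap)) {
    dh <- d[hap, , drop = FALSE]
    dh[dh == 1L] <- NA_integer_
    dh[dh == 2L] <- 1L
    d[hap, ] <- dh
  }
  d
}

#' Subset a genotype matrix
#'
#' @param g a [geno] object.
#' @param samples logical/integer/character index over samples, or NULL.
#' @param loci logical/integer/character index over loci, or NULL.
#' @return a [geno] object.
#' @export
geno_subset <- function(g, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$gt))
  if (is.null(loci)) loci <- seq_len(ncol(g$gt))
  sub2 <- function(m) if (is.null(m)) NULL else m[samples, loci, drop = FALSE]
  out <- g
  out$gt <- g$gt[samples, loci, drop = FALSE]
  out$dp <- sub2(g$dp)
  out$ad_alt <- sub2(g$ad_alt)
  if (is.character(loci)) loci <- match(loci, colnames(g$gt))
  if (is.logical(loci)) loci <- which(loci)
  out$chrom <- g$chrom[loci]
  out$pos <- g$pos[loci]
  out$ref <- g$ref[loci]
  out$alt <- g$alt[loci]
  out$ploidy <- g$ploidy[samples]
  out
}

#' Per-locus alternate-allele frequency
#'
#' Frequencies are computed on non-missing allele copies, respecting
#' ploidy (a diploid contributes two copies, a haploid one).
#'
#' @param g a [geno] object.
#' @param samples optional sample subset (index as in [geno_subset()]).
#' @return list with `freq` (alt-allele frequency), `n` (non-missing allele
#'   copies) and `alt_count` per locus.
#' @export
allele_freq <- function(g, samples = NULL) {
  if (!is.null(samples)) g <- geno_subset(g, samples = samples)
  d <- dosage(g)
  pl <- matrix(g$ploidy, nrow = nrow(d), ncol = ncol(d))
  pl[is.na(d)] <- 0L
  n <- colSums(pl)
  ac <- colSums(d, na.rm = TRUE)
  list(freq = ifelse(n > 0, ac / n, NA_real_), n = n, alt_count = ac)
}

#' Combine two genotype matrices over the same samples (locus concatenation)
#' @param a,b [geno] objects with identical samples and ploidy.
#' @return a [geno] object.
#' @export
geno_cbind <- function(a, b) {
  stopifnot(identical(rownames(a$gt), rownames(b$gt)),
            identical(a$ploidy, b$ploidy))
  cb <- function(x, y) if (is.null(x) || is.null(y)) NULL else cbind(x, y)
  geno(cbind(a$gt, b$gt), c(a$chrom, b$chrom), c(a$pos, b$pos),
       c(a$ref, b$ref), c(a$alt, b$alt), a$ploidy,
       dp = cb(a$dp, b$dp), ad_alt = cb(a$ad_alt, b$ad_alt),
       compartment = a$compartment)
}
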