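#' Classify coding positions by codon degeneracy
#'
#' A coding position is 4-fold degenerate when every nucleotide substitution
#' at that position leaves the amino acid unchanged, and 0-fold when every
#' substitution changes it; intermediate cases are `other`. Classification
#' uses the standard genetic code; codons containing ambiguous bases yield
#' `other` for all three positions.
#'
#' @param cds coding sequence (character scalar, 5'->3' on the coding
#'   strand, or on the genome strand if `strand = "-"`).
#' @param frame 0, 1 or 2 bases to skip before the first complete codon;
#'   skipped bases are classified `other`.
#' @param strand `"+"` or `"-"`; for `"-"` the sequence is reverse-
#'   complemented before classification and the result reported in input
#'   orientation.
#' @return character vector (`fold0`, `fold4`, `other`), one per input base.
#' @export
classify_degeneracy <- function(cds, frame = 0, strand = "+") {
  stopifnot(length(cds) == 1L, frame %in% 0:2, strand %in% c("+", "-"))
  s <- toupper(cds)
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  bases <- strsplit(s, "")[[1]]
  n <- length(bases)
  cls <- rep("other", n)
  usable <- seq.int(frame + 1L, n)
  usable <- usable[seq_len((length(usable) %/% 3L) * 3L)]
  if (length(usable)) {
    code <- Biostrings::GENETIC_CODE
    nts <- c("A", "C", "G", "T")
    for (ci in seq(1L, length(usable), by = 3L)) {
      pos3 <- usable[ci:(ci + 2L)]
      codon <- bases[pos3]
      if (!all(codon %in% nts)) next
      aa <- code[[paste(codon, collapse = "")]]
      for (w in 1:3) {
        alt_aa <- vapply(setdiff(nts, codon[w]), function(nt) {
          cd <- codon; cd[w] <- nt
          code[[paste(cd, collapse = "")]]
        }, character(1))
        n_syn <- sum(alt_aa == aa)
        cls[pos3[w]] <- if (n_syn == 3L) "fold4"
        else if (n_syn == 0L) "fold0" else "other"
      }
    }
  }
  if (strand == "-") cls <- rev(cls)
  cls
}

#' Per-locus site-class annotation
#'
#' @param class character/factor per locus, values in `fold0`, `fold4`,
#'   `neutral`, `other`.
#' @param accessible_bp named numeric: total accessible (monomorphic +
#'   polymorphic) length per class, used as the denominator of per-site
#'   diversity. Must be at least the number of SNPs of that class.
#' @return object of class `site_annotation`.
#' @export
site_annotation <- function(class, accessible_bp) {
  class <- as.character(class)
  stopifnot(all(class %in% c("fold0", "fold4", "neutral", "other")))
  tab <- table(class)
  for (cl in names(tab)) {
    if (!is.na(accessible_bp[cl]) && accessible_bp[cl] < tab[[cl]])
      stop("accessible_bp for ", cl, " below its SNP count", call. = FALSE)
  }
  structure(list(class = class, accessible_bp = accessible_bp),
            class = "site_annotation")
}

# per-site unbiased heterozygosity sum: sum_l 2 k (n - k) / (n (n - 1))
pi_numerator <- function(ac, n) {
  ok <- n >= 2
  sum(2 * ac[ok] * (n[ok] - ac[ok]) / (n[ok] * (n[ok] - 1)))
}

#' Nucleotide diversity per population for a site class
#'
#' Average pairwise difference per site: the sum over SNPs of the unbiased
#' per-site heterozygosity `2 p q n / (n - 1)` divided by the accessible
#' length of the class (monomorphic accessible sites contribute length but
#' no differences).
#'
#' @param g a [geno] object.
#' @param sheet sample sheet.
#' @param ann a [site_annotation()] covering the loci of `g`.
#' @param class site class to evaluate (`"fold4"`, `"fold0"`, ...).
#' @return named numeric vector of per-population diversity.
#' @export
pi_diversity <- function(g, sheet, ann, class = "fold4") {
  L <- ann$accessible_bp[class]
  if (is.na(L) || L <= 0)
    stop("class ", class, " has no accessible length", call. = FALSE)
  loci <- ann$class == class
  pops <- unique(sheet$population)
  out <- vapply(pops, function(p) {
    rows <- sheet$sample[sheet$population == p]
    af <- allele_freq(geno_subset(g, samples = match(rows, rownames(g$gt)),
                                  loci = loci))
    pi_numerator(af$alt_count, af$n) / L
  }, numeric(1))
  stats::setNames(out, pops)
}

#' Ratio of 0-fold to 4-fold diversity per population
#'
#' A proxy for the strength of purifying selection / genetic load: values
#' well below 1 indicate constrained 0-fold positions.
#'
#' @inheritParams pi_diversity
#' @return named numeric vector (NA where the 4-fold diversity is zero).
#' @export
pi_ratio <- function(g, sheet, ann) {
  p0 <- pi_diversity(g, sheet, ann, "fold0")
  p4 <- pi_diversity(g, sheet, ann, "fold4")
  ifelse(p4 > 0, p0 / p4, NA_real_)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_core <- function(ac, n) {
  seg <- ac > 0 & ac < n & n >= 2
  ac <- ac[seg]; n <- n[seg]
  S <- length(ac)
  if (S < 1L) return(NA_real_)
  nn <- stats::median(n)
  if (nn < 4) return(NA_real_)
  k <- tajima_constants(nn)
  pi_hat <- sum(2 * ac * (n - ac) / (n * (n - 1)))
  D_num <- pi_hat - S / k$a1
  D_den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  D_num / D_den
}

#' Tajima's D per population
#'
#' Classic Tajima (1989) statistic contrasting mean pairwise diversity with
#' the Watterson estimator. With missing data, per-site statistics use the
#' site-specific number of non-missing allele copies while the normalizing
#' constants use the median sample size. `mode = "projected"` first projects
#' the folded spectrum to a common size with the hypergeometric
#' distribution and evaluates D on the projected (real-valued) spectrum.
#'
#' @param g a [geno] object (typically subset to 4-fold degenerate SNPs).
#' @param sheet optional sample sheet; when given, D is computed per
#'   population, otherwise once for the whole panel.
#' @param mode `"raw"` (default) or `"projected"`.
#' @param n_proj projection size for `mode = "projected"` (defaults to 50%
#'   of the haploid sample size, rounded down to even).
#' @return numeric (named per population when `sheet` is given); NA with
#'   fewer than one segregating site or n < 4.
#' @export
tajimas_d <- function(g, sheet = NULL, mode = c("raw", "projected"),
                      n_proj = NULL) {
  mode <- match.arg(mode)
  one <- function(gs) {
    af <- allele_freq(gs)
    if (mode == "raw") return(tajima_core(af$alt_count, af$n))
    sfs <- folded_sfs_project(gs, n_proj)
    np <- sfs$n_proj
    cls <- seq_along(sfs$counts)
    S <- sum(sfs$counts)
    if (S <= 0) return(NA_real_)
    k <- tajima_constants(np)
    # folded class m pools j = m and np - m; pairwise-het term is symmetric
    pi_hat <- sum(sfs$counts * 2 * cls * (np - cls) / (np * (np - 1)))
    (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  if (is.null(sheet)) return(one(g))
  pops <- unique(sheet$population)
  stats::setNames(vapply(pops, function(p) {
    rows <- match(sheet$sample[sheet$population == p], rownames(g$gt))
    one(geno_subset(g, samples = rows[!is.na(rows)]))
  }, numeric(1)), pops)
}

#' Folded site-frequency spectrum with hypergeometric projection
#'
#' Each segregating site with `k` alternate alleles among `n` non-missing
#' copies distributes hypergeometric mass over minor-allele classes of a
#' projected sample of `n_proj` copies; mass landing on the monomorphic
#' classes (0 and `n_proj`) is discarded, and the spectrum is folded
#' (classes `j` and `n_proj - j` pooled, the central class not doubled).
#' Sites with fewer than `n_proj` non-missing copies are skipped and
#' reported. The accounting ledger satisfies
#' `retained + discarded + skipped = segregating sites` exactly.
#'
#' @param g a [geno] object.
#' @param n_proj projected haploid sample size; defaults to 50% of the
#'   panel's haploid genome copies, rounded down to an even number.
#' @param L accessible length to carry along (optional).
#' @return object of class `folded_sfs`: `n_proj`, `counts` (mass at minor
#'   classes `1..floor(n_proj/2)`), `L`, and `ledger` (n_seg, retained,
#'   discarded, skipped).
#' @export
folded_sfs_project <- function(g, n_proj = NULL, L = NA_real_) {
  af <- allele_freq(g)
  n_init <- sum(g$ploidy)
  if (is.null(n_proj)) n_proj <- (n_init %/% 2L) %/% 2L * 2L
  n_proj <- as.integer(n_proj)
  if (n_proj < 2L) stop("n_proj must be >= 2", call. = FALSE)
  if (n_proj > n_init)
    stop("n_proj exceeds the haploid sample size", call. = FALSE)
  seg <- which(af$alt_count > 0 & af$alt_count < af$n)
  counts <- numeric(n_proj %/% 2L)
  discarded <- 0
  skipped <- 0L
  for (l in seg) {
    n <- af$n[l]; k <- af$alt_count[l]
    if (n < n_proj) { skipped <- skipped + 1L; next }
    j <- seq(0L, n_proj)
    mass <- stats::dhyper(j, k, n - k, n_proj)
    discarded <- discarded + mass[1] + mass[n_proj + 1]
    for (jj in seq(1L, n_proj - 1L)) {
      m <- min(jj, n_proj - jj)
      counts[m] <- counts[m] + mass[jj + 1]
    }
  }
  structure(list(n_proj = n_proj, counts = counts, L = L,
                 ledger = list(n_seg = length(seg),
                               retained = sum(counts),
                               discarded = discarded,
                               skipped = skipped)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("<folded_sfs> n_proj=%d, %d classes, retained mass %.3f of %d segregating sites\n",
              x$n_proj, length(x$counts), x$ledger$retained, x$ledger$n_seg))
  invisible(x)
}

#' Write a Stairway-plot-2 style blueprint from a folded SFS
#'
#' Serializes the projected folded spectrum together with the accessible
#' sequence length, mutation rate and generation time in the blueprint text
#' layout consumed by Stairway plot 2. No demographic fitting is performed.
#'
#' @param sfs a [folded_sfs_project()] result.
#' @param L accessible sequence length in bp (must be positive).
#' @param mu mutation rate per bp per generation (default 15.9e-9).
#' @param gen_time generation time in years (default 20).
#' @param popid population label written in the header.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_stairway_input <- function(sfs, L, mu = 15.9e-9, gen_time = 20,
                                  popid = "pop", path) {
  stopifnot(inherits(sfs, "folded_sfs"))
  if (!is.finite(L) || L <= 0) stop("L must be positive", call. = FALSE)
  nseq <- sfs$n_proj
  nbin <- length(sfs$counts)
  lines <- c(
    "# blueprint file (folded SFS; no fitting performed)",
    sprintf("popid: %s", popid),
    sprintf("nseq: %d", nseq),
    sprintf("L: %s", format(L, scientific = FALSE)),
    "whether_folded: true",
    sprintf("SFS: %s", paste(format(sfs$counts, digits = 17),
                             collapse = "\t")),
    "smallest_size_of_SFS_bin_used_for_estimation: 1",
    sprintf("largest_size_of_SFS_bin_used_for_estimation: %d", nbin),
    "pct_training: 0.67",
    sprintf("nrand: %d %d %d %d",
            max(1, (nseq - 2) %/% 4), max(1, (nseq - 2) %/% 2),
            max(1, (nseq - 2) * 3 %/% 4), max(1, nseq - 2)),
    "project_dir: stairway_out",
    "stairway_plot_dir: stairway_plot_es",
    "ninput: 200",
    sprintf("mu: %s", format(mu, digits = 17)),
    sprintf("year_per_generation: %s", format(gen_time, digits = 17)),
    sprintf("plot_title: %s", popid),
    "xrange: 0,0",
    "yrange: 0,0",
    "fontsize: 12"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a blueprint written by [export_stairway_input()]
#' @param path blueprint file path.
#' @return list with `popid`, `nseq`, `L`, `sfs`, `mu`, `gen_time`.
#' @export
read_stairway_input <- function(path) {
  ln <- readLines(path)
  getv <- function(key) {
    hit <- grep(paste0("^", key, ": "), ln, value = TRUE)[1]
    sub(paste0("^", key, ": "), "", hit)
  }
  list(popid = getv("popid"),
       nseq = as.integer(getv("nseq")),
       L = as.numeric(getv("L")),
       sfs = as.numeric(strsplit(getv("SFS"), "\t")[[1]]),
       mu = as.numeric(getv("mu")),
       gen_time = as.numeric(getv("year_per_generation")))
}
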