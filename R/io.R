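#' Write a genotype matrix as VCF 4.2
#'
#' Genotypes are written diploid-coded for every sample (the convention of
#' variant callers run at ploidy 2 on haploid libraries); sample ploidy
#' travels in the sample sheet, not the VCF. Coordinates are 1-based. DP and
#' AD FORMAT fields are emitted when depth information is present.
#'
#' @param g a [geno] object.
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pinepop",
    sprintf("##contig=<ID=%s,length=%d>", names(g$contig_len),
            g$contig_len),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(g$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (!is.null(g$ad_alt))
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$gt)), collapse = "\t")
  ), con)
  fmt <- paste(c("GT", if (!is.null(g$dp)) "DP",
                 if (!is.null(g$ad_alt)) "AD"), collapse = ":")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$gt + 1L], nrow(g$gt))
  gt_str[is.na(g$gt)] <- "./."
  for (l in seq_len(ncol(g$gt))) {
    cells <- gt_str[, l]
    if (!is.null(g$dp)) cells <- paste(cells, g$dp[, l], sep = ":")
    if (!is.null(g$ad_alt))
      cells <- paste(cells, paste(g$dp[, l] - g$ad_alt[, l],
                                  g$ad_alt[, l], sep = ","), sep = ":")
    writeLines(paste(c(g$chrom[l], g$pos[l], colnames(g$gt)[l], g$ref[l],
                       g$alt[l], ".", "PASS", ".", fmt, cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x with VariantAnnotation, keeping biallelic SNP records
#' (others are skipped and counted). Haploid samples may be encoded either
#' as single-allele GT (`0`, `1`) or as forced-homozygous diploid GT
#' reinterpreted through `ploidy_map`; heterozygous diploid-coded calls in
#' haploid samples are preserved as such (they are QC signal). DP and AD
#' fields are captured when present.
#'
#' @param path VCF file path.
#' @param ploidy_map named integer vector `sample -> ploidy (1 or 2)`. Every
#'   VCF sample must be present, otherwise a hard error lists offenders.
#' @param compartment compartment label for the resulting object.
#' @return a [geno] object with an attribute `skipped` (count of skipped
#'   records).
#' @export
read_vcf <- function(path, ploidy_map, compartment = "nuclear") {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  samples <- colnames(vcf)
  missing_p <- setdiff(samples, names(ploidy_map))
  if (length(missing_p))
    stop("samples absent from ploidy_map: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- lengths(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) &
    nchar(alt1) == 1L & alt1 %in% c("A", "C", "G", "T") &
    ref %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  gt_raw <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  parse_gt <- function(s) {
    if (s %in% c(".", "./.", ".|.", "")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    al <- al[al != "."]
    if (!length(al)) return(NA_integer_)
    a <- as.integer(al)
    if (length(a) == 1L) return(2L * a) # single-allele haploid GT
    if (a[1] != a[2]) 1L else 2L * a[1]
  }
  codes <- vapply(as.vector(gt_raw), parse_gt, integer(1), USE.NAMES = FALSE)
  gt <- t(matrix(codes, nrow = nrow(gt_raw)))
  rownames(gt) <- samples
  gn <- VariantAnnotation::geno(vcf)
  dp <- NULL
  ad_alt <- NULL
  if ("DP" %in% names(gn)) dp <- t(gn$DP[keep, , drop = FALSE])
  if ("AD" %in% names(gn)) {
    ad <- gn$AD[keep, , drop = FALSE]
    ad_alt <- t(matrix(vapply(as.vector(ad), function(x)
      if (length(x) >= 2L) as.integer(x[2]) else NA_integer_,
      integer(1)), nrow = nrow(ad)))
  }
  g <- geno(gt,
            chrom = as.character(GenomicRanges::seqnames(rr))[keep],
            pos = GenomicRanges::start(rr)[keep],
            ref = ref[keep], alt = alt1[keep],
            ploidy = as.integer(ploidy_map[samples]),
            dp = dp, ad_alt = ad_alt, compartment = compartment)
  attr(g, "skipped") <- skipped
  g
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample`, `population`, `region`, `source_pool`,
#' `lat`, `lon`, `ploidy`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  need <- c("sample", "population", "region", "source_pool", "lat", "lon",
            "ploidy")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sheet$ploidy <- as.integer(sheet$ploidy)
  sheet
}

#' Write a sample sheet TSV
#' @param sheet data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genomic windows as BED (0-based half-open)
#' @param bed data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(bed, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: 0-based half-open coordinates", con)
  if (nrow(bed))
    utils::write.table(bed[, c("chrom", "start", "end")], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a site-class annotation from TSV or BED-like file
#'
#' Accepts either a per-locus TSV with columns `chrom`, `pos` (1-based) and
#' `class`, matched against the loci of `g`; loci not annotated default to
#' `neutral`. Accessible lengths per class come from a `#accessible
#' class=bp` header line or the `accessible_bp` argument.
#'
#' @param path annotation path.
#' @param g the [geno] object to annotate.
#' @param accessible_bp optional named vector overriding header-provided
#'   accessible lengths.
#' @return a [site_annotation()].
#' @export
read_annotation <- function(path, g, accessible_bp = NULL) {
  ln <- readLines(path)
  hdr <- grep("^#accessible", ln, value = TRUE)
  acc <- c(fold0 = NA_real_, fold4 = NA_real_, neutral = NA_real_,
           other = NA_real_)
  for (h in hdr) {
    kv <- regmatches(h, gregexpr("[a-z0-9]+=[0-9.]+", h))[[1]]
    for (x in kv) {
      p <- strsplit(x, "=", fixed = TRUE)[[1]]
      acc[p[1]] <- as.numeric(p[2])
    }
  }
  if (!is.null(accessible_bp)) acc[names(accessible_bp)] <- accessible_bp
  df <- utils::read.delim(textConnection(ln[!startsWith(ln, "#")]),
                          stringsAsFactors = FALSE)
  cls <- rep("neutral", ncol(g$gt))
  key <- paste(g$chrom, g$pos)
  hit <- match(key, paste(df$chrom, df$pos))
  cls[!is.na(hit)] <- df$class[hit[!is.na(hit)]]
  site_annotation(cls, acc)
}

#' Write a structured-text (JSON) truth sidecar
#' @param truth list of ground-truth records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  drop_heavy <- function(x) {
    if (is.list(x)) lapply(x, drop_heavy)
    else if (inherits(x, "phylo")) ape::write.tree(x)
    else x
  }
  jsonlite::write_json(drop_heavy(truth), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
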