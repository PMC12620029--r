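#' Minor-allele counts in the pooled reference (source) samples
#'
#' For every locus, counts both alleles across the pooled samples of all
#' source pools and records the count `c` of the rarer allele and its
#' identity. Ties (equal counts) resolve to the alternate allele and are
#' flagged. Loci missing in all source samples are excluded (`c = NA`).
#'
#' @param g a [geno] object.
#' @param sheet sample sheet.
#' @param source_pools named list mapping pool name to member population
#'   labels.
#' @return list with per-locus `c` (minor-allele count in the pooled
#'   sources), `minor_is_alt`, `tie`, and `freq` (pools x loci matrix of
#'   minor-allele frequencies in each source pool, computed on non-missing
#'   alleles).
#' @export
minor_allele_counts <- function(g, sheet, source_pools) {
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  src_rows <- lapply(source_pools, function(m) which(pop %in% m))
  pooled <- sort(unique(unlist(src_rows)))
  if (!length(pooled)) stop("no source samples found", call. = FALSE)
  af <- allele_freq(geno_subset(g, samples = pooled))
  alt_c <- af$alt_count
  ref_c <- af$n - af$alt_count
  evaluable <- af$n > 0
  minor_is_alt <- alt_c <= ref_c # tie -> alternate
  tie <- evaluable & alt_c == ref_c
  cc <- ifelse(evaluable, pmin(alt_c, ref_c), NA_integer_)
  fr <- do.call(rbind, lapply(src_rows, function(rr) {
    a <- allele_freq(geno_subset(g, samples = rr))
    ifelse(minor_is_alt, a$freq, 1 - a$freq)
  }))
  rownames(fr) <- names(source_pools)
  list(c = cc, minor_is_alt = minor_is_alt, tie = tie, freq = fr)
}

#' Proportion of shared rare alleles (PSRA)
#'
#' For individual `i` and minor-allele count class `c`, consider the `n`
#' loci at which `i` carries (dosage >= 1) an allele whose count in the
#' pooled source samples is exactly `c`. The PSRA toward source `j` is the
#' mean over those loci of source `j`'s share of the summed source
#' frequencies of that allele:
#' `PSRA(c)_{i,j} = (1/n) * sum_l f_{l,j} / sum_s f_{l,s}`.
#' The three proportions sum to one exactly for every defined cell. Loci
#' whose minor allele is absent from every source (`sum_s f = 0`, possible
#' only for query carriers) are excluded from `n`.
#'
#' @param g a [geno] object.
#' @param sheet sample sheet.
#' @param source_pools named list of source pools.
#' @param c_max largest minor-allele count class (default 8).
#' @param leave_one_out when TRUE, a source member's own alleles are removed
#'   from its pool's frequencies before computing its shares (off by
#'   default, matching the plain estimator).
#' @return object of class `psra_table`: long data.frame with columns
#'   `sample`, `population`, `c`, one column per source, and `n_loci`;
#'   cells with `n = 0` are absent (undefined, not zero).
#' @export
psra <- function(g, sheet, source_pools, c_max = 8, leave_one_out = FALSE) {
  mac <- minor_allele_counts(g, sheet, source_pools)
  d <- dosage(g)
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  pools <- names(source_pools)
  src_rows <- lapply(source_pools, function(m) which(pop %in% m))
  rows <- list()
  for (i in seq_len(nrow(d))) {
    # carrying the *minor* allele: for minor=alt need alt dosage>=1; for
    # minor=ref need at least one ref copy
    pl <- g$ploidy[i]
    carries_minor <- ifelse(mac$minor_is_alt,
                            !is.na(d[i, ]) & d[i, ] >= 1L,
                            !is.na(d[i, ]) & d[i, ] < pl)
    for (cc in seq_len(c_max)) {
      loci <- which(!is.na(mac$c) & mac$c == cc & carries_minor)
      if (!length(loci)) next
      fr <- mac$freq[, loci, drop = FALSE]
      if (leave_one_out) {
        own <- which(vapply(src_rows, function(rr) i %in% rr, logical(1)))
        if (length(own) == 1L) {
          rr <- setdiff(src_rows[[own]], i)
          a <- allele_freq(geno_subset(g, samples = rr, loci = loci))
          fr[own, ] <- ifelse(mac$minor_is_alt[loci], a$freq, 1 - a$freq)
        }
      }
      fr[is.na(fr)] <- 0
      tot <- colSums(fr)
      use <- tot > 0
      if (!any(use)) next
      shares <- rowMeans(fr[, use, drop = FALSE] /
                           rep(tot[use], each = nrow(fr)))
      row <- data.frame(sample = rownames(d)[i], population = pop[i],
                        c = cc, n_loci = sum(use),
                        stringsAsFactors = FALSE)
      for (k in seq_along(pools)) row[[pools[k]]] <- shares[k]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  structure(list(table = out, pools = pools, c_max = c_max),
            class = "psra_table")
}

#' Population summaries of PSRA profiles
#'
#' Unweighted mean and standard deviation over individuals and count
#' classes 1..c_max of the PSRA toward each source, per population.
#' Populations with no defined cell are omitted.
#'
#' @param tab a [psra()] result.
#' @param sheet sample sheet (unused beyond population labels already in
#'   the table; accepted for interface symmetry).
#' @return data.frame with one row per (population, source): `mean`, `sd`,
#'   `n_cells`.
#' @export
psra_summary <- function(tab, sheet = NULL) {
  stopifnot(inherits(tab, "psra_table"))
  df <- tab$table
  if (is.null(df) || !nrow(df)) return(NULL)
  out <- list()
  for (p in unique(df$population)) {
    sub <- df[df$population == p, , drop = FALSE]
    for (src in tab$pools) {
      v <- sub[[src]]
      out[[length(out) + 1L]] <- data.frame(
        population = p, source = src,
        mean = mean(v), sd = stats::sd(v), n_cells = length(v),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
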