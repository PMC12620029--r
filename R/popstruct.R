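#' Weir-Cockerham F_st between two populations
#'
#' Multilocus variance-components estimator of Weir and Cockerham (1984):
#' the ratio of summed among-population components to summed total
#' components across loci. With diploid samples in both populations the full
#' three-component (a, b, c) estimator with the heterozygosity correction is
#' used; with haploid (or mixed-ploidy) data the design collapses to a
#' one-level analysis of variance on allele frequencies.
#'
#' Negative multilocus estimates are reported as computed (finite-sample
#' behaviour under no differentiation), not truncated.
#'
#' @param g a [geno] object.
#' @param sheet sample sheet.
#' @param pop_a,pop_b population labels.
#' @return multilocus theta (NA when no locus is informative in both
#'   populations).
#' @export
wc_fst <- function(g, sheet, pop_a, pop_b) {
  comp <- wc_components(g, sheet, c(pop_a, pop_b))
  if (comp$den == 0) return(NA_real_)
  comp$num / comp$den
}

# summed numerator (a) and denominator (a+b+c) across loci
wc_components <- function(g, sheet, pops) {
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  rows <- lapply(pops, function(p) which(pop == p))
  pl <- g$ploidy
  all_dip <- all(pl[unlist(rows)] == 2L)
  d <- dosage(g)
  num <- den <- 0
  if (all_dip) {
    r <- length(pops)
    stat <- lapply(rows, function(rr) {
      gt <- d[rr, , drop = FALSE]
      n <- colSums(!is.na(gt))
      p <- colSums(gt, na.rm = TRUE) / (2 * n)
      h <- colSums(gt == 1L, na.rm = TRUE) / n
      list(n = n, p = p, h = h)
    })
    n_i <- do.call(rbind, lapply(stat, `[[`, "n"))
    p_i <- do.call(rbind, lapply(stat, `[[`, "p"))
    h_i <- do.call(rbind, lapply(stat, `[[`, "h"))
    ok <- colSums(n_i >= 2L) == r & apply(is.finite(p_i), 2, all)
    for (l in which(ok)) {
      ni <- n_i[, l]; pi <- p_i[, l]; hi <- h_i[, l]
      nbar <- mean(ni)
      nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  } else {
    r <- length(pops)
    stat <- lapply(rows, function(rr) {
      gt <- d[rr, , drop = FALSE]
      plr <- matrix(pl[rr], length(rr), ncol(gt))
      plr[is.na(gt)] <- 0L
      n <- colSums(plr)
      ac <- colSums(gt, na.rm = TRUE)
      list(n = n, p = ifelse(n > 0, ac / n, NA_real_))
    })
    n_i <- do.call(rbind, lapply(stat, `[[`, "n"))
    p_i <- do.call(rbind, lapply(stat, `[[`, "p"))
    ok <- colSums(n_i >= 2L) == r
    for (l in which(ok)) {
      ni <- n_i[, l]; pi <- p_i[, l]
      N <- sum(ni)
      pbar <- sum(ni * pi) / N
      if (pbar <= 0 || pbar >= 1) next
      nc <- (N - sum(ni^2) / N) / (r - 1)
      msp <- sum(ni * (pi - pbar)^2) / (r - 1)
      msg <- sum(ni * pi * (1 - pi)) / (N - r)
      a <- (msp - msg) / nc
      num <- num + a
      den <- den + a + msg
    }
  }
  list(num = num, den = den)
}

#' Pairwise F_st matrix over all populations
#'
#' @param g a [geno] object.
#' @param sheet sample sheet.
#' @param pops populations to include (default: all in the sheet).
#' @return symmetric matrix of multilocus Weir-Cockerham theta, diagonal 0.
#' @export
fst_matrix <- function(g, sheet, pops = NULL) {
  pops <- pops %||% unique(sheet$population)
  P <- length(pops)
  m <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
    m[i, j] <- m[j, i] <- wc_fst(g, sheet, pops[i], pops[j])
  }
  m
}

#' Two-level AMOVA (within / among populations)
#'
#' Analysis of molecular variance on haplotypic pairwise-mismatch distances
#' (the count of differing, jointly called loci between two samples). All
#' samples must be haploid; split diploids first with [split_diploids()].
#'
#' @param g an all-haploid [geno] object.
#' @param sheet sample sheet.
#' @return list with `sigma` (variance components among/within), `percent`
#'   (percentages summing to 100) and `phi_st`. With a single population the
#'   among component is undefined (`NA`).
#' @export
amova_two_level <- function(g, sheet) {
  if (any(g$ploidy != 1L))
    stop("amova_two_level expects haploid samples; use split_diploids()",
         call. = FALSE)
  pop <- sheet$population[match(rownames(g$gt), sheet$sample)]
  if (length(unique(pop)) < 2L)
    return(list(sigma = c(among = NA_real_, within = NA_real_),
                percent = c(among = NA_real_, within = NA_real_),
                phi_st = NA_real_, single_deme = TRUE))
  d2 <- as.matrix(hamming_matrix(g)$distances) # mismatch counts = squared d
  N <- nrow(d2)
  ssd_tot <- sum(d2[upper.tri(d2)]) / N
  pops <- unique(pop)
  ssd_w <- 0
  for (p in pops) {
    rr <- which(pop == p)
    if (length(rr) > 1L) {
      sub <- d2[rr, rr, drop = FALSE]
      ssd_w <- ssd_w + sum(sub[upper.tri(sub)]) / length(rr)
    }
  }
  ssd_a <- ssd_tot - ssd_w
  P <- length(pops)
  n_p <- as.numeric(table(pop)[pops])
  sigma_w <- ssd_w / (N - P)
  n_prime <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ssd_a / (P - 1) - sigma_w) / n_prime
  tot <- sigma_a + sigma_w
  list(sigma = c(among = sigma_a, within = sigma_w),
       percent = c(among = 100 * sigma_a / tot,
                   within = 100 * sigma_w / tot),
       phi_st = sigma_a / tot, single_deme = FALSE)
}

#' Principal component analysis of a genotype matrix
#'
#' smartpca-style normalization: each locus is mean-centred and scaled by
#' `sqrt(p (1 - p))` with `p` the alternate-allele frequency; missing
#' entries are imputed to the locus mean (zero after centring); monomorphic
#' loci are dropped. Eigendecomposition of the sample-by-sample covariance.
#'
#' @param g a [geno] object (typically LD-pruned and diploid-split).
#' @param n_pcs number of axes to return (default: all).
#' @return list with `scores` (samples x axes, eigenvector scaled by the
#'   square root of its eigenvalue), `eigvec`, `eigval` and `varfrac`
#'   (fraction of total variance per axis).
#' @export
pca_genotypes <- function(g, n_pcs = NULL) {
  d <- dosage(g)
  pl <- g$ploidy
  x <- d / pl
  p <- colMeans(x, na.rm = TRUE)
  poly <- is.finite(p) & p > 0 & p < 1
  if (sum(poly) < 2L) stop("need >= 2 polymorphic loci", call. = FALSE)
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  m <- sweep(x, 2, p)
  m <- sweep(m, 2, sqrt(p * (1 - p)), "/")
  m[is.na(m)] <- 0
  G <- tcrossprod(m) / ncol(m)
  e <- eigen(G, symmetric = TRUE)
  K <- min(n_pcs %||% (nrow(m) - 1L), nrow(m) - 1L)
  ev <- pmax(e$values[seq_len(K)], 0)
  scores <- e$vectors[, seq_len(K), drop = FALSE] %*% diag(sqrt(ev), K)
  rownames(scores) <- rownames(g$gt)
  colnames(scores) <- paste0("PC", seq_len(K))
  list(scores = scores,
       eigvec = e$vectors[, seq_len(K), drop = FALSE],
       eigval = ev,
       varfrac = e$values[seq_len(K)] / sum(pmax(e$values, 0)))
}

# least squares on the probability simplex (convex combination of pool
# centroids), solved exactly by enumerating active subsets - the number of
# pools is small. Plain NNLS followed by renormalization is unstable for
# individuals near the PC origin (all coefficients shrink to zero), so the
# sum-to-one constraint enters the optimization itself.
simplex_ls <- function(C, y) {
  K <- ncol(C)
  best <- NULL
  best_res <- Inf
  for (bits in seq_len(2^K - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(K) - 1)) > 0)
    cs <- C[, S, drop = FALSE]
    k <- length(S)
    # KKT system for min ||y - cs w||^2 subject to sum(w) = 1
    A <- rbind(cbind(2 * crossprod(cs), rep(1, k)), c(rep(1, k), 0))
    b <- c(2 * crossprod(cs, y), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    co <- sol[seq_len(k)]
    if (any(!is.finite(co)) || any(co < -1e-9)) next
    res <- sum((y - cs %*% co)^2)
    if (res < best_res - 1e-15) {
      best_res <- res
      w <- numeric(K)
      w[S] <- pmax(co, 0)
      best <- w
    }
  }
  best %||% rep(1 / K, K)
}

#' Shared-ancestry profiles from PC space
#'
#' Expresses each sample's position in the first `n_pcs` principal
#' components as the closest convex combination (nonnegative, sum-to-one
#' least squares) of source-pool centroids: an operational surrogate for
#' eigen-decomposition ancestry estimators (EIGMIX-style) driven entirely by
#' the PCA.
#'
#' @param scores PCA score matrix (samples x axes) from [pca_genotypes()].
#' @param sheet sample sheet.
#' @param source_pools named list mapping pool name to member population
#'   labels; each pool needs at least 2 samples.
#' @param n_pcs number of leading axes used (default 20, capped at the
#'   available axes).
#' @return object of class `ancestry_profile`: `weights` (samples x pools,
#'   rows sum to 1), `n_pcs`, and `non_identifiable` (TRUE when pool
#'   centroids are collinear in the retained PC space).
#' @export
eigmix_ancestry <- function(scores, sheet, source_pools, n_pcs = 20) {
  n_pcs <- min(n_pcs, ncol(scores))
  sc <- scores[, seq_len(n_pcs), drop = FALSE]
  pop <- sheet$population[match(rownames(sc), sheet$sample)]
  cents <- vapply(source_pools, function(members) {
    rr <- which(pop %in% members)
    if (length(rr) < 2L)
      stop("each source pool needs >= 2 samples", call. = FALSE)
    colMeans(sc[rr, , drop = FALSE])
  }, numeric(n_pcs))
  non_ident <- qr(cents)$rank < ncol(cents)
  w <- t(apply(sc, 1, function(y) {
    v <- simplex_ls(cents, y)
    v / sum(v)
  }))
  colnames(w) <- names(source_pools)
  structure(list(weights = w, n_pcs = n_pcs, non_identifiable = non_ident),
            class = "ancestry_profile")
}
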