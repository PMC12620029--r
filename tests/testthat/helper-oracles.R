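# Independent brute-force oracles. These re-derive the statistics from
# first principles (explicit pair loops, full enumerations, literal
# textbook transcriptions) and must never call the package's own
# implementation paths.

# --- nucleotide diversity: explicit average over all sample pairs --------
oracle_pi <- function(hapmat, L) {
  # average pairwise difference at each site over pairs with data there
  persite <- 0
  for (l in seq_len(ncol(hapmat))) {
    x <- hapmat[, l]
    x <- x[!is.na(x)]
    n_l <- length(x)
    if (n_l < 2) next
    diffs <- 0
    for (i in seq_len(n_l - 1)) for (j in seq((i + 1), n_l))
      diffs <- diffs + (x[i] != x[j])
    persite <- persite + diffs / choose(n_l, 2)
  }
  persite / L
}

# --- Tajima's D: literal transcription of the 1989 formulas --------------
oracle_tajima <- function(hapmat) {
  n <- nrow(hapmat)
  ac <- colSums(hapmat)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k_hat <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n))
    k_hat <- k_hat + sum(hapmat[i, ] != hapmat[j, ])
  k_hat <- k_hat / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Weir & Cockerham 1984: literal per-locus component transcription ----
# diploid genotype matrices per population, codes 0/1/2
oracle_wc_diploid <- function(gt_by_pop) {
  r <- length(gt_by_pop)
  num <- den <- 0
  L <- ncol(gt_by_pop[[1]])
  for (l in seq_len(L)) {
    n_i <- p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      x <- gt_by_pop[[k]][, l]
      x <- x[!is.na(x)]
      n_i[k] <- length(x)
      p_i[k] <- sum(x) / (2 * length(x))
      h_i[k] <- mean(x == 1)
    }
    if (any(n_i < 2)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# haploid allele matrices (0/1) per population
oracle_wc_haploid <- function(al_by_pop) {
  r <- length(al_by_pop)
  num <- den <- 0
  L <- ncol(al_by_pop[[1]])
  for (l in seq_len(L)) {
    n_i <- p_i <- numeric(r)
    for (k in seq_len(r)) {
      x <- al_by_pop[[k]][, l]
      x <- x[!is.na(x)]
      n_i[k] <- length(x)
      p_i[k] <- mean(x)
    }
    if (any(n_i < 2)) next
    N <- sum(n_i)
    pbar <- sum(n_i * p_i) / N
    if (pbar <= 0 || pbar >= 1) next
    msp <- sum(n_i * (p_i - pbar)^2) / (r - 1)
    msg <- sum(n_i * p_i * (1 - p_i)) / (N - r)
    nc <- (N - sum(n_i^2) / N) / (r - 1)
    num <- num + (msp - msg) / nc
    den <- den + (msp - msg) / nc + msg
  }
  num / den
}

# --- exact HWE test by explicit enumeration ------------------------------
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n - na
  if (na == 0 || nb == 0) return(1)
  hets <- seq(na %% 2, min(na, nb), by = 2)
  pr <- sapply(hets, function(h) {
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_ab, hets)] + 1e-12])
}

# --- windowed error recount: direct per-window loop ----------------------
oracle_window_screen <- function(chrom, pos, flagged, window_bp = 250,
                                 err_max = 0.10) {
  key <- paste(chrom, (pos - 1) %/% window_bp)
  excluded_keys <- character()
  for (k in unique(key)) {
    idx <- which(key == k)
    rate <- sum(flagged[idx]) / length(idx)
    if (rate > err_max) excluded_keys <- c(excluded_keys, k)
  }
  !(key %in% excluded_keys)
}

# --- hypergeometric projection by explicit combinatorial enumeration -----
oracle_project_mass <- function(k, n, n_proj) {
  sapply(0:n_proj, function(j) {
    choose(k, j) * choose(n - k, n_proj - j) / choose(n, n_proj)
  })
}

# small genotype builder used across tests
make_geno <- function(gt, ploidy, pos = NULL, chrom = NULL, ...) {
  gt <- as.matrix(gt)
  geno(gt,
       chrom = chrom %||% rep("ctg0001", ncol(gt)),
       pos = pos %||% (100L * seq_len(ncol(gt))),
       ploidy = ploidy, ...)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

sheet_for <- function(g, pop) {
  data.frame(sample = rownames(g$gt), population = pop,
             region = pop, source_pool = NA_character_,
             lat = 45, lon = 10, ploidy = g$ploidy,
             stringsAsFactors = FALSE)
}
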