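#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' Defaults describe the kind of panel the downstream statistics assume: many
#' weakly differentiated populations (multilocus F_st around 0.05), three
#' designated source pools seeding rare private alleles, organellar
#' compartments with seed-limited maternal dispersal, and read depths typical
#' of targeted capture.
#'
#' @param n_pops number of populations.
#' @param samples_per_pop samples per population (scalar or per-population).
#' @param ploidy sample ploidy, 1 or 2 (scalar or per-population).
#' @param n_loci number of nuclear SNP loci.
#' @param fst_target Balding-Nichols differentiation parameter in `[0, 1)`;
#'   0 collapses all populations onto the ancestral frequencies.
#' @param source_pools named list mapping pool name to member population
#'   names; defaults to the first three populations as three one-population
#'   pools (`southwest`, `italy`, `carpathian`) when `n_pops >= 3`.
#' @param admixture optional list of admixed sample groups, each a list with
#'   `group` (label), `n` (individuals), `weights` (named vector over source
#'   pools summing to 1) and optional `ploidy` (default 1).
#' @param rare_private_fraction fraction of loci overwritten as low-frequency
#'   alleles private to a single source pool (default 0.25), emulating
#'   geographically restricted recent variants.
#' @param rare_excess_fraction fraction of loci whose ancestral frequency is
#'   drawn from a low-frequency band (Uniform(0.01, 0.10)) instead of the
#'   Uniform(0.05, 0.95) baseline, giving every population an excess of rare
#'   alleles. The default 0.8 is tuned once so that per-population Tajima's D
#'   falls in the post-expansion range (-1, 0); the exact spectrum is a free
#'   parameter of the stated world.
#' @param rare_max_freq upper bound on the within-pool frequency of a rare
#'   private allele (default 0.1).
#' @param organelle_migration numeric pair `c(m_seed, m_pollen)`:
#'   per-generation migration fractions carried by seeds and by pollen. The
#'   maternal (mitochondrial) compartment migrates at `m_seed`, the paternal
#'   (chloroplast) one at `m_seed + m_pollen`.
#' @param organelle_K number of founder haplotypes per organelle.
#' @param organelle_deme_size haploid deme size for organelle drift.
#' @param organelle_sites expected number of segregating organelle sites.
#' @param n_generations forward-time generations for the organelle model.
#' @param migration_model `"island"` (migrant pool) or `"stepping"`
#'   (one-dimensional nearest-neighbour exchange).
#' @param error_windows list with `n_windows`, `window_len` (bp, default 250)
#'   and `error_prob` (per-locus corruption probability inside a window).
#' @param depth_mean mean per-genotype sequencing depth (Poisson).
#' @param miss_rate fraction of genotype calls set missing at random.
#' @param spacing_bp spacing between adjacent simulated SNPs; loci are laid
#'   on synthetic 10 kb contigs.
#' @param seed integer master seed; every generator derives its own stream
#'   from it, so identical configs give bit-identical outputs.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_pops = 10, samples_per_pop = 10, ploidy = 1,
                       n_loci = 5000, fst_target = 0.05,
                       source_pools = NULL, admixture = NULL,
                       rare_private_fraction = 0.25,
                       rare_excess_fraction = 0.8, rare_max_freq = 0.1,
                       organelle_migration = c(m_seed = 0.001, m_pollen = 0.02),
                       organelle_K = 8, organelle_deme_size = 200,
                       organelle_sites = 60, n_generations = 100,
                       migration_model = c("island", "stepping"),
                       error_windows = list(n_windows = 0, window_len = 250,
                                            error_prob = 0.5),
                       depth_mean = 20, miss_rate = 0.02, spacing_bp = 100,
                       seed = 1) {
  stopifnot(n_pops >= 1, n_loci >= 1)
  samples_per_pop <- rep_len(as.integer(samples_per_pop), n_pops)
  ploidy <- rep_len(as.integer(ploidy), n_pops)
  if (!all(ploidy %in% c(1L, 2L))) stop("ploidy must be 1 or 2", call. = FALSE)
  if (!is.finite(fst_target) || fst_target < 0 || fst_target >= 1)
    stop("fst_target must be finite in [0, 1)", call. = FALSE)
  check_fraction(rare_private_fraction, "rare_private_fraction")
  check_fraction(rare_excess_fraction, "rare_excess_fraction")
  check_fraction(rare_max_freq, "rare_max_freq")
  check_fraction(miss_rate, "miss_rate")
  if (length(organelle_migration) != 2L || any(!is.finite(organelle_migration)))
    stop("organelle_migration must be c(m_seed, m_pollen)", call. = FALSE)
  check_fraction(organelle_migration, "organelle_migration")
  if (!is.finite(depth_mean) || depth_mean <= 0)
    stop("depth_mean must be positive", call. = FALSE)
  pops <- sprintf("P%02d", seq_len(n_pops))
  if (is.null(source_pools) && n_pops >= 3)
    source_pools <- list(southwest = pops[1], italy = pops[2],
                         carpathian = pops[3])
  if (!is.null(source_pools)) {
    if (!all(unlist(source_pools) %in% pops))
      stop("source_pools refer to unknown populations", call. = FALSE)
  }
  if (!is.null(admixture)) {
    for (a in admixture) {
      if (abs(sum(a$weights) - 1) > 1e-9)
        stop("admixture weights must sum to 1 within 1e-9", call. = FALSE)
      if (!all(names(a$weights) %in% names(source_pools)))
        stop("admixture weights must be over named source pools",
             call. = FALSE)
    }
  }
  structure(list(
    n_pops = n_pops, pops = pops, samples_per_pop = samples_per_pop,
    ploidy = ploidy, n_loci = as.integer(n_loci), fst_target = fst_target,
    source_pools = source_pools, admixture = admixture,
    rare_private_fraction = rare_private_fraction,
    rare_excess_fraction = rare_excess_fraction,
    rare_max_freq = rare_max_freq,
    organelle_migration = stats::setNames(as.numeric(organelle_migration),
                                          c("m_seed", "m_pollen")),
    organelle_K = as.integer(organelle_K),
    organelle_deme_size = as.integer(organelle_deme_size),
    organelle_sites = as.integer(organelle_sites),
    n_generations = as.integer(n_generations),
    migration_model = match.arg(migration_model),
    error_windows = error_windows,
    depth_mean = depth_mean, miss_rate = miss_rate,
    spacing_bp = as.integer(spacing_bp), seed = as.integer(seed)
  ), class = "sim_config")
}

# Sample sheet implied by a config: populations on a southwest-to-northeast
# diagonal so geographic distances are non-degenerate, regions derived from
# pool membership, admixed groups appended.
#' Sample sheet implied by a simulation configuration
#' @param cfg a [sim_config()].
#' @return data.frame with columns sample, population, region, source_pool,
#'   lat, lon, ploidy.
#' @export
sim_sheet <- function(cfg) {
  lat <- seq(40, 66, length.out = cfg$n_pops)
  lon <- seq(-3, 50, length.out = cfg$n_pops)
  pool_of <- rep(NA_character_, cfg$n_pops)
  for (pl in names(cfg$source_pools))
    pool_of[match(cfg$source_pools[[pl]], cfg$pops)] <- pl
  rows <- do.call(rbind, lapply(seq_len(cfg$n_pops), function(k) {
    n <- cfg$samples_per_pop[k]
    data.frame(
      sample = sprintf("%s_%02d", cfg$pops[k], seq_len(n)),
      population = cfg$pops[k],
      region = ifelse(is.na(pool_of[k]), "north_east", pool_of[k]),
      source_pool = pool_of[k],
      lat = lat[k], lon = lon[k], ploidy = cfg$ploidy[k],
      stringsAsFactors = FALSE)
  }))
  for (a in cfg$admixture %||% list()) {
    rows <- rbind(rows, data.frame(
      sample = sprintf("%s_%02d", a$group, seq_len(a$n)),
      population = a$group, region = "admixed", source_pool = NA_character_,
      lat = mean(lat), lon = mean(lon), ploidy = a$ploidy %||% 1L,
      stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

sim_positions <- function(n_loci, spacing_bp) {
  per_ctg <- max(1L, 10000L %/% spacing_bp)
  idx <- seq_len(n_loci) - 1L
  list(chrom = sprintf("ctg%04d", idx %/% per_ctg + 1L),
       pos = (idx %% per_ctg + 1L) * spacing_bp)
}

pool_freq <- function(pop_freq, pops, members) {
  colMeans(pop_freq[match(members, pops), , drop = FALSE])
}

#' Simulate a multi-population nuclear SNP panel with known truth
#'
#' Population allele frequencies follow the Balding-Nichols model: ancestral
#' frequencies are Uniform(0.05, 0.95) and each population's frequency is
#' Beta-distributed around them with differentiation `fst_target`. A fraction
#' of loci is overwritten as rare alleles private to one source pool.
#' Genotypes are binomial draws given ploidy; admixed individuals draw each
#' allele copy from a source pool chosen by their admixture weights. Per-
#' genotype depths are Poisson and allelic depths binomial, so the QC module
#' can be exercised end to end.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` (a [geno] object with depth fields), `sheet`
#'   (see [sim_sheet()]) and `truth` (ancestral and per-population
#'   frequencies, rare-allele table, admixture weights, pools, seed).
#' @export
simulate_nuclear <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sheet <- sim_sheet(cfg)
  L <- cfg$n_loci
  P <- cfg$n_pops
  with_seed(sub_seed(cfg$seed, 1L), {
    anc <- stats::runif(L, 0.05, 0.95)
    if (cfg$rare_excess_fraction > 0) {
      low <- stats::runif(L) < cfg$rare_excess_fraction
      anc[low] <- stats::runif(sum(low), 0.01, 0.10)
    }
    if (cfg$fst_target > 0) {
      f <- cfg$fst_target
      a <- anc * (1 - f) / f
      b <- (1 - anc) * (1 - f) / f
      pop_freq <- t(vapply(seq_len(P),
                           function(k) stats::rbeta(L, a, b),
                           numeric(L)))
    } else {
      pop_freq <- matrix(anc, nrow = P, ncol = L, byrow = TRUE)
    }
    rownames(pop_freq) <- cfg$pops

    rare <- NULL
    n_rare <- floor(cfg$rare_private_fraction * L)
    if (n_rare > 0 && length(cfg$source_pools)) {
      rare_idx <- sort(sample.int(L, n_rare))
      rare_pool <- sample(names(cfg$source_pools), n_rare, replace = TRUE)
      rare_f <- stats::runif(n_rare, 0.02, cfg$rare_max_freq)
      pop_freq[, rare_idx] <- 0
      for (i in seq_len(n_rare)) {
        mem <- cfg$source_pools[[rare_pool[i]]]
        pop_freq[match(mem, cfg$pops), rare_idx[i]] <- rare_f[i]
      }
      rare <- data.frame(locus = rare_idx, pool = rare_pool, freq = rare_f)
    }

    n_tot <- nrow(sheet)
    gt <- matrix(NA_integer_, n_tot, L,
                 dimnames = list(sheet$sample, NULL))
    for (k in seq_len(P)) {
      rows <- which(sheet$population == cfg$pops[k])
      pk <- pop_freq[k, ]
      for (r in rows)
        gt[r, ] <- stats::rbinom(L, sheet$ploidy[r], pk) *
          (if (sheet$ploidy[r] == 1L) 2L else 1L)
    }

    adm_truth <- NULL
    if (length(cfg$admixture)) {
      pools <- names(cfg$source_pools)
      pf <- do.call(rbind, lapply(pools, function(pl)
        pool_freq(pop_freq, cfg$pops, cfg$source_pools[[pl]])))
      rownames(pf) <- pools
      adm_rows <- list()
      for (a in cfg$admixture) {
        w <- a$weights[pools]
        w[is.na(w)] <- 0
        pld <- a$ploidy %||% 1L
        rows <- which(sheet$population == a$group)
        for (r in rows) {
          copies <- vapply(seq_len(pld), function(cp) {
            src <- sample.int(length(pools), L, replace = TRUE, prob = w)
            stats::rbinom(L, 1L, pf[cbind(src, seq_len(L))])
          }, integer(L))
          g <- as.integer(rowSums(copies))
          gt[r, ] <- if (pld == 1L) g * 2L else g
          adm_rows[[sheet$sample[r]]] <- w
        }
      }
      adm_truth <- do.call(rbind, adm_rows)
    }

    dp <- matrix(stats::rpois(n_tot * L, cfg$depth_mean), n_tot, L,
                 dimnames = dimnames(gt))
    ad_alt <- matrix(0L, n_tot, L, dimnames = dimnames(gt))
    het <- which(gt == 1L & matrix(sheet$ploidy == 2L, n_tot, L))
    ad_alt[het] <- stats::rbinom(length(het), dp[het], 0.5)
    hom_alt <- which(gt == 2L)
    ad_alt[hom_alt] <- dp[hom_alt]
    if (cfg$miss_rate > 0) {
      gt[stats::runif(n_tot * L) < cfg$miss_rate] <- NA_integer_
    }
    coords <- sim_positions(L, cfg$spacing_bp)
    g <- geno(gt, coords$chrom, coords$pos, ploidy = sheet$ploidy,
              dp = dp, ad_alt = ad_alt, compartment = "nuclear")
    list(geno = g, sheet = sheet,
         truth = list(ancestral = anc, pop_freq = pop_freq, rare = rare,
                      admixture = adm_truth, pools = cfg$source_pools,
                      fst_target = cfg$fst_target, seed = cfg$seed))
  })
}

# one forward generation: deterministic migration then multinomial drift
forward_step <- function(freq, m, N, model) {
  P <- nrow(freq)
  if (P == 1L || m == 0) {
    mig <- freq
  } else if (model == "island") {
    pool <- colMeans(freq)
    mig <- (1 - m) * freq + m * matrix(pool, P, ncol(freq), byrow = TRUE)
  } else { # stepping stone on a line
    nb <- freq[c(2, seq_len(P - 1)), , drop = FALSE] +
      freq[c(2:P, P - 1), , drop = FALSE]
    mig <- (1 - m) * freq + m * nb / 2
  }
  t(apply(mig, 1, function(x) {
    as.numeric(stats::rmultinom(1, N, pmax(x, 0))) / N
  }))
}

coalescent_haplotypes <- function(K, n_sites) {
  tre <- ape::rcoal(K)
  S <- max(1L, stats::rpois(1, n_sites))
  br <- tre$edge.length
  site_branch <- sample.int(length(br), S, replace = TRUE, prob = br)
  # tips descending from each edge
  pp <- ape::prop.part(tre)
  hap <- matrix(0L, K, S)
  for (s in seq_len(S)) {
    node <- tre$edge[site_branch[s], 2]
    tips <- if (node <= K) node else pp[[node - K]]
    hap[tips, s] <- 1L
  }
  rownames(hap) <- tre$tip.label
  list(hap = hap, tree = tre)
}

sim_one_organelle <- function(cfg, sheet, m, compartment, stream) {
  with_seed(sub_seed(cfg$seed, stream), {
    K <- cfg$organelle_K
    ch <- coalescent_haplotypes(K, cfg$organelle_sites)
    P <- cfg$n_pops
    freq <- matrix(1 / K, P, K) # shared founding pool
    freq <- t(apply(freq, 1, function(x)
      as.numeric(stats::rmultinom(1, cfg$organelle_deme_size, x)) /
        cfg$organelle_deme_size))
    for (gen in seq_len(cfg$n_generations))
      freq <- forward_step(freq, m, cfg$organelle_deme_size,
                           cfg$migration_model)
    hap_id <- integer(nrow(sheet))
    for (k in seq_len(P)) {
      rows <- which(sheet$population == cfg$pops[k])
      if (length(rows))
        hap_id[rows] <- sample.int(K, length(rows), replace = TRUE,
                                   prob = freq[k, ])
    }
    # admixed / unknown rows draw from the migrant pool
    rows <- which(!sheet$population %in% cfg$pops)
    if (length(rows))
      hap_id[rows] <- sample.int(K, length(rows), replace = TRUE,
                                 prob = colMeans(freq))
    S <- ncol(ch$hap)
    gt <- 2L * ch$hap[hap_id, , drop = FALSE]
    rownames(gt) <- sheet$sample
    g <- geno(gt, chrom = rep(compartment, S), pos = 100L * seq_len(S),
              ploidy = rep(1L, nrow(sheet)), compartment = compartment)
    list(geno = g,
         truth = list(m = m, final_freq = freq, haplotypes = ch$hap,
                      hap_id = stats::setNames(hap_id, sheet$sample),
                      tree = ch$tree, single_deme = P == 1L))
  })
}

#' Simulate maternally and paternally dispersed organelle compartments
#'
#' Haplotype frequencies evolve forward in time in an island (or 1-D
#' stepping-stone) model. The maternal compartment (mitochondrial; dispersed
#' only through seeds) migrates at `m_seed` per generation; the paternal one
#' (chloroplast; dispersed through pollen and seeds) at `m_seed + m_pollen`.
#' Haplotypes descend from a simulated coalescent genealogy, so pairwise
#' Hamming distances count mutations on the genealogy.
#'
#' @param cfg a [sim_config()].
#' @return list with `mito` and `chloro` (haploid [geno] objects), `sheet`
#'   and `truth` (per-compartment migration rates, final frequencies,
#'   haplotype assignments; `single_deme` flags the degenerate one-population
#'   case in which among-population variance is undefined).
#' @export
simulate_organelles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sheet <- sim_sheet(cfg)
  m <- cfg$organelle_migration
  mito <- sim_one_organelle(cfg, sheet, m[["m_seed"]], "mito", 11L)
  chlo <- sim_one_organelle(cfg, sheet, m[["m_seed"]] + m[["m_pollen"]],
                            "chloro", 12L)
  list(mito = mito$geno, chloro = chlo$geno, sheet = sheet,
       truth = list(mito = mito$truth, chloro = chlo$truth,
                    m_seed = m[["m_seed"]], m_pollen = m[["m_pollen"]],
                    single_deme = cfg$n_pops == 1L))
}

#' Overlay paralog-collapse genotyping errors in 250 bp windows
#'
#' Inside chosen windows a second, collapsed paralog signal corrupts
#' genotype calls: haploid samples gain heterozygous calls, diploid
#' heterozygosity is inflated above 60%, and allelic read ratios at diploid
#' heterozygotes skew away from 1:1. Data outside the windows is untouched.
#' This is the error mode the window screen in the QC module is designed to
#' recover.
#'
#' @param g a [geno] object with depth (`dp`) fields.
#' @param cfg a [sim_config()]; `cfg$error_windows` gives the number of
#'   windows, window length and per-locus corruption probability.
#' @param windows optional explicit data.frame (`chrom`, `start`, `end`;
#'   0-based half-open) instead of randomly chosen windows; windows beyond
#'   the contig length are rejected.
#' @return list with `geno` (corrupted copy), `windows` (0-based half-open
#'   truth coordinates) and `loci` (indices of corrupted loci).
#' @export
inject_paralog_errors <- function(g, cfg, windows = NULL) {
  stopifnot(inherits(g, "geno"))
  if (is.null(g$dp))
    stop("inject_paralog_errors requires per-genotype depth fields",
         call. = FALSE)
  ew <- cfg$error_windows
  wl <- as.integer(ew$window_len %||% 250L)
  if (is.null(windows)) {
    nw <- as.integer(ew$n_windows %||% 0L)
    if (nw == 0L)
      return(list(geno = g, windows = data.frame(chrom = character(),
                                                 start = integer(),
                                                 end = integer()),
                  loci = integer()))
    tile <- (g$pos - 1L) %/% wl
    cand <- unique(data.frame(chrom = g$chrom, start = tile * wl))
    if (nw > nrow(cand))
      stop("requested more error windows than SNP-bearing tiles",
           call. = FALSE)
    windows <- with_seed(sub_seed(cfg$seed, 21L), {
      pick <- sample.int(nrow(cand), nw)
      data.frame(chrom = cand$chrom[pick], start = cand$start[pick],
                 end = cand$start[pick] + wl)
    })
  } else {
    windows$end <- windows$end %||% (windows$start + wl)
    too_long <- windows$end > g$contig_len[windows$chrom]
    if (any(is.na(too_long)) || any(too_long))
      stop("error windows exceed contig bounds", call. = FALSE)
  }
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  in_win <- rep(FALSE, ncol(g$gt))
  for (i in seq_len(nrow(windows))) {
    in_win <- in_win | (g$chrom == windows$chrom[i] &
                          g$pos > windows$start[i] &
                          g$pos <= windows$end[i])
  }
  with_seed(sub_seed(cfg$seed, 22L), {
    loci <- which(in_win & stats::runif(ncol(g$gt)) <
                    (cfg$error_windows$error_prob %||% 0.5))
    hap <- g$ploidy == 1L
    for (l in loci) {
      hit <- stats::runif(nrow(g$gt)) < ifelse(hap, 0.5, 0.7)
      g$gt[hit, l] <- 1L
      dh <- which(hit & !hap)
      if (length(dh) && !is.null(g$ad_alt))
        g$ad_alt[dh, l] <- stats::rbinom(length(dh), g$dp[dh, l], 0.15)
    }
    list(geno = g, windows = windows, loci = loci)
  })
}

#' Simulate one panmictic equilibrium population under the coalescent
#'
#' Infinite-sites mutations are dropped on a standard neutral coalescent
#' genealogy, giving a haploid sample whose expected site-frequency spectrum
#' is the equilibrium 1/i spectrum (Tajima's D centred on zero). Used to
#' calibrate the demographic statistics.
#'
#' @param n haploid sample size.
#' @param n_sites expected number of segregating sites (Poisson).
#' @param seed integer seed.
#' @return a haploid, single-contig [geno] object.
#' @export
simulate_neutral_pop <- function(n, n_sites = 50, seed = 1) {
  with_seed(seed, {
    ch <- coalescent_haplotypes(n, n_sites)
    gt <- 2L * ch$hap
    rownames(gt) <- sprintf("N_%03d", seq_len(n))
    geno(gt, chrom = rep("ctg0001", ncol(gt)),
         pos = 100L * seq_len(ncol(gt)), ploidy = rep(1L, n))
  })
}

#' Simulate a complete synthetic dataset (nuclear + organelles + sheet)
#'
#' @param cfg a [sim_config()].
#' @return list with `nuclear`, `mito`, `chloro` ([geno] objects), `sheet`
#'   and `truth` (nuclear and organelle ground truth combined).
#' @export
simulate_dataset <- function(cfg) {
  nuc <- simulate_nuclear(cfg)
  org <- simulate_organelles(cfg)
  err <- NULL
  g <- nuc$geno
  if ((cfg$error_windows$n_windows %||% 0L) > 0L) {
    inj <- inject_paralog_errors(g, cfg)
    g <- inj$geno
    err <- inj$windows
  }
  list(nuclear = g, mito = org$mito, chloro = org$chloro, sheet = nuc$sheet,
       truth = c(nuc$truth, list(organelle = org$truth,
                                 error_windows = err)))
}
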