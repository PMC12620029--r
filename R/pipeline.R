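#' Pipeline run configuration
#'
#' Collects input paths (or in-memory objects), stage toggles and every
#' stage parameter, with defaults at the thresholds the statistics were
#' designed around. Unknown parameter names are rejected, and every
#' stochastic stage receives a seed derived from the master seed.
#'
#' @param nuclear_vcf,mito_vcf,chloro_vcf VCF paths or [geno] objects
#'   (organelles optional).
#' @param sheet sample-sheet path or data.frame.
#' @param annotation optional annotation path or [site_annotation()].
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides for stage parameters: `het_max` (0.6), `d_max`
#'   (20), `hwe_alpha` (0.05), `hwe_pops` (3), `window` (250), `window_err`
#'   (0.10), `min_depth` (6), `max_miss` (0.6), `pop_call` (0.5), `r2`
#'   (0.8), `ld_window` (10000), `n_pcs` (20), `n_perm` (999),
#'   `resolution` (0.2), `c_max` (8), plus stage toggles `run_qc`,
#'   `run_structure`, `run_geneflow`, `run_psra`, `run_organelle` (all
#'   TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(nuclear_vcf, sheet, mito_vcf = NULL,
                       chloro_vcf = NULL, annotation = NULL,
                       out_dir = "pinepop_out", seed = 1, ...) {
  defaults <- list(
    het_max = 0.6, d_max = 20, hwe_alpha = 0.05, hwe_pops = 3,
    window = 250, window_err = 0.10, min_depth = 6, max_miss = 0.6,
    pop_call = 0.5, r2 = 0.8, ld_window = 10000, n_pcs = 20,
    n_perm = 999, resolution = 0.2, c_max = 8,
    run_qc = TRUE, run_structure = TRUE, run_geneflow = TRUE,
    run_psra = TRUE, run_organelle = TRUE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown run_config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  defaults[names(dots)] <- dots
  c(list(nuclear_vcf = nuclear_vcf, sheet = sheet, mito_vcf = mito_vcf,
         chloro_vcf = chloro_vcf, annotation = annotation,
         out_dir = out_dir, seed = as.integer(seed)),
    defaults)
}

pp_log <- function(log, ...) {
  msg <- sprintf(...)
  log$lines <- c(log$lines, msg)
  message(msg)
  log
}

#' Run the full analysis pipeline
#'
#' Executes the stage graph qc -> prune/split -> diversity -> structure ->
#' geneflow -> psra -> organelle on the configured inputs, writing TSV/BED
#' artifacts and a manifest log to the output directory. Stages whose
#' preconditions fail are skipped with a logged reason (e.g. the gene-flow
#' stage without coordinates); hard input errors abort with the stage name.
#'
#' @param cfg a [run_config()].
#' @return invisible list of stage results plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(lines = character())
  res <- list()

  sheet <- if (is.character(cfg$sheet)) read_sheet(cfg$sheet) else cfg$sheet
  pmap <- stats::setNames(sheet$ploidy, sheet$sample)
  load_geno <- function(x, compartment) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "geno")) x else read_vcf(x, pmap, compartment)
  }
  g <- load_geno(cfg$nuclear_vcf, "nuclear")
  log <- pp_log(log, "[input] nuclear: %d samples x %d loci; seed=%d",
                nrow(g$gt), ncol(g$gt), cfg$seed)

  # --- qc ---------------------------------------------------------------
  if (cfg$run_qc) {
    fl <- qc_flags(g, sheet, het_max = cfg$het_max, d_max = cfg$d_max,
                   hwe_alpha = cfg$hwe_alpha, hwe_pops = cfg$hwe_pops)
    ws <- window_screen(fl, g, window_bp = cfg$window,
                        err_max = cfg$window_err)
    g1 <- geno_subset(fl$geno, loci = ws$keep)
    g1 <- depth_missing_filter(g1, sheet, min_depth = cfg$min_depth,
                               max_miss = cfg$max_miss,
                               pop_call = cfg$pop_call)
    write_bed(ws$excluded_bed, file.path(cfg$out_dir,
                                         "excluded_windows.bed"))
    flag_df <- data.frame(chrom = g$chrom, pos = g$pos,
                          flagged = fl$union)
    utils::write.table(flag_df, file.path(cfg$out_dir, "error_flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- pp_log(log,
      "[qc] flagged %d/%d loci; excluded %d windows (%d bp); kept %d loci",
      sum(fl$union), ncol(g$gt), sum(ws$windows$excluded), ws$excluded_bp,
      ncol(g1$gt))
    res$qc <- list(flags = fl, windows = ws$windows)
  } else g1 <- g

  # --- prune / split ----------------------------------------------------
  hap_idx <- which(g1$ploidy == 1L)
  dip_idx <- which(g1$ploidy == 2L)
  keep_loci <- rep(TRUE, ncol(g1$gt))
  for (idx in list(hap_idx, dip_idx)) {
    if (length(idx) >= 2L) {
      pr <- ld_prune(geno_subset(g1, samples = idx), r2_max = cfg$r2,
                     window_bp = cfg$ld_window,
                     seed = sub_seed(cfg$seed, 31L))
      keep_loci <- keep_loci & colnames(g1$gt) %in% colnames(pr$gt)
    }
  }
  g_pruned <- geno_subset(g1, loci = keep_loci)
  g_split <- split_diploids(g_pruned, seed = sub_seed(cfg$seed, 32L))
  sheet_split <- split_sheet(sheet)
  log <- pp_log(log, "[prune] %d -> %d loci after LD pruning; %d pseudo-haploids",
                ncol(g1$gt), ncol(g_pruned$gt), nrow(g_split$gt))
  res$pruned <- g_pruned
  res$split <- g_split

  # --- diversity --------------------------------------------------------
  ann <- cfg$annotation
  if (is.character(ann)) ann <- read_annotation(ann, g1)
  if (!is.null(ann)) {
    div <- data.frame(population = unique(sheet$population))
    ok4 <- is.finite(ann$accessible_bp["fold4"]) &&
      ann$accessible_bp["fold4"] > 0
    if (ok4) {
      div$pi_4 <- pi_diversity(g1, sheet, ann, "fold4")[div$population]
      if (is.finite(ann$accessible_bp["fold0"]) &&
          ann$accessible_bp["fold0"] > 0)
        div$pi0_pi4 <- pi_ratio(g1, sheet, ann)[div$population]
      g4 <- geno_subset(g1, loci = ann$class == "fold4")
      div$tajimas_d <- tajimas_d(g4, sheet)[div$population]
      utils::write.table(div, file.path(cfg$out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log <- pp_log(log, "[diversity] per-population table written (%d pops)",
                    nrow(div))
      res$diversity <- div
    } else {
      log <- pp_log(log, "[diversity] skipped: no fold4 accessible length")
    }
  } else {
    log <- pp_log(log, "[diversity] skipped: no annotation supplied")
  }

  # --- structure --------------------------------------------------------
  pools <- split(sheet$population, sheet$source_pool)
  pools <- lapply(pools, unique)
  if (cfg$run_structure) {
    fst <- fst_matrix(g_split, sheet_split)
    utils::write.table(fst, file.path(cfg$out_dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    am <- amova_two_level(g_split, sheet_split)
    pc <- pca_genotypes(g_split)
    utils::write.table(pc$scores, file.path(cfg$out_dir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE)
    anc <- NULL
    if (length(pools) >= 2L) {
      anc <- eigmix_ancestry(pc$scores, sheet_split, pools,
                             n_pcs = cfg$n_pcs)
      utils::write.table(anc$weights,
                         file.path(cfg$out_dir, "ancestry.tsv"),
                         sep = "\t", quote = FALSE)
    }
    log <- pp_log(log,
      "[structure] mean pairwise Fst %.4f; AMOVA among %.1f%%",
      mean(fst[upper.tri(fst)], na.rm = TRUE), am$percent[["among"]])
    res$structure <- list(fst = fst, amova = am, pca = pc, ancestry = anc)
  }

  # --- geneflow ---------------------------------------------------------
  if (cfg$run_geneflow && cfg$run_structure) {
    if (any(is.na(sheet$lat)) || any(is.na(sheet$lon))) {
      log <- pp_log(log, "[geneflow] skipped: missing lat/lon")
    } else {
      pairs <- distance_pairs(res$structure$fst, sheet, pools)
      utils::write.table(pairs, file.path(cfg$out_dir, "ibd_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gd <- matrix(0, nrow(res$structure$fst), ncol(res$structure$fst),
                   dimnames = dimnames(res$structure$fst))
      for (k in seq_len(nrow(pairs))) {
        gd[pairs$pop_a[k], pairs$pop_b[k]] <- pairs$geo_km[k]
        gd[pairs$pop_b[k], pairs$pop_a[k]] <- pairs$geo_km[k]
      }
      lin <- res$structure$fst / (1 - res$structure$fst)
      mt <- mantel_test(lin, gd, n_perm = cfg$n_perm,
                        seed = sub_seed(cfg$seed, 41L))
      nm <- tryCatch(rousset_nm(pairs), error = function(e) NULL)
      log <- pp_log(log, "[geneflow] Mantel r=%.3f p=%.4f; Nm=%s",
                    mt$r, mt$p,
                    if (is.null(nm) || is.na(nm$nm)) "undefined"
                    else sprintf("%.1f", nm$nm))
      res$geneflow <- list(pairs = pairs, mantel = mt, nm = nm)
    }
  }

  # --- psra -------------------------------------------------------------
  if (cfg$run_psra) {
    if (length(pools) < 2L) {
      log <- pp_log(log, "[psra] skipped: fewer than 2 source pools")
    } else {
      pt <- psra(g_split, sheet_split, pools, c_max = cfg$c_max)
      if (!is.null(pt$table)) {
        utils::write.table(pt$table, file.path(cfg$out_dir, "psra.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        sm <- psra_summary(pt)
        utils::write.table(sm, file.path(cfg$out_dir, "psra_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        log <- pp_log(log, "[psra] %d defined cells over %d populations",
                      nrow(pt$table), length(unique(pt$table$population)))
        res$psra <- list(table = pt, summary = sm)
      } else {
        log <- pp_log(log, "[psra] no defined cells")
      }
    }
  }

  # --- organelle --------------------------------------------------------
  if (cfg$run_organelle) {
    for (cmp in c("mito", "chloro")) {
      src <- cfg[[paste0(if (cmp == "mito") "mito" else "chloro", "_vcf")]]
      if (is.null(src)) next
      go <- load_geno(src, cmp)
      go <- organelle_filter(go)
      if (ncol(go$gt) < 1L || nrow(go$gt) < 2L) {
        log <- pp_log(log, "[organelle:%s] skipped: empty after filtering",
                      cmp)
        next
      }
      hm <- hamming_matrix(go)
      net <- build_network(hm$distances)
      com <- detect_communities(net, resolution = cfg$resolution,
                                seed = sub_seed(cfg$seed, 51L))
      sheet_o <- sheet[match(rownames(go$gt), sheet$sample), ]
      am <- amova_two_level(go, sheet_o)
      utils::write.table(net$edges,
                         file.path(cfg$out_dir,
                                   paste0(cmp, "_network.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(sample = names(com), community = com),
        file.path(cfg$out_dir, paste0(cmp, "_communities.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      log <- pp_log(log,
        "[organelle:%s] %d samples, %d loci, %d communities, among %.1f%%",
        cmp, nrow(go$gt), ncol(go$gt), length(unique(com)),
        am$percent[["among"]])
      res[[paste0("organelle_", cmp)]] <-
        list(geno = go, network = net, communities = com, amova = am)
    }
  }

  writeLines(log$lines, file.path(cfg$out_dir, "manifest.log"))
  res$manifest <- log$lines
  invisible(res)
}
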