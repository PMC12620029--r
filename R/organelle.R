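#' Organelle-specific genotype filtering
#'
#' Organellar (mitochondrial, chloroplast) data is haploid, so heterozygous
#' calls are artifacts. The filter applies, in this fixed order: (1) mark
#' every heterozygous call missing; (2) drop loci where any heterozygous
#' call was observed; (3) drop samples with more than `max_miss_sample`
#' missing data; (4) drop loci with more than `max_miss_locus` missing
#' data. No minimum-depth rule is applied (organelle coverage is low).
#'
#' @param g a [geno] object with compartment `mito` or `chloro`.
#' @param max_miss_sample,max_miss_locus missingness ceilings (default 0.25
#'   each).
#' @return the filtered [geno] object (possibly empty; a message reports
#'   the surviving dimensions).
#' @export
organelle_filter <- function(g, max_miss_sample = 0.25,
                             max_miss_locus = 0.25) {
  if (!g$compartment %in% c("mito", "chloro"))
    stop("organelle_filter expects a mito or chloro compartment",
         call. = FALSE)
  had_het <- colSums(g$gt == 1L, na.rm = TRUE) > 0L
  g$gt[g$gt == 1L] <- NA_integer_
  g <- geno_subset(g, loci = !had_het)
  keep_s <- rowMeans(is.na(g$gt)) <= max_miss_sample
  g <- geno_subset(g, samples = keep_s)
  keep_l <- colMeans(is.na(g$gt)) <= max_miss_locus
  g <- geno_subset(g, loci = keep_l)
  g
}

#' Pairwise Hamming distances between haplotypes
#'
#' Counts mismatching, jointly non-missing loci for every sample pair.
#' Pairs sharing fewer than `min_joint` of the loci are flagged as
#' low-confidence; under missingness the triangle inequality can fail,
#' which is reported, not repaired.
#'
#' @param g an all-haploid [geno] object.
#' @param min_joint minimum fraction of jointly called loci (default 0.5).
#' @return list with `distances` (symmetric integer matrix),
#'   `low_confidence` (logical matrix) and `n_joint`.
#' @export
hamming_matrix <- function(g, min_joint = 0.5) {
  d <- dosage(g)
  n <- nrow(d)
  L <- ncol(d)
  called <- !is.na(d)
  d0 <- d
  d0[!called] <- 0L
  storage.mode(d0) <- "double"
  called_n <- called * 1
  joint <- tcrossprod(called_n)
  # mismatches among jointly called binary loci:
  # sum x(1-y) + y(1-x) over joint sites
  xy <- tcrossprod(d0 * called_n, d0 * called_n)
  x_joint <- (d0 * called_n) %*% t(called_n)
  mism <- x_joint + t(x_joint) - 2 * xy
  dist <- round(mism)
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(d), rownames(d))
  list(distances = dist, low_confidence = joint < min_joint * L,
       n_joint = joint)
}

#' Minimum spanning haplotype network
#'
#' Builds a minimum spanning network: the edges of a minimum spanning tree
#' plus every tied alternative - at each distance level, all edges of that
#' length joining components that were distinct when the level started are
#' kept. Edge labels are mutation counts. Deterministic (no randomized tie
#' handling).
#'
#' @param dist symmetric distance matrix (e.g. from [hamming_matrix()]).
#' @return object of class `haplo_network`: `edges` (data.frame `node_a`,
#'   `node_b`, `mutations`, `weight = 1/(1+mutations)`), `nodes`.
#' @export
build_network <- function(dist) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  nodes <- rownames(dist) %||% as.character(seq_len(n))
  comp <- seq_len(n) # union-find parent vector
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- list()
  ut <- which(upper.tri(dist), arr.ind = TRUE)
  lev <- sort(unique(dist[upper.tri(dist)]))
  for (d0 in lev) {
    at <- ut[dist[ut] == d0, , drop = FALSE]
    comp_at_start <- vapply(seq_len(n), find, integer(1))
    for (e in seq_len(nrow(at))) {
      i <- at[e, 1]; j <- at[e, 2]
      # keep every edge of this length bridging components as they stood
      # when the level started: the MST plus all ties
      if (comp_at_start[i] != comp_at_start[j]) {
        edges[[length(edges) + 1L]] <- data.frame(
          node_a = nodes[i], node_b = nodes[j], mutations = d0,
          stringsAsFactors = FALSE)
        ri <- find(i); rj <- find(j)
        if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
      }
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1L) break
  }
  ed <- do.call(rbind, edges)
  if (is.null(ed))
    ed <- data.frame(node_a = character(), node_b = character(),
                     mutations = numeric(), stringsAsFactors = FALSE)
  ed$weight <- 1 / (1 + ed$mutations)
  structure(list(edges = ed, nodes = nodes), class = "haplo_network")
}

#' Louvain communities on a haplotype network
#'
#' Louvain modularity optimization with a resolution parameter. Mutation
#' counts are distances, whereas Louvain expects affinities, so edges are
#' weighted by the similarity transform `1/(1 + mutations)` (larger
#' mutation counts weaken community ties). Node ordering is seeded for
#' reproducibility.
#'
#' @param net a [build_network()] result.
#' @param resolution Louvain resolution (default 0.2; low values limit the
#'   number of clusters).
#' @param seed integer seed.
#' @return named integer vector: community id per node (a partition).
#' @export
detect_communities <- function(net, resolution = 0.2, seed = 1) {
  stopifnot(inherits(net, "haplo_network"))
  if (length(net$nodes) == 1L)
    return(stats::setNames(1L, net$nodes))
  gr <- igraph::graph_from_data_frame(
    net$edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  with_seed(seed, {
    cl <- igraph::cluster_louvain(gr, weights = net$edges$weight,
                                  resolution = resolution)
    m <- igraph::membership(cl)
    stats::setNames(as.integer(m), names(m))[net$nodes]
  })
}
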