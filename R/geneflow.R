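#' Great-circle distance between two coordinates
#'
#' Haversine formula with an Earth radius of 6371.0 km.
#'
#' @param lat_a,lon_a,lat_b,lon_b coordinates in decimal degrees.
#' @return distance in km.
#' @export
geo_distance <- function(lat_a, lon_a, lat_b, lon_b) {
  if (any(abs(c(lat_a, lat_b)) > 90) || any(abs(c(lon_a, lon_b)) > 180))
    stop("coordinates out of range", call. = FALSE)
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat_b - lat_a) * to_rad
  dlon <- (lon_b - lon_a) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(lat_a * to_rad) * cos(lat_b * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(h)))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries; the two-sided p-value
#' compares |r| with its distribution under `n_perm` seeded joint
#' row/column permutations: `p = (1 + #{|r*| >= |r|}) / (n_perm + 1)`.
#'
#' @param gen_mat,geo_mat square symmetric matrices over the same
#'   populations.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm` and `warning` (set with fewer than
#'   4 populations, where the permutation distribution is too coarse).
#' @export
mantel_test <- function(gen_mat, geo_mat, n_perm = 999, seed = 1) {
  gen_mat <- as.matrix(gen_mat)
  geo_mat <- as.matrix(geo_mat)
  stopifnot(all(dim(gen_mat) == dim(geo_mat)),
            nrow(gen_mat) == ncol(gen_mat))
  P <- nrow(gen_mat)
  lt <- lower.tri(gen_mat)
  x <- gen_mat[lt]
  y <- geo_mat[lt]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_obs <- stats::cor(x, y)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(P)
      rp <- stats::cor(gen_mat[idx, idx][lt], y)
      if (abs(rp) >= abs(r_obs) - 1e-15) cnt <- cnt + 1L
    }
    cnt
  })
  list(r = r_obs, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
       warning = if (P < 4) "fewer than 4 populations: p unreliable"
       else NULL)
}

#' Build the population-pair table for isolation-by-distance analyses
#'
#' Combines a pairwise F_st matrix and population coordinates into one row
#' per unordered pair with the linearized genetic distance
#' `F_st / (1 - F_st)` and the great-circle distance in km. Pairs touching a
#' refugial source pool are tagged for subsetting.
#'
#' @param fst pairwise F_st matrix (row/col names are populations).
#' @param sheet sample sheet with per-population `lat`/`lon`.
#' @param source_pools optional named list mapping pool name to populations.
#' @return data.frame with columns `pop_a`, `pop_b`, `geo_km`, `fst`,
#'   `lin_fst`, `refugium_tag` (comma-joined pool names the pair touches).
#' @export
distance_pairs <- function(fst, sheet, source_pools = NULL) {
  pops <- rownames(fst)
  coord <- unique(sheet[, c("population", "lat", "lon")])
  rownames(coord) <- coord$population
  pool_of <- function(p) {
    hits <- names(source_pools)[vapply(source_pools, function(m) p %in% m,
                                       logical(1))]
    if (length(hits)) hits else character()
  }
  out <- list()
  for (i in seq_len(length(pops) - 1)) for (j in seq((i + 1), length(pops))) {
    a <- pops[i]; b <- pops[j]
    f <- fst[a, b]
    if (!is.finite(f) || f >= 1) next
    tags <- unique(c(pool_of(a), pool_of(b)))
    out[[length(out) + 1L]] <- data.frame(
      pop_a = a, pop_b = b,
      geo_km = geo_distance(coord[a, "lat"], coord[a, "lon"],
                            coord[b, "lat"], coord[b, "lon"]),
      fst = f, lin_fst = f / (1 - f),
      refugium_tag = paste(tags, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Rousset's Nm from the isolation-by-distance regression
#'
#' Ordinary least squares of the linearized genetic distance
#' `F_st / (1 - F_st)` on the natural log of geographic distance; the
#' effective number of migrants is the inverse of the slope. Pairs at zero
#' geographic distance are excluded (log undefined). Optionally restricts
#' to pairs touching a focal refugium (one population inside, one outside),
#' or excluding given pools entirely.
#'
#' @param pairs a [distance_pairs()] table.
#' @param subset `"all"` (default), a pool name (keep pairs with exactly one
#'   member in that pool), or `c("exclude", pool names)` to drop populations
#'   belonging to those pools.
#' @param source_pools pool definition needed for the subsets.
#' @return list with `slope`, `intercept`, `nm` (NA with a diagnostic when
#'   the slope is not positive), `n_pairs` and `subset`.
#' @export
rousset_nm <- function(pairs, subset = "all", source_pools = NULL) {
  lab <- paste(subset, collapse = "+")
  if (!identical(subset, "all")) {
    in_pool <- function(p, pools) {
      any(vapply(pools, function(m) p %in% m, logical(1)))
    }
    if (subset[1] == "exclude") {
      pools <- source_pools[subset[-1]]
      drop <- vapply(seq_len(nrow(pairs)), function(i)
        in_pool(pairs$pop_a[i], pools) || in_pool(pairs$pop_b[i], pools),
        logical(1))
      pairs <- pairs[!drop, , drop = FALSE]
    } else {
      mem <- source_pools[[subset]]
      if (is.null(mem)) stop("unknown subset ", subset, call. = FALSE)
      one <- (pairs$pop_a %in% mem) + (pairs$pop_b %in% mem) == 1L
      pairs <- pairs[one, , drop = FALSE]
    }
  }
  pairs <- pairs[pairs$geo_km > 0, , drop = FALSE]
  if (nrow(pairs) < 3L)
    stop("need >= 3 pairs with positive distance", call. = FALSE)
  fit <- stats::lm(lin_fst ~ log(geo_km), data = pairs)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  nm <- if (is.finite(slope) && slope > 0) 1 / slope else NA_real_
  list(slope = slope, intercept = intercept, nm = nm,
       n_pairs = nrow(pairs), subset = lab,
       diagnostic = if (is.na(nm)) "non-positive slope: Nm undefined"
       else NULL)
}

#' Ennos pollen/seed gene-flow ratios
#'
#' Island-model equilibrium algebra contrasting differentiation of
#' biparentally inherited (nuclear), maternally inherited (mitochondrial,
#' seed-dispersed) and paternally inherited (chloroplast, pollen- and
#' seed-dispersed) markers:
#' `r5 = ((1/fst_bi - 1) - 2 (1/fst_mat - 1)) / (1/fst_mat - 1)` and
#' `r6 = (1/fst_pat - 1) / (1/fst_mat - 1) - 1`.
#'
#' @param fst_bi,fst_mat,fst_pat multilocus F_st of the biparental,
#'   maternal and paternal marker sets; each must lie strictly in (0, 1).
#'   Pass NA to skip the corresponding ratio.
#' @return list with `r_eq5`, `r_eq6` and `warning` (set when a ratio is
#'   negative, a violation of the equilibrium model).
#' @export
ennos_ratio <- function(fst_bi = NA, fst_mat, fst_pat = NA) {
  chk <- function(x, nm) {
    if (!is.na(x) && (!is.finite(x) || x <= 0 || x >= 1))
      stop(nm, " must lie strictly in (0,1)", call. = FALSE)
  }
  chk(fst_bi, "fst_bi"); chk(fst_mat, "fst_mat"); chk(fst_pat, "fst_pat")
  gm <- 1 / fst_mat - 1
  r5 <- if (is.na(fst_bi)) NA_real_ else ((1 / fst_bi - 1) - 2 * gm) / gm
  r6 <- if (is.na(fst_pat)) NA_real_ else (1 / fst_pat - 1) / gm - 1
  warn <- NULL
  if ((!is.na(r5) && r5 < 0) || (!is.na(r6) && r6 < 0))
    warn <- "negative pollen/seed ratio: equilibrium model violated"
  list(r_eq5 = r5, r_eq6 = r6, warning = warn)
}
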