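#' Trait centroid of a species
#'
#' The centroid of species s is the per-trait arithmetic mean over its
#' members, \code{B_k(s) = sum_i T_k(i) / n_s}. Means of simplex points stay
#' on the simplex.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param s a species label present on the grid.
#' @return \code{list(species, centroid, abundance)}.
#' @export
species_centroid <- function(grid, s) {
  idx <- which(grid$species == s)
  if (length(idx) == 0L) stop("species ", s, " is not present on the grid")
  list(species = as.integer(s),
       centroid = colMeans(grid$traits[idx, , drop = FALSE]),
       abundance = length(idx))
}

#' Surviving species
#'
#' @param grid a \code{\link{community_grid}}.
#' @return \code{list(count, labels)}; the count is non-increasing along a
#'   trajectory since no new labels ever arise.
#' @export
surviving_species <- function(grid) {
  labels <- sort(unique(grid$species))
  list(count = length(labels), labels = labels)
}

# centroid matrix of the surviving species (rows named by label)
centroid_matrix <- function(grid) {
  sums <- rowsum(grid$traits, grid$species)
  counts <- as.vector(table(grid$species)[rownames(sums)])
  sums / counts
}

#' Mean interspecies distance
#'
#' The distance between two species is the normalised L1 distance between
#' their trait centroids, \code{d_ss' = sum_k |B_k(s) - B_k(s')| / n};
#' reported is the mean over all unordered pairs of surviving species.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return a number in [0, 2/n], or \code{NA} when fewer than 2 species
#'   survive.
#' @export
mean_interspecies_distance <- function(grid) {
  B <- centroid_matrix(grid)
  S <- nrow(B)
  if (S < 2L) return(NA_real_)
  mean(stats::dist(B, method = "manhattan")) / ncol(B)
}

#' Mean intraspecific distance
#'
#' For each species with at least 2 members, the mean trait complementarity
#' over all its ordered pairs of members,
#' \code{d_s = sum_{i,j in s} c_ij / (n_s (n_s - 1))}; reported is the
#' unweighted mean of \code{d_s} over the qualifying species.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return a number in [0, 2/n], or \code{NA} when no species has 2 members.
#' @export
mean_intraspecific_distance <- function(grid) {
  n <- grid$n
  labels <- sort(unique(grid$species))
  ds <- vapply(labels, function(s) {
    idx <- which(grid$species == s)
    m <- length(idx)
    if (m < 2L) return(NA_real_)
    tot <- 0
    for (k in seq_len(n)) tot <- tot + l1_pair_total(grid$traits[idx, k])
    2 * tot / (n * m * (m - 1))
  }, numeric(1))
  if (all(is.na(ds))) NA_real_ else mean(ds, na.rm = TRUE)
}

# sum over unordered pairs of |x_i - x_j| in O(N log N)
l1_pair_total <- function(x) {
  N <- length(x)
  xs <- sort(x)
  sum(xs * (2 * seq_len(N) - 1 - N))
}

#' Mean local complementarity (LC)
#'
#' The community average of \code{\link{local_complementarity}} over all
#' \code{N = L^2} sites: the mean trait distance of individuals to their
#' spatial neighbours, i.e. the realised reduction in local competition.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return a number in [0, 2/n].
#' @export
mean_local_complementarity <- function(grid) {
  mean(compute_local_C(grid$traits, grid$kernel))
}

#' Global complementarity (GC, GC_intra, GC_inter)
#'
#' GC is the mean complementarity over all ordered pairs of individuals
#' regardless of position, \code{GC = sum_{i, j != i} c_ij / (N (N - 1))};
#' GC_intra and GC_inter restrict the average to conspecific and
#' heterospecific pairs respectively. The abundance-weighted identity
#' \code{GC * N(N-1) = GC_intra * #conspecific + GC_inter * #heterospecific}
#' holds exactly.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return named numeric vector \code{c(GC, GC_intra, GC_inter)};
#'   \code{GC_intra} is \code{NA} if every species is a singleton and
#'   \code{GC_inter} is \code{NA} for a monoculture (use
#'   \code{\link{relative_complementarity}} with a second realization).
#' @export
global_complementarity <- function(grid) {
  n <- grid$n
  N <- grid$L^2
  total <- 0
  for (k in seq_len(n)) total <- total + l1_pair_total(grid$traits[, k])
  intra <- 0
  intra_pairs <- 0
  for (s in unique(grid$species)) {
    idx <- which(grid$species == s)
    m <- length(idx)
    if (m < 2L) next
    for (k in seq_len(n)) intra <- intra + l1_pair_total(grid$traits[idx, k])
    intra_pairs <- intra_pairs + m * (m - 1) / 2
  }
  all_pairs <- N * (N - 1) / 2
  inter_pairs <- all_pairs - sum(table(grid$species) * (table(grid$species) - 1) / 2)
  c(GC = total / (n * all_pairs),
    GC_intra = if (intra_pairs > 0) intra / (n * intra_pairs) else NA_real_,
    GC_inter = if (inter_pairs > 0) (total - intra) / (n * inter_pairs) else NA_real_)
}

#' Relative complementarity (RC)
#'
#' \code{RC = GC_inter - GC_intra}: the average difference in competition
#' level between randomly sampled heterospecific and conspecific pairs. For a
#' monoculture, heterospecific pairs do not exist within one community, so
#' GC_inter is measured across two independent realizations of the same
#' process: the mean complementarity over all cross-realization pairs, with
#' GC_intra pooled over the within-realization pairs of both.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param grid2 an independent replicate community; required when
#'   \code{grid} is a monoculture, ignored otherwise.
#' @return RC (may be negative).
#' @export
relative_complementarity <- function(grid, grid2 = NULL) {
  if (length(unique(grid$species)) >= 2L) {
    gc <- global_complementarity(grid)
    return(unname(gc["GC_inter"] - gc["GC_intra"]))
  }
  if (is.null(grid2))
    stop("monoculture RC needs a second independent realization ('grid2')")
  n <- grid$n
  cross <- 0
  for (k in seq_len(n))
    cross <- cross + l1_cross_total(grid$traits[, k], grid2$traits[, k])
  gc_inter <- cross / (n * nrow(grid$traits) * nrow(grid2$traits))
  w1 <- monoculture_within(grid)
  w2 <- monoculture_within(grid2)
  gc_intra <- (w1$sum + w2$sum) / (grid$n * (w1$pairs + w2$pairs))
  gc_inter - gc_intra
}

monoculture_within <- function(grid) {
  N <- nrow(grid$traits)
  tot <- 0
  for (k in seq_len(grid$n)) tot <- tot + l1_pair_total(grid$traits[, k])
  list(sum = tot, pairs = N * (N - 1) / 2)
}

# sum over all cross pairs of |x_i - y_j| in O((N+M) log M)
l1_cross_total <- function(x, y) {
  ys <- sort(y)
  cs <- cumsum(ys)
  M <- length(ys)
  m <- findInterval(x, ys)
  tot_y <- cs[M]
  csm <- c(0, cs)[m + 1L]
  sum(x * (2 * m - M) - 2 * csm + tot_y)
}

#' Multi-species Moran's I
#'
#' Spatial autocorrelation of species occupancy. For each species s with
#' abundance at least 2, the classical Moran statistic is computed on the
#' 0/1 indicator x of s with binary weights \code{w_ij = 1} iff j is in i's
#' neighbour kernel:
#' \code{I_s = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2}, \code{W = sum_ij w_ij}. The community index is the
#' abundance-weighted mean of \code{I_s} over qualifying species. Positive
#' values indicate conspecific clustering; negative values conspecific
#' avoidance; random labels give the permutation-null expectation
#' \code{-1 / (N - 1)}.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param per_species return the per-species values instead of the community
#'   index.
#' @return the community index in approximately [-1, 1], or \code{NA} when
#'   fewer than 2 species have abundance >= 2.
#' @export
morans_index <- function(grid, per_species = FALSE) {
  N <- grid$L^2
  nb <- grid$kernel$nb
  W <- sum(grid$kernel$nb_count)
  ab <- table(grid$species)
  labels <- as.integer(names(ab))[ab >= 2L]
  ab <- as.integer(ab[ab >= 2L])
  ok <- ab < N   # a species filling the whole grid has zero indicator variance
  labels <- labels[ok]
  ab <- ab[ok]
  Is <- vapply(labels, function(s) {
    z <- as.numeric(grid$species == s)
    z <- z - mean(z)
    lag <- numeric(N)
    for (j in seq_len(ncol(nb))) {
      nbj <- nb[, j]
      if (anyNA(nbj)) {
        okj <- which(!is.na(nbj))
        lag[okj] <- lag[okj] + z[nbj[okj]]
      } else {
        lag <- lag + z[nbj]
      }
    }
    (N / W) * sum(z * lag) / sum(z^2)
  }, numeric(1))
  if (per_species) return(stats::setNames(Is, labels))
  if (length(Is) < 2L) return(NA_real_)
  stats::weighted.mean(Is, ab)
}

#' Mean distance to the nearest simplex vertex
#'
#' The L1 distance of a phenotype to its nearest vertex of the trade-off
#' simplex is \code{2 (1 - max_k T_k) / n}; the community mean measures the
#' degree of specialization (0 = every individual a perfect specialist).
#'
#' @param grid a \code{\link{community_grid}}.
#' @return a number in [0, 2(1 - 1/n)/n].
#' @export
mean_vertex_distance <- function(grid) {
  mean(nearest_vertex_distance(grid$traits))
}

#' Group phenotypically equivalent species
#'
#' Single-linkage grouping of the surviving species whose pairwise centroid
#' distances fall below \code{eps}; groups of size >= 2 flag coexisting,
#' phenotypically (near-)equivalent species occupying the same niche region.
#'
#' @param grid a \code{\link{community_grid}} with >= 2 surviving species.
#' @param eps centroid-distance threshold (> 0).
#' @return a list of integer vectors of species labels (singletons included),
#'   ordered by smallest member label.
#' @export
detect_equivalent_species <- function(grid, eps) {
  if (eps <= 0) stop("'eps' must be > 0")
  B <- centroid_matrix(grid)
  labels <- as.integer(rownames(B))
  S <- length(labels)
  if (S < 2L) stop("need at least 2 surviving species")
  D <- as.matrix(stats::dist(B, method = "manhattan")) / ncol(B)
  groups_from_adjacency(D < eps, labels)
}

# connected components of an adjacency matrix via union-find
groups_from_adjacency <- function(adj, labels) {
  S <- length(labels)
  parent <- seq_len(S)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S)
    if (adj[i, j]) parent[max(find(i), find(j))] <- min(find(i), find(j))
  roots <- vapply(seq_len(S), find, integer(1))
  out <- lapply(split(labels, roots), sort)
  names(out) <- NULL
  out[order(vapply(out, min, integer(1)))]
}

#' One generation's biodiversity indices
#'
#' Computes the full index record for a community: surviving-species count,
#' mean inter- and intraspecific trait distances, local complementarity (LC),
#' global complementarities (GC, GC_intra, GC_inter), relative
#' complementarity (RC = GC_inter - GC_intra), the multi-species Moran index,
#' and the mean distance to the nearest simplex vertex. Indices whose
#' preconditions fail (e.g. GC_inter for a monoculture, Moran's I with fewer
#' than two species of abundance >= 2) are reported as \code{NA}.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return a one-row data frame with columns \code{generation},
#'   \code{S_surviving}, \code{interspecies_distance},
#'   \code{intraspecific_distance}, \code{LC}, \code{GC}, \code{GC_intra},
#'   \code{GC_inter}, \code{RC}, \code{moran_I}, \code{vertex_distance}.
#' @export
community_metrics <- function(grid) {
  gc <- global_complementarity(grid)
  data.frame(
    generation = grid$generation,
    S_surviving = length(unique(grid$species)),
    interspecies_distance = mean_interspecies_distance(grid),
    intraspecific_distance = mean_intraspecific_distance(grid),
    LC = mean_local_complementarity(grid),
    GC = unname(gc["GC"]),
    GC_intra = unname(gc["GC_intra"]),
    GC_inter = unname(gc["GC_inter"]),
    RC = unname(gc["GC_inter"] - gc["GC_intra"]),
    moran_I = morans_index(grid),
    vertex_distance = mean_vertex_distance(grid)
  )
}
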