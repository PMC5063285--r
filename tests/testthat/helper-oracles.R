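# Independent brute-force oracles: direct loop implementations of every
# quantity, kept deliberately naive and separate from the package's
# vectorized code paths.

# all sites within Chebyshev distance <= radius of site i, by exhaustive
# enumeration over the full lattice
oracle_neighbors <- function(i, L, radius, periodic = TRUE) {
  r0 <- (i - 1) %% L
  c0 <- (i - 1) %/% L
  out <- integer(0)
  for (j in seq_len(L * L)) {
    if (j == i) next
    r1 <- (j - 1) %% L
    c1 <- (j - 1) %/% L
    dr <- abs(r1 - r0); dc <- abs(c1 - c0)
    if (periodic) { dr <- min(dr, L - dr); dc <- min(dc, L - dc) }
    if (max(dr, dc) <= radius) out <- c(out, j)
  }
  sort(out)
}

oracle_c <- function(a, b) sum(abs(a - b)) / length(a)

oracle_local_C <- function(grid, i) {
  nbs <- oracle_neighbors(i, grid$L, grid$kernel$radius,
                          grid$kernel$boundary == "periodic")
  if (grid$kernel$boundary == "bounded") {
    # re-enumerate without wraparound
    nbs <- Filter(function(j) {
      dr <- abs((j - 1) %% grid$L - (i - 1) %% grid$L)
      dc <- abs((j - 1) %/% grid$L - (i - 1) %/% grid$L)
      max(dr, dc) <= grid$kernel$radius
    }, setdiff(seq_len(grid$L^2), i))
  }
  mean(vapply(nbs, function(j) oracle_c(grid$traits[i, ], grid$traits[j, ]),
              numeric(1)))
}

oracle_LC <- function(grid) {
  mean(vapply(seq_len(grid$L^2), function(i) oracle_local_C(grid, i), numeric(1)))
}

oracle_GC <- function(grid) {
  N <- grid$L^2
  tot <- 0; intra <- 0; np_intra <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    cij <- oracle_c(grid$traits[i, ], grid$traits[j, ])
    tot <- tot + cij
    if (grid$species[i] == grid$species[j]) { intra <- intra + cij; np_intra <- np_intra + 1 }
  }
  np <- N * (N - 1) / 2
  c(GC = tot / np,
    GC_intra = if (np_intra > 0) intra / np_intra else NA_real_,
    GC_inter = if (np > np_intra) (tot - intra) / (np - np_intra) else NA_real_)
}

oracle_centroid <- function(grid, s) {
  idx <- which(grid$species == s)
  tot <- rep(0, grid$n)
  for (i in idx) tot <- tot + grid$traits[i, ]
  tot / length(idx)
}

oracle_interspecies <- function(grid) {
  labs <- sort(unique(grid$species))
  if (length(labs) < 2) return(NA_real_)
  ds <- c()
  for (a in seq_along(labs)[-length(labs)]) for (b in (a + 1):length(labs))
    ds <- c(ds, oracle_c(oracle_centroid(grid, labs[a]), oracle_centroid(grid, labs[b])))
  mean(ds)
}

oracle_intraspecific <- function(grid) {
  labs <- sort(unique(grid$species))
  ds <- c()
  for (s in labs) {
    idx <- which(grid$species == s)
    m <- length(idx)
    if (m < 2) next
    tot <- 0
    for (i in idx) for (j in idx) if (i != j)
      tot <- tot + oracle_c(grid$traits[i, ], grid$traits[j, ])
    ds <- c(ds, tot / (m * (m - 1)))
  }
  if (length(ds)) mean(ds) else NA_real_
}

# full-weight-matrix Moran's I for one species indicator
oracle_moran_species <- function(grid, s) {
  N <- grid$L^2
  wmat <- matrix(0, N, N)
  for (i in seq_len(N))
    wmat[i, oracle_neighbors(i, grid$L, grid$kernel$radius,
                             grid$kernel$boundary == "periodic")] <- 1
  x <- as.numeric(grid$species == s)
  z <- x - mean(x)
  (N / sum(wmat)) * sum(wmat * outer(z, z)) / sum(z^2)
}

oracle_moran <- function(grid) {
  ab <- table(grid$species)
  labs <- as.integer(names(ab))[ab >= 2 & ab < grid$L^2]
  if (length(labs) < 2) return(NA_real_)
  Is <- vapply(labs, function(s) oracle_moran_species(grid, s), numeric(1))
  sum(Is * as.integer(ab[as.character(labs)])) / sum(as.integer(ab[as.character(labs)]))
}

# random community grid with traits scattered on the simplex
random_grid <- function(L, S, n = 3, radius = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kernel <- make_neighbor_kernel(L, radius = radius)
  N <- L * L
  e <- matrix(rexp(N * n), N, n)
  community_grid(sample.int(S, N, replace = TRUE), e / rowSums(e), kernel)
}
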