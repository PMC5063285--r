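#' Local complementarity of individuals
#'
#' The (local) complementarity of individual i is the mean trait
#' complementarity to its K spatial neighbours,
#' \code{C_i = sum_{j in nn(i)} c_ij / K}. It measures how different an
#' individual is from the plants it actually competes with: \code{C_i = 0}
#' when all neighbours share its phenotype, and at most 2/n.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param site site index (1..L^2), or a vector of site indices.
#' @return numeric vector of complementarities, one per requested site.
#' @export
local_complementarity <- function(grid, site) {
  N <- grid$L^2
  if (any(site < 1L | site > N)) stop("site index out of range 1..", N)
  compute_local_C(grid$traits, grid$kernel, sites = site)
}

# local C for all sites (sites = NULL) or a subset; bounded-edge sites
# normalise over their actual neighbour count.
compute_local_C <- function(traits, kernel, sites = NULL) {
  n <- ncol(traits)
  nb <- kernel$nb
  if (is.null(sites)) {
    acc <- numeric(nrow(nb))
    for (j in seq_len(ncol(nb))) {
      nbj <- nb[, j]
      if (anyNA(nbj)) {
        ok <- which(!is.na(nbj))
        acc[ok] <- acc[ok] +
          rowSums(abs(traits[ok, , drop = FALSE] - traits[nbj[ok], , drop = FALSE]))
      } else {
        acc <- acc + rowSums(abs(traits - traits[nbj, , drop = FALSE]))
      }
    }
    acc / (n * kernel$nb_count)
  } else {
    vapply(sites, function(i) {
      js <- nb[i, ]
      js <- js[!is.na(js)]
      d <- abs(traits[js, , drop = FALSE] -
                 matrix(traits[i, ], nrow = length(js), ncol = n, byrow = TRUE))
      sum(d) / (n * length(js))
    }, numeric(1))
  }
}

# well-mixed complementarity: mean c_ij of each individual against all N-1
# others. Per trait component, the per-point sum of absolute differences is
# computed in O(N log N) from the sorted order and prefix sums.
compute_wellmixed_C <- function(traits) {
  N <- nrow(traits)
  n <- ncol(traits)
  acc <- numeric(N)
  for (k in seq_len(n)) acc <- acc + l1_allpair_sums(traits[, k])
  acc / (n * (N - 1))
}

# s_i = sum_j |x_i - x_j| for every i (j over all elements, including i)
l1_allpair_sums <- function(x) {
  N <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  s <- xs * (2 * seq_len(N) - N) - 2 * cs + cs[N]
  out <- numeric(N)
  out[o] <- s
  out
}

#' Performance of an individual
#'
#' Maps complementarity C to reproductive performance. The default is the
#' exponential kernel \code{exp(beta * C)}; the alternative families are
#' \code{"linear"} (\code{1 + beta * C}) and \code{"gaussian"}
#' (\code{exp(beta * (1 - (1 - C)^2))}), all strictly positive and
#' non-decreasing in C, and all equal to a constant at \code{beta = 0}
#' (so selection becomes uniform and the dynamics neutral).
#'
#' @param C complementarity value(s), >= 0.
#' @param beta competition strength, >= 0.
#' @param kernel_type \code{"exponential"}, \code{"linear"} or
#'   \code{"gaussian"}.
#' @return positive numeric vector the same length as \code{C}.
#' @examples
#' performance_weight(0.5, 10)  # exp(5)
#' @export
performance_weight <- function(C, beta, kernel_type = "exponential") {
  if (any(beta < 0)) stop("'beta' must be >= 0")
  if (any(C < 0)) stop("'C' must be >= 0")
  switch(kernel_type,
    exponential = exp(beta * C),
    linear = 1 + beta * C,
    gaussian = exp(beta * (1 - (1 - C)^2)),
    stop("unknown kernel type: '", kernel_type, "'"))
}

# selection weights proportional to performance, shifted inside the
# exponential to avoid overflow at large beta (softmax is shift-invariant).
selection_weights <- function(C, beta, kernel_type = "exponential") {
  switch(kernel_type,
    exponential = exp(beta * (C - max(C, na.rm = TRUE))),
    linear = 1 + beta * C,
    gaussian = {
      e <- beta * (1 - (1 - C)^2)
      exp(e - max(e, na.rm = TRUE))
    },
    stop("unknown kernel type: '", kernel_type, "'"))
}

# multiplicative reward factor w(T) = 1 + a * T^f (1 everywhere when a = 0)
reward_multiplier <- function(traits, reward_a, reward_trait) {
  if (reward_a == 0) return(NULL)
  1 + reward_a * traits[, reward_trait]
}

# k weighted draws (with replacement) from indices 1..length(w);
# zero-total weights fall back to uniform sampling.
weighted_sample <- function(w, k) {
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  if (!is.finite(tot) || tot <= 0)
    return(sample.int(length(w), k, replace = TRUE))
  u <- stats::runif(k) * tot
  pmin.int(findInterval(u, cw) + 1L, length(w))
}

# one weighted draw per row of the weight matrix W (NA treated as 0);
# returns the chosen column index per row.
row_weighted_pick <- function(W) {
  W[is.na(W)] <- 0
  K <- ncol(W)
  cs <- W %*% upper.tri(diag(K), diag = TRUE)   # row-wise cumulative sums
  tot <- cs[, K]
  zero <- tot <= 0
  if (any(zero)) {                               # all-underflow rows: uniform
    W[zero, ] <- ifelse(W[zero, , drop = FALSE] >= 0, 1, 0)
    cs[zero, ] <- W[zero, , drop = FALSE] %*% upper.tri(diag(K), diag = TRUE)
    tot <- cs[, K]
  }
  u <- stats::runif(nrow(W)) * tot
  pick <- rowSums(cs < u) + 1L
  pmin.int(pick, K)
}

#' Select the mother for a vacant site
#'
#' All individuals die simultaneously at the start of a generation; the
#' vacant site is refilled by an offspring whose mother is drawn from the K
#' neighbours of the site, with probability proportional to her performance
#' in the pre-update grid: \code{P(j) = exp(beta * C_j) / sum_j'
#' exp(beta * C_j')} for the exponential kernel. At \code{beta = 0} every
#' neighbour is equally likely.
#'
#' Consumes the global RNG stream.
#'
#' @param grid the pre-update \code{\link{community_grid}}.
#' @param vacant_site site index being refilled.
#' @param beta competition strength.
#' @param kernel_type performance kernel (see
#'   \code{\link{performance_weight}}).
#' @param reward_a,reward_trait optional asymmetric trade-off reward (see
#'   \code{\link{biased_performance}}).
#' @param ndraws number of independent draws to return (default 1).
#' @return site index (or vector of site indices) of the selected mother(s),
#'   always neighbours of \code{vacant_site}.
#' @export
select_mother <- function(grid, vacant_site, beta,
                          kernel_type = "exponential",
                          reward_a = 0, reward_trait = 1L, ndraws = 1L) {
  N <- grid$L^2
  if (length(vacant_site) != 1L || vacant_site < 1L || vacant_site > N)
    stop("'vacant_site' must be a single site index in 1..", N)
  nbs <- grid$kernel$nb[vacant_site, ]
  nbs <- nbs[!is.na(nbs)]
  C <- compute_local_C(grid$traits, grid$kernel, sites = nbs)
  w <- selection_weights(C, beta, kernel_type)
  rw <- reward_multiplier(grid$traits, reward_a, reward_trait)
  if (!is.null(rw)) w <- w * rw[nbs]
  nbs[weighted_sample(w, ndraws)]
}

#' Select the father for a chosen mother
#'
#' The father is drawn from all conspecifics of the mother anywhere on the
#' lattice (the pool includes the mother herself, so a sole-surviving
#' conspecific effectively selfs), with probability proportional to
#' performance \code{exp(beta * C_l)}.
#'
#' Consumes the global RNG stream.
#'
#' @param grid the pre-update \code{\link{community_grid}}.
#' @param mother_site site index of the selected mother.
#' @param beta competition strength.
#' @param kernel_type,reward_a,reward_trait as in \code{\link{select_mother}}.
#' @param ndraws number of independent draws to return (default 1).
#' @return site index (or vector) of the selected father(s), conspecific with
#'   the mother.
#' @export
select_father <- function(grid, mother_site, beta,
                          kernel_type = "exponential",
                          reward_a = 0, reward_trait = 1L, ndraws = 1L) {
  N <- grid$L^2
  if (length(mother_site) != 1L || mother_site < 1L || mother_site > N)
    stop("'mother_site' must be a single site index in 1..", N)
  pool <- which(grid$species == grid$species[mother_site])
  if (length(pool) == 1L) return(rep(pool, ndraws))   # selfing
  C <- compute_local_C(grid$traits, grid$kernel, sites = pool)
  w <- selection_weights(C, beta, kernel_type)
  rw <- reward_multiplier(grid$traits, reward_a, reward_trait)
  if (!is.null(rw)) w <- w * rw[pool]
  pool[weighted_sample(w, ndraws)]
}

#' Offspring of a sexual mating
#'
#' Offspring traits are a stochastic admixture of both (conspecific) parents
#' plus sum-preserving mutation noise:
#' \code{T_new = eta * T_mother + (1 - eta) * T_father + xi}, with
#' \code{eta ~ Uniform[0, 1]} drawn once per offspring (shared across trait
#' components) and \code{xi} from \code{\link{mutation_noise}}. Out-of-bound
#' components are repaired back onto the simplex
#' (\code{\link{repair_traits}}). The offspring inherits the parental species
#' label.
#'
#' Consumes the global RNG stream.
#'
#' @param mother,father individuals: lists with elements \code{species}
#'   (integer) and \code{traits} (simplex vector). Must be conspecific.
#' @param mu trait variability.
#' @param eta_per_trait draw a separate admixture proportion per component
#'   (default \code{FALSE}: one eta per offspring).
#' @return an individual: \code{list(species =, traits =)}.
#' @export
make_offspring <- function(mother, father, mu, eta_per_trait = FALSE) {
  if (mother$species != father$species)
    stop("parents must be conspecific (got species ",
         mother$species, " and ", father$species, ")")
  n <- length(mother$traits)
  eta <- if (eta_per_trait) stats::runif(n) else stats::runif(1)
  raw <- eta * mother$traits + (1 - eta) * father$traits + mutation_noise(n, mu)
  list(species = mother$species, traits = repair_traits(raw))
}

#' Extract the individual at a site
#'
#' @param grid a \code{\link{community_grid}}.
#' @param site site index.
#' @return \code{list(species =, traits =)}.
#' @export
grid_individual <- function(grid, site) {
  list(species = grid$species[site], traits = grid$traits[site, ])
}

#' Advance the community by one generation
#'
#' In synchronous (generational) mode every individual dies at once; each
#' vacant site is refilled by an offspring whose mother is drawn from the
#' site's neighbours and whose father from the mother's conspecifics, both
#' with performance-weighted probabilities computed on the pre-update grid.
#' In sequential mode sites are replaced one at a time in random order
#' against the continuously updated grid. In the well-mixed variant both the
#' complementarity and the mother pool span the whole lattice.
#'
#' The stochastic draws of a synchronous step occur in a fixed order
#' (mothers site-by-site, then fathers grouped by species in increasing label
#' order, then admixture proportions, then mutation noise, then any repair
#' draws), so a run is fully reproducible from the seed.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param config a \code{\link{simulation_config}} (its \code{L},
#'   \code{radius} and \code{boundary} must match the grid's kernel).
#' @return the next generation's \code{\link{community_grid}}.
#' @export
step_generation <- function(grid, config) {
  if (grid$L != config$L) stop("config lattice side does not match the grid")
  if (config$update_mode == "sequential") return(step_sequential(grid, config))

  N <- grid$L^2
  n <- grid$n
  traits <- grid$traits
  C <- if (config$dispersal == "well_mixed") compute_wellmixed_C(traits)
       else compute_local_C(traits, grid$kernel)
  w <- selection_weights(C, config$beta, config$performance_kernel)
  rw <- reward_multiplier(traits, config$reward_a, config$reward_trait)
  if (!is.null(rw)) w <- w * rw

  if (config$dispersal == "well_mixed") {
    mother_site <- weighted_sample(w, N)
  } else {
    nb <- grid$kernel$nb
    W <- matrix(w[nb], nrow = N)
    pick <- row_weighted_pick(W)
    mother_site <- nb[cbind(seq_len(N), pick)]
  }
  msp <- grid$species[mother_site]
  Tm <- traits[mother_site, , drop = FALSE]

  if (config$reproduction == "sexual") {
    father_site <- integer(N)
    for (s in sort(unique(msp))) {
      idx <- which(msp == s)
      pool <- which(grid$species == s)
      father_site[idx] <- pool[weighted_sample(w[pool], length(idx))]
    }
    Tf <- traits[father_site, , drop = FALSE]
    eta <- if (config$eta_per_trait) matrix(stats::runif(N * n), N, n)
           else stats::runif(N)
    raw <- eta * Tm + (1 - eta) * Tf + mutation_noise(n, config$mu, draws = N)
  } else {
    raw <- Tm + mutation_noise(n, config$mu, draws = N)
  }
  community_grid(msp, repair_traits_matrix(raw), grid$kernel,
                 generation = grid$generation + 1L)
}

# sequential (one-site-at-a-time) update; complementarities are recomputed
# against the current grid after every single replacement. Intended for
# small lattices.
step_sequential <- function(grid, config) {
  N <- grid$L^2
  n <- grid$n
  species <- grid$species
  traits <- grid$traits
  kernel <- grid$kernel
  wellmixed <- config$dispersal == "well_mixed"
  order_sites <- sample.int(N)
  for (i in order_sites) {
    cur <- community_grid_unchecked(species, traits, kernel, grid$generation)
    if (wellmixed) {
      C <- compute_wellmixed_C(traits)
      w <- selection_weights(C, config$beta, config$performance_kernel)
      rw <- reward_multiplier(traits, config$reward_a, config$reward_trait)
      if (!is.null(rw)) w <- w * rw
      mom <- weighted_sample(w, 1L)
      pool <- which(species == species[mom])
      dad <- if (config$reproduction == "sexual")
        pool[weighted_sample(w[pool], 1L)] else mom
    } else {
      mom <- select_mother(cur, i, config$beta, config$performance_kernel,
                           config$reward_a, config$reward_trait)
      dad <- if (config$reproduction == "sexual")
        select_father(cur, mom, config$beta, config$performance_kernel,
                      config$reward_a, config$reward_trait) else mom
    }
    if (config$reproduction == "sexual") {
      eta <- if (config$eta_per_trait) stats::runif(n) else stats::runif(1)
      raw <- eta * traits[mom, ] + (1 - eta) * traits[dad, ] +
        mutation_noise(n, config$mu)
    } else {
      raw <- traits[mom, ] + mutation_noise(n, config$mu)
    }
    species[i] <- species[mom]
    traits[i, ] <- repair_traits(raw)
  }
  community_grid(species, traits, kernel, generation = grid$generation + 1L)
}

# fast-path constructor for internal loops (invariants hold by construction)
community_grid_unchecked <- function(species, traits, kernel, generation) {
  structure(list(L = kernel$L, n = ncol(traits), species = species,
                 traits = traits, kernel = kernel,
                 generation = as.integer(generation)),
            class = "community_grid")
}

#' Run a full simulation
#'
#' Initialises a community from the configuration and iterates the
#' generation update, recording biodiversity indices
#' (\code{\link{community_metrics}}) at the configured generations and
#' optional grid snapshots. If \code{config$seed} is set the run is fully
#' reproducible: identical configurations yield identical trajectories.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param track_centroids also record every species' trait centroid at every
#'   generation (used for coexistence-time measurements).
#' @param verbose print seed, configuration and extinction events.
#' @return an object of class \code{eco_trajectory}: a list with the
#'   \code{config}, a \code{metrics} data frame (one row per recorded
#'   generation), \code{snapshots} (named list of grids), \code{extinctions}
#'   (data frame of species label and generation), optional
#'   \code{centroids}, and the \code{final_grid}.
#' @examples
#' tr <- run_simulation(simulation_config(L = 8, S = 4, generations = 5, seed = 1))
#' tr$metrics
#' @export
run_simulation <- function(config, track_centroids = FALSE, verbose = FALSE) {
  validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (verbose) {
    message("seed: ", if (is.null(config$seed)) "none" else config$seed)
    print(config)
  }
  mg <- if (is.null(config$metric_generations)) 0:config$generations
        else sort(unique(config$metric_generations))
  sg <- sort(unique(config$snapshot_generations))

  grid <- init_community(config)
  metrics <- vector("list", length(mg))
  snapshots <- list()
  centroids <- if (track_centroids) vector("list", config$generations + 1L) else NULL
  ext <- list()
  present <- sort(unique(grid$species))

  record <- function(g, grid) {
    if (g %in% mg) metrics[[match(g, mg)]] <<- community_metrics(grid)
    if (g %in% sg) snapshots[[paste0("gen", g)]] <<- grid
    if (track_centroids) centroids[[g + 1L]] <<- all_centroids(grid, config$S)
  }
  record(0L, grid)

  for (g in seq_len(config$generations)) {
    grid <- step_generation(grid, config)
    now <- sort(unique(grid$species))
    gone <- setdiff(present, now)
    if (length(gone)) {
      ext[[length(ext) + 1L]] <- data.frame(species = gone, generation = g)
      if (verbose) message("generation ", g, ": species ",
                           paste(gone, collapse = ", "), " went extinct")
      present <- now
    }
    record(g, grid)
  }
  structure(list(
    config = config,
    metrics = do.call(rbind, metrics),
    snapshots = snapshots,
    extinctions = if (length(ext)) do.call(rbind, ext)
                  else data.frame(species = integer(0), generation = integer(0)),
    centroids = centroids,
    final_grid = grid
  ), class = "eco_trajectory")
}

# S x n centroid matrix (NA rows for extinct labels)
all_centroids <- function(grid, S) {
  out <- matrix(NA_real_, nrow = S, ncol = grid$n)
  counts <- tabulate(grid$species, nbins = S)
  sums <- rowsum(grid$traits, grid$species)
  out[as.integer(rownames(sums)), ] <- sums / counts[counts > 0]
  out
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat(sprintf("eco_trajectory: %d generations on a %d x %d lattice (S = %d initial species)\n",
              x$config$generations, x$config$L, x$config$L, x$config$S))
  cat(sprintf("  %d metric records, %d snapshots, %d extinction events\n",
              nrow(x$metrics), length(x$snapshots), nrow(x$extinctions)))
  if (nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final: %d surviving species, LC = %.4f, RC = %s\n",
                last$S_surviving, last$LC,
                if (is.na(last$RC)) "NA" else sprintf("%.4f", last$RC)))
  }
  invisible(x)
}
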