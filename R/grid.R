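#' Construct a community grid
#'
#' A community grid is a saturated \code{L x L} lattice: every site holds
#' exactly one individual, described by an integer species label and a trait
#' vector on the simplex. Sites are stored in column-major order (site
#' \code{i = row + col * L + 1}, 0-based row/col).
#'
#' @param species integer vector of length \code{L^2} of species labels.
#' @param traits numeric \code{L^2 x n} matrix; every row a valid simplex
#'   point.
#' @param kernel a \code{\link{make_neighbor_kernel}} object whose lattice
#'   side matches.
#' @param generation nonnegative generation counter (default 0).
#' @return an object of class \code{community_grid}: a list with elements
#'   \code{L}, \code{n}, \code{species}, \code{traits}, \code{kernel},
#'   \code{generation}.
#' @export
community_grid <- function(species, traits, kernel, generation = 0L) {
  if (!inherits(kernel, "neighbor_kernel")) stop("'kernel' must be a neighbor_kernel")
  L <- kernel$L
  N <- L * L
  species <- as.integer(species)
  traits <- as.matrix(traits)
  if (length(species) != N) stop("'species' must have length L^2 = ", N)
  if (nrow(traits) != N) stop("'traits' must have L^2 rows")
  if (anyNA(species) || any(species < 1L)) stop("species labels must be positive integers")
  check_traits_matrix(traits)
  structure(list(L = L, n = ncol(traits), species = species, traits = traits,
                 kernel = kernel, generation = as.integer(generation)),
            class = "community_grid")
}

check_traits_matrix <- function(traits, tol = 1e-9) {
  if (ncol(traits) < 2L) stop("traits need >= 2 components")
  if (anyNA(traits)) stop("traits contain NA")
  if (any(traits < -tol) || any(traits > 1 + tol))
    stop("trait components must lie in [0, 1]")
  bad <- abs(rowSums(traits) - 1) > tol
  if (any(bad))
    stop(sum(bad), " trait row(s) do not sum to 1 (first: row ", which(bad)[1L], ")")
  invisible(traits)
}

#' @export
print.community_grid <- function(x, ...) {
  surv <- sort(unique(x$species))
  cat(sprintf("community_grid: %d x %d saturated lattice, n = %d traits, generation %d\n",
              x$L, x$L, x$n, x$generation))
  cat(sprintf("  %d species present: %s\n", length(surv),
              paste(utils::head(surv, 20L), collapse = " ")))
  invisible(x)
}

#' Initialise a community
#'
#' Builds the generation-0 grid for a configuration. Species labels
#' \code{1..S} are assigned to sites uniformly at random. In
#' \code{"common_gaussian"} mode every individual's phenotype is the simplex
#' centre \code{(1/n, ..., 1/n)} plus sum-preserving Gaussian scatter with
#' per-component standard deviation \code{init_sigma}, repaired onto the
#' simplex; in \code{"per_species_gaussian"} mode each species first draws
#' its own centre uniformly on the simplex and its members are scattered
#' around that centre. The scatter uses the same cyclic-difference generator
#' as \code{\link{mutation_noise}}, so raw vectors sum to 1 before repair.
#'
#' Consumes the global RNG stream; seed it (or set \code{config$seed} and use
#' \code{\link{run_simulation}}) for reproducibility.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{\link{community_grid}} at generation 0.
#' @export
init_community <- function(config) {
  validate_config(config)
  kernel <- make_neighbor_kernel(config$L, config$radius, config$boundary)
  N <- config$L^2
  n <- config$n
  species <- sample.int(config$S, N, replace = TRUE)
  # cyclic-difference noise with per-component sd init_sigma: the generator
  # variables need sd init_sigma / sqrt(2), i.e. mu = sqrt(2) * init_sigma.
  mu_init <- sqrt(2) * config$init_sigma
  if (config$init_mode == "common_gaussian") {
    centre <- matrix(1 / n, nrow = N, ncol = n)
  } else {
    sp_centre <- runif_simplex(config$S, n)
    centre <- sp_centre[species, , drop = FALSE]
  }
  raw <- centre + mutation_noise(n, mu_init, draws = N)
  traits <- repair_traits_matrix(raw)
  community_grid(species, traits, kernel, generation = 0L)
}

# uniform sampling on the (n-1)-simplex (Dirichlet(1, ..., 1))
runif_simplex <- function(m, n) {
  e <- matrix(stats::rexp(m * n), nrow = m, ncol = n)
  e / rowSums(e)
}

#' Deterministic fixture grids for testing and examples
#'
#' Small, fully deterministic community grids used across the test suite:
#' \describe{
#'   \item{\code{"checkerboard4"}}{4 x 4 torus, radius-1 kernel, two species
#'     in a perfect checkerboard pinned to the simplex vertices (1,0,0) and
#'     (0,1,0). Under the 8-neighbour Moore kernel its Moran's I is exactly
#'     zero: the 4 anti-correlated orthogonal neighbours cancel the 4
#'     correlated diagonal ones. Local complementarity is exactly 1/3.}
#'   \item{\code{"stripes4"}}{4 x 4 torus, radius-1 kernel, two vertex-pinned
#'     species in alternating columns; conspecifics avoid each other along
#'     rows and diagonals, so Moran's I is strictly negative (-0.5).}
#'   \item{\code{"pointmass6"}}{6 x 6 monoculture with every individual at
#'     the simplex centre; all complementarities are zero.}
#'   \item{\code{"threespecies8"}}{8 x 8 grid, three species in horizontal
#'     bands, pinned to the three vertices of the 2-simplex (rows 0-2 species
#'     1 at (1,0,0), rows 3-5 species 2 at (0,1,0), rows 6-7 species 3 at
#'     (0,0,1)); all pairwise centroid distances are 2/3.}
#' }
#'
#' @param name one of \code{"checkerboard4"}, \code{"stripes4"},
#'   \code{"pointmass6"}, \code{"threespecies8"}.
#' @return a \code{\link{community_grid}}.
#' @export
make_fixture <- function(name) {
  switch(name,
    checkerboard4 = {
      L <- 4L
      kernel <- make_neighbor_kernel(L, radius = 1L)
      rc <- site_rowcol(seq_len(L * L), L)
      species <- ifelse((rc[, "row"] + rc[, "col"]) %% 2L == 0L, 1L, 2L)
      traits <- matrix(0, L * L, 3L)
      traits[cbind(seq_len(L * L), species)] <- 1
      community_grid(species, traits, kernel)
    },
    stripes4 = {
      L <- 4L
      kernel <- make_neighbor_kernel(L, radius = 1L)
      rc <- site_rowcol(seq_len(L * L), L)
      species <- ifelse(rc[, "col"] %% 2L == 0L, 1L, 2L)
      traits <- matrix(0, L * L, 3L)
      traits[cbind(seq_len(L * L), species)] <- 1
      community_grid(species, traits, kernel)
    },
    pointmass6 = {
      L <- 6L
      kernel <- make_neighbor_kernel(L, radius = 2L)
      community_grid(rep(1L, L * L), matrix(1 / 3, L * L, 3L), kernel)
    },
    threespecies8 = {
      L <- 8L
      kernel <- make_neighbor_kernel(L, radius = 2L)
      rc <- site_rowcol(seq_len(L * L), L)
      species <- ifelse(rc[, "row"] <= 2L, 1L, ifelse(rc[, "row"] <= 5L, 2L, 3L))
      traits <- matrix(0, L * L, 3L)
      traits[cbind(seq_len(L * L), species)] <- 1
      community_grid(species, traits, kernel)
    },
    stop("unknown fixture name: '", name, "'")
  )
}
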