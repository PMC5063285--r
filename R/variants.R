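#' Offspring of an asexual (clonal) reproduction
#'
#' In the asexual variant no father is selected: offspring traits are the
#' mother's plus sum-preserving mutation noise, repaired onto the simplex.
#' Without the admixture of sexual reproduction pulling conspecifics
#' together, diversification proceeds within maternal lineages and
#' intraspecific trait variability grows much larger than in the sexual
#' model.
#'
#' Consumes the global RNG stream.
#'
#' @param mother an individual (\code{list(species =, traits =)}).
#' @param mu trait variability.
#' @return an individual with the mother's species label.
#' @export
asexual_offspring <- function(mother, mu) {
  n <- length(mother$traits)
  raw <- mother$traits + mutation_noise(n, mu)
  list(species = mother$species, traits = repair_traits(raw))
}

#' Advance one generation of the well-mixed variant
#'
#' In the well-mixed (long-distance dispersal and competition) variant an
#' individual's complementarity is its mean trait distance to all N - 1
#' other individuals, and the mother of every offspring is drawn from the
#' entire lattice with performance-weighted probability. Spatial structure
#' then plays no role: Moran's I stays at the permutation null. At
#' \code{beta = 0} the dynamics reduce to neutral (Wright-Fisher-like) drift.
#'
#' Equivalent to \code{\link{step_generation}} with
#' \code{dispersal = "well_mixed"}.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param config a \code{\link{simulation_config}}; its dispersal flag is
#'   forced to \code{"well_mixed"}.
#' @return the next generation's grid.
#' @export
wellmixed_step <- function(grid, config) {
  config$dispersal <- "well_mixed"
  step_generation(grid, config)
}

#' Well-mixed complementarity of every individual
#'
#' Mean pairwise complementarity of each individual against all others,
#' used in place of the local kernel average in the well-mixed variant.
#'
#' @param grid a \code{\link{community_grid}}.
#' @return numeric vector of length L^2.
#' @export
wellmixed_complementarity <- function(grid) {
  compute_wellmixed_C(grid$traits)
}

#' Performance under an asymmetric trade-off reward
#'
#' In the biased-reward variant, positions in the trade-off space are not
#' equally rewarding a priori: performance is multiplied by
#' \code{w(T) = 1 + a * T_f} for a focal trait f and bias strength
#' \code{a >= 0}, so individuals allocating more to the favoured trait
#' reproduce more. \code{a = 0} recovers the symmetric model exactly.
#'
#' @param traits a trait vector (or matrix of trait rows).
#' @param C complementarity value(s).
#' @param beta competition strength.
#' @param reward_a bias strength (>= 0).
#' @param reward_trait index of the favoured trait.
#' @param kernel_type performance kernel family.
#' @return positive performance value(s).
#' @export
biased_performance <- function(traits, C, beta, reward_a, reward_trait = 1L,
                               kernel_type = "exponential") {
  if (reward_a < 0) stop("'reward_a' must be >= 0")
  tf <- if (is.matrix(traits)) traits[, reward_trait] else traits[reward_trait]
  (1 + reward_a * tf) * performance_weight(C, beta, kernel_type)
}
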