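#' Simulation configuration
#'
#' Collects every free parameter of the model in one validated object.
#' Defaults are the headline parameter set of the study conditions:
#' a 64 x 64 lattice with the 24-site kernel (radius 2, periodic
#' boundaries), S = 16 species, 3-dimensional trade-off space,
#' competition strength beta = 10 and trait variability mu = 0.025.
#'
#' @param L lattice side (>= 2 * radius + 1).
#' @param S initial species count (1 <= S <= L^2).
#' @param n trait dimension (>= 2).
#' @param beta competition strength (>= 0; 0 gives neutral dynamics).
#' @param mu trait variability of inherited traits (>= 0).
#' @param radius neighbour-shell count of the kernel (default 2, K = 24).
#' @param boundary \code{"periodic"} or \code{"bounded"}.
#' @param generations number of reproductive cycles to simulate (>= 0).
#' @param seed integer RNG seed; \code{NULL} leaves the RNG state alone.
#' @param init_mode \code{"common_gaussian"} (all individuals scattered
#'   around the simplex centre) or \code{"per_species_gaussian"} (each
#'   species scattered around its own random centre).
#' @param init_sigma per-component standard deviation of the initial trait
#'   scatter (default 0.1).
#' @param reproduction \code{"sexual"} (default) or \code{"asexual"}.
#' @param dispersal \code{"local"} (default) or \code{"well_mixed"}.
#' @param performance_kernel map from complementarity to performance:
#'   \code{"exponential"} (default, \code{exp(beta * C)}), \code{"linear"}
#'   (\code{1 + beta * C}) or \code{"gaussian"}
#'   (\code{exp(beta * (1 - (1 - C)^2))}).
#' @param reward_a bias strength of the asymmetric trade-off reward
#'   (>= 0; 0 disables the reward and recovers the symmetric model).
#' @param reward_trait index of the favoured trait when \code{reward_a > 0}.
#' @param update_mode \code{"synchronous"} (generational, default) or
#'   \code{"sequential"} (sites replaced one at a time in random order).
#' @param eta_per_trait if \code{TRUE}, a separate admixture proportion is
#'   drawn for every trait component instead of one per offspring
#'   (sensitivity analysis only; default \code{FALSE}).
#' @param metric_generations generations at which biodiversity indices are
#'   recorded; \code{NULL} (default) records every generation 0..generations.
#' @param snapshot_generations generations at which full grid snapshots are
#'   retained in the trajectory (default none).
#'
#' @return an object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- simulation_config(L = 16, S = 4, generations = 10, seed = 1)
#' @export
simulation_config <- function(L = 64L, S = 16L, n = 3L,
                              beta = 10, mu = 0.025,
                              radius = 2L, boundary = "periodic",
                              generations = 100L, seed = NULL,
                              init_mode = "common_gaussian", init_sigma = 0.1,
                              reproduction = "sexual", dispersal = "local",
                              performance_kernel = "exponential",
                              reward_a = 0, reward_trait = 1L,
                              update_mode = "synchronous",
                              eta_per_trait = FALSE,
                              metric_generations = NULL,
                              snapshot_generations = integer(0)) {
  cfg <- list(
    L = as.integer(L), S = as.integer(S), n = as.integer(n),
    beta = as.numeric(beta), mu = as.numeric(mu),
    radius = as.integer(radius),
    boundary = match.arg(boundary, c("periodic", "bounded")),
    generations = as.integer(generations),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    init_mode = match.arg(init_mode, c("common_gaussian", "per_species_gaussian")),
    init_sigma = as.numeric(init_sigma),
    reproduction = match.arg(reproduction, c("sexual", "asexual")),
    dispersal = match.arg(dispersal, c("local", "well_mixed")),
    performance_kernel = match.arg(performance_kernel,
                                   c("exponential", "linear", "gaussian")),
    reward_a = as.numeric(reward_a), reward_trait = as.integer(reward_trait),
    update_mode = match.arg(update_mode, c("synchronous", "sequential")),
    eta_per_trait = isTRUE(eta_per_trait),
    metric_generations = if (is.null(metric_generations)) NULL
                         else as.integer(metric_generations),
    snapshot_generations = as.integer(snapshot_generations)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (radius < 1L) stop("'radius' must be >= 1")
    if (L < 2L * radius + 1L) stop("'L' must be >= 2 * radius + 1")
    if (S < 1L) stop("'S' must be >= 1")
    if (S > L^2) stop("'S' must not exceed the number of lattice sites L^2")
    if (n < 2L) stop("'n' must be >= 2")
    if (beta < 0) stop("'beta' must be >= 0")
    if (mu < 0) stop("'mu' must be >= 0")
    if (generations < 0L) stop("'generations' must be >= 0")
    if (init_sigma < 0) stop("'init_sigma' must be >= 0")
    if (reward_a < 0) stop("'reward_a' must be >= 0")
    if (reward_trait < 1L || reward_trait > n)
      stop("'reward_trait' must index one of the n traits")
    if (!is.null(metric_generations) &&
        (any(metric_generations < 0L) || any(metric_generations > generations)))
      stop("'metric_generations' must lie in 0..generations")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  lattice %d x %d (radius %d, %s), S = %d, n = %d\n",
              x$L, x$L, x$radius, x$boundary, x$S, x$n))
  cat(sprintf("  beta = %g, mu = %g, generations = %d, seed = %s\n",
              x$beta, x$mu, x$generations,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  init: %s (sigma = %g); reproduction: %s; dispersal: %s\n",
              x$init_mode, x$init_sigma, x$reproduction, x$dispersal))
  cat(sprintf("  performance kernel: %s; reward a = %g (trait %d); update: %s\n",
              x$performance_kernel, x$reward_a, x$reward_trait, x$update_mode))
  invisible(x)
}
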