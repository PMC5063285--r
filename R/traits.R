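#' Validate a trait vector on the trade-off simplex
#'
#' A phenotype is a point on the (n-1)-simplex: \code{n >= 2} allocation
#' fractions, each in [0, 1], summing to 1 within an absolute tolerance of
#' 1e-9. Think of the components as shares of a fixed resource budget
#' (e.g. biomass allocated to roots, stems/leaves, flowers).
#'
#' @param x numeric vector of length n.
#' @param tol absolute tolerance on the unit sum (default 1e-9).
#' @return \code{x}, invisibly, if valid; otherwise an error.
#' @export
validate_traits <- function(x, tol = 1e-9) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("a trait vector needs at least 2 numeric components")
  if (anyNA(x))
    stop("trait vector contains NA")
  if (any(x < -tol) || any(x > 1 + tol))
    stop("trait components must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop("trait components must sum to 1 (got ", format(sum(x)), ")")
  invisible(x)
}

#' Trait complementarity between two individuals
#'
#' The complementarity of two phenotypes is their normalised L1 distance in
#' trade-off space, \code{c = sum_k |a_k - b_k| / n}. It is symmetric, zero
#' iff the phenotypes coincide, attains its maximum 2/n at two distinct
#' simplex vertices, and is independent of species labels. High
#' complementarity means the two individuals exploit different resources and
#' so compete weakly.
#'
#' @param a,b numeric trait vectors of equal length n.
#' @return a number in [0, 2/n].
#' @examples
#' pair_complementarity(c(1, 0, 0), c(0, 1, 0))  # 2/3
#' @export
pair_complementarity <- function(a, b) {
  if (length(a) != length(b))
    stop("trait vectors have mismatched dimensions (", length(a), " vs ", length(b), ")")
  sum(abs(a - b)) / length(a)
}

#' Sum-preserving mutation noise
#'
#' Draws the trait perturbation added to an offspring's phenotype. To keep
#' the unit-sum constraint exactly, the n components are generated as cyclic
#' differences \code{xi_k = r_k - r_{k+1}} (with \code{r_{n+1} = r_1}) of n
#' independent Gaussian variables with mean 0 and standard deviation
#' \code{mu / 2}. The telescoping sum makes \code{sum(xi) = 0} exactly; each
#' component has variance \code{mu^2 / 2} and cyclically adjacent components
#' have covariance \code{-mu^2 / 4}.
#'
#' Consumes the global RNG stream.
#'
#' @param n trait dimension (>= 2).
#' @param mu trait-variability parameter (>= 0); \code{mu = 0} returns zeros.
#' @param draws number of independent noise vectors to draw (default 1).
#' @return if \code{draws == 1}, a numeric vector of length n; otherwise a
#'   \code{draws x n} matrix, one noise vector per row.
#' @export
mutation_noise <- function(n, mu, draws = 1L) {
  if (n < 2L) stop("'n' must be >= 2")
  if (mu < 0) stop("'mu' must be >= 0")
  if (mu == 0) {
    out <- matrix(0, nrow = draws, ncol = n)
  } else {
    r <- matrix(stats::rnorm(draws * n, mean = 0, sd = mu / 2), nrow = draws, ncol = n)
    out <- r - r[, c(2:n, 1L), drop = FALSE]
  }
  if (draws == 1L) drop(out) else out
}

#' Repair a raw trait vector back onto the simplex
#'
#' Offspring traits are built as an interpolation of the parents plus
#' mutation noise; the construction preserves the unit sum but a component
#' can stray outside [0, 1]. Repair truncates each violating component to the
#' nearest bound and adds the truncated difference to another component
#' chosen uniformly at random, iterating until the vector is a valid simplex
#' point. The sum is preserved throughout and components never touched by a
#' repair are unchanged.
#'
#' @param raw numeric vector of length n summing to 1 (components may lie
#'   outside [0, 1]).
#' @return a valid trait vector (see \code{\link{validate_traits}}).
#' @export
repair_traits <- function(raw) {
  out <- repair_traits_matrix(matrix(raw, nrow = 1L))
  drop(out)
}

# Vectorised repair over a matrix of raw trait rows. Violations are rare for
# small mu, so only offending rows are visited. The iteration cap (100 * n
# passes) guards against pathological non-termination.
repair_traits_matrix <- function(raw) {
  n <- ncol(raw)
  if (n < 2L) stop("trait matrices need >= 2 columns")
  max_pass <- 100L * n
  for (pass in seq_len(max_pass)) {
    bad <- which(rowSums(raw < 0 | raw > 1) > 0L)
    if (length(bad) == 0L) return(raw)
    for (i in bad) {
      v <- raw[i, ]
      k <- which(v < 0 | v > 1)[1L]
      target <- if (v[k] < 0) 0 else 1
      excess <- v[k] - target
      v[k] <- target
      recipient <- if (n == 2L) (3L - k) else sample(seq_len(n)[-k], 1L)
      v[recipient] <- v[recipient] + excess
      raw[i, ] <- v
    }
  }
  stop("trait repair did not converge (internal error)")
}

# distance from every row of a trait matrix to its nearest simplex vertex:
# L1 distance to vertex e_k is 2 * (1 - T_k), minimised at the largest share.
nearest_vertex_distance <- function(traits) {
  n <- ncol(traits)
  2 * (1 - apply(traits, 1L, max)) / n
}
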