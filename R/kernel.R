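#' Build a neighbourhood kernel for a square lattice
#'
#' Constructs the set of neighbour sites for every site of an \code{L x L}
#' square lattice. The neighbourhood of a site is all sites within Chebyshev
#' distance \code{radius} (i.e. \code{radius} full shells around the site),
#' excluding the site itself. Under periodic boundaries (a torus) every site
#' has exactly \code{K = (2 * radius + 1)^2 - 1} neighbours; with
#' \code{radius = 2} this is the 24-site kernel used throughout the
#' simulations. Under bounded (absorbing-edge) boundaries, edge sites have
#' fewer neighbours and all computations normalise over the actual count.
#'
#' Sites are indexed \code{1..L^2} in column-major order: site
#' \code{i = row + col * L + 1} with 0-based \code{row}, \code{col}.
#'
#' @param L lattice side (integer, \code{L >= 2 * radius + 1}).
#' @param radius number of neighbour shells (integer, >= 1; default 2).
#' @param boundary \code{"periodic"} (default) or \code{"bounded"}.
#'
#' @return An object of class \code{neighbor_kernel}: a list with elements
#'   \code{L}, \code{radius}, \code{boundary}, \code{K} (maximum neighbour
#'   count), \code{nb} (an \code{L^2 x K} integer matrix of neighbour site
#'   indices, \code{NA} where a bounded-edge neighbour is missing) and
#'   \code{nb_count} (actual neighbour count per site).
#'
#' @examples
#' k <- make_neighbor_kernel(8, radius = 2)
#' k$K            # 24
#' k$nb[1, ]      # the 24 neighbours of site 1
#' @export
make_neighbor_kernel <- function(L, radius = 2, boundary = c("periodic", "bounded")) {
  boundary <- match.arg(boundary)
  L <- as.integer(L)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1)
    stop("'radius' must be an integer >= 1")
  if (is.na(L) || L < 2L * radius + 1L)
    stop("'L' must be at least 2 * radius + 1 = ", 2L * radius + 1L)

  N <- L * L
  row <- rep.int(0:(L - 1L), L)          # 0-based, column-major
  col <- rep(0:(L - 1L), each = L)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0L & offs$dc == 0L), , drop = FALSE]
  K <- nrow(offs)

  nb <- matrix(NA_integer_, nrow = N, ncol = K)
  for (j in seq_len(K)) {
    nr <- row + offs$dr[j]
    nc <- col + offs$dc[j]
    if (boundary == "periodic") {
      nr <- nr %% L
      nc <- nc %% L
      nb[, j] <- nr + nc * L + 1L
    } else {
      ok <- nr >= 0L & nr < L & nc >= 0L & nc < L
      nb[ok, j] <- nr[ok] + nc[ok] * L + 1L
    }
  }
  structure(
    list(L = L, radius = radius, boundary = boundary, K = K,
         nb = nb, nb_count = as.integer(rowSums(!is.na(nb)))),
    class = "neighbor_kernel"
  )
}

#' @export
print.neighbor_kernel <- function(x, ...) {
  cat(sprintf("neighbor_kernel: %d x %d lattice, radius %d, %s boundaries, K = %d\n",
              x$L, x$L, x$radius, x$boundary, x$K))
  invisible(x)
}

# site index helpers (0-based row/col <-> 1-based column-major site index)
site_index <- function(row, col, L) row + col * L + 1L
site_rowcol <- function(i, L) {
  i0 <- i - 1L
  cbind(row = i0 %% L, col = i0 %/% L)
}
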