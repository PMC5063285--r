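#' Plot a trajectory's biodiversity indices
#'
#' Minimal base-graphics helper: draws the recorded time series of selected
#' indices against generation.
#'
#' @param x an \code{eco_trajectory} from \code{\link{run_simulation}}.
#' @param which character vector of metric columns to draw.
#' @param ... forwarded to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.eco_trajectory <- function(x, which = c("LC", "RC", "interspecies_distance",
                                             "intraspecific_distance"), ...) {
  m <- x$metrics
  which <- intersect(which, names(m))
  if (!length(which)) stop("none of the requested metrics were recorded")
  graphics::matplot(m$generation, as.matrix(m[, which, drop = FALSE]),
                    type = "l", lty = 1, xlab = "generation", ylab = "index",
                    ...)
  graphics::legend("topleft", legend = which, lty = 1,
                   col = seq_along(which), bty = "n")
  invisible(x)
}
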