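#' Read a simulation configuration from a YAML file
#'
#' The file is a flat key-value mapping whose keys are the arguments of
#' \code{\link{simulation_config}}; unset keys take their defaults and an
#' empty file yields the full default configuration. Unknown keys are
#' rejected by name; domain violations are reported per field.
#'
#' @param path path to a YAML config file.
#' @return a \code{\link{simulation_config}}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a key-value mapping")
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$metric_generations))
    raw$metric_generations <- as.integer(unlist(raw$metric_generations))
  if (!is.null(raw$snapshot_generations))
    raw$snapshot_generations <- as.integer(unlist(raw$snapshot_generations))
  do.call(simulation_config, raw)
}

#' Write a simulation configuration to a YAML file
#'
#' Inverse of \code{\link{read_config}}: \code{read_config(write_config(cfg))}
#' reproduces the configuration exactly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  if (length(x$snapshot_generations) == 0L) x$snapshot_generations <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a community snapshot to a plain-text CSV file
#'
#' One data row per site, in row-major site order (row 0 column 0 first),
#' with 0-based row/column indices and a header:
#' \code{generation,row,col,species,T1,...,Tn}.
#'
#' @param grid a \code{\link{community_grid}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(grid, path) {
  L <- grid$L
  rc <- site_rowcol(seq_len(L * L), L)
  ord <- order(rc[, "row"], rc[, "col"])   # row-major file order
  df <- data.frame(generation = grid$generation,
                   row = rc[ord, "row"], col = rc[ord, "col"],
                   species = grid$species[ord])
  tr <- grid$traits[ord, , drop = FALSE]
  colnames(tr) <- paste0("T", seq_len(ncol(tr)))
  utils::write.csv(cbind(df, tr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a community snapshot written by \code{\link{write_snapshot}}
#'
#' The round trip is lossless: species labels are reproduced exactly and
#' traits to full printed precision. Rows whose traits leave the simplex
#' (components outside [0, 1] or sums off 1 by more than \code{tol}) are
#' rejected with their row numbers, as are incomplete lattices.
#'
#' @param path path to a snapshot CSV.
#' @param radius,boundary kernel parameters to attach to the grid (the file
#'   stores only the community itself); defaults radius 2, periodic.
#' @param tol absolute tolerance on trait-row sums (default 1e-9).
#' @return a \code{\link{community_grid}}.
#' @export
read_snapshot <- function(path, radius = 2L, boundary = "periodic", tol = 1e-9) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("generation", "row", "col", "species")
  if (!all(need %in% names(df)))
    stop("snapshot is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  tcols <- grep("^T[0-9]+$", names(df), value = TRUE)
  if (length(tcols) < 2L) stop("snapshot needs at least 2 trait columns T1, T2, ...")
  tcols <- paste0("T", seq_along(tcols))
  L <- as.integer(round(sqrt(nrow(df))))
  if (L * L != nrow(df)) stop("snapshot has ", nrow(df), " rows; not a square lattice")
  if (any(df$row < 0L | df$row >= L | df$col < 0L | df$col >= L))
    stop("row/col indices out of range for a ", L, " x ", L, " lattice")
  idx <- site_index(df$row, df$col, L)
  if (anyDuplicated(idx)) stop("duplicate lattice coordinates in snapshot")

  traits <- as.matrix(df[, tcols, drop = FALSE])
  bad <- which(abs(rowSums(traits) - 1) > tol | apply(traits, 1L, min) < -tol |
                 apply(traits, 1L, max) > 1 + tol)
  if (length(bad))
    stop("non-simplex trait row(s) at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))

  species <- integer(L * L)
  species[idx] <- df$species
  tmat <- matrix(0, L * L, length(tcols))
  tmat[idx, ] <- traits
  kernel <- make_neighbor_kernel(L, radius = radius, boundary = boundary)
  community_grid(species, tmat, kernel, generation = df$generation[1L])
}

#' Write a metrics time series to CSV
#'
#' One row per recorded generation with the columns of
#' \code{\link{community_metrics}}; missing values are written as empty
#' fields.
#'
#' @param metrics a metrics data frame (from a trajectory or
#'   \code{\link{community_metrics}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
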