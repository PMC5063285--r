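#' Run an ensemble of replicate simulations
#'
#' Runs R independent replicates of a configuration with replicate seeds
#' derived deterministically from \code{base_seed}, and aggregates every
#' biodiversity index into per-generation mean, standard deviation and
#' per-cell replicate counts (missing values are excluded cell-wise).
#'
#' For monoculture configurations (S = 1), GC_inter cannot be measured
#' within one community; consecutive replicates are paired (1-2, 3-4, ...)
#' and the cross-realization GC_inter and RC are computed per pair at every
#' recorded generation (see \code{\link{relative_complementarity}}), and
#' aggregated over pairs.
#'
#' @param config a \code{\link{simulation_config}} (its own seed is ignored).
#' @param R number of replicates (>= 1).
#' @param base_seed integer seed from which replicate seeds are derived.
#' @param keep_replicates retain every replicate's metrics table (default
#'   \code{TRUE}).
#' @return an object of class \code{eco_ensemble}: a list with
#'   \code{config}, \code{R}, \code{seeds}, \code{summary} (data frame of
#'   \code{<metric>_mean}, \code{<metric>_sd}, \code{<metric>_n} per
#'   recorded generation), \code{replicates} (list of metric data frames or
#'   \code{NULL}), and \code{extinctions} (data frame with a replicate
#'   column).
#' @export
run_ensemble <- function(config, R, base_seed, keep_replicates = TRUE) {
  if (R < 1L) stop("'R' must be >= 1")
  validate_config(config)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, R)

  mono_rc <- config$S == 1L && R >= 2L
  mg <- if (is.null(config$metric_generations)) 0:config$generations
        else sort(unique(config$metric_generations))
  if (mono_rc) {
    # keep trait snapshots at the recorded generations for cross-replicate RC
    config$snapshot_generations <-
      sort(unique(c(config$snapshot_generations, mg)))
  }

  reps <- vector("list", R)
  exts <- vector("list", R)
  snaps <- if (mono_rc) vector("list", R) else NULL
  for (i in seq_len(R)) {
    cfg <- config
    cfg$seed <- seeds[i]
    tr <- tryCatch(run_simulation(cfg), error = function(e)
      stop("replicate ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e)))
    reps[[i]] <- tr$metrics
    if (nrow(tr$extinctions))
      exts[[i]] <- cbind(replicate = i, tr$extinctions)
    if (mono_rc) snaps[[i]] <- tr$snapshots
  }

  metric_cols <- setdiff(names(reps[[1L]]), "generation")
  gens <- reps[[1L]]$generation
  summary <- data.frame(generation = gens)
  for (col in metric_cols) {
    vals <- vapply(reps, function(m) m[[col]], numeric(length(gens)))
    vals <- matrix(vals, nrow = length(gens))
    summary[[paste0(col, "_mean")]] <- rowMeans(vals, na.rm = TRUE)
    summary[[paste0(col, "_sd")]] <- apply(vals, 1L, stats::sd, na.rm = TRUE)
    summary[[paste0(col, "_n")]] <- rowSums(!is.na(vals))
  }

  rc_pairs <- NULL
  if (mono_rc) {
    npair <- R %/% 2L
    rc_mat <- matrix(NA_real_, nrow = length(gens), ncol = npair)
    for (p in seq_len(npair)) {
      s1 <- snaps[[2L * p - 1L]]
      s2 <- snaps[[2L * p]]
      for (gi in seq_along(gens)) {
        key <- paste0("gen", gens[gi])
        g1 <- s1[[key]]
        g2 <- s2[[key]]
        if (!is.null(g1) && !is.null(g2) &&
            length(unique(g1$species)) == 1L && length(unique(g2$species)) == 1L)
          rc_mat[gi, p] <- relative_complementarity(g1, g2)
      }
    }
    rc_pairs <- rc_mat
    summary$RC_mean <- rowMeans(rc_mat, na.rm = TRUE)
    summary$RC_sd <- apply(rc_mat, 1L, stats::sd, na.rm = TRUE)
    summary$RC_n <- rowSums(!is.na(rc_mat))
  }

  structure(list(
    config = config, R = R, seeds = seeds, summary = summary,
    replicates = if (keep_replicates) reps else NULL,
    extinctions = if (length(exts)) do.call(rbind, exts)
                  else data.frame(replicate = integer(0), species = integer(0),
                                  generation = integer(0)),
    rc_pairs = rc_pairs
  ), class = "eco_ensemble")
}

#' @export
print.eco_ensemble <- function(x, ...) {
  cat(sprintf("eco_ensemble: %d replicates, L = %d, S = %d, beta = %g, mu = %g, %d generations\n",
              x$R, x$config$L, x$config$S, x$config$beta, x$config$mu,
              x$config$generations))
  invisible(x)
}

#' Sweep the diversification experiment over S, beta and mu
#'
#' Runs one ensemble per combination of initial species count, competition
#' strength and trait variability, capturing grid snapshots at generations
#' 1, 3, 10 and 100 (where within range). This is the computational
#' experiment behind the time-series comparisons of inter/intraspecific
#' distances, complementarities and Moran's I across community compositions.
#'
#' @param S_values,beta_values,mu_values nonempty parameter vectors.
#' @param L lattice side (default 32: a reduced scale at which the
#'   qualitative orderings are robust; the full-scale study uses 64).
#' @param generations number of generations (default 200).
#' @param R replicates per combination (default 20).
#' @param base_seed integer; each combination's ensemble seed is derived
#'   from it deterministically.
#' @param metric_generations generations at which indices are recorded
#'   (default every generation).
#' @param ... further arguments forwarded to
#'   \code{\link{simulation_config}}.
#' @return \code{list(results, manifest)}: \code{results} is a named list of
#'   \code{\link{run_ensemble}} objects (names \code{S<j>_beta<b>_mu<m>}),
#'   \code{manifest} a data frame of the combinations and ensemble seeds.
#' @export
diversification_experiment <- function(S_values, beta_values, mu_values,
                                       L = 32L, generations = 200L, R = 20L,
                                       base_seed = 1L,
                                       metric_generations = NULL, ...) {
  if (!length(S_values) || !length(beta_values) || !length(mu_values))
    stop("parameter grids must be nonempty")
  combos <- expand.grid(S = S_values, beta = beta_values, mu = mu_values)
  snap <- intersect(c(1L, 3L, 10L, 100L), 0:generations)
  results <- list()
  manifest <- combos
  manifest$seed <- base_seed + seq_len(nrow(combos)) - 1L
  manifest$name <- sprintf("S%d_beta%g_mu%g", combos$S, combos$beta, combos$mu)
  for (r in seq_len(nrow(combos))) {
    cfg <- simulation_config(L = L, S = combos$S[r], beta = combos$beta[r],
                             mu = combos$mu[r], generations = generations,
                             metric_generations = metric_generations,
                             snapshot_generations = snap, ...)
    results[[manifest$name[r]]] <- run_ensemble(cfg, R, manifest$seed[r])
  }
  list(results = results, manifest = manifest)
}

#' Coexistence times of phenotypically equivalent species
#'
#' Tracks, per replicate, how long groups of species whose trait centroids
#' stay within \code{eps} of each other (single linkage;
#' \code{\link{detect_equivalent_species}}) persist with an unchanged
#' membership: the durations of emergent-neutral coexistence.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param eps centroid-distance threshold (> 0).
#' @param R number of replicates.
#' @param base_seed integer seed for replicate-seed derivation.
#' @return a data frame with columns \code{replicate}, \code{group}
#'   (member labels joined by \code{"+"}), \code{start_generation} and
#'   \code{duration} (generations over which the identical group persisted);
#'   zero rows if no group of size >= 2 ever forms (e.g. monocultures).
#' @export
coexistence_times <- function(config, eps, R, base_seed) {
  if (eps <= 0) stop("'eps' must be > 0")
  validate_config(config)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, R)
  out <- list()
  for (i in seq_len(R)) {
    cfg <- config
    cfg$seed <- seeds[i]
    tr <- run_simulation(cfg, track_centroids = TRUE)
    sigs <- lapply(tr$centroids, function(B) {
      alive <- which(!is.na(B[, 1L]))
      if (length(alive) < 2L) return(character(0))
      D <- as.matrix(stats::dist(B[alive, , drop = FALSE],
                                 method = "manhattan")) / ncol(B)
      grp <- groups_from_adjacency(D < eps, alive)
      vapply(grp[lengths(grp) >= 2L], paste, character(1), collapse = "+")
    })
    all_groups <- unique(unlist(sigs))
    for (g in all_groups) {
      present <- vapply(sigs, function(s) g %in% s, logical(1))
      r <- rle(present)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          replicate = i, group = g,
          start_generation = starts[hit] - 1L,   # generations are 0-based
          duration = r$lengths[hit])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(replicate = integer(0), group = character(0),
                  start_generation = integer(0), duration = integer(0))
}
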