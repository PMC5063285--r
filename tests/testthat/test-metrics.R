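test_that("species centroids match direct summation", {
  g <- make_fixture("threespecies8")
  c1 <- species_centroid(g, 1)
  expect_equal(c1$centroid, c(1, 0, 0))
  expect_equal(c1$abundance, 24)
  expect_error(species_centroid(g, 9), "not present")

  gr <- random_grid(6, S = 3, seed = 31)
  for (s in sort(unique(gr$species)))
    expect_equal(species_centroid(gr, s)$centroid, oracle_centroid(gr, s),
                 tolerance = 1e-12)
})

test_that("inter- and intraspecific distances match exhaustive loops", {
  g <- make_fixture("threespecies8")
  expect_equal(mean_interspecies_distance(g), 2 / 3)
  expect_equal(mean_intraspecific_distance(g), 0)

  gr <- random_grid(8, S = 4, seed = 32)
  expect_equal(mean_interspecies_distance(gr), oracle_interspecies(gr),
               tolerance = 1e-12)
  expect_equal(mean_intraspecific_distance(gr), oracle_intraspecific(gr),
               tolerance = 1e-12)

  mono <- make_fixture("pointmass6")
  expect_true(is.na(mean_interspecies_distance(mono)))
})

test_that("LC is exact on the checkerboard and matches the site-loop oracle", {
  cb <- make_fixture("checkerboard4")
  # 4 of the 8 Moore neighbours differ, each at distance 2/3
  expect_equal(mean_local_complementarity(cb), (4 / 8) * (2 / 3))
  expect_equal(mean_local_complementarity(make_fixture("pointmass6")), 0)

  gr <- random_grid(6, S = 3, seed = 33)
  expect_equal(mean_local_complementarity(gr), oracle_LC(gr), tolerance = 1e-12)
})

test_that("global complementarities match loops and satisfy the weighted identity", {
  set.seed(34)
  for (rep in 1:8) {
    L <- sample(4:8, 1)
    gr <- random_grid(L, S = sample(2:4, 1), radius = 1)
    gc <- global_complementarity(gr)
    ogc <- oracle_GC(gr)
    expect_equal(unname(gc), unname(ogc), tolerance = 1e-12)
    N <- L^2
    tab <- table(gr$species)
    cp <- sum(tab * (tab - 1))
    hp <- N * (N - 1) - cp
    expect_equal(gc[["GC"]] * N * (N - 1),
                 gc[["GC_intra"]] * cp + gc[["GC_inter"]] * hp,
                 tolerance = 1e-12)
  }
})

test_that("monoculture RC needs a second realization and is 0 for point masses", {
  mono <- make_fixture("pointmass6")
  expect_error(relative_complementarity(mono), "second")
  expect_equal(relative_complementarity(mono, mono), 0)

  # two-species community with all individuals at one point: RC = 0
  g <- make_fixture("pointmass6")
  g$species[1:18] <- 2L
  expect_equal(relative_complementarity(g), 0)

  # cross-realization arithmetic matches brute force
  set.seed(35)
  g1 <- random_grid(4, S = 1, radius = 1)
  g2 <- random_grid(4, S = 1, radius = 1)
  cross <- mean(outer(1:16, 1:16, Vectorize(function(i, j)
    oracle_c(g1$traits[i, ], g2$traits[j, ]))))
  within <- function(g) oracle_GC(g)[["GC"]]
  rc_direct <- cross - (sum(sapply(list(g1, g2), function(g) {
    np <- 16 * 15 / 2
    within(g) * np
  })) / (2 * 16 * 15 / 2))
  expect_equal(relative_complementarity(g1, g2), rc_direct, tolerance = 1e-12)
})

test_that("Moran's index matches enumeration, signs, and the ape cross-check", {
  # checkerboard under the Moore kernel: orthogonal avoidance exactly cancels
  # diagonal clustering, so I = 0; enumeration confirms it
  cb <- make_fixture("checkerboard4")
  I_cb <- morans_index(cb)
  expect_equal(I_cb, 0)
  expect_equal(I_cb, oracle_moran(cb), tolerance = 1e-12)

  # striped conspecific avoidance: strictly negative, matches enumeration
  st <- make_fixture("stripes4")
  I_st <- morans_index(st)
  expect_equal(I_st, -0.5)
  expect_equal(I_st, oracle_moran(st), tolerance = 1e-12)

  # two solid half-planes: strongly positive
  kernel <- make_neighbor_kernel(8, radius = 1)
  rc <- cbind(rep(0:7, 8), rep(0:7, each = 8))
  species <- ifelse(rc[, 2] < 4, 1L, 2L)
  traits <- matrix(1 / 3, 64, 3)
  hp <- community_grid(species, traits, kernel)
  expect_gt(morans_index(hp), 0)
  expect_equal(morans_index(hp), oracle_moran(hp), tolerance = 1e-12)

  # independent library cross-check on a random grid (per-species I)
  skip_if_not_installed("ape")
  gr <- random_grid(5, S = 2, radius = 1, seed = 36)
  W <- matrix(0, 25, 25)
  for (i in 1:25) W[i, gr$kernel$nb[i, ]] <- 1
  for (s in 1:2) {
    x <- as.numeric(gr$species == s)
    expect_equal(unname(morans_index(gr, per_species = TRUE)[as.character(s)]),
                 ape::Moran.I(x, W)$observed, tolerance = 1e-10)
  }

  # monoculture: undefined
  expect_true(is.na(morans_index(make_fixture("pointmass6"))))
})

test_that("the full metrics record matches the oracles on random grids", {
  set.seed(37)
  for (rep in 1:6) {
    gr <- random_grid(sample(4:8, 1), S = sample(2:5, 1), radius = 1)
    m <- community_metrics(gr)
    expect_equal(m$LC, oracle_LC(gr), tolerance = 1e-12)
    expect_equal(m$GC, unname(oracle_GC(gr)["GC"]), tolerance = 1e-12)
    expect_equal(m$interspecies_distance, oracle_interspecies(gr), tolerance = 1e-12)
    expect_equal(m$intraspecific_distance, oracle_intraspecific(gr), tolerance = 1e-12)
    om <- oracle_moran(gr)
    if (is.na(om)) expect_true(is.na(m$moran_I))
    else expect_equal(m$moran_I, om, tolerance = 1e-12)
    expect_equal(m$RC, unname(oracle_GC(gr)["GC_inter"] - oracle_GC(gr)["GC_intra"]),
                 tolerance = 1e-12)
    n <- gr$n
    for (col in c("LC", "GC", "GC_intra", "GC_inter",
                  "interspecies_distance", "intraspecific_distance"))
      if (!is.na(m[[col]])) { expect_gte(m[[col]], 0); expect_lte(m[[col]], 2 / n) }
  }
})

test_that("phenotypically equivalent species are grouped by single linkage", {
  g <- make_fixture("threespecies8")
  expect_error(detect_equivalent_species(g, 0), "eps")
  grp <- detect_equivalent_species(g, 0.05)
  expect_equal(grp, list(1L, 2L, 3L))

  # move species 2 onto species 1's vertex: one pair groups at any eps > 0
  g2 <- g
  g2$traits[g2$species == 2L, ] <- matrix(rep(c(1, 0, 0), sum(g2$species == 2L)),
                                          ncol = 3, byrow = TRUE)
  grp2 <- detect_equivalent_species(g2, 0.01)
  expect_equal(grp2, list(c(1L, 2L), 3L))

  # centroid distances {0.01, ~0.5, ~0.5}: exactly one pair groups at eps 0.05
  kernel <- make_neighbor_kernel(8, radius = 2)
  species <- rep(1:3, length.out = 64)
  traits <- matrix(0, 64, 3)
  traits[species == 1L, ] <- matrix(rep(c(0.985, 0.015, 0), sum(species == 1L)),
                                    ncol = 3, byrow = TRUE)
  traits[species == 2L, ] <- matrix(rep(c(1, 0, 0), sum(species == 2L)),
                                    ncol = 3, byrow = TRUE)
  traits[species == 3L, ] <- matrix(rep(c(0.25, 0.75, 0), sum(species == 3L)),
                                    ncol = 3, byrow = TRUE)
  g3 <- community_grid(species, traits, kernel)
  d12 <- pair_complementarity(c(0.985, 0.015, 0), c(1, 0, 0))
  expect_equal(d12, 0.01)
  grp3 <- detect_equivalent_species(g3, 0.05)
  expect_equal(grp3, list(c(1L, 2L), 3L))
})

test_that("vertex distance measures specialization", {
  expect_equal(mean_vertex_distance(make_fixture("threespecies8")), 0)
  expect_equal(mean_vertex_distance(make_fixture("pointmass6")),
               2 * (1 - 1 / 3) / 3)
})
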