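test_that("the lattice stays saturated and labels are conserved", {
  cfg <- simulation_config(L = 8, S = 5, generations = 0, seed = 10)
  set.seed(10)
  g <- init_community(cfg)
  present <- sort(unique(g$species))
  for (i in 1:15) {
    g2 <- step_generation(g, cfg)
    expect_equal(length(g2$species), 64L)
    expect_equal(nrow(g2$traits), 64L)
    expect_true(all(unique(g2$species) %in% present))
    expect_true(max(abs(rowSums(g2$traits) - 1)) < 1e-9)
    expect_equal(g2$generation, g$generation + 1L)
    present <- sort(unique(g2$species))
    g <- g2
  }
})

test_that("without mutation the trait hull cannot grow", {
  cfg <- simulation_config(L = 8, S = 1, mu = 0, beta = 6, generations = 0, seed = 11)
  set.seed(11)
  g <- init_community(cfg)
  rng0 <- apply(g$traits, 2, range)
  for (i in 1:10) {
    g <- step_generation(g, cfg)
    rng <- apply(g$traits, 2, range)
    expect_true(all(rng[1, ] >= rng0[1, ] - 1e-12))
    expect_true(all(rng[2, ] <= rng0[2, ] + 1e-12))
  }
})

test_that("at beta = 0 realised mother choices are uniform over the kernel", {
  # aggregate the offset of chosen mothers relative to each vacant site over
  # many neutral steps; frequencies over the 8 radius-1 offsets must be flat
  cfg <- simulation_config(L = 10, S = 3, beta = 0, mu = 0.02, radius = 1,
                           generations = 0, seed = 12)
  set.seed(12)
  g <- init_community(cfg)
  counts <- integer(8)
  for (rep in 1:400) {
    site <- sample.int(100, 1)
    m <- select_mother(g, site, beta = 0)
    counts[match(m, g$kernel$nb[site, ])] <- counts[match(m, g$kernel$nb[site, ])] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("runs are reproducible from the seed and generations = 0 is a no-op run", {
  cfg <- simulation_config(L = 8, S = 4, generations = 12, seed = 77)
  tra <- run_simulation(cfg)
  trb <- run_simulation(cfg)
  expect_identical(tra$metrics, trb$metrics)
  expect_identical(tra$final_grid$traits, trb$final_grid$traits)

  cfg0 <- simulation_config(L = 8, S = 4, generations = 0, seed = 78)
  t0 <- run_simulation(cfg0)
  expect_equal(nrow(t0$metrics), 1L)
  expect_equal(t0$metrics$generation, 0)
  expect_equal(t0$final_grid$generation, 0L)
})

test_that("surviving-species count is non-increasing along a run", {
  cfg <- simulation_config(L = 12, S = 16, beta = 10, mu = 0.025,
                           generations = 60, seed = 13)
  tr <- run_simulation(cfg)
  expect_true(all(diff(tr$metrics$S_surviving) <= 0))
})

test_that("sequential updating keeps all core invariants", {
  cfg <- simulation_config(L = 6, S = 3, generations = 5, seed = 14,
                           update_mode = "sequential")
  tr <- run_simulation(cfg)
  g <- tr$final_grid
  expect_equal(length(g$species), 36L)
  expect_true(all(g$species %in% 1:3))
  expect_true(max(abs(rowSums(g$traits) - 1)) < 1e-9)
  expect_true(all(diff(tr$metrics$S_surviving) <= 0))
})

test_that("variant flags at their neutral settings reproduce the baseline bit-for-bit", {
  base <- simulation_config(L = 8, S = 4, generations = 8, seed = 15)
  expl <- simulation_config(L = 8, S = 4, generations = 8, seed = 15,
                            reproduction = "sexual", dispersal = "local",
                            performance_kernel = "exponential", reward_a = 0)
  expect_identical(run_simulation(base)$metrics, run_simulation(expl)$metrics)
})

test_that("well-mixed complementarity equals the direct all-pairs mean", {
  g <- random_grid(3, S = 2, radius = 1, seed = 16)
  C <- wellmixed_complementarity(g)
  for (i in 1:9) {
    direct <- mean(vapply(setdiff(1:9, i), function(j)
      oracle_c(g$traits[i, ], g$traits[j, ]), numeric(1)))
    expect_equal(C[i], direct, tolerance = 1e-12)
  }
})

test_that("well-mixed runs erase spatial structure", {
  cfg <- simulation_config(L = 12, S = 6, beta = 8, mu = 0.05,
                           dispersal = "well_mixed", generations = 40,
                           seed = 17, metric_generations = c(0L, 40L))
  tr <- run_simulation(cfg)
  I <- tr$metrics$moran_I[2]
  # permutation null is -1/(N-1); allow generous sampling noise
  if (!is.na(I)) expect_lt(abs(I - (-1 / (144 - 1))), 0.06)
})

test_that("initialisation seats species multinomially and honours init_sigma = 0", {
  cfg <- simulation_config(L = 16, S = 4, init_sigma = 0, generations = 0, seed = 18)
  set.seed(18)
  g <- init_community(cfg)
  expect_true(all(abs(g$traits - 1 / 3) < 1e-12))
  counts <- tabulate(g$species, 4)
  # binomial fluctuation around 256/4 = 64: 4 SEs
  expect_true(all(abs(counts - 64) < 4 * sqrt(256 * 0.25 * 0.75)))

  cfg1 <- simulation_config(L = 8, S = 1, generations = 0, seed = 19)
  set.seed(19)
  expect_true(all(init_community(cfg1)$species == 1L))

  cfgS <- simulation_config(L = 6, S = 3, generations = 0, seed = 20,
                            init_mode = "per_species_gaussian", init_sigma = 0)
  set.seed(20)
  gS <- init_community(cfgS)
  # zero spread: all members of a species sit exactly on its centre
  for (s in 1:3) {
    tr <- gS$traits[gS$species == s, , drop = FALSE]
    expect_true(all(abs(sweep(tr, 2, tr[1, ])) < 1e-12))
  }
  expect_error(simulation_config(L = 4, S = 17, radius = 1), "exceed")
})
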