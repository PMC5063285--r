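# hand-built grid: L x L lattice, all individuals at the simplex centre
# except chosen sites pinned elsewhere, so complementarities are controlled.
flat_grid <- function(L, radius = 2, S = 1, n = 3) {
  kernel <- make_neighbor_kernel(L, radius = radius)
  community_grid(rep_len(seq_len(S), L * L), matrix(1 / n, L * L, n), kernel)
}

test_that("mother selection is uniform over neighbours at beta = 0", {
  g <- random_grid(7, S = 3, radius = 2, seed = 11)
  set.seed(5)
  draws <- select_mother(g, vacant_site = 25L, beta = 0, ndraws = 1e5)
  nbs <- g$kernel$nb[25L, ]
  expect_true(all(draws %in% nbs))
  tab <- table(factor(draws, levels = sort(nbs)))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("mother selection follows the softmax of beta * C", {
  # focal neighbourhood: all at centre except one neighbour at a vertex.
  # That neighbour's C exceeds its peers'; with beta = 10 its selection
  # frequency must match the closed-form softmax within 3 binomial SEs.
  g <- flat_grid(9, radius = 2)
  vac <- 41L  # (row 4, col 4)
  nbs <- g$kernel$nb[vac, ]
  special <- nbs[1L]
  g$traits[special, ] <- c(1, 0, 0)
  C <- local_complementarity(g, nbs)
  w <- exp(10 * C)
  p_true <- w[1L] / sum(w)
  set.seed(6)
  ndraw <- 1e5
  draws <- select_mother(g, vac, beta = 10, ndraws = ndraw)
  phat <- mean(draws == special)
  se <- sqrt(p_true * (1 - p_true) / ndraw)
  expect_lt(abs(phat - p_true), 3 * se)
})

test_that("father selection is conspecific, softmax-weighted, and selfs when alone", {
  g <- flat_grid(6, radius = 2, S = 1)
  # species 2 has exactly 3 members with distinct complementarities
  members <- c(1L, 15L, 30L)
  g$species[members] <- 2L
  g$traits[members[1], ] <- c(0.5, 0.3, 0.2)
  g$traits[members[2], ] <- c(0.1, 0.8, 0.1)
  g$traits[members[3], ] <- c(0, 0, 1)
  C <- local_complementarity(g, members)
  w <- exp(4 * C)
  p_true <- w / sum(w)
  set.seed(7)
  ndraw <- 1e5
  draws <- select_father(g, mother_site = members[1], beta = 4, ndraws = ndraw)
  expect_true(all(draws %in% members))
  phat <- as.vector(table(factor(draws, levels = members))) / ndraw
  se <- sqrt(p_true * (1 - p_true) / ndraw)
  expect_true(all(abs(phat - p_true) < 3 * se))

  # sole conspecific: the mother herself is returned
  g2 <- flat_grid(5, radius = 2, S = 1)
  g2$species[13L] <- 2L
  expect_equal(select_father(g2, 13L, beta = 10), 13L)

  # beta = 0: uniform over the m members
  set.seed(8)
  draws0 <- select_father(g, members[2], beta = 0, ndraws = 6e4)
  tab <- table(factor(draws0, levels = members))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("selection is deterministic under a fixed seed", {
  g <- random_grid(8, S = 4, radius = 2, seed = 21)
  set.seed(33); a <- select_mother(g, 10L, beta = 5, ndraws = 50)
  set.seed(33); b <- select_mother(g, 10L, beta = 5, ndraws = 50)
  expect_identical(a, b)
})

test_that("performance kernels are positive, monotone, and neutral at beta = 0", {
  expect_equal(performance_weight(0.37, 0), 1)
  expect_equal(performance_weight(0, 12), 1)
  expect_equal(performance_weight(0.5, 10), exp(5))
  Cs <- seq(0, 2 / 3, length.out = 20)
  for (kt in c("exponential", "linear", "gaussian")) {
    w <- performance_weight(Cs, 7, kt)
    expect_true(all(w > 0))
    expect_true(all(diff(w) >= 0))
  }
  expect_error(performance_weight(0.1, -1), "beta")
  expect_error(performance_weight(0.1, 1, "cubic"), "unknown")
})
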