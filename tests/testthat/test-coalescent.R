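test_that("forced two-lineage genealogies coalesce after tau", {
  withr::local_seed(1)
  m <- two_species_model(3, 1, 1)
  tm <- replicate(4000, {
    g <- simulate_genealogy(m)
    g$time[g$root]
  })
  expect_true(all(tm >= 3))
  # TMRCA - tau is exponential(1)
  expect_lt(abs(mean(tm - 3) - 1), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("a single panmictic pair coalesces after one unit on average", {
  withr::local_seed(2)
  m <- two_species_model(0, 2, 1)
  # with tau = 0 the three lineages coalesce freely; the first pair event
  # for a specific pair has expectation 1, so check the root of n=2 subcase
  m2 <- two_species_model(0, 1, 1)
  tm <- replicate(6000, simulate_genealogy(m2)$time[2 * 2 - 1])
  expect_lt(abs(mean(tm) - 1), 3 * sd(tm) / sqrt(length(tm)))
})

test_that("genealogies are structurally valid", {
  withr::local_seed(3)
  for (r in 1:20) {
    m <- two_species_model(sample(c(0, 0.5, 2), 1), sample(1:5, 1),
                           sample(1:5, 1))
    g <- simulate_genealogy(m)
    n <- g$n1 + g$n2
    # node times increase rootward along every parent link
    has_par <- g$parent > 0
    expect_true(all(g$time[g$parent[has_par]] >= g$time[has_par]))
    # the root carries every tip
    expect_equal(unname(g$comp[g$root, ]), c(g$n1, g$n2))
    # before tau, no lineage mixes the two species
    pre <- which(g$time > 0 & g$time < m$tau)
    if (length(pre))
      expect_true(all(g$comp[pre, 1] == 0 | g$comp[pre, 2] == 0))
    # merge events reduce the lineage count one at a time down to the root
    expect_equal(g$root, 2L * n - 1L)
    expect_equal(g$parent[g$root], 0L)
  }
})

test_that("reciprocal monophyly is detected from lineage compositions", {
  # ((a1,a2),(b1,b2)): both species coalesce internally first
  g <- structure(list(
    n1 = 2L, n2 = 2L, species = c(1L, 1L, 2L, 2L),
    parent = c(5L, 5L, 6L, 6L, 7L, 7L, 0L),
    time = c(0, 0, 0, 0, 0.2, 0.3, 1.5),
    comp = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                 c(2, 0), c(0, 2), c(2, 2)),
    root = 7L, tau = 1), class = "genealogy")
  expect_true(reciprocal_monophyly(g))
  # ((a1,b1),(a2,b2)): interleaved
  g$comp <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                  c(1, 1), c(1, 1), c(2, 2))
  expect_false(reciprocal_monophyly(g))
  # singleton species is monophyletic by convention
  g1 <- structure(list(
    n1 = 1L, n2 = 2L, species = c(1L, 2L, 2L),
    parent = c(5L, 4L, 4L, 5L, 0L),
    time = c(0, 0, 0, 0.4, 2),
    comp = rbind(c(1, 0), c(0, 1), c(0, 1), c(0, 2), c(1, 2)),
    root = 5L, tau = 1), class = "genealogy")
  expect_true(reciprocal_monophyly(g1))
})

test_that("P(RM) matches exact small-sample results", {
  est <- prm_estimate(0, 2, 2, reps = 40000, seed = 10)
  expect_lt(abs(est$p_hat - 1 / 9), 3 * est$se)
  est1 <- prm_estimate(1, 1, 2, reps = 40000, seed = 11)
  expect_lt(abs(est1$p_hat - (1 - (2 / 3) * exp(-1))), 3 * est1$se)
  expect_gte(prm_estimate(20, 3, 2, reps = 4000, seed = 12)$p_hat, 0.999)
  expect_equal(prm_estimate(0, 1, 1, reps = 50, seed = 13)$p_hat, 1)
  expect_equal(prm_estimate(7, 1, 1, reps = 50, seed = 13)$p_hat, 1)
})

test_that("the lean P(RM) path agrees with explicit genealogy simulation", {
  withr::local_seed(14)
  direct <- mean(replicate(4000, {
    reciprocal_monophyly(simulate_genealogy(two_species_model(1.5, 2, 3)))
  }))
  est <- prm_estimate(1.5, 2, 3, reps = 20000, seed = 15)
  se <- sqrt(direct * (1 - direct) / 4000 + est$se^2)
  expect_lt(abs(direct - est$p_hat), 3.5 * se)
})

test_that("P(RM) is deterministic given a seed and non-decreasing in tau", {
  a <- prm_estimate(2, 3, 3, reps = 5000, seed = 99)
  b <- prm_estimate(2, 3, 3, reps = 5000, seed = 99)
  expect_identical(a$p_hat, b$p_hat)
  taus <- c(0, 0.5, 1, 2, 4, 8)
  ps <- vapply(seq_along(taus), function(i)
    prm_estimate(taus[i], 2, 2, reps = 20000, seed = 100 + i)$p_hat,
    numeric(1))
  ses <- sqrt(ps * (1 - ps) / 20000)
  for (i in seq_len(length(taus) - 1)) {
    expect_gte(ps[i + 1], ps[i] - 3 * sqrt(ses[i]^2 + ses[i + 1]^2))
  }
})

test_that("tau_from_ratio maps the 4x calibration to coalescent time", {
  expect_equal(tau_from_ratio(4, "calibration"), 4)
  expect_equal(tau_from_ratio(4, "ancestral_adjusted"), 3)
  expect_equal(tau_from_ratio(0, "calibration"), 0)
  expect_equal(tau_from_ratio(0.5, "ancestral_adjusted"), 0)
  expect_error(tau_from_ratio(-1), "nonnegative")
})

test_that("the alignment generator respects theta = 0 and records truth", {
  sim <- simulate_two_species_alignment(
    two_species_model(5, 4, 3, theta_site = 0, L = 100, seed = 8))
  aln <- sim$alignment
  expect_equal(aln$n, 7L)
  expect_true(all(apply(aln$seq, 2, function(col) length(unique(col)) == 1)))
  expect_equal(sim$truth$tau, 5)
  expect_equal(unname(sim$truth$species[["sp2_01"]]), "species_2")
  expect_s3_class(sim$truth$genealogy, "genealogy")
})

test_that("the generator is reproducible and the JC mode runs", {
  m <- two_species_model(4, 3, 3, 0.02, 300, seed = 9)
  a1 <- simulate_two_species_alignment(m)$alignment
  a2 <- simulate_two_species_alignment(m)$alignment
  expect_identical(a1$seq, a2$seq)
  jc <- simulate_two_species_alignment(m, mutation_model = "JC")$alignment
  expect_equal(jc$n, 6L)
  expect_equal(jc$L, 300L)
})

test_that("infinite-sites placement refuses more mutations than sites", {
  m <- two_species_model(50, 6, 6, theta_site = 2, L = 20, seed = 10)
  expect_error(simulate_two_species_alignment(m), "JC")
})

test_that("within-species differences calibrate to theta", {
  withr::local_seed(16)
  d <- replicate(150, {
    sim <- simulate_two_species_alignment(
      two_species_model(2, 6, 1, 0.01, 800, seed = sample.int(1e7, 1)))
    mean_pairwise_within(sim$alignment, sp1_ids(6))
  })
  expect_lt(abs(mean(d) - 0.01), 3 * sd(d) / sqrt(length(d)))
})

test_that("a P(RM) grid is tabulated and exported", {
  out <- file.path(withr::local_tempdir(), "grid.tsv")
  g <- prm_grid(tau = c(0, 4), n1 = 2, n2 = c(2, 3), reps = 2000, seed = 3,
                file = out)
  expect_equal(nrow(g), 4L)
  expect_true(all(g$p_rm >= 0 & g$p_rm <= 1))
  expect_true(file.exists(out))
  expect_equal(nrow(utils::read.delim(out)), 4L)
})
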