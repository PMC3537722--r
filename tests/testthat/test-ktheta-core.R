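test_that("mean pairwise difference within a clade", {
  aln <- dna_alignment(c(u = "AAAA", v = "AAAT", w = "AAAA"))
  expect_equal(mean_pairwise_within(aln, c("u", "v", "w")), 0.5 / 3,
               tolerance = 1e-12)
  same <- dna_alignment(c(u = "ACGT", v = "ACGT"))
  expect_equal(mean_pairwise_within(same, c("u", "v")), 0)
  # two sequences differing at 1 of 258 sites
  s <- strrep("A", 258)
  s2 <- paste0("T", strrep("A", 257))
  aln258 <- dna_alignment(c(p = s, q = s2))
  expect_equal(mean_pairwise_within(aln258, c("p", "q")), 1 / 258,
               tolerance = 1e-12)
  # singleton signals NA, not an error
  expect_true(is.na(mean_pairwise_within(aln, "u")))
  expect_error(mean_pairwise_within(aln, "nope"), "not in alignment")
})

test_that("pi_hat applies the sample-size correction", {
  expect_equal(round(pi_hat(0.0076, 8), 4), 0.0087)
  expect_equal(round(pi_hat(0.002, 17), 4), 0.0021)
  expect_equal(pi_hat(0, 12), 0)
  expect_error(pi_hat(0.01, 1), "n >= 2")
  expect_error(pi_hat(1.2, 5), "d_bar")
})

test_that("the d = 0 diversity floor is 2/(L n (n-1))", {
  expect_equal(pi_floor_zero(258, 3), 2 / 1548, tolerance = 1e-12)
  expect_equal(pi_floor_zero(564, 2), 2 / 1128, tolerance = 1e-12)
  expect_equal(pi_floor_zero(1000, 2), 1 / 1000)  # one pair: 1/L
  expect_error(pi_floor_zero(100, 1), "n >= 2")
})

test_that("theta_hat applies the small-diversity correction", {
  expect_equal(round(theta_hat(pi_hat(0.0076, 8)), 4), 0.0088)
  expect_equal(theta_hat(0), 0)
  expect_equal(theta_hat(0.3), 0.5)
  expect_error(theta_hat(0.8), "3/4")
})

test_that("diversity_estimate flags the floor and handles singletons", {
  aln <- dna_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGA"))
  de <- diversity_estimate(aln, c("a", "b"))
  expect_true(de$zero_d)
  expect_equal(de$pi, 2 / (8 * 2 * 1))
  de2 <- diversity_estimate(aln, c("a", "c"))
  expect_false(de2$zero_d)
  expect_equal(de2$pi, (1 / 8) * 2)
  ds <- diversity_estimate(aln, "a")
  expect_equal(ds$n, 1L)
  expect_true(is.na(ds$theta))
})

test_that("between-clade divergence: D uncorrected, K corrected", {
  aln <- dna_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "TTAA", b2 = "TTAA"))
  dk <- between_clade_K(aln, c("a1", "a2"), c("b1", "b2"), "JC69")
  expect_equal(dk$D, 0.5)
  expect_equal(dk$K, 0.8239592, tolerance = 1e-6)   # -0.75 log(1/3)
  clones <- dna_alignment(c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGT"))
  dk0 <- between_clade_K(clones, c("x1", "x2"), "y1", "JC69")
  expect_equal(dk0$D, 0)
  expect_equal(dk0$K, 0)
  expect_error(between_clade_K(aln, c("a1", "b1"), c("b1", "b2")), "disjoint")
})

test_that("K dominates D below saturation across random clade pairs", {
  withr::local_seed(21)
  for (r in 1:10) {
    sim <- simulate_two_species_alignment(
      two_species_model(sample(1:6, 1), 4, 4, 0.02, 400,
                        seed = sample.int(1e7, 1)))
    dk <- between_clade_K(sim$alignment, sp1_ids(4), sp2_ids(4), "JC69")
    expect_gte(dk$K, dk$D)
  }
})

test_that("ratio_test uses the larger theta and validates input", {
  expect_equal(round(ratio_test(0.0206, theta_hat(pi_hat(0.0076, 8)), 0.002), 2),
               2.34)
  expect_equal(round(ratio_test(0.0349, theta_hat(pi_hat(0.002, 17)), 0.001), 1),
               16.4)
  expect_equal(ratio_test(0, 0.01, 0.02), 0)
  expect_error(ratio_test(0.1, 0, 0), "zero")
  expect_error(ratio_test(0.1, NA_real_, NA_real_), "singleton")
})

test_that("the 4x rule classifies with an inclusive boundary", {
  expect_equal(classify_pair(16.4), "distinct_species")
  expect_equal(classify_pair(2.3), "single_species")
  expect_equal(classify_pair(4.0), "distinct_species")
  expect_equal(classify_pair(3.999999), "single_species")
  expect_equal(classify_pair(10, ratio_threshold = 12), "single_species")
})

test_that("theta >= pi >= d_bar whenever n >= 2", {
  withr::local_seed(31)
  for (r in 1:12) {
    n <- sample(2:8, 1)
    sim <- simulate_two_species_alignment(
      two_species_model(1, n, 1, 0.02, 300, seed = sample.int(1e7, 1)))
    de <- diversity_estimate(sim$alignment, sp1_ids(n))
    expect_gte(de$pi, de$d_bar)
    expect_gte(de$theta, de$pi)
    if (de$d_bar > 0) expect_gt(de$theta, de$d_bar)
  }
})

test_that("the ratio is scale-invariant to first order in pi", {
  grid <- expand.grid(d = c(0.001, 0.005, 0.02), n = c(4, 10), D = c(0.02, 0.1))
  for (i in seq_len(nrow(grid))) {
    d <- grid$d[i]; n <- grid$n[i]; D <- grid$D[i]
    r1 <- D / theta_hat(pi_hat(d, n))
    r2 <- (2 * D) / theta_hat(pi_hat(2 * d, n))
    pi <- pi_hat(d, n)
    expect_lte(abs(r2 - r1) / r1, 5 * pi)
  }
})

test_that("pooling genealogical sister clades does not drop d_bar below the smaller side", {
  withr::local_seed(41)
  for (r in 1:10) {
    sim <- simulate_two_species_alignment(
      two_species_model(2, 5, 5, 0.01, 800, seed = sample.int(1e7, 1)))
    aln <- sim$alignment
    dA <- mean_pairwise_within(aln, sp1_ids(5))
    dB <- mean_pairwise_within(aln, sp2_ids(5))
    dAB <- mean_pairwise_within(aln, c(sp1_ids(5), sp2_ids(5)))
    expect_gte(dAB, min(dA, dB) - 1e-12)
  }
})

test_that("pair_test assembles the full record with gates", {
  a <- strrep("A", 39)
  aln <- dna_alignment(c(a1 = paste0(a, "A"), a2 = paste0(a, "T"),
                         b1 = paste0(strrep("T", 20), strrep("A", 19), "A"),
                         b2 = paste0(strrep("T", 20), strrep("A", 19), "T")))
  pt <- pair_test(aln, c("a1", "a2"), c("b1", "b2"), model = "uncorrected")
  expect_equal(pt$n1, 2L)
  expect_equal(pt$D, 0.5125)   # 20 fixed + shared polymorphic site, L = 40
  expect_equal(pt$decision, "distinct_species")
  # same data, but flagged as not support-qualified: cannot split
  pt2 <- pair_test(aln, c("a1", "a2"), c("b1", "b2"), model = "uncorrected",
                   support_qualified = FALSE)
  expect_equal(pt2$decision, "single_species")
  expect_equal(pt2$ratio, pt$ratio)
  # two singletons are indeterminate
  pt3 <- pair_test(aln, "a1", "b1")
  expect_equal(pt3$decision, "indeterminate")
  expect_true(is.na(pt3$ratio))
})

test_that("a floor-based theta never supports a split, however large the ratio", {
  aln <- dna_alignment(c(a1 = strrep("A", 100), a2 = strrep("A", 100),
                         b1 = paste0(strrep("T", 10), strrep("A", 90))))
  pt <- pair_test(aln, c("a1", "a2"), "b1", model = "uncorrected")
  expect_true(pt$theta_floor)
  expect_gt(pt$ratio, 4)
  expect_equal(pt$decision, "single_species")
})

test_that("delimit splits two simulated clusters and keeps panmixia whole", {
  # two well-separated clusters
  sim <- simulate_two_species_alignment(
    two_species_model(10, 8, 8, 0.01, 1000, seed = 901))
  tr <- fixture_tree(8, 8)
  sup <- bootstrap_supports(sim$alignment, "JC69", B = 80, seed = 901)
  dl <- delimit(sim$alignment, tr, sup, prm_reps = 500, seed = 901)
  expect_equal(length(unique(dl$partition$species)), 2L)
  split_row <- dl$pair_tests[dl$pair_tests$decision == "distinct_species", ]
  expect_equal(nrow(split_row), 1L)
  expect_gte(split_row$ratio, 4)
  expect_gte(split_row$p_rm, 0.95)
  # same members as the two simulated populations
  part <- dl$partition
  expect_equal(length(unique(part$species[part$id %in% sp1_ids(8)])), 1L)
  expect_equal(length(unique(part$species[part$id %in% sp2_ids(8)])), 1L)

  # a panmictic sample tested at an arbitrary bipartition stays one species
  pan <- simulate_two_species_alignment(
    two_species_model(0, 8, 8, 0.01, 1000, seed = 902))
  sup_forced <- support_map(list(sp1_ids(8)), pan$alignment$ids)
  dl0 <- delimit(pan$alignment, tr, sup_forced, prm_reps = 0)
  expect_equal(length(unique(dl0$partition$species)), 1L)
  tested <- dl0$pair_tests[dl0$pair_tests$n1 > 1 & dl0$pair_tests$n2 > 1, ]
  expect_true(all(tested$ratio < 4))
})

test_that("a singleton sister to a five-member clade can found a species", {
  withr::local_seed(55)
  clade <- vapply(1:5, function(i) {
    s <- rep("A", 200)
    s[sample(200, 2)] <- "C"            # within-clade variation, d > 0
    paste(s, collapse = "")
  }, character(1))
  lone <- paste(c(rep("T", 60), rep("A", 140)), collapse = "")
  aln <- dna_alignment(c(setNames(clade, paste0("c", 1:5)), lone = lone))
  tr <- ape::read.tree(text = "((c1,c2,c3,c4,c5),lone);")
  sup <- support_map(list(paste0("c", 1:5)), aln$ids, 98)
  dl <- delimit(aln, tr, sup, prm_reps = 0)
  expect_equal(length(unique(dl$partition$species)), 2L)
  row <- dl$pair_tests[dl$pair_tests$n1 == 1 | dl$pair_tests$n2 == 1, ]
  row <- row[row$decision == "distinct_species", ]
  expect_equal(nrow(row), 1L)
  # theta comes from the clade side, not the singleton
  clade_theta <- diversity_estimate(aln, paste0("c", 1:5))$theta
  expect_equal(row$theta_used, clade_theta)
})

test_that("delimit is deterministic and validates leaf sets", {
  sim <- simulate_two_species_alignment(
    two_species_model(8, 5, 5, 0.01, 500, seed = 77))
  tr <- fixture_tree(5, 5)
  sup <- bootstrap_supports(sim$alignment, "JC69", B = 50, seed = 77)
  d1 <- delimit(sim$alignment, tr, sup, prm_reps = 300, seed = 5)
  d2 <- delimit(sim$alignment, tr, sup, prm_reps = 300, seed = 5)
  expect_identical(d1$pair_tests, d2$pair_tests)
  expect_identical(d1$partition, d2$partition)
  bad <- ape::read.tree(text = "((sp1_01,zzz),sp2_01);")
  expect_error(delimit(sim$alignment, bad, sup), "missing from alignment")
})

test_that("a raven-like three-clade structure reproduces the published logic", {
  # Chihuahuan-like clade sister to a California-like clade (ratio < 4, merge),
  # their union against a Holarctic-like clade (ratio >> 4, split)
  withr::local_seed(66)
  L <- 258
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mutate <- function(s, sites, alt) { s[sites] <- alt; s }
  hol_sites <- 1:12                       # deep divergence of the third clade
  cal_sites <- 20:21                      # shallow split of the sister pair
  mk <- function(n, prefix, fixed_sites, alt) {
    out <- character(n)
    for (i in seq_len(n)) {
      s <- base
      s <- mutate(s, fixed_sites, alt)
      poly <- 100 + i                      # one private site per sequence
      s <- mutate(s, poly, "T")
      out[i] <- paste(s, collapse = "")
    }
    setNames(out, paste0(prefix, seq_len(n)))
  }
  seqs <- c(mk(8, "chi", cal_sites, "G"), mk(6, "cal", integer(0), "A"),
            mk(10, "hol", hol_sites, "C"))
  aln <- dna_alignment(seqs)
  tr <- ape::read.tree(text = sprintf("(((%s),(%s)),(%s));",
                                      paste(names(seqs)[1:8], collapse = ","),
                                      paste(names(seqs)[9:14], collapse = ","),
                                      paste(names(seqs)[15:24], collapse = ",")))
  sup <- support_map(list(names(seqs)[1:8], names(seqs)[9:14],
                          names(seqs)[1:14], names(seqs)[15:24]),
                     aln$ids, c(95, 73, 90, 87))
  dl <- delimit(aln, tr, sup, model = "uncorrected", prm_reps = 0)
  expect_equal(length(unique(dl$partition$species)), 2L)
  pt <- dl$pair_tests
  sister <- pt[grepl("chi", pt$A) & grepl("cal", pt$B) |
               grepl("cal", pt$A) & grepl("chi", pt$B), ]
  sister <- sister[sister$n1 > 1 & sister$n2 > 1, ]
  expect_true(all(sister$decision == "single_species"))
  deep <- pt[pt$decision == "distinct_species", ]
  expect_equal(nrow(deep), 1L)
  expect_gt(deep$ratio, 4)
})
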