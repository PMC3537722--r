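# Two-population coalescent machinery: genealogy simulation, reciprocal
# monophyly, Monte Carlo P(RM) (the stand-in for the unpublished
# reciprocal-monophyly probability table), and a synthetic two-species
# alignment generator.
#
# Time is measured in pairwise-coalescent units: 1 unit = Ne generations for
# a uniparental genome, so a random pair within a population coalesces after
# an expected 1 unit, theta = 2*Ne*mu is the expected within-population
# pairwise difference per site, and the 4x-rule calibration time
# (K = 8*Ne*mu) is exactly tau = 4.

#' Two-species divergence model
#'
#' Parameter container for the split model: a single population divides at
#' time `tau` (pairwise-coalescent units) before the present into two
#' completely isolated populations, from which `n1` and `n2` sequences of
#' `L` sites are sampled today.
#'
#' @param tau divergence time, >= 0 (coalescent units; `Inf` allowed).
#' @param n1,n2 sample sizes, >= 1.
#' @param theta_site `2*Ne*mu` per site (expected within-population pairwise
#'   difference).
#' @param L number of sites.
#' @param reps Monte Carlo replicates for probability estimation.
#' @param seed integer RNG seed (mandatory for reproducible pipelines).
#' @return a `two_species_model` object.
#' @export
two_species_model <- function(tau, n1, n2, theta_site = 0.01, L = 1000L,
                              reps = 100000L, seed = NULL) {
  stopifnot(tau >= 0, n1 >= 1L, n2 >= 1L, theta_site >= 0, L >= 1L, reps >= 1L)
  structure(list(tau = tau, n1 = as.integer(n1), n2 = as.integer(n2),
                 theta_site = theta_site, L = as.integer(L),
                 reps = as.integer(reps), seed = seed),
            class = "two_species_model")
}

#' @export
print.two_species_model <- function(x, ...) {
  cat(sprintf("two-species coalescent model: tau=%g, n1=%d, n2=%d, theta=%g/site, L=%d\n",
              x$tau, x$n1, x$n2, x$theta_site, x$L))
  invisible(x)
}

#' Simulate one gene genealogy under the split model
#'
#' Standard two-population coalescent: within each population, each pair of
#' lineages coalesces at rate 1 per coalescent unit until `tau`; the
#' surviving lineages then coalesce freely in the ancestral population at
#' the same pair rate. Uses the current RNG stream.
#'
#' @param model a [two_species_model()].
#' @return a `genealogy`: tips `1..n1` are species 1, `n1+1..n1+n2` species
#'   2, internal nodes numbered in coalescence order; `parent` links
#'   (0 for the root), `time` of every node (tips at 0), and `comp`, the
#'   per-node count of descendant tips from each species.
#' @export
simulate_genealogy <- function(model) {
  stopifnot(inherits(model, "two_species_model"))
  tau <- model$tau
  n1 <- model$n1
  n2 <- model$n2
  n <- n1 + n2
  nn <- 2L * n - 1L
  parent <- integer(nn)
  time <- numeric(nn)
  comp <- matrix(0L, nn, 2L)
  comp[seq_len(n1), 1L] <- 1L
  if (n2 > 0L) comp[n1 + seq_len(n2), 2L] <- 1L
  nxt <- n + 1L
  pools <- list(seq_len(n1), n1 + seq_len(n2))
  for (p in 1:2) {
    act <- pools[[p]]
    t <- 0
    while (length(act) >= 2L) {
      k <- length(act)
      w <- stats::rexp(1L, k * (k - 1L) / 2)
      if (t + w > tau) break
      t <- t + w
      pick <- sample.int(k, 2L)
      a <- act[pick[1L]]
      b <- act[pick[2L]]
      parent[a] <- parent[b] <- nxt
      time[nxt] <- t
      comp[nxt, ] <- comp[a, ] + comp[b, ]
      act <- c(act[-pick], nxt)
      nxt <- nxt + 1L
    }
    pools[[p]] <- act
  }
  act <- c(pools[[1L]], pools[[2L]])
  t <- tau
  while (length(act) >= 2L) {
    k <- length(act)
    t <- t + stats::rexp(1L, k * (k - 1L) / 2)
    pick <- sample.int(k, 2L)
    a <- act[pick[1L]]
    b <- act[pick[2L]]
    parent[a] <- parent[b] <- nxt
    time[nxt] <- t
    comp[nxt, ] <- comp[a, ] + comp[b, ]
    act <- c(act[-pick], nxt)
    nxt <- nxt + 1L
  }
  structure(list(n1 = n1, n2 = n2,
                 species = rep(1:2, c(n1, n2)),
                 parent = parent, time = time, comp = comp,
                 root = nn, tau = tau),
            class = "genealogy")
}

#' Is a genealogy reciprocally monophyletic?
#'
#' `TRUE` iff the species-1 tips and the species-2 tips each form a clade
#' in the gene tree. A species sampled once is monophyletic by convention.
#' A clade of the gene tree corresponds exactly to an ancestral lineage at
#' some time, so the check scans the recorded lineage compositions.
#'
#' @param g a [simulate_genealogy()] result.
#' @return logical.
#' @export
reciprocal_monophyly <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  m1 <- any(g$comp[, 1L] == g$n1 & g$comp[, 2L] == 0L)
  m2 <- any(g$comp[, 2L] == g$n2 & g$comp[, 1L] == 0L)
  m1 && m2
}

# one lean reciprocal-monophyly draw; labels: 1 = pure species-1 lineage,
# 2 = pure species-2, 0 = mixed (a mixed lineage can never be ancestral to a
# pure clade again, so monophyly of species s is decided the moment the pure
# s-lineages collapse to one while no mixed lineage exists)
.rm_draw <- function(tau, n1, n2) {
  mono1 <- n1 == 1L
  mono2 <- n2 == 1L
  surv <- c(n1, n2)
  for (p in 1:2) {
    k <- surv[p]
    t <- 0
    while (k >= 2L) {
      w <- stats::rexp(1L, k * (k - 1L) / 2)
      if (t + w > tau) break
      t <- t + w
      k <- k - 1L
    }
    surv[p] <- k
  }
  if (surv[1L] == 1L) mono1 <- TRUE
  if (surv[2L] == 1L) mono2 <- TRUE
  lab <- c(rep(1L, surv[1L]), rep(2L, surv[2L]))
  while (length(lab) >= 2L && !(mono1 && mono2)) {
    pick <- sample.int(length(lab), 2L)
    a <- lab[pick[1L]]
    b <- lab[pick[2L]]
    newl <- if (a == 1L && b == 1L) 1L else if (a == 2L && b == 2L) 2L else 0L
    lab <- c(lab[-pick], newl)
    if (newl == 1L && sum(lab == 1L) == 1L && !any(lab == 0L)) mono1 <- TRUE
    if (newl == 2L && sum(lab == 2L) == 1L && !any(lab == 0L)) mono2 <- TRUE
  }
  mono1 && mono2
}

#' Monte Carlo probability of reciprocal monophyly
#'
#' Estimates the probability that samples of `n1` and `n2` sequences from
#' two populations separated `tau` coalescent units ago are reciprocally
#' monophyletic in their gene tree, by simulating genealogies under the
#' split model. This replaces the tabulated probabilities that the original
#' workflow looked up. Deterministic given `seed`.
#'
#' @param tau divergence time in pairwise-coalescent units.
#' @param n1,n2 sample sizes.
#' @param reps Monte Carlo replicates.
#' @param seed integer RNG seed.
#' @return list with `p_hat`, binomial `se`, and the call parameters.
#' @examples
#' prm_estimate(0, 2, 2, reps = 2000, seed = 1)$p_hat   # ~ 1/9
#' @export
prm_estimate <- function(tau, n1, n2, reps = 100000L, seed) {
  stopifnot(tau >= 0, n1 >= 1L, n2 >= 1L, reps >= 1L)
  hits <- with_seed(seed, {
    h <- 0L
    for (r in seq_len(reps)) if (.rm_draw(tau, n1, n2)) h <- h + 1L
    h
  })
  p <- hits / reps
  list(p_hat = p, se = sqrt(p * (1 - p) / reps),
       tau = tau, n1 = n1, n2 = n2, reps = reps, seed = seed)
}

#' Divergence time implied by a K/theta ratio
#'
#' Under the calibration `theta = 2*Ne*mu` and `K = 2*mu*T` accumulating
#' since the split, `K/theta = T/Ne`, i.e. the ratio *is* the divergence
#' time in pairwise-coalescent units (`mode = "calibration"`; the 4x rule's
#' `K = 8*Ne*mu` at `T = 4*Ne` generations is the special case ratio = 4).
#' Because the expected between-clade difference under the unconditioned
#' coalescent is `E[K] = theta * (tau + 1)` -- divergence plus ancestral
#' polymorphism -- `mode = "ancestral_adjusted"` subtracts that ancestral
#' contribution: `tau = max(ratio - 1, 0)`.
#'
#' @param ratio K/theta ratio, >= 0.
#' @param mode `"calibration"` or `"ancestral_adjusted"`.
#' @return divergence time in pairwise-coalescent units.
#' @export
tau_from_ratio <- function(ratio, mode = c("calibration", "ancestral_adjusted")) {
  mode <- match.arg(mode)
  if (ratio < 0) stop("ratio must be nonnegative")
  switch(mode, calibration = ratio, ancestral_adjusted = max(ratio - 1, 0))
}

#' Simulate a two-species alignment with known truth
#'
#' Simulates a genealogy under the split model, drops Poisson mutations on
#' its branches at rate `theta_site/2` per site per coalescent unit (so the
#' expected within-species pairwise difference equals `theta_site` and the
#' expected between-species difference is `theta_site * (tau + 1)`), and
#' applies them to a random ancestral sequence. Under the default
#' infinite-sites placement every mutation hits a fresh site, keeping
#' observed differences exactly proportional to branch length; `"JC"` mode
#' allows repeat hits for saturation testing.
#'
#' @param model a [two_species_model()]; its `seed`, if non-`NULL`, fixes
#'   the RNG for this dataset.
#' @param mutation_model `"infinite_sites"` or `"JC"`.
#' @return list with `alignment` (a [dna_alignment()]; ids `sp1_*`/`sp2_*`)
#'   and `truth` (tau, theta_site, L, seed, species assignment, genealogy).
#' @export
simulate_two_species_alignment <- function(model,
    mutation_model = c("infinite_sites", "JC")) {
  stopifnot(inherits(model, "two_species_model"))
  mutation_model <- match.arg(mutation_model)
  run <- function() {
    g <- simulate_genealogy(model)
    n <- model$n1 + model$n2
    nn <- 2L * n - 1L
    L <- model$L
    bases <- c("A", "C", "G", "T")
    bl <- numeric(nn)
    has_par <- g$parent > 0L
    bl[has_par] <- g$time[g$parent[has_par]] - g$time[has_par]
    nmut <- stats::rpois(nn, bl * model$theta_site / 2 * L)
    anc <- sample(bases, L, replace = TRUE)
    seqs <- matrix(anc, n, L, byrow = TRUE)
    ch <- split(which(has_par), g$parent[has_par])
    if (mutation_model == "infinite_sites") {
      M <- sum(nmut)
      if (M > L)
        stop("infinite-sites placement needs ", M, " distinct sites but L = ",
             L, "; increase L or use mutation_model = \"JC\"")
      sites <- if (M > 0L) sample.int(L, M) else integer(0)
      # descendant tip sets, children always created before parents
      tipset <- vector("list", nn)
      for (i in seq_len(n)) tipset[[i]] <- i
      for (nd in seq.int(n + 1L, nn)) {
        tipset[[nd]] <- unlist(lapply(ch[[as.character(nd)]],
                                      function(k) tipset[[k]]))
      }
      idx <- 0L
      for (nd in which(nmut > 0L)) {
        for (m in seq_len(nmut[nd])) {
          idx <- idx + 1L
          s <- sites[idx]
          seqs[tipset[[nd]], s] <- sample(setdiff(bases, anc[s]), 1L)
        }
      }
    } else {
      evolve <- function(nd, s) {
        k <- nmut[nd]
        if (k > 0L) {
          for (site in sample.int(L, k, replace = TRUE))
            s[site] <- sample(setdiff(bases, s[site]), 1L)
        }
        if (nd <= n) seqs[nd, ] <<- s
        else for (c in ch[[as.character(nd)]]) evolve(c, s)
      }
      evolve(g$root, anc)
    }
    ids <- c(sprintf("sp1_%02d", seq_len(model$n1)),
             sprintf("sp2_%02d", seq_len(model$n2)))
    species <- stats::setNames(rep(c("species_1", "species_2"),
                                   c(model$n1, model$n2)), ids)
    list(alignment = dna_alignment(seqs, ids = ids),
         truth = list(tau = model$tau, theta_site = model$theta_site,
                      L = L, seed = model$seed, species = species,
                      genealogy = g))
  }
  if (!is.null(model$seed)) with_seed(model$seed, run()) else run()
}

#' Tabulate reciprocal-monophyly probabilities over a parameter grid
#'
#' Convenience replacement for a lookup table: estimates P(RM) on the
#' Cartesian grid of `tau`, `n1`, `n2` values, optionally writing a
#' tab-separated table.
#'
#' @param tau,n1,n2 vectors of parameter values.
#' @param reps Monte Carlo replicates per cell.
#' @param seed base seed; each cell uses `seed + cell index`.
#' @param file optional output path for a TSV.
#' @return data.frame with columns `tau`, `n1`, `n2`, `p_rm`, `se`.
#' @export
prm_grid <- function(tau, n1, n2, reps = 10000L, seed = 1L, file = NULL) {
  grid <- expand.grid(tau = tau, n1 = n1, n2 = n2, KEEP.OUT.ATTRS = FALSE)
  est <- lapply(seq_len(nrow(grid)), function(i) {
    prm_estimate(grid$tau[i], grid$n1[i], grid$n2[i], reps = reps,
                 seed = seed + i)
  })
  grid$p_rm <- vapply(est, `[[`, numeric(1L), "p_hat")
  grid$se <- vapply(est, `[[`, numeric(1L), "se")
  if (!is.null(file)) {
    utils::write.table(format(grid, digits = 6), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  grid
}
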