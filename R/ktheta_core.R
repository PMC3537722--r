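# The K/theta estimators and decision rule: d_bar -> pi -> theta within a
# clade, D/K between clades, the larger-theta convention, the 4x rule, and
# the tip-up delimitation traversal with singleton handling.

#' Mean pairwise uncorrected difference within a clade
#'
#' Averages the uncorrected per-site difference proportion over all
#' `n(n-1)/2` sequence pairs in the clade (pairwise deletion of gaps and
#' ambiguous residues). This is the `d` from which nucleotide
#' diversity is estimated; multiple-hit corrections are never applied within
#' clades.
#'
#' @param aln a [dna_alignment()].
#' @param clade character vector of sequence ids (subset of `aln$ids`).
#' @return mean difference per site; `NA` with a message attribute when the
#'   clade is a singleton (the caller decides how to handle singletons).
#' @export
mean_pairwise_within <- function(aln, clade) {
  stopifnot(inherits(aln, "dna_alignment"))
  bad <- setdiff(clade, aln$ids)
  if (length(bad)) stop("clade id(s) not in alignment: ",
                        paste(bad, collapse = ", "))
  n <- length(clade)
  if (n < 2L) return(NA_real_)
  enc <- .encode_alignment(aln)[clade, , drop = FALSE]
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      tot <- tot + .site_counts_enc(enc[i, ], enc[j, ], who = clade[c(i, j)])$p
    }
  }
  tot / (n * (n - 1L) / 2L)
}

#' Nucleotide diversity from the mean pairwise difference
#'
#' `pi = d_bar * n / (n - 1)`: the sample-size correction turns the mean
#' pairwise difference into an unbiased estimate of nucleotide diversity.
#'
#' @param d_bar mean pairwise difference within the clade (per site).
#' @param n number of sequences in the clade (>= 2).
#' @return nucleotide diversity estimate.
#' @examples
#' pi_hat(0.0076, 8)   # 0.008686
#' @export
pi_hat <- function(d_bar, n) {
  if (n < 2L) stop("pi_hat needs n >= 2; use pi_floor_zero or the singleton policy")
  if (d_bar < 0 || d_bar > 1) stop("d_bar must lie in [0, 1]")
  d_bar * n / (n - 1)
}

#' Non-zero diversity floor for clades with no observed differences
#'
#' When every pair in a clade is identical (`d_bar = 0`), theta would be
#' zero and K/theta undefined. The convention is to assume one pairwise
#' difference equals `1/L` instead of zero, giving `pi = 2 / (L n (n - 1))`.
#'
#' @param L number of sites.
#' @param n number of sequences in the clade (>= 2).
#' @return the floored diversity estimate.
#' @examples
#' pi_floor_zero(258, 3)   # 2/1548
#' @export
pi_floor_zero <- function(L, n) {
  if (n < 2L) stop("pi_floor_zero needs n >= 2")
  if (L < 1L) stop("L must be >= 1")
  2 / (L * n * (n - 1))
}

#' Theta from nucleotide diversity
#'
#' Estimates `theta = 2*Ne*mu` per site from nucleotide diversity by the
#' small-diversity correction `theta = pi / (1 - 4 pi / 3)`.
#'
#' @param pi nucleotide diversity in `[0, 3/4)`.
#' @return theta estimate.
#' @examples
#' theta_hat(0.008686)   # 0.008787
#' @export
theta_hat <- function(pi) {
  if (pi < 0 || pi >= 0.75)
    stop("pi must lie in [0, 3/4) for the theta correction")
  pi / (1 - 4 * pi / 3)
}

#' Per-clade diversity summary
#'
#' Computes the full within-clade record: `n`, `L`, `d_bar`, `pi`, `theta`,
#' applying the [pi_floor_zero()] convention when no differences are
#' observed (flagged by `zero_d`). Singleton clades get `NA` estimates.
#'
#' @param aln a [dna_alignment()].
#' @param clade character vector of sequence ids.
#' @return a `diversity_estimate` object.
#' @export
diversity_estimate <- function(aln, clade) {
  n <- length(clade)
  L <- aln$L
  if (n < 2L) {
    return(structure(list(n = n, L = L, d_bar = NA_real_, pi = NA_real_,
                          theta = NA_real_, zero_d = FALSE),
                     class = "diversity_estimate"))
  }
  d <- mean_pairwise_within(aln, clade)
  if (d == 0) {
    pi <- pi_floor_zero(L, n)
    zd <- TRUE
  } else {
    pi <- pi_hat(d, n)
    zd <- FALSE
  }
  structure(list(n = n, L = L, d_bar = d, pi = pi, theta = theta_hat(pi),
                 zero_d = zd),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("n=%d L=%d d_bar=%s pi=%s theta=%s%s\n", x$n, x$L,
              format(x$d_bar, digits = 4), format(x$pi, digits = 4),
              format(x$theta, digits = 4),
              if (isTRUE(x$zero_d)) " [d=0 floor]" else ""))
  invisible(x)
}

#' Between-clade divergence, uncorrected and corrected
#'
#' `D` is the mean uncorrected difference over all cross pairs between the
#' two clades; `K` is the mean of the model-corrected cross-pair distances.
#' Both are returned; the delimitation policy selects which one feeds the
#' ratio (D when small, K otherwise).
#'
#' @param aln a [dna_alignment()].
#' @param A,B disjoint, nonempty id sets.
#' @param model correction model for `K`.
#' @param allow_saturated if `FALSE` (default), a saturated cross pair under
#'   `model` is an error; if `TRUE`, saturated pairs are excluded from the
#'   `K` mean and counted in `n_saturated`.
#' @return list with `D`, `K`, `model`, `n_pairs`, `n_saturated`.
#' @export
between_clade_K <- function(aln, A, B, model = "JC69",
                            allow_saturated = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (!length(A) || !length(B)) stop("both clades must be nonempty")
  if (length(intersect(A, B))) stop("clades A and B must be disjoint")
  bad <- setdiff(c(A, B), aln$ids)
  if (length(bad)) stop("id(s) not in alignment: ", paste(bad, collapse = ", "))
  enc <- .encode_alignment(aln)
  Dsum <- 0
  Ksum <- 0
  nsat <- 0L
  npairs <- 0L
  for (a in A) {
    for (b in B) {
      sc <- .site_counts_enc(enc[a, ], enc[b, ], who = c(a, b))
      Dsum <- Dsum + sc$p
      k <- correct_distance(sc, model)
      if (is.na(k)) {
        if (!allow_saturated)
          stop("saturated cross pair under ", model, ": ", a, " - ", b)
        nsat <- nsat + 1L
      } else {
        Ksum <- Ksum + as.numeric(k)
        npairs <- npairs + 1L
      }
    }
  }
  list(D = Dsum / (length(A) * length(B)),
       K = if (npairs) Ksum / npairs else NA_real_,
       model = model, n_pairs = length(A) * length(B), n_saturated = nsat)
}

#' The K/theta ratio with the larger-theta convention
#'
#' Divides the between-clade divergence by the larger of the two clade
#' thetas -- the conservative choice, since it makes the ratio smaller and
#' so less likely to split.
#'
#' @param div between-clade divergence (`D` or `K`).
#' @param thetaA,thetaB per-clade theta estimates; use `NA` for a singleton
#'   clade (its theta cannot be estimated and the other clade's is used).
#' @return the ratio `div / max(thetaA, thetaB)`.
#' @examples
#' ratio_test(0.0206, 0.008787, 0.002)   # ~2.34
#' @export
ratio_test <- function(div, thetaA, thetaB = NA_real_) {
  if (div < 0) stop("divergence must be nonnegative")
  cand <- c(thetaA, thetaB)
  cand <- cand[!is.na(cand)]
  if (!length(cand))
    stop("no usable theta: both clades are singletons")
  th <- max(cand)
  if (th <= 0)
    stop("both theta estimates are zero; apply the d=0 floor (pi_floor_zero)")
  div / th
}

#' Classify a sister pair by the 4x rule
#'
#' @param ratio the K/theta (or D/theta) ratio.
#' @param ratio_threshold decision threshold; the calibration
#'   `K = 8*Ne*mu` at the time 95% of sister pairs are reciprocally
#'   monophyletic, against `theta = 2*Ne*mu`, gives the default 4. The
#'   boundary is inclusive.
#' @return `"distinct_species"` or `"single_species"`.
#' @export
classify_pair <- function(ratio, ratio_threshold = 4) {
  if (is.na(ratio)) return("indeterminate")
  if (ratio < 0) stop("ratio must be nonnegative")
  if (ratio >= ratio_threshold) "distinct_species" else "single_species"
}

#' Full K/theta test for one pair of clades
#'
#' Builds the complete per-pair record: per-clade diversity estimates (with
#' the d=0 floor), between-clade `D` and `K`, the divergence actually used
#' (`D` when `D < dk_switch`, else `K`), theta under the larger-theta /
#' singleton conventions, the ratio, the 4x-rule decision, and optionally
#' the coalescent probability of reciprocal monophyly at the divergence time
#' implied by the ratio.
#'
#' Singletons: a singleton sister to a clade takes theta from that clade;
#' two sister singletons are `indeterminate` (theta cannot be estimated
#' from either side).
#'
#' @param aln a [dna_alignment()].
#' @param A,B disjoint id sets.
#' @param model correction model for `K`.
#' @param dk_switch use `D` instead of `K` when `D` is below this level.
#' @param ratio_threshold 4x-rule threshold.
#' @param prm_reps Monte Carlo replicates for the reciprocal-monophyly
#'   probability; set to 0 to skip.
#' @param seed RNG seed for the Monte Carlo run (required when
#'   `prm_reps > 0`).
#' @param tau_mode mapping from ratio to divergence time, see
#'   [tau_from_ratio()].
#' @param support_qualified whether the pair counts as a well-supported
#'   sister-clade pair (both sides singletons or bootstrap-supported
#'   clades). Only support-qualified pairs can be declared
#'   `distinct_species`; [delimit()] computes this from the bootstrap map,
#'   and it defaults to `TRUE` for standalone use.
#' @return a one-row `data.frame` (class `pair_test`) with columns
#'   `A, B, n1, n2, d1, d2, pi1, pi2, theta1, theta2, zero_d1, zero_d2,
#'   D, K, model, div_used, theta_used, theta_floor, ratio, tau, p_rm,
#'   qualified, decision`. `theta_floor` records whether the theta actually
#'   used came from the d = 0 floor; such estimates are treated as too
#'   uncertain to split on, so the pair is kept `single_species` however
#'   large its ratio (the ratio itself is reported for inspection).
#' @export
pair_test <- function(aln, A, B, model = "JC69", dk_switch = 0.05,
                      ratio_threshold = 4, prm_reps = 0L, seed = NULL,
                      tau_mode = "calibration", support_qualified = TRUE) {
  ea <- diversity_estimate(aln, A)
  eb <- diversity_estimate(aln, B)
  dk <- between_clade_K(aln, A, B, model)
  div_used <- if (dk$D < dk_switch) "D" else "K"
  div <- if (div_used == "D") dk$D else dk$K
  n1 <- ea$n
  n2 <- eb$n
  if (n1 == 1L && n2 == 1L) {
    theta_used <- NA_real_
    floor_used <- FALSE
    ratio <- NA_real_
    decision <- "indeterminate"
  } else {
    if (n1 == 1L) {
      theta_used <- eb$theta
      floor_used <- eb$zero_d
    } else if (n2 == 1L) {
      theta_used <- ea$theta
      floor_used <- ea$zero_d
    } else if (ea$theta >= eb$theta) {
      theta_used <- ea$theta
      floor_used <- ea$zero_d
    } else {
      theta_used <- eb$theta
      floor_used <- eb$zero_d
    }
    ratio <- div / theta_used
    decision <- if (classify_pair(ratio, ratio_threshold) ==
                    "distinct_species" && support_qualified && !floor_used)
                  "distinct_species" else "single_species"
  }
  tau <- if (is.na(ratio)) NA_real_ else tau_from_ratio(ratio, tau_mode)
  p_rm <- NA_real_
  if (!is.na(tau) && prm_reps > 0L) {
    if (is.null(seed)) stop("a seed is required for the P(RM) Monte Carlo run")
    p_rm <- prm_estimate(tau, n1, n2, reps = prm_reps, seed = seed)$p_hat
  }
  out <- data.frame(
    A = .clade_label(A), B = .clade_label(B), n1 = n1, n2 = n2,
    d1 = ea$d_bar, d2 = eb$d_bar, pi1 = ea$pi, pi2 = eb$pi,
    theta1 = ea$theta, theta2 = eb$theta,
    zero_d1 = ea$zero_d, zero_d2 = eb$zero_d,
    D = dk$D, K = dk$K, model = model, div_used = div_used,
    theta_used = theta_used, theta_floor = floor_used, ratio = ratio,
    tau = tau, p_rm = p_rm, qualified = support_qualified,
    decision = decision, stringsAsFactors = FALSE)
  class(out) <- c("pair_test", class(out))
  out
}

# zero-row pair-test table with the right columns
.empty_pair_tests <- function() {
  data.frame(A = character(0), B = character(0), n1 = integer(0),
             n2 = integer(0), d1 = numeric(0), d2 = numeric(0),
             pi1 = numeric(0), pi2 = numeric(0), theta1 = numeric(0),
             theta2 = numeric(0), zero_d1 = logical(0), zero_d2 = logical(0),
             D = numeric(0), K = numeric(0), model = character(0),
             div_used = character(0), theta_used = numeric(0),
             theta_floor = logical(0), ratio = numeric(0), tau = numeric(0),
             p_rm = numeric(0), qualified = logical(0),
             decision = character(0), stringsAsFactors = FALSE)
}

#' Delimit species on a rooted, support-annotated tree
#'
#' Runs the tip-up traversal: well-supported sister pairs are tested in
#' order; a `single_species` verdict merges the pair into one putative
#' species whose members pool (n and d recomputed on the union) for all
#' later tests, a `distinct_species` verdict freezes both clades as
#' species, and two sister singletons are recorded `indeterminate` and
#' merged for upstream testing. Deterministic given the inputs and seed.
#'
#' @param aln a [dna_alignment()].
#' @param tree a rooted `phylo` whose leaves are a subset of `aln$ids`.
#' @param supports a [bootstrap_supports()] object or named support vector.
#' @param support_threshold,ratio_threshold,model,dk_switch,prm_reps,seed,tau_mode
#'   tuning parameters, see [pair_test()].
#' @param all_tips leaf universe used to canonicalise bipartition keys when
#'   `tree` is a subtree of the tree the supports were computed on.
#' @return a list: `pair_tests` (data.frame, one row per tested pair, in
#'   testing order), `partition` (data.frame `id`, `species`), `log`
#'   (character vector of merge/freeze actions).
#' @export
delimit <- function(aln, tree, supports, support_threshold = 70,
                    ratio_threshold = 4, model = "JC69", dk_switch = 0.05,
                    prm_reps = 10000L, seed = 1L, tau_mode = "calibration",
                    all_tips = NULL) {
  stopifnot(inherits(aln, "dna_alignment"), inherits(tree, "phylo"))
  bad <- setdiff(tree$tip.label, aln$ids)
  if (length(bad))
    stop("tree leaf/leaves missing from alignment: ",
         paste(bad, collapse = ", "))
  Dmat <- distance_matrix(
    dna_alignment(aln$seq[tree$tip.label, , drop = FALSE]),
    "uncorrected")$matrix
  sup_map <- if (inherits(supports, "ktheta_supports")) supports$supports
             else supports
  tips_universe <- if (is.null(all_tips)) tree$tip.label else all_tips
  # a side of a pair is support-qualified when the hypothesis tree itself
  # backs it as a clade at/above the support threshold: a singleton, or a
  # unit whose members exactly form a tree clade with sufficient bootstrap
  # support (trivial splits -- the whole tree, the complement of one leaf --
  # count as supported by construction). A pooled union that does not
  # complete a tree clade is a putative species, not a supported clade, and
  # can never be frozen as a distinct species.
  tree_clades <- local({
    ntip <- length(tree$tip.label)
    kids <- split(tree$edge[, 2L], tree$edge[, 1L])
    out <- new.env(parent = emptyenv())
    tips_of <- function(nd) {
      if (nd <= ntip) return(tree$tip.label[nd])
      unlist(lapply(kids[[as.character(nd)]], tips_of))
    }
    for (nd in seq.int(ntip + 1L, ntip + tree$Nnode)) {
      tips <- tips_of(nd)
      s <- if (length(tips) <= 1L ||
               length(tips) >= length(tips_universe) - 1L) 100
           else {
             v <- sup_map[.bip_key(tips, tips_universe)]
             if (is.na(v)) 0 else unname(v)
           }
      assign(paste(sort(tips), collapse = ";"), s, envir = out)
    }
    out
  })
  side_qualified <- function(ids) {
    if (length(ids) == 1L) return(TRUE)
    key <- paste(sort(ids), collapse = ";")
    if (!exists(key, envir = tree_clades, inherits = FALSE)) return(FALSE)
    get(key, envir = tree_clades, inherits = FALSE) >= support_threshold
  }
  rows <- list()
  logs <- character(0)
  k <- 0L
  on_pair <- function(u, v) {
    k <<- k + 1L
    pt <- pair_test(aln, u$ids, v$ids, model = model, dk_switch = dk_switch,
                    ratio_threshold = ratio_threshold, prm_reps = prm_reps,
                    seed = if (prm_reps > 0L) seed + k else NULL,
                    tau_mode = tau_mode,
                    support_qualified = side_qualified(u$ids) &&
                                        side_qualified(v$ids))
    rows[[k]] <<- pt
    act <- switch(pt$decision,
                  distinct_species = "freeze",
                  single_species = "merge",
                  indeterminate = "merge")
    logs <<- c(logs, sprintf(
      "pair %d: {%s} vs {%s} ratio=%s decision=%s -> %s",
      k, pt$A, pt$B,
      if (is.na(pt$ratio)) "NA" else sprintf("%.2f", pt$ratio),
      pt$decision, act))
    list(action = act)
  }
  units <- if (length(tree$tip.label) == 1L) list(.unit(tree$tip.label))
           else .walk_units(tree, supports, support_threshold, Dmat, on_pair,
                            all_tips = all_tips)
  pair_tests <- if (length(rows)) do.call(rbind, rows) else .empty_pair_tests()
  species <- character(0)
  ids <- character(0)
  for (s in seq_along(units)) {
    ids <- c(ids, units[[s]]$ids)
    species <- c(species, rep(sprintf("species_%d", s),
                              length(units[[s]]$ids)))
  }
  partition <- data.frame(id = ids, species = species,
                          stringsAsFactors = FALSE)
  partition <- partition[order(match(partition$id, aln$ids)), , drop = FALSE]
  rownames(partition) <- NULL
  list(pair_tests = pair_tests, partition = partition, log = logs)
}
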