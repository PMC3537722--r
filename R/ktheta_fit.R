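# The user-facing model fit: full pipeline from alignment to species
# partition, returned as a classed object with the usual accessor methods.

#' Delimit species from an alignment with the K/theta method
#'
#' The complete analysis in one call: pairwise distances under `model`,
#' neighbor-joining tree, nonparametric bootstrap supports, rooting
#' (outgroup if given, midpoint otherwise), and the tip-up K/theta
#' delimitation of well-supported sister clades. Sister clades with
#' `K/theta >= ratio_threshold` (default 4) are classified as distinct
#' evolutionary species; each tested pair is also annotated with the
#' coalescent probability of reciprocal monophyly for its sample sizes.
#'
#' When an outgroup is supplied it is used for rooting only: outgroup
#' sequences are excluded from the delimitation and labelled `"outgroup"`
#' in the partition.
#'
#' @param aln a [dna_alignment()] (or path to a FASTA file).
#' @param model substitution model for tree distances and the between-clade
#'   correction `K`.
#' @param B bootstrap replicates.
#' @param seed integer seed governing every stochastic stage.
#' @param support_threshold minimum bootstrap percent for a clade to be
#'   testable (default 70).
#' @param ratio_threshold the 4x-rule threshold.
#' @param dk_switch use uncorrected `D` in the ratio when `D` is below this
#'   level, corrected `K` otherwise.
#' @param outgroup optional character vector of outgroup leaf ids.
#' @param prm_reps Monte Carlo replicates per pair for the
#'   reciprocal-monophyly probability (0 skips it).
#' @param tau_mode mapping from ratio to divergence time
#'   ([tau_from_ratio()]).
#' @param trim if `TRUE`, trim the alignment to the shared window first.
#' @return an object of class `ktheta`: list with `alignment`, `tree`
#'   (rooted, with supports), `supports`, `pair_tests` (one row per tested
#'   pair), `partition` (`id`, `species`), `n_species`, `log`, `config`,
#'   `call`.
#' @seealso [summary.ktheta()], [delimit()], [pair_test()]
#' @examples
#' sim <- simulate_two_species_alignment(
#'   two_species_model(tau = 10, n1 = 6, n2 = 6, theta_site = 0.01,
#'                     L = 600, seed = 7))
#' fit <- ktheta(sim$alignment, B = 100, seed = 7, prm_reps = 1000)
#' fit$n_species
#' @export
ktheta <- function(aln, model = c("JC69", "uncorrected", "K2P", "K81"),
                   B = 1000L, seed, support_threshold = 70,
                   ratio_threshold = 4, dk_switch = 0.05, outgroup = NULL,
                   prm_reps = 100000L,
                   tau_mode = c("calibration", "ancestral_adjusted"),
                   trim = FALSE) {
  cl <- match.call()
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignment(aln)
  stopifnot(inherits(aln, "dna_alignment"))
  model <- match.arg(model)
  tau_mode <- match.arg(tau_mode)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (trim) aln <- trim_to_shared_window(aln)
  if (aln$n < 3L) stop("need at least 3 sequences to build a tree")
  sup <- bootstrap_supports(aln, model = model, B = B, seed = seed)
  rooted <- if (!is.null(outgroup)) root_on_outgroup(sup$tree, outgroup)
            else phangorn::midpoint(sup$tree)
  config <- list(model = model, B = B, seed = seed,
                 support_threshold = support_threshold,
                 ratio_threshold = ratio_threshold, dk_switch = dk_switch,
                 outgroup = outgroup, prm_reps = prm_reps,
                 tau_mode = tau_mode, trim = trim)
  if (!is.null(outgroup)) {
    ntip <- length(rooted$tip.label)
    root <- ntip + 1L
    root_kids <- rooted$edge[rooted$edge[, 1L] == root, 2L]
    is_og_side <- vapply(root_kids, function(k) {
      tips <- if (k <= ntip) rooted$tip.label[k]
              else ape::extract.clade(rooted, k)$tip.label
      all(tips %in% outgroup)
    }, logical(1L))
    in_node <- root_kids[!is_og_side]
    if (length(in_node) != 1L)
      stop("could not isolate a single ingroup clade under the root")
    if (in_node <= ntip) {
      dl <- list(pair_tests = .empty_pair_tests(),
                 partition = data.frame(id = rooted$tip.label[in_node],
                                        species = "species_1",
                                        stringsAsFactors = FALSE),
                 log = character(0))
    } else {
      sub <- ape::extract.clade(rooted, in_node)
      dl <- delimit(aln, sub, sup,
                    support_threshold = support_threshold,
                    ratio_threshold = ratio_threshold, model = model,
                    dk_switch = dk_switch, prm_reps = prm_reps,
                    seed = seed, tau_mode = tau_mode,
                    all_tips = rooted$tip.label)
    }
    og <- data.frame(id = intersect(rooted$tip.label, outgroup),
                     species = "outgroup", stringsAsFactors = FALSE)
    dl$partition <- rbind(dl$partition, og)
  } else {
    dl <- delimit(aln, rooted, sup,
                  support_threshold = support_threshold,
                  ratio_threshold = ratio_threshold, model = model,
                  dk_switch = dk_switch, prm_reps = prm_reps,
                  seed = seed, tau_mode = tau_mode)
  }
  n_species <- length(unique(setdiff(dl$partition$species, "outgroup")))
  structure(list(call = cl, alignment = aln, model = model, tree = rooted,
                 supports = sup, pair_tests = dl$pair_tests,
                 partition = dl$partition, n_species = n_species,
                 log = dl$log, config = config),
            class = "ktheta")
}

#' @export
print.ktheta <- function(x, ...) {
  cat("K/theta species delimitation\n")
  cat(sprintf("  alignment: %d sequences x %d sites; model %s; %d bootstrap replicates\n",
              x$alignment$n, x$alignment$L, x$model, x$config$B))
  cat(sprintf("  pairs tested: %d; species found: %d\n",
              nrow(x$pair_tests), x$n_species))
  invisible(x)
}

#' Summarise a K/theta fit
#'
#' Rounds the per-pair table for reporting (pi and theta to 4 decimals,
#' ratios to 1, probabilities to 2; full precision stays in the fit object)
#' and tabulates the species partition.
#'
#' @param object a [ktheta()] fit.
#' @param ... unused.
#' @return a `summary.ktheta` object.
#' @export
summary.ktheta <- function(object, ...) {
  pt <- object$pair_tests
  tab <- data.frame(
    A = pt$A, B = pt$B, n1 = pt$n1, n2 = pt$n2,
    d1 = round(pt$d1, 4), d2 = round(pt$d2, 4),
    pi1 = round(pt$pi1, 4), pi2 = round(pt$pi2, 4),
    theta1 = round(pt$theta1, 4), theta2 = round(pt$theta2, 4),
    D = round(pt$D, 4), K = round(pt$K, 4), used = pt$div_used,
    ratio = round(pt$ratio, 1), p_rm = round(pt$p_rm, 2),
    decision = pt$decision, stringsAsFactors = FALSE)
  structure(list(pairs = tab,
                 partition = object$partition,
                 n_species = object$n_species,
                 model = object$model, B = object$config$B,
                 support_threshold = object$config$support_threshold,
                 ratio_threshold = object$config$ratio_threshold),
            class = "summary.ktheta")
}

#' @export
print.summary.ktheta <- function(x, ...) {
  cat(sprintf("K/theta delimitation: %d species (model %s, %d bootstraps, support >= %g%%, ratio >= %g)\n\n",
              x$n_species, x$model, x$B, x$support_threshold,
              x$ratio_threshold))
  if (nrow(x$pairs)) {
    cat("Tested sister-clade pairs:\n")
    print(x$pairs, row.names = FALSE)
  } else {
    cat("No sister-clade pair qualified for testing.\n")
  }
  cat("\nSpecies assignment:\n")
  print(table(x$partition$species))
  invisible(x)
}

#' @export
coef.ktheta <- function(object, ...) {
  pt <- object$pair_tests
  if (!nrow(pt)) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(pt$ratio, paste0("{", pt$A, "} vs {", pt$B, "}"))
}

#' Plot a K/theta fit
#'
#' Draws the rooted tree with bootstrap supports on the internal nodes and
#' tips coloured by assigned species.
#'
#' @param x a [ktheta()] fit.
#' @param show_support draw bootstrap percentages at internal nodes.
#' @param cex tip label size.
#' @param ... passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.ktheta <- function(x, show_support = TRUE, cex = 0.8, ...) {
  sp <- x$partition$species[match(x$tree$tip.label, x$partition$id)]
  cols <- stats::setNames(
    grDevices::hcl.colors(max(2L, length(unique(sp))), "Dark 3"),
    unique(sp))
  ape::plot.phylo(x$tree, tip.color = cols[sp], cex = cex, ...)
  if (show_support) {
    tl <- x$tree$tip.label
    ntip <- length(tl)
    labs <- vapply(seq_len(x$tree$Nnode), function(i) {
      nd <- ntip + i
      tips <- ape::extract.clade(x$tree, nd)$tip.label
      if (length(tips) <= 1L || length(tips) >= ntip - 1L) return("")
      key <- .bip_key(tips, tl)
      v <- x$supports$supports[key]
      if (is.na(v)) "" else sprintf("%.0f", v)
    }, character(1L))
    ape::nodelabels(labs, frame = "none", adj = c(1.2, -0.3), cex = 0.7)
  }
  invisible(x)
}

#' Simulate alignments from a fitted pair
#'
#' Parametric simulation: takes one tested sister-clade pair from the fit
#' and generates alignments under the two-species coalescent at the
#' divergence time implied by its ratio, with the pair's theta and sample
#' sizes.
#'
#' @param object a [ktheta()] fit with at least one tested pair.
#' @param nsim number of alignments.
#' @param seed integer seed.
#' @param pair row index into `object$pair_tests`.
#' @param ... unused.
#' @return list of [simulate_two_species_alignment()] results.
#' @export
simulate.ktheta <- function(object, nsim = 1, seed = NULL, pair = 1L, ...) {
  pt <- object$pair_tests
  if (!nrow(pt)) stop("fit has no tested pair to simulate from")
  if (pair < 1L || pair > nrow(pt)) stop("no such pair: ", pair)
  row <- pt[pair, ]
  if (is.na(row$tau)) stop("pair ", pair, " has no defined ratio/tau")
  theta <- if (is.na(row$theta_used)) 1 / object$alignment$L else row$theta_used
  lapply(seq_len(nsim), function(i) {
    simulate_two_species_alignment(two_species_model(
      tau = row$tau, n1 = row$n1, n2 = row$n2, theta_site = theta,
      L = object$alignment$L,
      seed = if (is.null(seed)) NULL else seed + i - 1L))
  })
}
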