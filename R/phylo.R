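# Neighbor-joining trees, bootstrap supports, rooting, and extraction of
# well-supported sister-clade pairs in tip-up testing order.

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the canonical neighbor-joining tree (Q-criterion agglomeration via
#' [ape::nj()]). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with the deficit transferred to
#' the sibling branch; the number of clamped edges is recorded in attribute
#' `"clamped_edges"`. On an additive matrix the tree reproduces all
#' leaf-to-leaf path lengths exactly.
#'
#' @param d a [distance_matrix()] result, a symmetric numeric matrix, or a
#'   `dist` object; at least 3 taxa.
#' @return an unrooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "ktheta_dist")) d$matrix else as.matrix(d)
  n <- nrow(m)
  if (n < 3L) stop("neighbor-joining needs at least 3 sequences")
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (anyNA(m))
    stop("distance matrix contains NA entries (saturated pairs?); ",
         "neighbor-joining needs complete distances")
  phy <- ape::nj(m)
  .clamp_negative_edges(phy)
}

# negative NJ branches: set to 0, add the deficit to a sibling branch at the
# same node so local path lengths are approximately preserved (standard
# practice); residual negatives after transfer are zeroed
.clamp_negative_edges <- function(phy) {
  neg <- which(phy$edge.length < 0)
  if (!length(neg)) {
    attr(phy, "clamped_edges") <- 0L
    return(phy)
  }
  for (e in neg) {
    deficit <- -phy$edge.length[e]
    phy$edge.length[e] <- 0
    sib <- setdiff(which(phy$edge[, 1L] == phy$edge[e, 1L]), e)
    if (length(sib))
      phy$edge.length[sib[1L]] <- phy$edge.length[sib[1L]] + deficit
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped_edges") <- length(neg)
  phy
}

#' Root a tree on an outgroup
#'
#' @param phy a `phylo` tree.
#' @param outgroup character vector of outgroup leaf labels; must be present
#'   and monophyletic when detached from the tree.
#' @return a rooted `phylo` tree with the outgroup sister to the ingroup.
#'   Rooting is idempotent: rooting an already-rooted tree on the same
#'   outgroup returns the same tree.
#' @export
root_on_outgroup <- function(phy, outgroup) {
  stopifnot(inherits(phy, "phylo"))
  outgroup <- as.character(outgroup)
  missing <- setdiff(outgroup, phy$tip.label)
  if (length(missing))
    stop("outgroup leaf/leaves not in tree: ", paste(missing, collapse = ", "))
  if (setequal(outgroup, phy$tip.label))
    stop("outgroup cannot contain every leaf")
  phy <- ape::unroot(phy)
  if (length(outgroup) > 1L && !ape::is.monophyletic(phy, outgroup)) {
    ing <- setdiff(phy$tip.label, outgroup)[1L]
    rt <- ape::root(phy, outgroup = ing, resolve.root = TRUE)
    mrca <- ape::getMRCA(rt, outgroup)
    clade <- ape::extract.clade(rt, mrca)$tip.label
    stop("outgroup is not monophyletic; its smallest containing clade also ",
         "holds: ", paste(setdiff(clade, outgroup), collapse = ", "))
  }
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

# canonical key for the bipartition separating `tips` from the rest:
# the side not containing the alphabetically first leaf, sorted and joined
.bip_key <- function(tips, all_tips) {
  ref <- sort(all_tips)[1L]
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = ";")
}

#' Nonparametric bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree from each resampled alignment under the same substitution model, and
#' tallies, for every internal bipartition of the point-estimate tree, the
#' percentage of replicates containing it. Deterministic given `seed`.
#'
#' @param aln a [dna_alignment()].
#' @param model substitution model for the distances.
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @return a `ktheta_supports` object: `tree` (the unrooted point-estimate
#'   NJ tree), `supports` (named numeric vector, percent, keyed by canonical
#'   bipartition), `B`, `model`, `seed`.
#' @export
bootstrap_supports <- function(aln, model = "JC69", B = 1000L, seed) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (B < 1L) stop("B must be >= 1")
  enc <- .encode_alignment(aln)
  point <- nj_tree(.pairwise_dist_enc(enc, model, ids = aln$ids))
  boots <- with_seed(seed, lapply(seq_len(B), function(b) {
    cols <- sample.int(aln$L, aln$L, replace = TRUE)
    .clamp_negative_edges(
      ape::nj(.pairwise_dist_enc(enc[, cols, drop = FALSE], model,
                                 ids = aln$ids)))
  }))
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  parts <- ape::prop.part(point)
  labels <- attr(parts, "labels")
  ntip <- length(labels)
  keys <- character(0)
  pct <- numeric(0)
  for (k in seq_along(parts)) {
    tips <- labels[parts[[k]]]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next  # trivial
    keys <- c(keys, .bip_key(tips, labels))
    pct <- c(pct, 100 * counts[k] / B)
  }
  structure(list(tree = point, supports = stats::setNames(pct, keys),
                 B = B, model = model, seed = seed),
            class = "ktheta_supports")
}

#' @export
print.ktheta_supports <- function(x, ...) {
  cat("bootstrap supports:", x$B, "replicates, model", x$model, "\n")
  cat("  ", length(x$supports), "internal bipartition(s); support range ",
      if (length(x$supports)) paste(range(x$supports), collapse = "-") else "-",
      "%\n", sep = "")
  invisible(x)
}

# ---- tip-up traversal engine -------------------------------------------
#
# Walks a rooted tree tips-first, emitting pairs of testable units.
# Internal edges below the support threshold are collapsed; a subtree that
# contains no supported internal structure at all is one pooled unit (its
# leaves are an unresolved sample, never tested against each other -- the
# way a large clade with unsupported internal branches is treated as a
# single clade in practice). Where supported structure exists, the
# effective members of a node are its tips, its supported child clades,
# and pooled units for unsupported regions; the two members with the
# smallest mean between-group uncorrected distance are compared first and
# each later member is paired against whichever existing unit (or merged
# union) is nearest -- the resolution of the ladder rule "compare A and B
# first, then compare C to the nearer".
#
# `on_pair(u, v)` is called for every emitted pair of units (a unit is a
# list with `ids` and `frozen`); it must return list(action = "merge") or
# list(action = "freeze").

.unit <- function(ids) list(ids = ids, frozen = FALSE)

.walk_units <- function(tree, supports, threshold, Dmat, on_pair,
                        all_tips = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tl <- tree$tip.label
  ntip <- length(tl)
  if (is.null(all_tips)) all_tips <- tl
  sup_map <- if (inherits(supports, "ktheta_supports")) supports$supports
             else supports
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  # descendant tip labels per node (recursive, order-agnostic)
  node_tips <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) node_tips[[i]] <- tl[i]
  fill_tips <- function(nd) {
    if (nd <= ntip) return(node_tips[[nd]])
    val <- unlist(lapply(kids[[as.character(nd)]], fill_tips))
    node_tips[[nd]] <<- val
    val
  }
  fill_tips(ntip + 1L)
  supp_of <- function(nd) {
    tips <- node_tips[[nd]]
    if (length(tips) <= 1L || length(tips) >= length(all_tips) - 1L)
      return(100)
    key <- .bip_key(tips, all_tips)
    if (key %in% names(sup_map)) unname(sup_map[[key]]) else 0
  }
  is_supported <- function(nd) nd > ntip && supp_of(nd) >= threshold
  # does any internal node strictly below nd pass the support threshold?
  has_structure <- local({
    memo <- rep(NA, ntip + tree$Nnode)
    function(nd) {
      if (nd <= ntip) return(FALSE)
      if (!is.na(memo[nd])) return(memo[nd])
      res <- FALSE
      for (k in kids[[as.character(nd)]]) {
        if (k > ntip && (is_supported(k) || Recall(k))) {
          res <- TRUE
          break
        }
      }
      memo[nd] <<- res
      res
    }
  })
  # effective members of nd's (possibly collapsed) polytomy: tips,
  # supported child clades, recursively spliced unsupported children that
  # contain structure, and pooled units for structureless regions
  members <- function(nd) {
    out <- list()
    for (k in kids[[as.character(nd)]]) {
      if (k <= ntip || is_supported(k)) {
        out <- c(out, list(k))
      } else if (has_structure(k)) {
        out <- c(out, members(k))
      } else {
        out <- c(out, list(node_tips[[k]]))   # pooled unresolved region
      }
    }
    out
  }
  group_ids <- function(g) unlist(lapply(g, `[[`, "ids"))
  nearest_unit <- function(g, other_ids) {
    if (length(g) == 1L) return(1L)
    dd <- vapply(g, function(u) mean(Dmat[u$ids, other_ids]), numeric(1L))
    which.min(dd)
  }
  # successive nearest-pair contests among groups of units; every contest
  # emits one pair through on_pair and unifies the two groups
  contest <- function(groups) {
    while (length(groups) > 1L) {
      gids <- lapply(groups, group_ids)
      best <- c(1L, 2L)
      bestd <- Inf
      for (i in seq_len(length(groups) - 1L)) {
        for (j in seq.int(i + 1L, length(groups))) {
          dd <- mean(Dmat[gids[[i]], gids[[j]]])
          if (dd < bestd) {
            bestd <- dd
            best <- c(i, j)
          }
        }
      }
      i <- best[1L]
      j <- best[2L]
      ui <- nearest_unit(groups[[i]], gids[[j]])
      vj <- nearest_unit(groups[[j]], gids[[i]])
      u <- groups[[i]][[ui]]
      v <- groups[[j]][[vj]]
      res <- on_pair(u, v)
      gi <- groups[[i]]
      gj <- groups[[j]]
      if (identical(res$action, "merge")) {
        merged <- list(ids = c(u$ids, v$ids), frozen = u$frozen || v$frozen)
        gi <- gi[-ui]
        gj <- gj[-vj]
        newgrp <- c(gi, gj, list(merged))
      } else if (identical(res$action, "freeze")) {
        gi[[ui]]$frozen <- TRUE
        gj[[vj]]$frozen <- TRUE
        newgrp <- c(gi, gj)
      } else stop("on_pair must return action 'merge' or 'freeze'")
      groups <- c(groups[-c(i, j)], list(newgrp))
    }
    groups[[1L]]
  }
  process <- function(nd) {
    if (nd <= ntip) return(list(.unit(tl[nd])))
    contest(lapply(members(nd), function(m) {
      if (is.character(m)) list(.unit(m)) else process(m)
    }))
  }
  process(ntip + 1L)
}

#' Well-supported sister-clade pairs in tip-up testing order
#'
#' Collapses internal edges whose bootstrap support is below `threshold`
#' (default 70%), then emits the remaining sister-clade pairs starting at
#' the tips of the tree. At a polytomy or ladder the closest two groups (by
#' mean between-group uncorrected distance) are compared first; each
#' further clade is then paired with whichever already-compared unit -- or
#' their union -- lies nearest to it.
#'
#' @param tree a rooted `phylo` tree.
#' @param supports a [bootstrap_supports()] object, or a named numeric
#'   vector of support percents keyed by canonical bipartition.
#' @param threshold minimum support percent for an edge to be retained.
#' @param dm an uncorrected [distance_matrix()] (or plain matrix) over the
#'   same leaves, used to resolve polytomy ordering.
#' @return a list of pairs; each element is `list(A = , B = )` of leaf-id
#'   vectors, in testing order. Empty list when no internal edge survives.
#' @export
supported_sister_pairs <- function(tree, supports, threshold = 70, dm) {
  if (inherits(supports, "ktheta_supports") &&
      !setequal(supports$tree$tip.label, tree$tip.label))
    stop("supports were computed on a different leaf set")
  Dmat <- if (inherits(dm, "ktheta_dist")) dm$matrix else as.matrix(dm)
  pairs <- list()
  on_pair <- function(u, v) {
    pairs[[length(pairs) + 1L]] <<- list(A = u$ids, B = v$ids)
    list(action = "merge")
  }
  .walk_units(tree, supports, threshold, Dmat, on_pair)
  pairs
}
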