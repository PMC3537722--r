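# Pairwise divergence: site-pattern counting and multiple-hit corrections.

.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)

# encode an alignment as an integer matrix: A=1 C=2 G=3 T=4, everything else
# (gaps, N, ambiguity codes) NA -> excluded pairwise from comparisons
.encode_alignment <- function(aln) {
  e <- .base_code[aln$seq]
  dim(e) <- dim(aln$seq)
  rownames(e) <- aln$ids
  e
}

.as_residues <- function(x) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  toupper(x)
}

# core tally on encoded rows; `who` names the pair for error messages
.site_counts_enc <- function(ea, eb, who = NULL) {
  ok <- !is.na(ea) & !is.na(eb)
  m <- sum(ok)
  if (m == 0L)
    stop("no comparable sites",
         if (!is.null(who)) paste0(" between ", who[1L], " and ", who[2L]))
  da <- ea[ok]
  db <- eb[ok]
  diff <- da != db
  s <- da[diff] + db[diff]
  # differing pairs by code sum: 3={A,C} 4={A,G} 5={A,T},{C,G} 6={C,T} 7={G,T}
  nP <- sum(s == 4L | s == 6L)          # transitions
  nQ1 <- sum(s == 5L)                   # A<->T, G<->C
  nQ2 <- sum(s == 3L | s == 7L)         # A<->C, G<->T
  structure(list(m = m, n_diff = sum(diff), p = sum(diff) / m,
                 P = nP / m, Q1 = nQ1 / m, Q2 = nQ2 / m),
            class = "site_counts")
}

#' Tally site patterns between two aligned sequences
#'
#' Compares two equal-length sequences site by site under pairwise deletion:
#' any site where either residue is not an unambiguous base (`A`,`C`,`G`,`T`)
#' is excluded from the comparison. Differences are partitioned into
#' transitions (`P`: A-G, C-T) and the two transversion classes used by the
#' Kimura three-substitution-type model (`Q1`: A-T, G-C; `Q2`: A-C, G-T).
#'
#' @param a,b sequences as character vectors of residues or single strings.
#' @return a `site_counts` object: `m` compared sites, `n_diff` differing
#'   sites, and the proportions `p = n_diff/m`, `P`, `Q1`, `Q2`
#'   (with `P + Q1 + Q2 = p`).
#' @examples
#' site_pattern_counts("ACGT", "ACGA")  # one A-T transversion
#' @export
site_pattern_counts <- function(a, b) {
  a <- .as_residues(a)
  b <- .as_residues(b)
  if (length(a) != length(b))
    stop("sequences have different lengths (", length(a), " vs ", length(b), ")")
  .site_counts_enc(.base_code[a], .base_code[b])
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site counts: m=%d differing=%d p=%.6g (P=%.6g Q1=%.6g Q2=%.6g)\n",
              x$m, x$n_diff, x$p, x$P, x$Q1, x$Q2))
  invisible(x)
}

#' Correct a pairwise distance for multiple hits
#'
#' Converts observed difference proportions into an evolutionary distance in
#' substitutions per site under one of four models:
#' \describe{
#'   \item{uncorrected}{`d = p`}
#'   \item{JC69}{`d = -(3/4) log(1 - 4p/3)`}
#'   \item{K2P}{`d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` with
#'     `Q = Q1 + Q2`}
#'   \item{K81}{`d = -(1/4) [log(1 - 2P - 2Q1) + log(1 - 2P - 2Q2) +
#'     log(1 - 2Q1 - 2Q2)]`}
#' }
#' A pair is *saturated* when any logarithm argument is non-positive; the
#' returned value is then `NA` with attribute `saturated = TRUE` so callers
#' can flag rather than silently drop such pairs.
#'
#' @param counts a [site_pattern_counts()] result, or any list with the
#'   components the chosen model needs (`p` for JC69, `P`/`Q1`/`Q2` for
#'   K2P/K81).
#' @param model one of `"uncorrected"`, `"JC69"`, `"K2P"`, `"K81"`.
#' @return distance in substitutions per site.
#' @examples
#' correct_distance(list(p = 0.1), "JC69")            # 0.107326
#' correct_distance(list(P = 0.1, Q1 = 0.05, Q2 = 0), "K2P")
#' @export
correct_distance <- function(counts,
                             model = c("uncorrected", "JC69", "K2P", "K81")) {
  model <- match.arg(model)
  P <- counts$P
  Q1 <- counts$Q1
  Q2 <- counts$Q2
  p <- counts$p
  if (is.null(p) && !is.null(P)) p <- P + Q1 + Q2
  sat <- function() structure(NA_real_, saturated = TRUE)
  switch(model,
    uncorrected = {
      if (is.null(p)) stop("'counts' must supply p")
      p
    },
    JC69 = {
      if (is.null(p)) stop("'counts' must supply p")
      a <- 1 - 4 * p / 3
      if (a <= 0) return(sat())
      -0.75 * log(a)
    },
    K2P = {
      if (is.null(P) || is.null(Q1)) stop("'counts' must supply P, Q1, Q2")
      Q <- Q1 + Q2
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      if (a1 <= 0 || a2 <= 0) return(sat())
      -0.5 * log(a1) - 0.25 * log(a2)
    },
    K81 = {
      if (is.null(P) || is.null(Q1) || is.null(Q2))
        stop("'counts' must supply P, Q1, Q2")
      a1 <- 1 - 2 * P - 2 * Q1
      a2 <- 1 - 2 * P - 2 * Q2
      a3 <- 1 - 2 * Q1 - 2 * Q2
      if (a1 <= 0 || a2 <= 0 || a3 <= 0) return(sat())
      -0.25 * (log(a1) + log(a2) + log(a3))
    })
}

# distance matrix on an encoded alignment, vectorised as base-indicator
# matrix products (this sits inside the bootstrap inner loop)
.pairwise_dist_enc <- function(enc, model, allow_saturated = FALSE,
                               ids = rownames(enc)) {
  n <- nrow(enc)
  valid <- !is.na(enc)
  storage.mode(valid) <- "double"
  m <- tcrossprod(valid)                      # compared sites per pair
  X <- lapply(1:4, function(b) {
    xb <- !is.na(enc) & enc == b
    storage.mode(xb) <- "double"
    xb
  })
  off <- row(m) != col(m)
  if (any(m[off] == 0)) {
    w <- which(m == 0 & off, arr.ind = TRUE)[1L, ]
    stop("no comparable sites between ", ids[w[1L]], " and ", ids[w[2L]])
  }
  same <- tcrossprod(X[[1L]]) + tcrossprod(X[[2L]]) +
          tcrossprod(X[[3L]]) + tcrossprod(X[[4L]])
  cross <- function(i, j) X[[i]] %*% t(X[[j]]) + X[[j]] %*% t(X[[i]])
  p <- (m - same) / m
  D <- switch(model,
    uncorrected = p,
    JC69 = {
      a <- 1 - 4 * p / 3
      ifelse(a > 0, -0.75 * log(pmax(a, 1e-300)), NA_real_)
    },
    K2P = {
      P <- cross(1L, 3L) / m + cross(2L, 4L) / m
      Q <- p - P
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      ifelse(a1 > 0 & a2 > 0,
             -0.5 * log(pmax(a1, 1e-300)) - 0.25 * log(pmax(a2, 1e-300)),
             NA_real_)
    },
    K81 = {
      P <- cross(1L, 3L) / m + cross(2L, 4L) / m
      Q1 <- cross(1L, 4L) / m + cross(2L, 3L) / m
      Q2 <- p - P - Q1
      a1 <- 1 - 2 * P - 2 * Q1
      a2 <- 1 - 2 * P - 2 * Q2
      a3 <- 1 - 2 * Q1 - 2 * Q2
      ifelse(a1 > 0 & a2 > 0 & a3 > 0,
             -0.25 * (log(pmax(a1, 1e-300)) + log(pmax(a2, 1e-300)) +
                      log(pmax(a3, 1e-300))),
             NA_real_)
    },
    stop("unknown model: ", model))
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  sat <- is.na(D)
  diag(sat) <- FALSE
  if (any(sat) && !allow_saturated) {
    w <- which(sat, arr.ind = TRUE)[1L, ]
    stop("saturated pair under ", model, ": ", ids[w[1L]], " - ", ids[w[2L]],
         " (set allow_saturated = TRUE to flag instead)")
  }
  attr(D, "saturated") <- sat
  D
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln a [dna_alignment()] with at least two sequences.
#' @param model substitution model passed to [correct_distance()].
#' @param allow_saturated if `FALSE` (default) a saturated pair is an error;
#'   if `TRUE` saturated entries are `NA` and flagged in the `saturated`
#'   matrix.
#' @return a `ktheta_dist` object: `matrix` (symmetric, zero diagonal),
#'   `model`, `labels`, and logical `saturated` matrix.
#' @export
distance_matrix <- function(aln, model = c("uncorrected", "JC69", "K2P", "K81"),
                            allow_saturated = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  model <- match.arg(model)
  if (aln$n < 2L) stop("need at least 2 sequences for a distance matrix")
  enc <- .encode_alignment(aln)
  D <- .pairwise_dist_enc(enc, model, allow_saturated, ids = aln$ids)
  structure(list(matrix = D[, , drop = FALSE], model = model,
                 labels = aln$ids, saturated = attr(D, "saturated")),
            class = "ktheta_dist")
}

#' @export
print.ktheta_dist <- function(x, ...) {
  cat("pairwise distances (", x$model, "), ", length(x$labels),
      " sequences\n", sep = "")
  if (any(x$saturated)) cat("  [", sum(x$saturated) / 2, " saturated pair(s) ]\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' @export
as.matrix.ktheta_dist <- function(x, ...) {
  m <- x$matrix
  attr(m, "saturated") <- NULL
  m
}

#' Export a distance matrix as a spreadsheet-friendly lower triangle
#'
#' Writes a tab-separated lower-triangular table with a header row of
#' sequence ids.
#'
#' @param x a [distance_matrix()] result.
#' @param file output path.
#' @param digits decimal places.
#' @return `file`, invisibly.
#' @export
write_distance_tsv <- function(x, file, digits = 6L) {
  stopifnot(inherits(x, "ktheta_dist"))
  m <- x$matrix
  n <- nrow(m)
  lines <- paste(c("", x$labels), collapse = "\t")
  for (i in seq_len(n)) {
    vals <- if (i > 1L) sprintf(paste0("%.", digits, "f"), m[i, seq_len(i - 1L)])
            else character(0)
    lines <- c(lines, paste(c(x$labels[i], vals), collapse = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}
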