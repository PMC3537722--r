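# Alignment container and FASTA input/output.

# residues accepted in an alignment: bases, IUPAC ambiguity codes, gap/missing
.dna_alphabet <- c("A", "C", "G", "T", "U",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
                   "-", "?", ".")

#' DNA alignment object
#'
#' A rectangular DNA alignment: `n` sequences by `L` sites, stored as an
#' uppercase character matrix with one residue per cell. Sequence ids must
#' be unique; descriptions (the FASTA header after the first whitespace)
#' are retained for reports but ignored for identity.
#'
#' @param seqs character matrix (one residue per cell) or character vector
#'   of equal-length sequence strings.
#' @param ids unique sequence identifiers; defaults to row/element names.
#' @param desc optional named character vector of descriptions.
#' @return an object of class `dna_alignment` with elements `seq` (character
#'   matrix), `ids`, `desc`, `n`, `L`.
#' @examples
#' aln <- dna_alignment(c(a = "ACGTACGT", b = "ACGAACGT", c = "acgtacga"))
#' aln$n; aln$L
#' @export
dna_alignment <- function(seqs, ids = NULL, desc = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(ids)) ids <- names(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
      ref <- lens[1L]
      bad <- ids[lens != ref]
      stop("alignment is ragged: sequence(s) ", paste(bad, collapse = ", "),
           " differ in length from '", ids[1L], "' (", ref, " sites)")
    }
    seqs <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                   nrow = length(seqs), byrow = TRUE)
  }
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("'seqs' must be a character matrix or a vector of sequence strings")
  if (is.null(ids)) ids <- rownames(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  n <- nrow(seqs)
  L <- ncol(seqs)
  if (n < 1L || L < 1L)
    stop("an alignment needs at least one sequence and one site")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(seqs)
  bad <- setdiff(unique(as.vector(seqs)), .dna_alphabet)
  if (length(bad))
    stop("invalid residue(s) in alignment: ", paste(bad, collapse = ", "))
  rownames(seqs) <- ids
  structure(list(seq = seqs, ids = as.character(ids), desc = desc, n = n, L = L),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", x$n, "sequence(s) x", x$L, "sites\n")
  show <- utils::head(x$ids, 6L)
  cat("  ids:", paste(show, collapse = ", "),
      if (x$n > 6L) paste0("... (", x$n - 6L, " more)") else "", "\n")
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads aligned DNA sequences from a FASTA file (arbitrary line wrapping).
#' All records must have the same length; residues are stored uppercase.
#' The identifier is the header up to the first whitespace; the remainder is
#' kept as a description.
#'
#' @param file path to a FASTA file.
#' @param format input format; only `"fasta"` is supported.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(file, format = "fasta") {
  format <- match.arg(format)
  if (!file.exists(file))
    stop("cannot read alignment: no such file: ", file)
  recs <- suppressWarnings(ape::read.FASTA(file))
  if (is.null(recs) || length(recs) == 0L)
    stop("no FASTA records found in ", file)
  headers <- names(recs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  names(desc) <- ids
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    ref <- lens[1L]
    bad <- ids[lens != ref]
    stop("ragged alignment: sequence(s) ", paste(bad, collapse = ", "),
         " (length ", paste(unique(lens[lens != ref]), collapse = "/"),
         ") differ from '", ids[1L], "' (", ref, " sites)")
  }
  chs <- as.character(recs)
  m <- matrix(toupper(unlist(chs, use.names = FALSE)),
              nrow = length(recs), byrow = TRUE)
  dna_alignment(m, ids = ids, desc = desc)
}

#' Write an alignment to FASTA
#'
#' @param x a [dna_alignment()].
#' @param file output path.
#' @param width line-wrap width for sequence lines.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(x, file, width = 70L) {
  stopifnot(inherits(x, "dna_alignment"))
  hdr <- x$ids
  if (!is.null(x$desc)) {
    d <- x$desc[x$ids]
    hdr <- ifelse(is.na(d) | d == "", x$ids, paste(x$ids, d))
  }
  out <- character(0)
  starts <- seq(1L, x$L, by = width)
  for (i in seq_len(x$n)) {
    s <- paste(x$seq[i, ], collapse = "")
    out <- c(out, paste0(">", hdr[i]),
             substring(s, starts, pmin(starts + width - 1L, x$L)))
  }
  writeLines(out, file)
  invisible(file)
}

#' Trim sequences to the window of sites shared by every record
#'
#' Finds the maximal contiguous column window covered (non-gap, non-missing)
#' by every sequence and drops the flanks. Coverage is delimited by the
#' first and last resolved residue of each record, so isolated internal
#' missing bases (stored as `N`) are retained, not trimmed. This mirrors the
#' common situation of sequences of unequal read lengths aligned to a shared
#' coordinate system.
#'
#' @param x a [dna_alignment()] (flanks padded with `-`/`N`/`?`), or a
#'   character vector of possibly ragged sequences together with `starts`.
#' @param starts optional 1-based start offset of each ragged record on the
#'   common coordinate system (default: all records start at column 1, in
#'   which case they must already be equal length).
#' @return the trimmed [dna_alignment()]; attribute `"trim"` records the
#'   retained window (1-based inclusive, in original coordinates) and the
#'   number of columns dropped on each side.
#' @examples
#' recs <- c(a = strrep("A", 300), b = strrep("C", 258))
#' tr <- trim_to_shared_window(recs, starts = c(1, 43))
#' tr$L                 # 258
#' attr(tr, "trim")
#' @export
trim_to_shared_window <- function(x, starts = NULL) {
  if (!inherits(x, "dna_alignment")) {
    s <- as.character(x)
    ids <- names(s)
    if (is.null(ids)) ids <- paste0("seq", seq_along(s))
    if (is.null(starts)) starts <- rep(1L, length(s))
    stopifnot(length(starts) == length(s), all(starts >= 1L))
    width <- max(starts + nchar(s) - 1L)
    padded <- vapply(seq_along(s), function(i) {
      paste0(strrep("-", starts[i] - 1L), s[i],
             strrep("-", width - (starts[i] - 1L) - nchar(s[i])))
    }, character(1L))
    names(padded) <- ids
    x <- dna_alignment(padded, ids = ids)
  }
  miss <- c("-", "N", "?", ".")
  orig_L <- x$L
  off_left <- 0L
  repeat {
    covered <- matrix(!(x$seq %in% miss), nrow = x$n)
    firsts <- integer(x$n)
    lasts <- integer(x$n)
    for (i in seq_len(x$n)) {
      w <- which(covered[i, ])
      if (!length(w))
        stop("no shared window: sequence '", x$ids[i], "' has no resolved sites")
      firsts[i] <- w[1L]
      lasts[i] <- w[length(w)]
    }
    ws <- max(firsts)
    we <- min(lasts)
    if (ws > we)
      stop("no shared window: sequences cover disjoint column ranges")
    if (ws == 1L && we == x$L) break
    off_left <- off_left + ws - 1L
    x <- dna_alignment(x$seq[, ws:we, drop = FALSE], ids = x$ids, desc = x$desc)
  }
  attr(x, "trim") <- list(start = off_left + 1L,
                          end = off_left + x$L,
                          dropped_left = off_left,
                          dropped_right = orig_L - (off_left + x$L))
  x
}
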