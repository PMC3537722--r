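# Shared fixtures: everything is generated in code at test time.

# write a FASTA file into the session temp dir and return its path
tmp_fasta <- function(lines, name = "aln.fasta") {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# rooted two-clade hypothesis tree over the generator's tip ids
fixture_tree <- function(n1, n2) {
  a <- paste(sprintf("sp1_%02d", seq_len(n1)), collapse = ",")
  b <- paste(sprintf("sp2_%02d", seq_len(n2)), collapse = ",")
  ape::read.tree(text = sprintf("((%s),(%s));", a, b))
}

sp1_ids <- function(n) sprintf("sp1_%02d", seq_len(n))
sp2_ids <- function(n) sprintf("sp2_%02d", seq_len(n))

# named support vector for explicit clades
support_map <- function(clades, all_tips, support = 100) {
  stats::setNames(rep(support, length.out = length(clades)),
                  vapply(clades, ktheta:::.bip_key, "", all_tips = all_tips))
}

# random additive distance matrix from a random tree; returns both
random_additive_case <- function(ntaxa, seed) {
  withr::local_seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.05, 1))
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

# small alignment with two obvious blocks separated at 40% of sites
two_block_alignment <- function(n_per_block = 4, L = 100, frac = 0.4) {
  base <- rep("A", L)
  other <- base
  other[seq_len(ceiling(frac * L))] <- "T"
  seqs <- c(replicate(n_per_block, paste(base, collapse = ""), simplify = TRUE),
            replicate(n_per_block, paste(other, collapse = ""), simplify = TRUE))
  names(seqs) <- c(paste0("a", seq_len(n_per_block)),
                   paste0("b", seq_len(n_per_block)))
  dna_alignment(seqs)
}
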