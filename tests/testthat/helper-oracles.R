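# Independent oracles used across the suite.

rnd_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.sw_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                    baseOnly = TRUE)

# Exhaustive Smith-Waterman best score over both query orientations
# (Biostrings dynamic programming; linear gap -2 per column).
sw_best_score <- function(q, s, mat = .sw_mat) {
  fwd <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  rev <- Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(q)),
    Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  max(Biostrings::score(fwd), Biostrings::score(rev))
}

# Unbanded global alignment identity (matches / all columns, gaps included)
# computed from a Biostrings end-to-end alignment.
global_identity_oracle <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .sw_mat, gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(pa == ps & pa != "-") / length(pa)
}

# Brute-force LCA: intersect full root paths, return the deepest member.
lca_bruteforce <- function(taxids, tax) {
  paths <- lapply(taxids, root_path_oracle, tax = tax)
  common <- Reduce(intersect, paths)
  common[which.max(vapply(common, function(t)
    length(root_path_oracle(t, tax)), numeric(1)))]
}

root_path_oracle <- function(taxid, tax) {
  parent <- setNames(tax$nodes$parent_taxid, tax$nodes$taxid)
  path <- taxid
  while (taxid != tax$root) {
    taxid <- parent[[as.character(taxid)]]
    path <- c(path, taxid)
  }
  path
}

# Random rooted taxonomy: node i's parent is drawn among nodes 1..i-1.
random_taxonomy <- function(n) {
  parents <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  taxonomy(data.frame(taxid = seq_len(n), parent_taxid = parents,
                      rank = "no rank", name = paste0("node", seq_len(n)),
                      stringsAsFactors = FALSE))
}

# A read record with an explicit per-base quality vector.
record_with_quals <- function(id, variant, seq, phreds) {
  stopifnot(nchar(seq) == length(phreds))
  structure(list(molecule_id = id, variant = variant, sequence = seq,
                 qual = intToUtf8(phreds + 33L), file_of_origin = NA_character_),
            class = "read_record")
}

fastq_lines <- function(id, seq, qual = strrep("I", nchar(seq))) {
  c(paste0("@", id), seq, "+", qual)
}
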