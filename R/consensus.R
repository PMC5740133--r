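#' Unique per-read species counts with phage precedence
#'
#' Each read is counted exactly once against the organism reference set.
#' If a read's best hits include the phage reference with a bit score at
#' least equal to its best bacterial bit score, it counts as phage (the
#' phage genome is integrated in the bacterial chromosome, so reads from
#' that region hit both; precedence resolves the ambiguity). Otherwise
#' the single best organism by bit score wins; ties between non-phage
#' organisms break lexicographically; reads with no qualifying hit are
#' unassigned.
#'
#' @param best_hits data frame with one row per (read, organism) best
#'   hit: columns `read_id`, `organism`, `bit_score`.
#' @param read_ids ids of all reads considered (supplies the unassigned
#'   count for reads absent from `best_hits`).
#' @param phage_label,bacterium_label organism labels the precedence
#'   rule applies to.
#' @return A `proportion_report`: data frame of per-organism counts and
#'   proportions (over counted organisms), with attributes `unassigned`
#'   and `total`.
#' @export
unique_species_counts <- function(best_hits, read_ids,
                                  phage_label = "phage",
                                  bacterium_label = "bacterium") {
  assign_one <- function(h) {
    if (nrow(h) == 0L) return(NA_character_)
    ph <- h$bit_score[h$organism == phage_label]
    ba <- h$bit_score[h$organism == bacterium_label]
    if (length(ph) == 1L && (length(ba) == 0L || ph >= max(ba)))
      if (max(h$bit_score) <= ph) return(phage_label)
    top <- h$organism[h$bit_score == max(h$bit_score)]
    if (phage_label %in% top) return(phage_label)
    sort(top)[1]
  }
  assigned <- vapply(read_ids, function(id)
    assign_one(best_hits[best_hits$read_id == id, , drop = FALSE]),
    character(1))
  counted <- assigned[!is.na(assigned)]
  counts <- table(counted)
  report <- data.frame(organism = names(counts),
                       count = as.integer(counts),
                       proportion = as.integer(counts) / max(1L, length(counted)),
                       stringsAsFactors = FALSE)
  report <- report[order(report$organism), , drop = FALSE]
  rownames(report) <- NULL
  structure(report, unassigned = sum(is.na(assigned)),
            total = length(read_ids), class = c("proportion_report",
                                                "data.frame"))
}

#' Best hit of each read against each organism reference
#'
#' Directed analysis helper: aligns every read against a one-record
#' index per organism and keeps the best-scoring hit per (read,
#' organism).
#'
#' @param reads list of `read_record`s.
#' @param organism_seqs named character vector of reference sequences.
#' @param scheme a [scoring_scheme()].
#' @return Data frame: read_id, organism, bit_score, raw_score, strand,
#'   q_start, q_end, s_start, s_end, evalue.
#' @export
organism_best_hits <- function(reads, organism_seqs,
                               scheme = scoring_scheme()) {
  idxs <- lapply(names(organism_seqs), function(o)
    build_index(organism_seqs[o], w = scheme$word_size, db_id = o))
  names(idxs) <- names(organism_seqs)
  rows <- list()
  for (r in reads) {
    for (o in names(idxs)) {
      hits <- align_read(r, idxs[[o]], scheme)
      if (nrow(hits) == 0L) next
      h <- hits[1, ]
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = r$molecule_id, organism = o, bit_score = h$bit_score,
        raw_score = h$raw_score, strand = h$strand, q_start = h$q_start,
        q_end = h$q_end, s_start = h$s_start, s_end = h$s_end,
        evalue = h$evalue, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(read_id = character(0), organism = character(0),
                      bit_score = numeric(0), raw_score = integer(0),
                      strand = character(0), q_start = integer(0),
                      q_end = integer(0), s_start = integer(0),
                      s_end = integer(0), evalue = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Map reads onto one reference for pileup
#'
#' Each read's best local hit locates it on the reference; the full read
#' is then realigned with a banded fitting alignment (read end-to-end,
#' free reference end gaps) inside a padded window around the hit,
#' yielding a CIGAR anchored at a reference position.
#'
#' @param reads list of `read_record`s.
#' @param ref_seq reference sequence (single string).
#' @param scheme a [scoring_scheme()].
#' @param band_fraction half-width of the DP band as a fraction of read
#'   length.
#' @return Data frame: read_id, s_start, cigar, seq (oriented to the
#'   reference forward strand). Reads without a qualifying hit are
#'   dropped.
#' @export
map_reads <- function(reads, ref_seq, scheme = scoring_scheme(),
                      band_fraction = 0.2) {
  idx <- build_index(c(ref = ref_seq), w = scheme$word_size, db_id = "ref")
  L <- nchar(ref_seq)
  rows <- list()
  for (r in reads) {
    hits <- align_read(r, idx, scheme)
    if (nrow(hits) == 0L) next
    h <- hits[1, ]
    seq <- if (h$strand == "-") reverse_complement(r$sequence) else r$sequence
    lq <- nchar(seq)
    qs <- if (h$strand == "-") lq - h$q_end else h$q_start
    pad <- max(50L, as.integer(0.1 * lq))
    w_lo <- max(0L, h$s_start - qs - pad)
    w_hi <- min(L, h$s_end + (lq - (qs + (h$q_end - h$q_start))) + pad)
    win <- substr(ref_seq, w_lo + 1L, w_hi)
    band <- max(as.integer(band_fraction * lq), 32L)
    diag0 <- (h$s_start - w_lo) - qs
    res <- banded_align(seq, win, scheme, band = band, free_b_ends = TRUE,
                        diag0 = diag0)
    if (!isTRUE(res$valid)) next
    # strip leading/trailing reference-only columns from the CIGAR
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = r$molecule_id, s_start = w_lo + res$b_start,
      cigar = res$cigar, seq = seq, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(read_id = character(0), s_start = integer(0),
                      cigar = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Banded global or fitting alignment with automatic band widening when
# the optimal path touches the band edge or the band cannot connect the
# endpoints.
banded_align <- function(a, b, scheme, band, free_b_ends = FALSE, diag0 = 0L,
                         max_band = NULL) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) stop("sequences must be nonempty")
  if (is.null(max_band)) max_band <- max(la, lb)
  feasible <- if (free_b_ends) 1L else abs(lb - la - diag0) + 1L
  if (band < feasible) {
    message("widening alignment band to ", feasible,
            " to connect the endpoints")
    band <- feasible
  }
  repeat {
    res <- C_banded_align(a, b, scheme$match, scheme$mismatch, scheme$gap,
                          as.integer(band), free_b_ends, as.integer(diag0))
    if (isTRUE(res$valid) && !isTRUE(res$touched_band_edge)) return(res)
    if (band >= max_band) {
      if (isTRUE(res$valid)) return(res)
      stop("banded alignment infeasible even at full band width")
    }
    band <- min(max_band, band * 2L)
    message("widening alignment band to ", band)
  }
}

#' Pileup consensus and coverage over one reference
#'
#' Per reference column, depth is the number of reads aligned across the
#' column. The consensus base is the strict majority (> 50% of covering
#' reads) over aligned bases; a column where gap symbols hold a strict
#' majority is deleted; without a strict majority the reference base is
#' kept; depth-0 columns emit `N`. Insertions relative to the reference
#' are included only when a strict majority of reads spanning the
#' junction contain one (the most common inserted sequence is used).
#'
#' @param alignments data frame from [map_reads()] (columns `s_start`,
#'   `cigar`, `seq`), all against the same reference.
#' @param ref_seq the reference sequence.
#' @param record_id id used in the outputs.
#' @return List with `consensus` (a `consensus_sequence`: record_id,
#'   sequence, covered_fraction) and `coverage` (a `coverage_map`:
#'   record_id, per-position depth).
#' @export
pileup_consensus <- function(alignments, ref_seq, record_id = "ref") {
  L <- nchar(ref_seq)
  p <- C_pileup(ref_seq, alignments$seq, alignments$cigar,
                as.integer(alignments$s_start))
  counts <- p$counts
  depth <- p$depth
  ref_codes <- .seq_to_codes(ref_seq)
  cons <- character(L)
  base_chars <- c("A", "C", "G", "T", "")
  for (j in seq_len(L)) {
    d <- depth[j]
    if (d == 0L) { cons[j] <- "N"; next }
    v <- counts[, j]
    top <- which.max(v)
    if (v[top] * 2L > d) cons[j] <- base_chars[top]
    else cons[j] <- base_chars[ref_codes[j]]  # no strict majority: keep reference
  }
  ins <- p$insertions
  if (nrow(ins) > 0) {
    spans <- cbind(alignments$s_start,
                   alignments$s_start + cigar_ref_span(alignments$cigar))
    for (j in unique(ins$junction)) {
      spanning <- sum(spans[, 1] < j & spans[, 2] > j)
      here <- ins[ins$junction == j, , drop = FALSE]
      here <- here[spans[here$read, 1] < j & spans[here$read, 2] > j, ,
                   drop = FALSE]
      if (nrow(here) * 2L > spanning && spanning > 0L) {
        tab <- sort(table(here$seq), decreasing = TRUE)
        modal <- sort(names(tab)[tab == max(tab)])[1]
        # junction j (0-based) sits before reference column j, 1-based j + 1
        cons[j + 1L] <- paste0(modal, cons[j + 1L])
      }
    }
  }
  sequence <- paste(cons, collapse = "")
  structure(list(
    consensus = structure(list(record_id = record_id, sequence = sequence,
                               covered_fraction = mean(depth >= 1L)),
                          class = "consensus_sequence"),
    coverage = structure(list(record_id = record_id, depth = depth),
                         class = "coverage_map")),
    class = "pileup_result")
}

cigar_ref_span <- function(cigars) {
  vapply(cigars, function(cg) {
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MID]", cg))[[1]]
    sum(lens[ops %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Gapped pairwise identity of a consensus against its reference
#'
#' Global (end-to-end) banded alignment under the scoring scheme;
#' identity is matched columns over total alignment columns, gap columns
#' included, as a percentage. The band auto-widens (with a notice) if it
#' cannot connect the endpoints or the optimal path touches its edge.
#'
#' @param consensus,reference nonempty sequences (strings or
#'   `consensus_sequence`).
#' @param scheme a [scoring_scheme()].
#' @param band_fraction band half-width as a fraction of the longer
#'   sequence (default 0.2).
#' @return Identity percentage in \[0, 100\].
#' @export
consensus_identity <- function(consensus, reference,
                               scheme = scoring_scheme(),
                               band_fraction = 0.2) {
  if (inherits(consensus, "consensus_sequence")) consensus <- consensus$sequence
  if (nchar(consensus) == 0L || nchar(reference) == 0L)
    stop("sequences must be nonempty")
  band <- max(8L, as.integer(band_fraction * max(nchar(consensus),
                                                 nchar(reference))))
  res <- banded_align(consensus, reference, scheme, band = band,
                      free_b_ends = FALSE, diag0 = 0L)
  100 * res$matches / res$columns
}

#' Write a coverage map as bedGraph-style TSV
#'
#' Columns record_id, start, end, depth with 0-based half-open
#' intervals; adjacent equal-depth positions are merged.
#'
#' @param coverage a `coverage_map`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_bedgraph <- function(coverage, path) {
  d <- coverage$depth
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  write.table(data.frame(coverage$record_id, starts, ends, r$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a consensus sequence as FASTA
#' @param consensus a `consensus_sequence`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_consensus_fasta <- function(consensus, path) {
  x <- Biostrings::DNAStringSet(consensus$sequence)
  names(x) <- sprintf("%s_consensus covered_fraction=%.4f",
                      consensus$record_id, consensus$covered_fraction)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
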