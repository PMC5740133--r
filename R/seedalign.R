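#' Scoring scheme for seed-and-extend alignment
#'
#' Match/mismatch/linear-gap scores, the seed word size, the x-drop
#' extension threshold, and the Karlin-Altschul parameters (`lambda`,
#' `K`) used to convert raw scores to bit scores and e-values. Defaults
#' are megablast-like: +1/-2 with linear gap -2 per column, word size 16,
#' lambda 1.28, K 0.46.
#'
#' @param word_size exact-match seed length (>= 4).
#' @param match,mismatch,gap integer scores; `gap` applies per gap column.
#' @param xdrop extension drop-off threshold.
#' @param lambda,K Karlin-Altschul statistics parameters.
#' @param evalue_cutoff hits with larger e-value are discarded.
#' @param max_seed_gap maximum distance between consecutive seeds chained
#'   on one diagonal.
#' @return A `scoring_scheme`.
#' @export
scoring_scheme <- function(word_size = 16L, match = 1L, mismatch = -2L,
                           gap = -2L, xdrop = 20L, lambda = 1.28, K = 0.46,
                           evalue_cutoff = 1e-5, max_seed_gap = 200L) {
  if (word_size < 4) stop("`word_size` must be >= 4")
  if (!(match > 0 && mismatch < 0 && gap < 0)) stop("need match > 0 > mismatch, gap")
  if (lambda <= 0 || K <= 0) stop("`lambda` and `K` must be positive")
  if (evalue_cutoff <= 0) stop("`evalue_cutoff` must be positive")
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 xdrop = as.integer(xdrop), lambda = lambda, K = K,
                 evalue_cutoff = evalue_cutoff,
                 max_seed_gap = as.integer(max_seed_gap)),
            class = "scoring_scheme")
}

#' Build a w-mer seed index over reference records
#'
#' Indexes every exact w-mer of every record's forward strand (w-mers
#' containing ambiguous bases are skipped); queries are searched on both
#' strands by reverse-complementing the query, so the effective search
#' space length stays the summed record length.
#'
#' @param records data frame with columns `record_id` and `sequence`
#'   (optionally `taxid`, `completeness`, carried along as metadata), or
#'   a named character vector of sequences.
#' @param w word size (>= 4).
#' @param db_id label for the index.
#' @return A `seed_index` with fields `db_id`, `word_size`,
#'   `total_db_length`, `records` (metadata) and the compiled index.
#' @export
build_index <- function(records, w = 16L, db_id = "db") {
  if (is.character(records))
    records <- data.frame(record_id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stop("`records` must be nonempty")
  if (w < 4) stop("`word_size` must be >= 4")
  ptr <- C_build_index(records$record_id, records$sequence, as.integer(w))
  structure(list(db_id = db_id, word_size = as.integer(w),
                 total_db_length = sum(nchar(records$sequence)),
                 records = records, ptr = ptr),
            class = "seed_index")
}

index_ptr <- function(index) {
  if (!C_index_valid(index$ptr)) {
    # external pointers do not survive serialization; rebuild transparently
    index$ptr <- C_build_index(index$records$record_id, index$records$sequence,
                               index$word_size)
  }
  index$ptr
}

#' Number of seed postings in an index
#' @param index a `seed_index`.
#' @return Total count of indexed w-mer positions (w-mers containing
#'   ambiguous bases are not indexed).
#' @export
n_postings <- function(index) {
  C_index_info(index_ptr(index))$n_postings
}

#' Karlin-Altschul bit score
#' @param raw_score integer raw alignment score.
#' @param scheme a [scoring_scheme()].
#' @return Bit score `(lambda * raw_score - ln K) / ln 2`.
#' @export
bit_score <- function(raw_score, scheme) {
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value of a raw alignment score
#'
#' `E = m * n * 2^(-bit_score)` with `m` the query length and `n` the
#' summed reference length of the index.
#'
#' @param raw_score integer raw score (>= 0).
#' @param query_len query length in bases.
#' @param index a `seed_index` (supplies `n`).
#' @param scheme a [scoring_scheme()].
#' @return Positive e-value.
#' @export
compute_evalue <- function(raw_score, query_len, index, scheme) {
  if (any(raw_score < 0)) stop("`raw_score` must be >= 0")
  if (query_len < 1) stop("`query_len` must be >= 1")
  query_len * index$total_db_length * 2^(-bit_score(raw_score, scheme))
}

empty_hits <- function() {
  data.frame(query_id = character(0), record_id = character(0),
             taxid = integer(0), strand = character(0), raw_score = integer(0),
             bit_score = numeric(0), evalue = numeric(0), identity = numeric(0),
             q_start = integer(0), q_end = integer(0), s_start = integer(0),
             s_end = integer(0), matches = integer(0), mismatches = integer(0),
             gap_columns = integer(0), stringsAsFactors = FALSE)
}

#' Align a read against a seed index
#'
#' Seed-and-extend local alignment: exact w-mer seeds on both query
#' orientations, greedy per-diagonal chaining, anchored gapped x-drop
#' extension, merging of overlapping hits per record (highest raw score
#' kept), e-value filtering at `scheme$evalue_cutoff`, and sorting by
#' ascending e-value, then descending bit score, then record id.
#'
#' @param read a `read_record` or a plain character sequence.
#' @param index a `seed_index` built at `scheme$word_size` (the index's
#'   own word size is used for seeding).
#' @param scheme a [scoring_scheme()].
#' @param query_id id used in the output (defaults to the record's
#'   molecule id).
#' @return Data frame of hits (0-based half-open intervals; query
#'   interval on the original read, subject interval forward-strand).
#'   Reads shorter than the word size yield zero hits.
#' @export
align_read <- function(read, index, scheme = scoring_scheme(),
                       query_id = NULL) {
  if (inherits(read, "read_record")) {
    if (is.null(query_id)) query_id <- read$molecule_id
    seq <- read$sequence
  } else {
    seq <- as.character(read)
    if (is.null(query_id)) query_id <- "query"
  }
  if (nchar(seq) < index$word_size) return(empty_hits())
  raw <- C_align_read(index_ptr(index), seq, scheme$match, scheme$mismatch,
                      scheme$gap, scheme$xdrop, scheme$max_seed_gap,
                      50L, 200L)
  if (nrow(raw) == 0L) return(empty_hits())
  ev <- compute_evalue(raw$raw_score, nchar(seq), index, scheme)
  cols <- raw$matches + raw$mismatches + raw$gap_columns
  out <- data.frame(
    query_id = query_id, record_id = raw$record_id,
    taxid = if ("taxid" %in% names(index$records))
      index$records$taxid[raw$record] else NA_integer_,
    strand = raw$strand, raw_score = raw$raw_score,
    bit_score = bit_score(raw$raw_score, scheme), evalue = ev,
    identity = ifelse(cols > 0, 100 * raw$matches / cols, 0),
    q_start = raw$q_start, q_end = raw$q_end,
    s_start = raw$s_start, s_end = raw$s_end,
    matches = raw$matches, mismatches = raw$mismatches,
    gap_columns = raw$gap_columns, stringsAsFactors = FALSE)
  out <- out[out$evalue <= scheme$evalue_cutoff, , drop = FALSE]
  out <- out[order(out$evalue, -out$bit_score, out$record_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sensitive rescue alignment
#'
#' Identical to [align_read()] but with word size 11 and e-value cutoff
#' 1e-8; used on reads left unidentified by the standard cascade.
#'
#' @param read a `read_record` or character sequence.
#' @param index a `seed_index` built at word size 11 over the same
#'   records (use [rescue_index()]).
#' @param scheme base scheme whose scores are reused.
#' @param query_id id used in the output.
#' @return Data frame of hits as in [align_read()].
#' @export
rescue_align <- function(read, index, scheme = scoring_scheme(),
                         query_id = NULL) {
  rescue_scheme <- scheme
  rescue_scheme$word_size <- 11L
  rescue_scheme$evalue_cutoff <- 1e-8
  if (index$word_size != 11L)
    stop("rescue alignment needs an index built at word size 11")
  align_read(read, index, rescue_scheme, query_id)
}

#' Rebuild an index at the rescue word size (11)
#' @param index a `seed_index`.
#' @return A `seed_index` over the same records with word size 11.
#' @export
rescue_index <- function(index) {
  build_index(index$records, w = 11L, db_id = paste0(index$db_id, "_rescue"))
}

#' Write hits in BLAST-outfmt6-like tabular form
#'
#' Columns: query_id, record_id, identity, alignment_length, mismatches,
#' gap_columns, q_start, q_end, s_start, s_end, evalue, bit_score.
#' Coordinates are 1-based inclusive; subject coordinates are reversed
#' (start > end) on the minus strand.
#'
#' @param hits data frame from [align_read()].
#' @param path output TSV path (no header, as in BLAST tabular output).
#' @return Invisibly, the reformatted data frame.
#' @export
write_hits_tsv <- function(hits, path) {
  minus <- hits$strand == "-"
  s1 <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  s2 <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  out <- data.frame(
    query_id = hits$query_id, record_id = hits$record_id,
    identity = sprintf("%.2f", hits$identity),
    alignment_length = hits$matches + hits$mismatches + hits$gap_columns,
    mismatches = hits$mismatches, gap_columns = hits$gap_columns,
    q_start = hits$q_start + 1L, q_end = hits$q_end,
    s_start = s1, s_end = s2,
    evalue = format(hits$evalue, digits = 3),
    bit_score = sprintf("%.1f", hits$bit_score), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(out)
}
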