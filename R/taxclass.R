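#' Construct a rooted taxonomy
#'
#' @param nodes data frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name`. Exactly one node must be its own parent (the root), and
#'   every node must reach the root by parent traversal.
#' @return A `taxonomy` object.
#' @export
taxonomy <- function(nodes) {
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(nodes))) stop("taxonomy needs columns: ",
                                         paste(need, collapse = ", "))
  if (anyDuplicated(nodes$taxid)) stop("duplicate taxids in taxonomy")
  root <- nodes$taxid[nodes$taxid == nodes$parent_taxid]
  if (length(root) != 1L) stop("taxonomy must have exactly one root node")
  parent <- setNames(nodes$parent_taxid, nodes$taxid)
  if (any(!nodes$parent_taxid %in% nodes$taxid))
    stop("parent taxid missing from taxonomy")
  # verify all nodes reach the root (also guards against cycles)
  for (t in nodes$taxid) {
    cur <- t
    for (step in seq_len(nrow(nodes) + 1L)) {
      if (cur == root) break
      cur <- parent[[as.character(cur)]]
      if (step > nrow(nodes)) stop("cycle detected in taxonomy at taxid ", t)
    }
    if (cur != root) stop("taxid ", t, " does not reach the root")
  }
  structure(list(nodes = nodes, root = root, parent = parent), class = "taxonomy")
}

#' Read a taxonomy from nodes/names-style TSV
#' @param path TSV with header line and columns taxid, parent_taxid,
#'   rank, name.
#' @return A `taxonomy`.
#' @export
read_taxonomy_tsv <- function(path) {
  taxonomy(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a taxonomy as TSV
#' @param tax a `taxonomy`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  write.table(tax$nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

root_path <- function(taxid, tax) {
  path <- taxid
  cur <- taxid
  while (cur != tax$root) {
    cur <- tax$parent[[as.character(cur)]]
    path <- c(path, cur)
  }
  path
}

taxon_depth <- function(taxid, tax) length(root_path(taxid, tax)) - 1L

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on the root-path of every input taxid;
#' commutative and idempotent. Implemented by depth-equalized parallel
#' parent walking.
#'
#' @param taxids nonempty vector of taxids present in the taxonomy.
#' @param tax a `taxonomy`.
#' @return A single taxid.
#' @export
lca <- function(taxids, tax) {
  taxids <- unique(taxids)
  if (length(taxids) == 0L) stop("`taxids` must be nonempty")
  if (any(!taxids %in% tax$nodes$taxid))
    stop("unknown taxid(s): ",
         paste(setdiff(taxids, tax$nodes$taxid), collapse = ", "))
  cur <- taxids[1]
  for (t in taxids[-1]) {
    a <- cur; b <- t
    da <- taxon_depth(a, tax); db <- taxon_depth(b, tax)
    while (da > db) { a <- tax$parent[[as.character(a)]]; da <- da - 1L }
    while (db > da) { b <- tax$parent[[as.character(b)]]; db <- db - 1L }
    while (a != b) {
      a <- tax$parent[[as.character(a)]]
      b <- tax$parent[[as.character(b)]]
    }
    cur <- a
  }
  cur
}

#' Is `ancestor` on the root-path of `taxid` (inclusive)?
#' @param taxid,ancestor taxids in the taxonomy.
#' @param tax a `taxonomy`.
#' @return Logical.
#' @export
is_ancestor <- function(ancestor, taxid, tax) ancestor %in% root_path(taxid, tax)

tier_names <- c("host", "viral", "bacterial", "eukaryote_nonchordate")

#' Build a reference tier from annotated records
#'
#' A tier is one database of the classification cascade (host, viral,
#' bacterial, eukaryote_nonchordate) with its seed index and e-value
#' cutoff. Records carry a taxid and a completeness class
#' (`complete_genome`, `complete_sequence`, `partial`).
#'
#' @param tier_name one of `host`, `viral`, `bacterial`,
#'   `eukaryote_nonchordate`.
#' @param records data frame with `record_id`, `taxid`, `completeness`,
#'   `sequence`.
#' @param taxonomy a `taxonomy`; every record taxid must be present.
#' @param evalue_cutoff tier cutoff (default 1e-5).
#' @param word_size seed word size (default 16).
#' @return A `reference_tier`.
#' @export
reference_tier <- function(tier_name, records, taxonomy,
                           evalue_cutoff = 1e-5, word_size = 16L) {
  tier_name <- match.arg(tier_name, tier_names)
  bad <- setdiff(records$taxid, taxonomy$nodes$taxid)
  if (length(bad) > 0)
    stop("record taxid(s) absent from taxonomy: ", paste(bad, collapse = ", "))
  ok_compl <- c("complete_genome", "complete_sequence", "partial")
  if (any(!records$completeness %in% ok_compl))
    stop("completeness must be one of: ", paste(ok_compl, collapse = ", "))
  structure(list(
    tier_name = tier_name,
    order = match(tier_name, tier_names),
    records = records,
    index = build_index(records, w = word_size, db_id = tier_name),
    evalue_cutoff = evalue_cutoff
  ), class = "reference_tier")
}

#' Read tier records from an annotated FASTA
#'
#' Header grammar: `>record_id taxid=<int> completeness=<class> <text>`.
#'
#' @param path FASTA path.
#' @return Data frame with `record_id`, `taxid`, `completeness`,
#'   `sequence`.
#' @export
read_tier_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  heads <- names(x)
  rid <- sub("\\s.*$", "", heads)
  taxid <- suppressWarnings(as.integer(sub(".*taxid=(\\d+).*", "\\1", heads)))
  compl <- sub(".*completeness=(\\S+).*", "\\1", heads)
  if (any(is.na(taxid)) || any(compl == heads))
    stop("FASTA headers must carry taxid=<int> and completeness=<class>: ", path)
  data.frame(record_id = rid, taxid = taxid, completeness = compl,
             sequence = as.character(x), stringsAsFactors = FALSE)
}

scheme_for_tier <- function(tier, scheme) {
  s <- scheme
  s$evalue_cutoff <- tier$evalue_cutoff
  s
}

#' Subtract host reads from a batch
#'
#' Reads with any hit against the host tier at or below its e-value
#' cutoff are split off; the remainder continues down the cascade. The
#' partition is exact.
#'
#' @param batch a `read_batch` or plain list of `read_record`s.
#' @param host_tier a `reference_tier` with `tier_name == "host"`.
#' @param scheme a [scoring_scheme()].
#' @return List with `host_reads`, `remainder` (lists of records) and
#'   `host_hits` (best host hit per host read).
#' @export
subtract_host <- function(batch, host_tier, scheme = scoring_scheme()) {
  stopifnot(host_tier$tier_name == "host")
  reads <- if (inherits(batch, "read_batch")) batch$reads else batch
  s <- scheme_for_tier(host_tier, scheme)
  is_host <- logical(length(reads))
  best <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    hits <- align_read(reads[[i]], host_tier$index, s)
    if (nrow(hits) > 0) {
      is_host[i] <- TRUE
      best[[i]] <- hits[1, , drop = FALSE]
    }
  }
  list(host_reads = reads[is_host], remainder = reads[!is_host],
       host_hits = do.call(rbind, best[is_host]))
}

#' Classify one read through the tier cascade
#'
#' Tiers are queried in cascade order; the first tier yielding any hit
#' at or below its cutoff terminates the cascade. Within that tier the
#' best hit by ascending e-value then descending bit score is retained;
#' exact bit-score ties for the maximum are resolved by assigning the
#' lowest common ancestor of the tied hits' taxids.
#'
#' @param read a `read_record` (already past host subtraction when the
#'   cascade excludes the host tier).
#' @param tiers list of `reference_tier`s in cascade order.
#' @param tax a `taxonomy`.
#' @param scheme a [scoring_scheme()].
#' @param rescue optional list of rescue (word size 11) `seed_index`es
#'   parallel to `tiers`, tried at cutoff 1e-8 when the cascade leaves
#'   the read unidentified.
#' @return One-row classification data frame: read_id, status
#'   (`host`/`assigned`/`unidentified`), stage, taxid, rank, name,
#'   record_id, evalue, identity, bit_score.
#' @export
classify_read <- function(read, tiers, tax, scheme = scoring_scheme(),
                          rescue = NULL) {
  ord <- order(vapply(tiers, function(t) t$order, numeric(1)))
  tiers <- tiers[ord]
  read_id <- if (inherits(read, "read_record")) read$molecule_id else "query"
  for (pass in if (is.null(rescue)) 1L else c(1L, 2L)) {
    for (k in seq_along(tiers)) {
      tier <- tiers[[k]]
      if (pass == 1L) {
        hits <- align_read(read, tier$index, scheme_for_tier(tier, scheme))
      } else {
        hits <- rescue_align(read, rescue[[ord[k]]], scheme)
        if (nrow(hits) > 0)
          hits$taxid <- tier$records$taxid[match(hits$record_id,
                                                 tier$records$record_id)]
      }
      if (nrow(hits) == 0L) next
      if (anyNA(hits$taxid) || any(!hits$taxid %in% tax$nodes$taxid))
        stop("record '", hits$record_id[which(is.na(hits$taxid) |
             !hits$taxid %in% tax$nodes$taxid)[1]],
             "' carries a taxid absent from the taxonomy")
      top <- hits[hits$bit_score == max(hits$bit_score), , drop = FALSE]
      taxid <- if (nrow(top) > 1L) lca(top$taxid, tax) else top$taxid[1]
      node <- tax$nodes[tax$nodes$taxid == taxid, ]
      status <- if (tier$tier_name == "host") "host" else "assigned"
      return(data.frame(
        read_id = read_id, status = status, stage = tier$tier_name,
        taxid = taxid, rank = node$rank, name = node$name,
        record_id = top$record_id[1], evalue = top$evalue[1],
        identity = top$identity[1], bit_score = top$bit_score[1],
        stringsAsFactors = FALSE))
    }
  }
  data.frame(read_id = read_id, status = "unidentified", stage = NA_character_,
             taxid = NA_integer_, rank = NA_character_, name = NA_character_,
             record_id = NA_character_, evalue = NA_real_,
             identity = NA_real_, bit_score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Classify a batch of reads
#' @param batch a `read_batch` or list of `read_record`s.
#' @inheritParams classify_read
#' @return Data frame with one classification row per read.
#' @export
classify_batch <- function(batch, tiers, tax, scheme = scoring_scheme(),
                           rescue = NULL) {
  reads <- if (inherits(batch, "read_batch")) batch$reads else batch
  if (length(reads) == 0L)
    return(classify_read(make_read_record("x", "template", "A", 10L),
                         tiers, tax, scheme)[0, ])
  do.call(rbind, lapply(reads, classify_read, tiers = tiers, tax = tax,
                        scheme = scheme, rescue = rescue))
}

completeness_priority <- c(complete_genome = 1L, complete_sequence = 2L,
                           partial = 3L)

#' Choose the representative reference for a species
#'
#' Candidates are first restricted to the highest-priority completeness
#' class present among the hit records (complete genomes, then complete
#' sequences, then partial sequences); within that class the record with
#' the most aligned reads wins; remaining ties break to the
#' lexicographically smallest record id.
#'
#' @param hits data frame of hits of reads assigned to the species; must
#'   contain `record_id` (one row per read-record assignment).
#' @param tier the `reference_tier` supplying completeness metadata.
#' @return The chosen record id.
#' @export
choose_reference <- function(hits, tier) {
  if (nrow(hits) == 0L) stop("`hits` must be nonempty")
  counts <- table(hits$record_id)
  ids <- names(counts)
  compl <- tier$records$completeness[match(ids, tier$records$record_id)]
  pri <- completeness_priority[compl]
  keep <- pri == min(pri)
  ids <- ids[keep]; cnt <- as.integer(counts)[keep]
  ids <- ids[cnt == max(cnt)]
  sort(ids)[1]
}

#' Create an empty live count table
#' @param refresh_interval seconds between report refreshes in streaming
#'   mode (default 30).
#' @return A `live_count_table`.
#' @export
live_count_table <- function(refresh_interval = 30) {
  structure(list(
    counts = data.frame(taxid = integer(0), stage = character(0),
                        count = integer(0), stringsAsFactors = FALSE),
    totals = c(host = 0L, assigned = 0L, unidentified = 0L),
    batch_index = -1L, refresh_interval = refresh_interval
  ), class = "live_count_table")
}

#' Fold a batch of classifications into the live counts
#' @param table a `live_count_table`.
#' @param batch_results classification data frame from
#'   [classify_batch()] (host rows included).
#' @param batch_index index of the folded batch.
#' @return The updated `live_count_table`.
#' @export
update_live_counts <- function(table, batch_results, batch_index = NULL) {
  for (s in names(table$totals))
    table$totals[[s]] <- table$totals[[s]] + sum(batch_results$status == s)
  tallied <- batch_results[!is.na(batch_results$taxid), , drop = FALSE]
  if (nrow(tallied) > 0) {
    agg <- stats::aggregate(count ~ taxid + stage,
                            data = data.frame(taxid = tallied$taxid,
                                              stage = tallied$stage, count = 1L),
                            FUN = sum)
    for (i in seq_len(nrow(agg))) {
      j <- which(table$counts$taxid == agg$taxid[i] &
                 table$counts$stage == agg$stage[i])
      if (length(j) == 1L) table$counts$count[j] <- table$counts$count[j] + agg$count[i]
      else table$counts <- rbind(table$counts, agg[i, c("taxid", "stage", "count")])
    }
  }
  table$batch_index <- if (is.null(batch_index)) table$batch_index + 1L
                       else as.integer(batch_index)
  table
}

#' Emit the live report as a JSON document
#'
#' The report carries totals (host/assigned/unidentified), the batch
#' index, and one entry per counted taxon with name, rank, stage
#' provenance, count, and proportion of all processed reads; this JSON
#' feed is what a refreshing donut chart would poll.
#'
#' @param table a `live_count_table`.
#' @param tax a `taxonomy` for name/rank lookup.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @param timestamp include a `generated_at` field (disable for
#'   byte-reproducible output).
#' @return The JSON string, invisibly when written to `path`.
#' @export
emit_report <- function(table, tax, path = NULL, timestamp = TRUE) {
  total <- sum(table$totals)
  cnt <- table$counts[order(-table$counts$count, table$counts$taxid), ,
                      drop = FALSE]
  entries <- lapply(seq_len(nrow(cnt)), function(i) {
    node <- tax$nodes[tax$nodes$taxid == cnt$taxid[i], ]
    list(taxid = cnt$taxid[i], name = node$name, rank = node$rank,
         stage = cnt$stage[i], count = cnt$count[i],
         proportion = if (total > 0) cnt$count[i] / total else 0)
  })
  doc <- list(batch_index = table$batch_index,
              refresh_interval = table$refresh_interval,
              totals = as.list(table$totals), entries = entries)
  if (timestamp) doc <- c(list(generated_at = format(Sys.time(), usetz = TRUE)), doc)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
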