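#' Run the full classification pipeline over a run directory
#'
#' Streams (or one-shot reads) the grouped FASTQ files of a run
#' directory, selects one read per molecule, subtracts host reads via
#' the host tier, classifies the remainder down the tier cascade, and
#' maintains a live count table, optionally re-emitting the JSON report
#' as batches complete.
#'
#' @param run_dir run directory written by [write_run_directory()] (or a
#'   sequencer emulating it).
#' @param tiers list of `reference_tier`s; cascade order is taken from
#'   their tier names (host first, then viral, bacterial,
#'   eukaryote_nonchordate).
#' @param tax a `taxonomy`.
#' @param scheme a [scoring_scheme()].
#' @param batch_size reads per batch (default 200).
#' @param mode `"oneshot"` (single pass over a completed directory) or
#'   `"stream"` (poll until the sentinel appears).
#' @param rescue if `TRUE`, reads left unidentified by the cascade are
#'   retried with the sensitive word-size-11 / 1e-8 rescue aligner.
#' @param report_path optional path re-written with the live JSON report
#'   as the run progresses.
#' @param refresh_interval minimum seconds between report refreshes in
#'   stream mode (default 30); ignored in one-shot mode.
#' @param poll_interval directory polling interval in stream mode.
#' @param timestamp include timestamps in reports (disable for
#'   byte-reproducible output).
#' @return List with `classifications` (one row per read, in processing
#'   order) and `live_table` (final `live_count_table`).
#' @export
run_pipeline <- function(run_dir, tiers, tax, scheme = scoring_scheme(),
                         batch_size = 200L, mode = c("oneshot", "stream"),
                         rescue = FALSE, report_path = NULL,
                         refresh_interval = 30, poll_interval = 2,
                         timestamp = TRUE) {
  mode <- match.arg(mode)
  ord <- order(vapply(tiers, function(t) t$order, numeric(1)))
  tiers <- tiers[ord]
  rescue_idx <- if (rescue) lapply(tiers, function(t) rescue_index(t$index))
                else NULL
  table <- live_count_table(refresh_interval = refresh_interval)
  results <- list()
  last_refresh <- Sys.time() - refresh_interval
  on_batch <- function(batch) {
    cls <- classify_batch(batch, tiers, tax, scheme, rescue = rescue_idx)
    results[[length(results) + 1L]] <<- cls
    table <<- update_live_counts(table, cls, batch$batch_index)
    if (!is.null(report_path)) {
      due <- mode == "oneshot" ||
        as.numeric(difftime(Sys.time(), last_refresh, units = "secs")) >=
          refresh_interval
      if (due) {
        emit_report(table, tax, report_path, timestamp = timestamp)
        last_refresh <<- Sys.time()
      }
    }
  }
  if (mode == "stream") {
    batch_stream(run_dir, size_limit = batch_size,
                 poll_interval = poll_interval, callback = on_batch)
  } else {
    reads <- collect_selected_reads(run_dir)
    starts <- seq(1L, max(1L, length(reads)), by = batch_size)
    bi <- 0L
    for (s in starts) {
      if (length(reads) == 0L) break
      chunk <- reads[s:min(length(reads), s + batch_size - 1L)]
      on_batch(read_batch(chunk, bi, batch_size))
      bi <- bi + 1L
    }
  }
  cls <- if (length(results) > 0) do.call(rbind, results) else
    classify_batch(list(), tiers, tax, scheme)
  if (!is.null(report_path))
    emit_report(table, tax, report_path, timestamp = timestamp)
  list(classifications = cls, live_table = table)
}

#' Write classifications as TSV
#' @param classifications data frame from [run_pipeline()] /
#'   [classify_batch()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_classifications_tsv <- function(classifications, path) {
  write.table(classifications, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Score classifications against simulation truth
#'
#' A non-host assignment is compatible with truth when its taxid is the
#' true source organism's taxid or an ancestor of it. Reads whose source
#' interval overlaps the integrated phage region of the bacterial genome
#' are genuinely ambiguous (the phage occurs verbatim inside the
#' bacterium), so for them an assignment to either the phage or the
#' bacterium lineage counts as compatible.
#'
#' @param classifications data frame from [run_pipeline()].
#' @param truth truth data frame from [simulate_reads()].
#' @param world the `toy_world` the reads were simulated from.
#' @return List: `n_assigned`, `n_compatible`, `accuracy` (fraction of
#'   assigned non-host reads compatible with truth), `n_host_true`,
#'   `n_host_called`, `n_unidentified`.
#' @export
score_classifications <- function(classifications, truth, world) {
  tax <- world$taxonomy
  org_taxid <- setNames(world$organisms$taxid, world$organisms$label)
  tr <- truth[match(classifications$read_id, truth$molecule_id), ]
  emb <- world$embed_interval
  overlaps_embed <- tr$organism == "bacterium" &
    tr$start < emb[2] & tr$end > emb[1]
  assigned <- classifications$status == "assigned"
  compatible <- logical(nrow(classifications))
  for (i in which(assigned)) {
    true_tax <- org_taxid[[tr$organism[i]]]
    ok <- is_ancestor(classifications$taxid[i], true_tax, tax)
    if (!ok && overlaps_embed[i])
      ok <- is_ancestor(classifications$taxid[i], org_taxid[["phage"]], tax)
    if (!ok && tr$organism[i] == "phage")
      ok <- is_ancestor(classifications$taxid[i], org_taxid[["bacterium"]], tax)
    compatible[i] <- ok
  }
  list(n_assigned = sum(assigned),
       n_compatible = sum(compatible[assigned]),
       accuracy = if (any(assigned)) mean(compatible[assigned]) else NA_real_,
       n_host_true = sum(tr$organism == "mammal_mito"),
       n_host_called = sum(classifications$status == "host"),
       n_unidentified = sum(classifications$status == "unidentified"))
}

#' Standard tier set for a toy world
#'
#' Builds the host (mammalian mitochondrion), viral (phage) and
#' bacterial tiers of the cascade from a [build_toy_world()] object.
#'
#' @param world a `toy_world`.
#' @param evalue_cutoff cutoff applied to every tier (default 1e-5).
#' @param word_size seed word size (default 16).
#' @return List of `reference_tier`s in cascade order.
#' @export
toy_world_tiers <- function(world, evalue_cutoff = 1e-5, word_size = 16L) {
  org <- world$organisms
  rec <- function(label) {
    i <- match(label, org$label)
    data.frame(record_id = label, taxid = org$taxid[i],
               completeness = org$completeness[i],
               sequence = world$genomes[[label]], stringsAsFactors = FALSE)
  }
  list(
    reference_tier("host", rec("mammal_mito"), world$taxonomy,
                   evalue_cutoff, word_size),
    reference_tier("viral", rec("phage"), world$taxonomy,
                   evalue_cutoff, word_size),
    reference_tier("bacterial", rec("bacterium"), world$taxonomy,
                   evalue_cutoff, word_size))
}
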