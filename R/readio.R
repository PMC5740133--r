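#' @title Grouped-FASTQ parsing and per-molecule read selection
#' @description The run directory dialect groups the basecall variants of
#'   one molecule (2D, 1D template, 1D complement) under read IDs of the
#'   form `<molecule_id>_<variant>` with variant one of `2d`, `template`,
#'   `complement`. This file provides the parser, the selection rule (2D
#'   preferred, otherwise the higher mean-quality 1D read) and batch
#'   streaming over a growing directory.
#' @name readio
NULL

#' Construct a molecule group
#'
#' @param molecule_id molecule identifier.
#' @param variants named list of `read_record` objects keyed by variant
#'   class (`two_direction`, `template`, `complement`).
#' @return A `molecule_group`.
#' @export
molecule_group <- function(molecule_id, variants) {
  ok <- c("two_direction", "template", "complement")
  if (length(variants) < 1 || length(variants) > 3 ||
      anyDuplicated(names(variants)) || any(!names(variants) %in% ok))
    stop("a molecule group holds 1-3 variants, at most one per class")
  structure(list(molecule_id = molecule_id, variants = variants),
            class = "molecule_group")
}

#' Per-base Phred qualities of a read record
#' @param record a `read_record`.
#' @return Integer vector of Phred scores (Sanger +33 encoding).
#' @export
phred_values <- function(record) utf8ToInt(record$qual) - 33L

mean_phred <- function(record) mean(utf8ToInt(record$qual)) - 33

# Structural pre-validation of a 4-line FASTQ file so format errors can
# name the offending record; content parsing is left to Biostrings.
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(0L))
  if (length(lines) %% 4L != 0L) {
    id <- sub("^@", "", lines[(length(lines) %/% 4L) * 4L + 1L])
    stop("truncated FASTQ record '", id, "' in ", path)
  }
  ids <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  heads <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0)
    stop("malformed FASTQ record '", ids[bad[1]], "' in ", path)
  bad <- which(nchar(seqs) != nchar(quals) | nchar(seqs) == 0L)
  if (length(bad) > 0)
    stop("sequence/quality length mismatch in FASTQ record '",
         ids[bad[1]], "' in ", path)
  invisible(length(ids))
}

#' Parse a grouped FASTQ file into molecule groups
#'
#' Records are grouped by the molecule-id prefix of their read ID,
#' preserving first-appearance order. Records whose variant suffix is not
#' `2d`, `template` or `complement` are rejected with a warning.
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @return List of `molecule_group` objects.
#' @export
parse_grouped_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  n <- validate_fastq(path)
  if (n == 0L) return(list())
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ids <- names(x)
  seqs <- as.character(x)
  quals <- as.character(Biostrings::quality(x))
  m <- regmatches(ids, regexec("^(.*)_(2[dD]|template|complement)$", ids))
  groups <- list()
  order_seen <- character(0)
  for (i in seq_along(ids)) {
    if (length(m[[i]]) != 3L) {
      warning("read '", ids[i], "' has an unknown variant suffix; skipped")
      next
    }
    mol <- m[[i]][2]
    variant <- c(`2d` = "two_direction", template = "template",
                 complement = "complement")[[tolower(m[[i]][3])]]
    rec <- structure(list(
      molecule_id = mol, variant = variant,
      sequence = unname(seqs[i]),
      qual = unname(quals[i]),
      file_of_origin = path
    ), class = "read_record")
    if (is.null(groups[[mol]])) {
      groups[[mol]] <- list()
      order_seen <- c(order_seen, mol)
    }
    if (!is.null(groups[[mol]][[variant]]))
      warning("duplicate ", variant, " record for molecule '", mol, "'; keeping first")
    else groups[[mol]][[variant]] <- rec
  }
  lapply(order_seen, function(mol) molecule_group(mol, groups[[mol]]))
}

#' Select the representative read of a molecule
#'
#' Returns the 2D read where available, otherwise the 1D read (template
#' or complement) with the higher arithmetic mean Phred quality; exact
#' ties go to the template strand.
#'
#' @param group a `molecule_group`.
#' @return The selected `read_record`.
#' @export
select_read <- function(group) {
  stopifnot(inherits(group, "molecule_group"))
  v <- group$variants
  if (length(v) == 0L) stop("empty molecule group")
  if (!is.null(v$two_direction)) return(v$two_direction)
  cands <- v[intersect(c("template", "complement"), names(v))]
  if (length(cands) == 1L) return(cands[[1]])
  qt <- mean_phred(cands$template)
  qc <- mean_phred(cands$complement)
  if (qc > qt) cands$complement else cands$template
}

read_batch <- function(reads, batch_index, size_limit) {
  structure(list(reads = reads, batch_index = batch_index,
                 size_limit = size_limit), class = "read_batch")
}

#' Stream selected reads from a run directory in fixed-size batches
#'
#' Polls `dir_path` for FASTQ files (processed in lexicographic order,
#' which for [write_run_directory()] output equals write order), selects
#' one read per molecule, and emits a batch every time `size_limit`
#' selected reads accumulate. When the `RUN_COMPLETE` sentinel is present
#' and all files have been consumed, any final partial batch is emitted
#' and the stream terminates.
#'
#' @param dir_path run directory.
#' @param size_limit reads per batch (default 200).
#' @param poll_interval seconds between directory scans.
#' @param callback optional `function(batch)` invoked as each batch is
#'   completed (used for live classification).
#' @param timeout seconds without progress or sentinel after which the
#'   stream aborts with an error.
#' @return Invisibly, the list of `read_batch` objects in emission order.
#' @export
batch_stream <- function(dir_path, size_limit = 200L, poll_interval = 2,
                         callback = NULL, timeout = 300) {
  if (!dir.exists(dir_path)) stop("no such directory: ", dir_path)
  seen <- character(0)
  pending <- list()
  batches <- list()
  bi <- 0L
  deadline <- Sys.time() + timeout
  flush_full <- function() {
    while (length(pending) >= size_limit) {
      b <- read_batch(pending[seq_len(size_limit)], bi, size_limit)
      pending <<- pending[-seq_len(size_limit)]
      batches[[length(batches) + 1L]] <<- b
      bi <<- bi + 1L
      if (!is.null(callback)) callback(b)
    }
  }
  repeat {
    if (!dir.exists(dir_path)) stop("run directory disappeared mid-stream")
    files <- sort(list.files(dir_path, pattern = "\\.fastq$"))
    new <- setdiff(files, seen)
    for (f in new) {
      groups <- parse_grouped_fastq(file.path(dir_path, f))
      pending <- c(pending, lapply(groups, select_read))
      seen <- c(seen, f)
      flush_full()
    }
    done <- file.exists(file.path(dir_path, "RUN_COMPLETE")) &&
      length(setdiff(sort(list.files(dir_path, pattern = "\\.fastq$")), seen)) == 0L
    if (done) {
      if (length(pending) > 0L) {
        b <- read_batch(pending, bi, size_limit)
        batches[[length(batches) + 1L]] <- b
        if (!is.null(callback)) callback(b)
      }
      break
    }
    if (length(new) > 0L) deadline <- Sys.time() + timeout
    if (Sys.time() > deadline)
      stop("timed out waiting for new files or the RUN_COMPLETE sentinel")
    Sys.sleep(poll_interval)
  }
  invisible(batches)
}

#' One-shot read selection over a completed run directory
#'
#' Parses every FASTQ file in lexicographic order and applies
#' [select_read()]; equivalent to the multiset of reads that
#' [batch_stream()] emits for the same completed directory.
#'
#' @param dir_path run directory.
#' @return List of selected `read_record` objects.
#' @export
collect_selected_reads <- function(dir_path) {
  files <- sort(list.files(dir_path, pattern = "\\.fastq$", full.names = TRUE))
  unlist(lapply(files, function(f)
    lapply(parse_grouped_fastq(f), select_read)), recursive = FALSE)
}
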