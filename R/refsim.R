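#' Error model for simulated nanopore reads
#'
#' Parameterizes the per-base error process and the read-length
#' distribution of a simulated organism. The total error rate is split
#' across substitutions, insertions and deletions (default 50/25/25);
#' read lengths are drawn from a log-normal distribution parameterized by
#' its median and log-scale spread, truncated to `[length_min, length_max]`.
#'
#' @param total_error total per-base error probability (substitution +
#'   insertion + deletion).
#' @param sub_frac,ins_frac,del_frac fractions of `total_error` allotted
#'   to each class; must sum to 1.
#' @param length_median median read length in bases.
#' @param length_sigma log-scale standard deviation of the length
#'   distribution.
#' @param length_min,length_max truncation bounds on read length.
#' @return An object of class `error_model`.
#' @examples
#' m <- error_model(0.172)
#' m$sub_rate + m$ins_rate + m$del_rate
#' @export
error_model <- function(total_error, sub_frac = 0.5, ins_frac = 0.25,
                        del_frac = 0.25, length_median = 5500,
                        length_sigma = 0.6, length_min = 80,
                        length_max = 72619) {
  if (total_error < 0 || total_error >= 1)
    stop("`total_error` must be in [0, 1)")
  if (abs(sub_frac + ins_frac + del_frac - 1) > 1e-9 ||
      min(sub_frac, ins_frac, del_frac) < 0)
    stop("substitution/insertion/deletion fractions must be >= 0 and sum to 1")
  if (length_min > length_median || length_median > length_max)
    stop("need length_min <= length_median <= length_max")
  if (length_sigma <= 0) stop("`length_sigma` must be positive")
  structure(list(
    sub_rate = total_error * sub_frac,
    ins_rate = total_error * ins_frac,
    del_rate = total_error * del_frac,
    total_error = total_error,
    length_median = as.integer(length_median),
    length_sigma = length_sigma,
    length_min = as.integer(length_min),
    length_max = as.integer(length_max)
  ), class = "error_model")
}

#' Per-organism error models for R7-era 2D nanopore chemistry
#'
#' Default models for the three-organism test mixture: total 2D error
#' rates of 18.4% (mouse/host), 17.2% (bacterium) and 15.9% (phage),
#' with median read length 5,500 bases.
#'
#' @param ... overrides passed to [error_model()] for every organism.
#' @return Named list of `error_model` objects with entries
#'   `bacterium`, `phage` and `mammal_mito`.
#' @export
r7_error_models <- function(...) {
  list(bacterium = error_model(0.172, ...),
       phage = error_model(0.159, ...),
       mammal_mito = error_model(0.184, ...))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

toy_taxonomy <- function() {
  taxonomy(data.frame(
    taxid = c(1L, 2L, 3L, 4L, 20L, 21L, 22L, 23L, 30L, 31L, 40L, 41L),
    parent_taxid = c(1L, 1L, 1L, 1L, 2L, 20L, 21L, 21L, 3L, 30L, 4L, 40L),
    rank = c("no rank", "superkingdom", "superkingdom", "superkingdom",
             "genus", "species", "strain", "strain",
             "genus", "species", "genus", "species"),
    name = c("root", "Bacteria", "Viruses", "Eukaryota",
             "Toybacterium", "Toybacterium coli", "Toybacterium coli strain A",
             "Toybacterium coli strain B", "Toyphagevirus", "phage toy-lambda",
             "Toymus", "Toymus musculus mitochondrion"),
    stringsAsFactors = FALSE))
}

#' Build a deterministic three-organism toy reference world
#'
#' Generates random genomes for a bacterium, a phage and a mammalian
#' mitochondrion, with the phage genome integrated verbatim into the
#' bacterial chromosome (so reads from the integrated region are
#' attributable to either organism, mimicking a prophage), plus a small
#' rooted taxonomy covering all three.
#'
#' @param seed integer seed; identical seeds and parameters give
#'   byte-identical worlds.
#' @param bact_len,phage_len,mito_len genome lengths in bases; the phage
#'   must be shorter than the bacterium.
#' @param gc GC fraction of the generated genomes, in (0, 1).
#' @return A `toy_world`: list with `genomes` (named character vector),
#'   `taxonomy`, `organisms` (label/taxid/completeness table),
#'   `embed_interval` (0-based half-open interval of the integrated
#'   phage in the bacterial genome) and `seed`.
#' @examples
#' w <- build_toy_world(seed = 1, bact_len = 5000, phage_len = 500, mito_len = 1000)
#' substr(w$genomes[["bacterium"]], w$embed_interval[1] + 1,
#'        w$embed_interval[2]) == w$genomes[["phage"]]
#' @export
build_toy_world <- function(seed, bact_len = 50000L, phage_len = 5000L,
                            mito_len = 16000L, gc = 0.5) {
  if (!(bact_len > phage_len && phage_len > 0)) stop("need bact_len > phage_len > 0")
  if (mito_len <= 0) stop("`mito_len` must be positive")
  if (gc <= 0 || gc >= 1) stop("`gc` must be inside (0, 1)")
  with_seed(seed, {
    phage <- random_dna(phage_len, gc)
    bact <- random_dna(bact_len, gc)
    mito <- random_dna(mito_len, gc)
    start <- sample.int(bact_len - phage_len + 1L, 1L) - 1L
    substr(bact, start + 1L, start + phage_len) <- phage
    structure(list(
      genomes = c(bacterium = bact, phage = phage, mammal_mito = mito),
      taxonomy = toy_taxonomy(),
      organisms = data.frame(
        label = c("bacterium", "phage", "mammal_mito"),
        taxid = c(21L, 31L, 41L),
        completeness = rep("complete_genome", 3L),
        stringsAsFactors = FALSE),
      embed_interval = c(start, start + phage_len),
      seed = as.integer(seed)
    ), class = "toy_world")
  })
}

# Apply the per-base error process to an integer-coded template (1..4).
# Each template base independently suffers deletion (p = del) or
# substitution (p = sub), and each junction after a base independently
# gains a single inserted base (p = ins); the three realized counts are
# returned with the read so the realized edit fraction is exact.
apply_errors <- function(codes, sub, ins, del) {
  L <- length(codes)
  if (L == 0L)
    return(list(codes = integer(0), n_sub = 0L, n_ins = 0L, n_del = 0L))
  u <- runif(L)
  is_del <- u < del
  is_sub <- !is_del & u < del + sub
  out <- codes
  nsub <- sum(is_sub)
  if (nsub > 0)
    out[is_sub] <- 1L + (out[is_sub] - 1L + sample.int(3L, nsub, replace = TRUE)) %% 4L
  keep <- which(!is_del)
  out <- out[keep]
  has_ins <- runif(L) < ins
  ins_after <- which(has_ins)  # template positions followed by an insertion
  if (length(ins_after) > 0) {
    # map template junctions onto positions in the deletion-filtered read
    pos_in_out <- findInterval(ins_after, keep)
    vals <- c(out, sample.int(4L, length(ins_after), replace = TRUE))
    ord <- order(c(seq_along(out), pos_in_out + 0.5))
    out <- vals[ord]
  }
  list(codes = out, n_sub = nsub, n_ins = length(ins_after), n_del = sum(is_del))
}

.codes_to_seq <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

.seq_to_codes <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

flat_phred <- function(total_error) {
  if (total_error <= 0) return(40L)
  max(1L, min(40L, as.integer(round(-10 * log10(total_error)))))
}

make_read_record <- function(molecule_id, variant, seq, phred, file = NA_character_) {
  structure(list(
    molecule_id = molecule_id, variant = variant, sequence = seq,
    qual = strrep(intToUtf8(phred + 33L), nchar(seq)),
    file_of_origin = file
  ), class = "read_record")
}

#' Simulate nanopore-like molecule groups from a toy world
#'
#' Draws molecules from the world's organisms, applies the per-organism
#' error model to produce a 2D variant, and adds 1D template/complement
#' variants at an inflated error rate. A configurable fraction of
#' molecules lacks the 2D variant, exercising the 1D fallback of the
#' read-selection rule. Base qualities are flat per variant at
#' `round(-10 log10(total_error))`.
#'
#' @param world a [build_toy_world()] object.
#' @param weights named organism sampling probabilities summing to 1.
#' @param n number of molecules.
#' @param models named list of [error_model()] per organism; defaults to
#'   [r7_error_models()] restricted to `names(weights)`.
#' @param seed integer seed.
#' @param onedim_inflation factor applied to the 2D error rate for the
#'   1D variants (total capped at 0.75).
#' @param no2d_fraction fraction of molecules lacking a 2D variant.
#' @return List with `groups` (list of `molecule_group`) and `truth`
#'   (data frame: molecule_id, organism, start, end, strand and realized
#'   per-variant edit counts; intervals are 0-based half-open on the
#'   source genome).
#' @export
simulate_reads <- function(world, weights, n, models = NULL, seed = 1L,
                           onedim_inflation = 2, no2d_fraction = 0.2) {
  stopifnot(inherits(world, "toy_world"))
  if (n < 0) stop("`n` must be non-negative")
  if (is.null(names(weights)) || any(!names(weights) %in% names(world$genomes)))
    stop("every organism in `weights` must exist in the world")
  if (abs(sum(weights) - 1) > 1e-9) stop("`weights` must sum to 1")
  if (is.null(models)) models <- r7_error_models()[names(weights)]
  if (any(!names(weights) %in% names(models)))
    stop("every organism in `weights` needs an error model")
  genome_codes <- lapply(world$genomes, .seq_to_codes)
  with_seed(seed, {
    orgs <- if (n > 0)
      sample(names(weights), n, replace = TRUE, prob = weights) else character(0)
    groups <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      org <- orgs[i]
      m <- models[[org]]
      gl <- length(genome_codes[[org]])
      # exact truncated log-normal draw via inverse CDF
      meanlog <- log(m$length_median)
      lmax <- min(m$length_max, gl)
      lmin <- min(m$length_min, lmax)
      pf <- plnorm(c(lmin, lmax), meanlog, m$length_sigma)
      len <- as.integer(round(qlnorm(runif(1, pf[1], pf[2]), meanlog, m$length_sigma)))
      len <- max(lmin, min(lmax, len))
      start <- sample.int(gl - len + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      frag <- genome_codes[[org]][(start + 1L):(start + len)]
      if (strand == "-") frag <- 5L - rev(frag)
      id <- sprintf("mol%06d", i)
      has2d <- runif(1) >= no2d_fraction
      inflate <- min(onedim_inflation, 0.75 / max(m$total_error, 1e-12))
      q2d <- flat_phred(m$total_error)
      q1d <- flat_phred(m$total_error * inflate)
      variants <- list()
      errs <- list(two_direction = NA_integer_, template = NA_integer_,
                   complement = NA_integer_)
      if (has2d) {
        e <- apply_errors(frag, m$sub_rate, m$ins_rate, m$del_rate)
        variants$two_direction <- make_read_record(id, "two_direction",
                                                   .codes_to_seq(e$codes), q2d)
        errs$two_direction <- e$n_sub + e$n_ins + e$n_del
      }
      et <- apply_errors(frag, m$sub_rate * inflate, m$ins_rate * inflate,
                         m$del_rate * inflate)
      variants$template <- make_read_record(id, "template",
                                            .codes_to_seq(et$codes), q1d)
      errs$template <- et$n_sub + et$n_ins + et$n_del
      ec <- apply_errors(5L - rev(frag), m$sub_rate * inflate,
                         m$ins_rate * inflate, m$del_rate * inflate)
      variants$complement <- make_read_record(id, "complement",
                                              .codes_to_seq(ec$codes), q1d)
      errs$complement <- ec$n_sub + ec$n_ins + ec$n_del
      groups[[i]] <- molecule_group(id, variants)
      truth[[i]] <- data.frame(
        molecule_id = id, organism = org, start = start, end = start + len,
        strand = strand, template_length = len,
        errors_two_direction = errs$two_direction,
        errors_template = errs$template, errors_complement = errs$complement,
        stringsAsFactors = FALSE)
    }
    list(groups = groups,
         truth = if (n > 0) do.call(rbind, truth) else data.frame(
           molecule_id = character(0), organism = character(0),
           start = integer(0), end = integer(0), strand = character(0),
           template_length = integer(0),
           errors_two_direction = integer(0), errors_template = integer(0),
           errors_complement = integer(0), stringsAsFactors = FALSE))
  })
}

variant_suffix <- c(two_direction = "2d", template = "template",
                    complement = "complement")

#' Write simulated molecule groups as an incrementally flushed run directory
#'
#' Emulates a sequencer download directory: FASTQ files are written in
#' chunks of `files_per_flush` molecules (all variants of a molecule stay
#' in one file), named with zero-padded indices so lexicographic order is
#' write order, followed by a terminal `RUN_COMPLETE` sentinel file.
#'
#' @param groups list of `molecule_group` objects.
#' @param dir_path output directory (created if needed).
#' @param files_per_flush molecules per FASTQ file (>= 1).
#' @return Invisibly, the manifest: character vector of file names in
#'   write order (sentinel last).
#' @export
write_run_directory <- function(groups, dir_path, files_per_flush = 200L) {
  if (files_per_flush < 1) stop("`files_per_flush` must be >= 1")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir_path)) stop("cannot create directory: ", dir_path)
  n <- length(groups)
  manifest <- character(0)
  chunk_starts <- if (n > 0) seq(1L, n, by = files_per_flush) else integer(0)
  for (k in seq_along(chunk_starts)) {
    lo <- chunk_starts[k]
    hi <- min(n, lo + files_per_flush - 1L)
    fname <- sprintf("reads_%05d.fastq", k)
    con <- file(file.path(dir_path, fname), "w")
    for (g in groups[lo:hi]) {
      for (v in names(g$variants)) {
        rec <- g$variants[[v]]
        writeLines(c(paste0("@", g$molecule_id, "_", variant_suffix[[v]]),
                     rec$sequence, "+", rec$qual), con)
      }
    }
    close(con)
    manifest <- c(manifest, fname)
  }
  file.create(file.path(dir_path, "RUN_COMPLETE"))
  invisible(c(manifest, "RUN_COMPLETE"))
}

#' Write the world's genomes as a tiered-reference FASTA
#'
#' Headers follow the reference grammar
#' `>record_id taxid=<int> completeness=<class> <free text>`.
#'
#' @param world a `toy_world`.
#' @param path output FASTA path.
#' @param labels organism labels to include (default all).
#' @return Invisibly, `path`.
#' @export
write_world_fasta <- function(world, path, labels = names(world$genomes)) {
  org <- world$organisms[match(labels, world$organisms$label), ]
  headers <- sprintf("%s taxid=%d completeness=%s simulated genome",
                     labels, org$taxid, org$completeness)
  seqs <- Biostrings::DNAStringSet(unlist(world$genomes[labels], use.names = FALSE))
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write ground-truth labels as TSV
#'
#' Columns: molecule_id, organism, start, end, strand (0-based half-open
#' intervals on the source genome).
#' @param truth truth data frame from [simulate_reads()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth[, c("molecule_id", "organism", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
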