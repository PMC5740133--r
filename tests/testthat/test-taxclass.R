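toy_tax <- build_toy_world(seed = 1, bact_len = 2000, phage_len = 200,
                           mito_len = 500)$taxonomy

test_that("taxonomy construction validates rootedness and reachability", {
  expect_s3_class(toy_tax, "taxonomy")
  expect_equal(toy_tax$root, 1L)
  no_root <- data.frame(taxid = 1:2, parent_taxid = c(2L, 1L),
                        rank = "no rank", name = c("a", "b"))
  expect_error(taxonomy(no_root), "exactly one root")
  two_roots <- data.frame(taxid = 1:2, parent_taxid = 1:2,
                          rank = "no rank", name = c("a", "b"))
  expect_error(taxonomy(two_roots), "exactly one root")
  orphan <- data.frame(taxid = c(1L, 2L), parent_taxid = c(1L, 9L),
                       rank = "no rank", name = c("a", "b"))
  expect_error(taxonomy(orphan), "missing")
})

test_that("taxonomy TSV round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy_tsv(toy_tax, f)
  back <- read_taxonomy_tsv(f)
  expect_equal(back$nodes, toy_tax$nodes)
})

test_that("lca matches its definition on the toy taxonomy", {
  expect_equal(lca(21L, toy_tax), 21L)                 # singleton
  expect_equal(lca(c(22L, 23L), toy_tax), 21L)         # strains -> species
  expect_equal(lca(c(31L, 21L), toy_tax), 1L)          # phage + bacterium -> root
  expect_equal(lca(c(22L, 23L), toy_tax),
               lca_bruteforce(c(22L, 23L), toy_tax))
  # commutative, associative under folding, root-absorbing
  expect_equal(lca(c(23L, 22L), toy_tax), lca(c(22L, 23L), toy_tax))
  expect_equal(lca(c(lca(c(22L, 23L), toy_tax), 41L), toy_tax),
               lca(c(22L, 23L, 41L), toy_tax))
  expect_equal(lca(c(22L, 1L), toy_tax), 1L)
  expect_error(lca(c(22L, 999L), toy_tax), "unknown taxid")
  expect_error(lca(integer(0), toy_tax), "nonempty")
})

test_that("lca equals brute-force root-path intersection on random taxonomies", {
  set.seed(53)
  for (rep in 1:5) {
    tax <- random_taxonomy(60)
    for (k in 1:40) {
      ids <- sample(tax$nodes$taxid, sample(1:5, 1))
      expect_equal(lca(ids, tax), lca_bruteforce(ids, tax))
    }
  }
})

make_tier <- function(name, ids, taxids, seqs, compl = NULL, tax = toy_tax,
                      cutoff = 1e-5, w = 16) {
  reference_tier(name, data.frame(
    record_id = ids, taxid = taxids,
    completeness = if (is.null(compl)) rep("complete_genome", length(ids))
                   else compl,
    sequence = seqs, stringsAsFactors = FALSE), tax, cutoff, w)
}

test_that("reference tiers validate taxids, completeness and cascade order", {
  set.seed(59)
  expect_error(make_tier("host", "r1", 999L, rnd_dna(100)),
               "absent from taxonomy")
  expect_error(make_tier("viral", "r1", 31L, rnd_dna(100), compl = "whole"),
               "completeness")
  host <- make_tier("host", "mito", 41L, rnd_dna(500))
  viral <- make_tier("viral", "phage", 31L, rnd_dna(500))
  bact <- make_tier("bacterial", "chrom", 21L, rnd_dna(500))
  expect_true(host$order < viral$order && viral$order < bact$order)
})

test_that("tier FASTA headers parse taxid and completeness", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">recA taxid=21 completeness=complete_genome toy chromosome",
               "ACGTACGTACGTACGT",
               ">recB taxid=31 completeness=partial toy fragment",
               "TTTTCCCCGGGGAAAA"), f)
  recs <- read_tier_fasta(f)
  expect_equal(recs$record_id, c("recA", "recB"))
  expect_equal(recs$taxid, c(21L, 31L))
  expect_equal(recs$completeness, c("complete_genome", "partial"))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">recA no annotations here", "ACGT"), f2)
  expect_error(read_tier_fasta(f2), "taxid")
})

test_that("host subtraction splits a batch exactly at the e-value cutoff", {
  set.seed(61)
  w <- build_toy_world(seed = 61, bact_len = 8000, phage_len = 800,
                       mito_len = 3000)
  host <- make_tier("host", "mito", 41L, w$genomes[["mammal_mito"]],
                    tax = w$taxonomy)
  models <- list(mammal_mito = error_model(0.10, length_median = 500,
                                           length_sigma = 0.3,
                                           length_min = 200,
                                           length_max = 1500),
                 bacterium = error_model(0.10, length_median = 500,
                                         length_sigma = 0.3,
                                         length_min = 200, length_max = 1500))
  mito <- simulate_reads(w, c(mammal_mito = 1), 20, models, seed = 3,
                         no2d_fraction = 0)
  bact <- simulate_reads(w, c(bacterium = 1), 20, models, seed = 4,
                         no2d_fraction = 0)
  reads <- c(lapply(mito$groups, select_read), lapply(bact$groups, select_read))
  res <- subtract_host(reads, host)
  expect_length(res$host_reads, 20)
  expect_length(res$remainder, 20)
  expect_true(all(res$host_hits$evalue <= 1e-5))
  got_host <- vapply(res$host_reads, function(r) r$molecule_id, character(1))
  expect_setequal(got_host, mito$truth$molecule_id)
  expect_equal(host$evalue_cutoff, 1e-5)

  # no host-similar reads: remainder is the whole batch
  res2 <- subtract_host(lapply(bact$groups, select_read), host)
  expect_length(res2$host_reads, 0)
  expect_length(res2$remainder, 20)
})

test_that("the cascade stops at the first qualifying tier and LCA resolves ties", {
  set.seed(67)
  phage_seq <- rnd_dna(600)
  other_seq <- rnd_dna(600)
  strain_seq <- rnd_dna(600)
  viral <- make_tier("viral", "phage1", 31L, phage_seq)
  # two identical bacterial records under sibling strain taxa
  bact <- make_tier("bacterial", c("strainA", "strainB"), c(22L, 23L),
                    c(strain_seq, strain_seq))

  read_v <- record_with_quals("rv", "two_direction", substr(phage_seq, 101, 400),
                              rep(12L, 300))
  cls <- classify_read(read_v, list(viral, bact), toy_tax)
  expect_identical(cls$status, "assigned")
  expect_identical(cls$stage, "viral")
  expect_equal(cls$taxid, 31L)

  # tie between sibling strains -> species node via LCA
  read_b <- record_with_quals("rb", "two_direction",
                              substr(strain_seq, 51, 350), rep(12L, 300))
  cls_b <- classify_read(read_b, list(viral, bact), toy_tax)
  expect_identical(cls_b$stage, "bacterial")
  expect_equal(cls_b$taxid, 21L)
  expect_identical(cls_b$rank, "species")

  # a read present in both tiers is always assigned at the viral tier
  both <- make_tier("bacterial", "chrom", 21L,
                    paste0(other_seq, phage_seq, rnd_dna(200)))
  cls_2 <- classify_read(read_v, list(bact = both, viral = viral), toy_tax)
  expect_identical(cls_2$stage, "viral")

  # no qualifying hit anywhere -> unidentified
  cls_u <- classify_read(record_with_quals("ru", "two_direction",
                                           rnd_dna(300), rep(12L, 300)),
                         list(viral, bact), toy_tax)
  expect_identical(cls_u$status, "unidentified")
  expect_true(is.na(cls_u$taxid) && is.na(cls_u$stage))
})

test_that("classification conserves reads across host/assigned/unidentified", {
  w <- build_toy_world(seed = 71, bact_len = 10000, phage_len = 1000,
                       mito_len = 3000)
  models <- lapply(c(bacterium = 0.15, phage = 0.15, mammal_mito = 0.15),
                   function(e) error_model(e, length_median = 400,
                                           length_sigma = 0.3,
                                           length_min = 150,
                                           length_max = 1200))
  sim <- simulate_reads(w, c(bacterium = 1, phage = 1, mammal_mito = 1) / 3,
                        90, models, seed = 73)
  reads <- lapply(sim$groups, select_read)
  cls <- classify_batch(reads, toy_world_tiers(w), w$taxonomy)
  expect_equal(nrow(cls), 90)
  expect_true(all(cls$status %in% c("host", "assigned", "unidentified")))
  expect_equal(sum(table(cls$status)), 90)
  # status=assigned implies stage and taxid set; unidentified implies neither
  expect_true(all(!is.na(cls$taxid[cls$status == "assigned"])))
  expect_true(all(is.na(cls$taxid[cls$status == "unidentified"])))
})

test_that("reference choice applies completeness priority before read counts", {
  set.seed(79)
  tier <- make_tier("viral", c("NC_0001", "NC_0002", "part1"),
                    c(31L, 31L, 31L), c(rnd_dna(60), rnd_dna(60), rnd_dna(60)),
                    compl = c("complete_genome", "complete_genome", "partial"))
  # partial with 5 reads loses to complete genome with 3 reads
  hits <- data.frame(record_id = c(rep("part1", 5), rep("NC_0001", 3)))
  expect_identical(choose_reference(hits, tier), "NC_0001")
  # single candidate
  expect_identical(choose_reference(data.frame(record_id = "part1"), tier),
                   "part1")
  # equal counts in the top class tie-break lexicographically
  hits2 <- data.frame(record_id = rep(c("NC_0002", "NC_0001"), each = 4))
  expect_identical(choose_reference(hits2, tier), "NC_0001")
  expect_error(choose_reference(data.frame(record_id = character(0)), tier),
               "nonempty")
})

test_that("live counts track totals and proportions and default to 30s refresh", {
  tbl <- live_count_table()
  expect_equal(tbl$refresh_interval, 30)
  tbl0 <- update_live_counts(tbl, classify_batch(list(),
                                                 toy_world_tiers(
                                                   build_toy_world(
                                                     seed = 1,
                                                     bact_len = 2000,
                                                     phage_len = 200,
                                                     mito_len = 500)),
                                                 toy_tax))
  expect_equal(sum(tbl0$totals), 0)

  cls <- data.frame(
    read_id = paste0("r", 1:4),
    status = c("host", "host", "host", "assigned"),
    stage = c("host", "host", "host", "viral"),
    taxid = c(41L, 41L, 41L, 31L), rank = NA, name = NA, record_id = NA,
    evalue = NA, identity = NA, bit_score = NA, stringsAsFactors = FALSE)
  tbl1 <- update_live_counts(tbl, cls, batch_index = 0L)
  expect_equal(unname(tbl1$totals), c(3L, 1L, 0L))
  expect_equal(sum(tbl1$totals), nrow(cls))
  json <- jsonlite::fromJSON(emit_report(tbl1, toy_tax, timestamp = FALSE))
  expect_equal(json$totals$host, 3)
  props <- setNames(json$entries$proportion, json$entries$taxid)
  expect_equal(unname(props[["41"]]), 0.75)
  expect_equal(unname(props[["31"]]), 0.25)
  expect_identical(json$entries$stage[json$entries$taxid == 31], "viral")
})
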