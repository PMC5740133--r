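loose <- function(w = 8) scoring_scheme(word_size = w, evalue_cutoff = 1e6)

test_that("the seed index counts postings by sliding windows and skips short or ambiguous words", {
  set.seed(101)
  idx <- build_index(c(r1 = rnd_dna(40)), w = 16)
  expect_equal(n_postings(idx), 25)  # 40 - 16 + 1
  expect_equal(idx$total_db_length, 40)

  idx2 <- build_index(c(short = rnd_dna(10), long = rnd_dna(20)), w = 16)
  expect_equal(n_postings(idx2), 5)  # short record contributes nothing

  withN <- paste0(rnd_dna(16), "N", rnd_dna(16))
  idx3 <- build_index(c(r = withN), w = 16)
  expect_equal(n_postings(idx3), 2)  # only the two N-free words

  expect_error(build_index(c(r = "ACGT"), w = 3), "word_size")
  expect_error(build_index(data.frame()), "nonempty")
})

test_that("scheme defaults follow megablast-like conventions", {
  s <- scoring_scheme()
  expect_equal(s$word_size, 16L)
  expect_equal(s$evalue_cutoff, 1e-5)
  expect_equal(c(s$match, s$mismatch, s$gap), c(1L, -2L, -2L))
  expect_error(scoring_scheme(word_size = 2), "word_size")
  expect_error(scoring_scheme(match = -1), "match")
})

test_that("an exact-copy read yields one full-length perfect hit", {
  set.seed(7)
  ref <- rnd_dna(500)
  idx <- build_index(c(ref1 = ref), w = 16)
  hits <- align_read(ref, idx, scoring_scheme())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 100)
  expect_equal(hits$raw_score, 500)
  expect_equal(c(hits$q_start, hits$q_end), c(0L, 500L))
  expect_equal(c(hits$s_start, hits$s_end), c(0L, 500L))
  expect_identical(hits$strand, "+")
})

test_that("seed-and-extend equals exhaustive local DP on planted-seed pairs", {
  set.seed(11)
  for (i in 1:120) {
    core <- rnd_dna(sample(12:30, 1))
    q <- paste0(rnd_dna(sample(0:40, 1)), core, rnd_dna(sample(0:40, 1)))
    s <- paste0(rnd_dna(sample(0:40, 1)), core, rnd_dna(sample(0:40, 1)))
    if (runif(1) < 0.3)
      q <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    hits <- align_read(q, build_index(c(r1 = s), w = 8), loose())
    expect_equal(max(hits$raw_score), sw_best_score(q, s),
                 info = paste("pair", i))
  }
})

test_that("a single internal substitution scores 27 under the default scheme", {
  set.seed(13)
  core <- rnd_dna(30)
  subj <- paste0(rnd_dna(15), core, rnd_dna(15))
  q <- core
  substr(q, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                               substr(q, 15, 15))[1]
  hits <- align_read(q, build_index(c(r1 = subj), w = 8), loose())
  expect_equal(hits$raw_score[1], 27)
  expect_equal(hits$raw_score[1], sw_best_score(q, subj))
})

test_that("aligning the reverse complement flips the strand but not the score", {
  set.seed(17)
  ref <- rnd_dna(800)
  idx <- build_index(c(r1 = ref), w = 16)
  scheme <- loose(16)
  read <- substr(ref, 101, 400)
  h_fwd <- align_read(read, idx, scheme)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h_rev <- align_read(rc, idx, scheme)
  expect_identical(h_fwd$strand[1], "+")
  expect_identical(h_rev$strand[1], "-")
  expect_equal(h_fwd$raw_score[1], h_rev$raw_score[1])
  expect_equal(h_fwd$s_start[1], h_rev$s_start[1])
  expect_equal(h_fwd$s_end[1], h_rev$s_end[1])
})

test_that("e-values follow the Karlin-Altschul closed form", {
  set.seed(19)
  idx <- build_index(c(r1 = rnd_dna(60)), w = 8)
  scheme <- scoring_scheme(word_size = 8)
  # oracle: direct evaluation of E = m n 2^(-(lambda S - ln K)/ln 2)
  expected <- 30 * 60 * 2^(-((1.28 * 27 - log(0.46)) / log(2)))
  expect_equal(compute_evalue(27, 30, idx, scheme), expected)
  # monotonicity in score
  expect_lt(compute_evalue(28, 30, idx, scheme),
            compute_evalue(27, 30, idx, scheme))
  # linearity in database size
  idx2 <- build_index(c(r1 = rnd_dna(60), r2 = rnd_dna(60)), w = 8)
  expect_equal(compute_evalue(27, 30, idx2, scheme),
               2 * compute_evalue(27, 30, idx, scheme))
  expect_error(compute_evalue(-1, 30, idx, scheme), "raw_score")
})

test_that("reads shorter than the word size return empty results, not errors", {
  set.seed(23)
  idx <- build_index(c(r1 = rnd_dna(100)), w = 16)
  expect_equal(nrow(align_read("ACGTACGTACGT", idx, scoring_scheme())), 0)
})

test_that("rescue alignment seeds shorter matches at word size 11 and cutoff 1e-8", {
  set.seed(29)
  ref <- rnd_dna(4000)
  # a diverged region whose exact stretches are 12-14 nt: never seedable at
  # w = 16, always seedable at w = 11
  region <- substr(ref, 1001, 1060)
  q <- region
  for (p in c(13, 27, 41, 55))
    substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
  idx16 <- build_index(c(r1 = ref), w = 16)
  expect_equal(nrow(align_read(q, idx16, scoring_scheme())), 0)
  idx11 <- rescue_index(idx16)
  expect_equal(idx11$word_size, 11L)
  got <- rescue_align(q, idx11)
  expect_gt(nrow(got), 0)
  expect_true(all(got$evalue <= 1e-8))
  expect_error(rescue_align(q, idx16), "word size 11")

  # on a read seedable at both word sizes the best record agrees
  read <- substr(ref, 2001, 2300)
  a <- align_read(read, idx16, scoring_scheme())
  b <- rescue_align(read, idx11)
  expect_identical(a$record_id[1], b$record_id[1])
  expect_equal(a$raw_score[1], b$raw_score[1])
})

test_that("raising the e-value cutoff never removes hits", {
  set.seed(31)
  ref <- rnd_dna(2000)
  idx <- build_index(c(r1 = ref), w = 8)
  read <- paste0(substr(ref, 501, 560), rnd_dna(40))
  strict <- align_read(read, idx, scoring_scheme(word_size = 8,
                                                 evalue_cutoff = 1e-10))
  lax <- align_read(read, idx, scoring_scheme(word_size = 8,
                                              evalue_cutoff = 1e-2))
  key <- function(h) paste(h$record_id, h$strand, h$s_start, h$s_end)
  expect_true(all(key(strict) %in% key(lax)))
})

test_that("simulated reads align to their source with identity above 1 - 2*error", {
  w <- build_toy_world(seed = 41, bact_len = 12000, phage_len = 1200,
                       mito_len = 2000)
  eps <- 0.10
  models <- list(bacterium = error_model(eps, length_median = 400,
                                         length_sigma = 0.3,
                                         length_min = 150, length_max = 1500))
  sim <- simulate_reads(w, c(bacterium = 1), 100, models, seed = 43,
                        no2d_fraction = 0)
  idx <- build_index(c(bacterium = w$genomes[["bacterium"]]), w = 16)
  idents <- vapply(sim$groups, function(g) {
    h <- align_read(g$variants$two_direction, idx, scoring_scheme())
    if (nrow(h) == 0) return(NA_real_)
    h$identity[1]
  }, numeric(1))
  expect_gte(mean(idents >= (1 - 2 * eps) * 100, na.rm = TRUE), 0.95)
  # banded-DP identity of reads vs their true interval centres near 1 - eps
  med <- median(idents, na.rm = TRUE)
  expect_gt(med, 88)
  expect_lt(med, 95)
})

test_that("tabular hit output is 1-based with reversed subject coordinates on minus strand", {
  set.seed(47)
  ref <- rnd_dna(300)
  idx <- build_index(c(r1 = ref), w = 16)
  read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(ref, 51, 150))))
  hits <- align_read(read, idx, loose(16))
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- write_hits_tsv(hits, f)
  expect_identical(out$q_start, 1L)
  expect_identical(out$q_end, 100L)
  expect_equal(out$s_start, 150)   # reversed: start > end on minus strand
  expect_equal(out$s_end, 51)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12)
})
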