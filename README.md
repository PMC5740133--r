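# nanotax

Real-time taxonomic classification of nanopore metagenomic reads, at
desk scale and with no external downloads.

Early nanopore sequencers write data molecule by molecule while the run
is still going, with long reads (median ~5–6 kb, extremes from 80 bp to
>70 kb) and per-read error rates of 15–20%. `nanotax` implements the
analysis stack that turns such a stream into live microbial
identification:

* **Read selection** — each molecule may carry a 2D basecall and 1D
  template/complement basecalls; the 2D read is taken where available,
  otherwise the higher mean-Phred 1D read.
* **Batch streaming** — a run directory is polled and selected reads
  are processed in batches of 200 as files appear, until a
  `RUN_COMPLETE` sentinel.
* **Seed-and-extend aligner** — an exact w-mer index (word size 16),
  greedy diagonal chaining, and gapped x-drop extension under
  match +1 / mismatch −2 / linear gap −2, with Karlin–Altschul
  statistics: `bit = (λS − ln K)/ln 2`, `E = m·n·2^(−bit)`
  (λ = 1.28, K = 0.46). Hits are kept at E ≤ 1e−5; a sensitive rescue
  mode (word size 11, E ≤ 1e−8) retries unidentified reads.
* **Cascade classification** — host subtraction, then viral, bacterial
  and optional non-chordate eukaryotic tiers in order; the first tier
  with a qualifying hit wins; the best hit by e-value is retained and
  exact bit-score ties are resolved to the lowest common ancestor (LCA)
  of the tied taxa; live counts are emitted as a JSON report (30 s
  refresh cadence in streaming mode).
* **Directed analysis** — unique per-read species counts with phage
  precedence (the phage genome is integrated in the bacterial
  chromosome, so tied reads count as phage), per-reference coverage
  maps, strict-majority pileup consensus, and banded global pairwise
  identity of consensus versus reference.
* **Simulator** — a nanopore-like read generator (log-normal lengths,
  substitution/insertion/deletion errors at per-organism rates of
  18.4/17.2/15.9%, 2D/1D variant structure, truth labels) so every
  stage is testable offline.

## Worked example

```r
library(nanotax)

world <- build_toy_world(seed = 1, bact_len = 20000, phage_len = 2000,
                         mito_len = 5000)
sim <- simulate_reads(world, c(bacterium = 1, phage = 1, mammal_mito = 1) / 3,
                      n = 300, seed = 1)
run_dir <- file.path(tempdir(), "demo_run")
write_run_directory(sim$groups, run_dir, files_per_flush = 100)

res <- run_pipeline(run_dir, toy_world_tiers(world), world$taxonomy,
                    batch_size = 200, mode = "oneshot")
res$live_table$totals
#>         host     assigned unidentified
#>          105          190            5

head(res$classifications[, c("read_id", "status", "stage", "taxid",
                             "evalue", "identity")], 5)
#>     read_id   status     stage taxid        evalue identity
#> 1 mol000001 assigned     viral    31  0.000000e+00 83.77519
#> 2 mol000002     host      host    41  0.000000e+00 83.72840
#> 3 mol000003     host      host    41  0.000000e+00 83.56251
#> 4 mol000004 assigned bacterial    21 1.983588e-272 73.01708
#> 5 mol000005 assigned     viral    31 4.441157e-254 74.19043
```

Every read lands in exactly one of host / assigned / unidentified.
The `identity` column is the per-read alignment identity (~74–84% at
these error rates — this is what raw 2D nanopore data looked like);
`evalue` is the Karlin–Altschul expectation of the retained best hit.
Scoring against the simulation truth and counting each read once with
phage precedence:

```r
score_classifications(res$classifications, sim$truth, world)$accuracy
#> [1] 1

reads <- collect_selected_reads(run_dir)
hits <- organism_best_hits(reads, world$genomes)
unique_species_counts(hits, vapply(reads, function(r) r$molecule_id,
                                   character(1)))
#>      organism count proportion
#> 1   bacterium    89  0.3016949
#> 2 mammal_mito   105  0.3559322
#> 3       phage   101  0.3423729
```

All 190 assigned reads carry the taxid of (or an ancestor of) their
true source organism, and the equimolar mixture is recovered at roughly
one-third per organism.

## Command line

A thin wrapper is installed at `inst/scripts/nanotax`:

```sh
nanotax simulate --seed 1 --n 600 --out demo/
nanotax classify --run-dir demo/run --host-fasta host.fasta \
    --viral-fasta viral.fasta --bacterial-fasta bact.fasta \
    --taxonomy demo/taxonomy.tsv --out-dir demo/cls --mode stream
nanotax report --run-dir demo/run --refs demo/references.fasta \
    --out-dir demo/rep
```

Flags can come from a flat `key=value` file via `--config` (explicit
flags win); `--deterministic` drops timestamps so identical seeds give
byte-identical outputs; exit codes are 0 (success), 1 (runtime
failure), 2 (usage/configuration error).

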