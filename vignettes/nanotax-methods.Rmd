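---
title: "Methods: real-time taxonomic classification of nanopore reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time taxonomic classification of nanopore reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotax)
```

## The problem

Early nanopore sequencing produced long (kilobase-scale) reads with
per-base error rates of 15–20%, written out molecule by molecule as the
run progressed. `nanotax` implements the analysis that makes such data
useful for *in situ* metagenomic identification: watch a download
directory, pick the best basecall per molecule, subtract the host,
classify the remaining reads against tiered reference databases, report
running organism counts, and — once enough reads accumulate — recover an
accurate consensus sequence despite the high per-read error.

The package targets the canonical three-organism validation mixture:
equimolar genomic DNA from a bacterium, a phage, and a mammal, with the
mitochondrial genome standing in for the mammalian reference at desk
scale. One deliberate wrinkle is preserved: the phage genome is
integrated verbatim in the bacterial chromosome, so reads from that
region are attributable to both organisms.

## Read selection

The 2D chemistry basecalls each molecule up to three ways: a template
strand read, a complement strand read, and a higher-accuracy 2D read
combining both. `select_read()` takes the 2D read where available and
otherwise the 1D read with the higher arithmetic mean Phred quality,
with exact ties going to the template strand. The original analysis does
not state which quality statistic it used; mean Phred is the
conventional proxy and is the documented choice here. Per-molecule
grouping uses a FASTQ dialect with read IDs `<molecule>_<variant>`
(variant `2d`, `template`, or `complement`), standing in for one-read-
per-FAST5 file layouts without any HDF5 machinery.

Streaming (`batch_stream()`) polls the run directory (default every
2 s), processes FASTQ files in lexicographic order, and emits batches of
200 selected reads (the batch size used in the original real-time
simulation); a `RUN_COMPLETE` sentinel file terminates the stream and
flushes the final partial batch. Polling rather than filesystem events
keeps the behaviour portable and deterministic under test.

## The aligner

Classification-grade alignment is provided by a from-scratch
seed-and-extend local aligner (`align_read()`):

* exact `w`-mer seeds (default `w = 16`, the word size used by the
  original cascade) located via a hash index of the reference forward
  strands; the query is searched in both orientations, so the search
  space size `n` stays the summed reference length;
* greedy chaining of seeds on each (record, diagonal), with chains split
  where consecutive seeds are more than 200 bases apart;
* gapped x-drop extension (drop-off 20) from the seed nearest each
  chain's midpoint, under match +1, mismatch −2, and linear gap −2 per
  column;
* overlapping hits on one record merged keeping the highest raw score;
* Karlin–Altschul statistics with `lambda = 1.28`, `K = 0.46`:
  `bit = (lambda*S − ln K)/ln 2`, `E = m*n*2^(−bit)`, and hits filtered
  at the tier cutoff (default `1e-5`; the sensitive rescue mode uses
  word size 11 and `1e-8`).

The original pipeline names tools and cutoffs but no scoring scheme;
the +1/−2 linear-gap constants are conventional megablast-like choices
and are exposed in `scoring_scheme()`. Linear (not affine) gaps keep
the dynamic programming simple; affine gaps are a documented extension
point. Two performance guards are deliberate implementation choices:
seeds whose `w`-mer occurs more than 200 times in the database are
skipped (a standard repeat filter), and a chain whose anchor falls
inside an already-extended hit on a nearby diagonal (within 50) is not
re-extended. Neither affects the oracle-equivalence tests, which
compare best raw scores against exhaustive Smith–Waterman on planted-
seed instances.

## Classification cascade

Tiers are queried in a fixed order — host, viral, bacterial, optionally
non-chordate eukaryotic — and the first tier producing any hit at or
below its e-value cutoff terminates the cascade. Host hits remove the
read from microbial consideration (host subtraction). Within the
terminating tier the best hit by ascending e-value then descending bit
score is retained; when several hits tie exactly on the maximum bit
score, the read is assigned the lowest common ancestor of the tied
taxids. Exact ties are the only parameter-free reading of "multiple top
hits", and are what the tests pin down. The source text is ambiguous
about whether host subtraction used the host genome or a comprehensive
nucleotide database; this implementation follows the methods wording
(a host reference tier).

Reference records carry their taxid and completeness class in the FASTA
header (`taxid=<int> completeness=complete_genome|complete_sequence|partial`).
`choose_reference()` picks the representative record per species by
treating completeness as a filter (best class present) and read count as
the ranking within that class, with lexicographic tie-breaks — the
reading under which the stated priority order is actually meaningful.

`update_live_counts()`/`emit_report()` maintain the running count table
and write the JSON feed a refreshing donut chart would poll (default
refresh 30 s in streaming mode). Totals (host/assigned/unidentified)
always sum to the number of reads processed.

## Directed analysis and consensus

For known targets, the directed layer (`organism_best_hits()`,
`unique_species_counts()`) aligns each read against each organism
reference and counts it exactly once. Because the phage genome occurs
verbatim inside the bacterial chromosome, a read wholly from the
integrated region hits both references equally well; such reads are
counted as phage (phage precedence). A read that extends beyond the
integrated region scores strictly better against the bacterium and is
counted as bacterial — precedence only resolves genuine ties, so the
blanket "assign all phage reads to the phage" rule does not siphon off
unambiguous bacterial reads.

`map_reads()` places each read via its best local hit, then realigns it
end-to-end with a banded fitting alignment (free reference end gaps)
inside a padded window, producing a CIGAR. `pileup_consensus()` calls,
per reference column, the strict majority (> 50% of covering reads)
over aligned bases; a strict gap majority deletes the column; without a
strict majority the reference base is kept; depth-0 columns emit `N`.
Insertions are included only when a strict majority of reads spanning
the junction contain one. The original study delegated consensus
calling to a GUI package without stating rules; strict majority with
reference fallback is the package's own, documented choice.

`consensus_identity()` is an end-to-end banded global alignment whose
identity denominator includes gap columns (the "fraction identity"
convention of the pairwise readout being emulated). The band defaults
to 0.2 × the longer length and widens automatically — with a logged
notice — whenever it cannot connect the endpoints or the optimal path
touches the band edge, so banded and unbanded identities agree whenever
the optimum fits the band.

When quoting a consensus error rate the package trims leading and
trailing zero-depth columns first: terminal coverage gaps reflect where
reads happened to start at finite depth, not consensus accuracy.
Interior zero-depth columns remain `N` and still count as errors.

## The simulator

`simulate_reads()` emulates the statistical signature of R7-era 2D
nanopore data rather than the signal-level process:

* **Error rates.** Defaults of 18.4% (mouse/host), 17.2% (bacterium),
  15.9% (phage) total error, split 50/25/25 across substitutions,
  insertions and deletions — only total rates are reported for the real
  data, so the split is a package choice. Each template base
  independently suffers deletion or substitution (mutually exclusive
  draws), and each junction independently gains a single inserted base.
  This construction makes the expected realized edit fraction exactly
  the configured total, which is what the parameter-recovery tests
  check to within three standard errors.
* **Read lengths.** Log-normal, parameterized by median (default 5,500,
  matching the reported 5,000–6,000 range) and log-sigma 0.6, truncated
  exactly (inverse-CDF sampling) to [80, 72,619] — the printed extreme
  read lengths. The distribution family itself is unreported; log-normal
  is the field's usual choice for nanopore length distributions.
* **1D variants.** Generated at 2× the 2D error rate (capped at 75%
  total), consistent with the reported 1D accuracy (74–80%) versus 2D
  (83–92%) without claiming a generative model; 20% of molecules lack a
  2D read by default. Both knobs are configurable and not inferred from
  any data.
* **Qualities.** Flat per variant at `round(−10·log10(total_error))` —
  the simplest encoding consistent with the realized error rate.

What the simulator does *not* model: homopolymer-biased errors,
context-dependent error clustering, chimeras, adapter sequence, quality
ramps along the read, or circular genomes (reads never wrap an origin).
Passing tests therefore demonstrate correctness of the pipeline's
algorithms under a realistic error *rate*, not robustness to every
artefact of real flowcells; the real-data reproduction (pooled counts,
per-organism length statistics) is out of desk scale and not claimed.

## Numerical choices and degenerate inputs

* Reads shorter than the word size return empty hit lists, not errors;
  empty groups and empty batches are contract violations and no-ops
  respectively.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  tabular output, with subject coordinates reversed on the minus
  strand (BLAST tabular convention).
* Tie-breaks are total and documented everywhere randomness is absent:
  hit sorting (e-value, bit score, record id), reference choice
  (completeness, count, id), selection (template over complement),
  unique counting (phage precedence, then lexicographic).
* All stochastic components consume one local, seeded RNG stream and
  restore the caller's RNG state, so identical seeds give byte-identical
  worlds, reads, and run directories in any calling context.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run entirely from simulation: a
50 kb bacterium with an embedded 5 kb phage and a 16 kb mitochondrion;
3,000 equimolar reads at the per-organism default error rates for the
end-to-end check (shorter reads, median 600, for the 2,000-read-per-
organism calibration check); 500 planted-seed pairs against exhaustive
Smith–Waterman; 1,000 random subsets of a 200-node taxonomy against
brute-force LCA; and a 2.5 kb reference at mean depth ≈ 37 for the
consensus check. These sizes were chosen as the smallest at which the
statistical assertions (3-standard-error bands, the 99% recovery bound,
the <2% consensus error bound) are comfortably powered.

## Known limitations

* E-value parameters (`lambda`, `K`) are fixed conventional constants,
  not fitted to the scoring scheme; absolute e-values are therefore
  approximate, which is harmless for thresholding and ranking but not
  for cross-tool comparison.
* The aligner is not a drop-in reimplementation of any named tool;
  agreement with exhaustive local DP is guaranteed only when an exact
  seed lies on the optimal path and the path never dips more than the
  x-drop below its running best.
* Host subtraction, like the cascade generally, is only as good as the
  host tier provided; at desk scale the mitochondrion stands in for a
  full host genome.
* The live report is a JSON feed; rendering (the donut chart) is out of
  scope.
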