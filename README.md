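# blastr

Parse, store and query NCBI BLAST plain-text ("pairwise") reports in R —
losslessly.

## The problem

Large similarity searches with `blastp`, `blastn`, `blastx` or `psiblast`
produce multi-query plain-text reports that are easy to read by eye and
painful to work with programmatically. Most parsers throw information away
— typically the alignments themselves — and force a full re-parse every
time a single result is needed. `blastr` is for pipelines (e.g. annotating
de novo transcriptome assemblies against a reference protein set) that
need three things at once:

1. **Lossless parsing.** Every report is modelled as a hierarchy — one
   `query_result` per query, one `iteration` per PSI-BLAST round, one
   `subject_alignment` per database hit, one `hsp` (high-scoring segment
   pair) per local alignment — and the verbatim header, one-line-summary
   and Karlin–Altschul footer blocks are retained alongside the parsed
   fields. Alignments (query string, midline, subject string) are kept in
   full.
2. **Random access without re-parsing.** A whole report is written once to
   a single database file keyed by query id; any result can then be
   fetched directly, now or in a later session, without touching the
   original report.
3. **SQL-like querying.** Filter by e-value or identity percentage, sort
   by identity within each query, or look up all hits of one query or one
   subject, and export the flat tables.

## The model in brief

Each HSP carries the statistics exactly as printed on its grades lines:

```
Score = 166 bits (419), Expect = 3e-39
Identities = 168/468 (35%), Positives = 184/468 (39%), Gaps = 69/468 (14%)
```

bit score and raw score, the e-value (token preserved verbatim, so
`e-104`-style bare exponents round-trip), and the identity/positive/gap
counts n/L with their printed percentages. BLAST *truncates* those
percentages — `floor(100·n/L)`, so 69/468 prints 14%, not 15% — and
`blastr` stores both the counts and the printed value, with the floor
relation kept as a checked invariant rather than a substitute for parsing.
Coordinates are stored exactly as printed (1-based, inclusive, descending
on minus strands; nucleotide units with a 3× step for translated blastx
queries), with strand and frame explicit.

Because real mixed-version BLAST output is awkward to assemble on demand,
the package also ships a deterministic synthetic-report generator with
exact ground truth; `parse(render(model)) == model` is the package's
central correctness oracle.

## Worked example

```r
library(blastr)

report <- "example.blast"
writeLines(generate_report(generator_spec(seed = 42, num_queries = 3,
  program_family = "blastp", subjects_per_query = c(2L, 3L))), report)

built <- build_store("example.db", report)   # parse + store in one pass
h <- built$handle
get_general_info(h)
#> <BLASTP 2.2.26> database: uniref100
#>   Posted date: May 30, 2007 11:40 PM
list_query_ids(h)
#> [1] "SYNQ00001.Contig74" "SYNQ00002.Contig75" "SYNQ00003.Contig12"

qr <- get_result(h, "SYNQ00001.Contig74")    # direct access, one record read
qr
#> <blast_query_result> SYNQ00001.Contig74 (163 letters), 1 iteration(s), 2 alignment(s)
cat(format_hsp_stats(qr$iterations[[1]]$alignments[[1]]$hsps[[1]]$stats), sep = "\n")
#> Score = 54.1 bits (119), Expect = 7e-113
#> Identities = 27/65 (41%), Positives = 37/65 (56%), Gaps = 5/65 (7%)

tab <- select_where_evalue_lower_than(h, 0.001, with_header = TRUE)
export_table(tab, no_timing = TRUE)
#> ##query | iter | subject | e-value
#> SYNQ00001.Contig74   0   UniRef100_9YTZCY   7e-113
#> SYNQ00001.Contig74   0   UniRef100_KS1U9V   2e-10
#> SYNQ00002.Contig75   0   UniRef100_NZ1RQ7   7e-56
#> SYNQ00002.Contig75   0   UniRef100_JSMWA7   9e-107
#> SYNQ00003.Contig12   0   UniRef100_9BLAL4   2e-94
#> SYNQ00003.Contig12   0   UniRef100_Y5LSYM   4e-164
#> retrieved 6 results; query time: 0 seconds

glance(h)
#> # A tibble: 1 × 7
#>   program database  n_queries n_alignments n_hsps min_evalue median_identity_pct
#> 1 BLASTP  uniref100         3            6      9     4e-164                  42
close_store(h)
```

The exported table has one row per (query, round, subject), summarised by
that subject's best HSP (lowest e-value, ties to the higher bit score);
the filter is a strict inequality. `tidy(h)` gives the per-HSP flat tibble
for dplyr/ggplot2 work, and `autoplot()` on any result table draws a
quick-look histogram.

A thin command-line wrapper (`inst/cli/blastr`) exposes the same
operations as `store`, `info`, `list`, `get`, `query` and
`export-fixture` subcommands for shell pipelines; see `run_cli()`.

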