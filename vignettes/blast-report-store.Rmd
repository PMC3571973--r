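---
title: "Lossless BLAST report parsing, storage and querying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless BLAST report parsing, storage and querying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastr)
```

## Scope and model

`blastr` reads the classic plain-text ("pairwise") output of NCBI BLAST —
`blastp`, `blastn`, `blastx` and `psiblast`, in the legacy layout up to
version 2.2.26 — and models it without loss of information. The object
hierarchy mirrors the report structure:

* `general_info`: program, version, database name and statistics, with the
  verbatim header block retained;
* `query_result`: one per `Query=` block, holding id (the first
  whitespace-delimited token of the title), the full title, the query
  length, the verbatim one-line-summary block(s), and the parsed footer;
* `iteration`: one per search round. PSI-BLAST reports print
  `Results from round N`; the stored `round_index` is 0-based and
  consecutive, and every non-PSI-BLAST program gets exactly one iteration
  with index 0, which is also what the flat tables print in their
  `iter`/`round` column;
* `subject_alignment`: one per `>` anchor, with wrapped description lines
  joined by single spaces;
* `hsp`: one per `Score =` anchor, carrying the statistics and the three
  gapped alignment strings.

Two representational choices matter downstream.

**Percentages are truncated, not rounded.** The printed grades line
`Identities = 69/468 (14%)` shows `floor(100 * 69/468)`; rounding would
give 15. Five of the six percentage pairs in the package's worked example
discriminate the two rules, and all follow the floor. `blastr` stores both
the counts and the printed percentage; `compute_truncated_pct()` defines
the rule (in exact integer arithmetic) and the equality is validated as an
invariant rather than used as a substitute for parsing.

**Nothing is recomputed.** Bit scores, raw scores and e-values are parsed,
never recalculated; the e-value is additionally kept as its verbatim
token, so `format_hsp_stats()` reproduces a parsed grades block
byte-for-byte, including bare-exponent tokens like `e-104` (read with an
implicit mantissa of 1, the standard convention) and `0.0` for converged
PSI-BLAST hits. Coordinates stay exactly as printed — 1-based, inclusive,
descending for minus-strand subjects and negative frames — with strand and
frame stored explicitly instead of silently swapping endpoints. For
translated (blastx) queries the coordinate span covers 3 nucleotides per
aligned residue, an invariant checked only when a `Frame =` line was
parsed.

## Parsing strategy

The parser streams push-style: `scan_query_blocks()` splits the input at
`Query=` anchors and yields one block at a time, so peak memory is bounded
by the largest single query block rather than the file. Within a block,
simple line-anchored regular expressions mark the sections: the program
name line, `Results from round`, the line-initial `>`, `Score =`, and the
indented `Database:` block that opens the per-query footer. The midline of
each alignment triplet is recovered by the column offset of the sequence
field in its flanking `Query:` line, which preserves leading spaces
(mismatch columns) exactly.

Both length-line dialects are accepted: the legacy parenthetical
`(468 letters)` / `Length = 500` and the later `Length=468` keyword form.

Malformed sections follow a *skip-and-diagnose* policy: a corrupt query
block is dropped, a warning with its line number is recorded, and parsing
continues — applications working with heterogeneous or interrupted BLAST
runs need the intact results more than they need an abort. `strict = TRUE`
turns the first corrupt block into an error (`blastr_corrupt_block`). A
corrupt *final* block additionally sets the `truncated` diagnostic flag,
the common symptom of a killed BLAST job. Detected failures include
missing length declarations, subjects without HSPs, malformed `Score =`
lines, segment-length mismatches within a triplet, and coordinate
discontinuities between consecutive triplets.

## Storage design

`build_store()` writes each result record as soon as its block is parsed,
so report size does not drive memory. The store is a single file by
design — one artifact per report avoids the bookkeeping confusion of
per-query files — containing an 8-byte magic, one serialized record per
query result, a serialized metadata block (format-version tag, general
info, query order, offset index, build diagnostics), and a 16-byte trailer
locating the metadata. Opening reads only the trailer and metadata;
`get_result()` seeks straight to one record. The handle counts record
reads, which is how the tests demonstrate that fetching 1 of 1000 results
touches 1 record while full iteration touches 1000.

Open questions the format had to settle:

* *Iteration order* is input (report) order — the only reproducible
  choice — and `list_query_ids()` shares the same metadata.
* *Duplicate query ids* are allowed at parse time; in the store the later
  record wins, the first position in the order is kept, and a diagnostic
  warning is recorded.
* A *format-version tag* is checked on open (`blastr_incompatible_store`
  on mismatch); silent misreads of stale files are worse than a hard
  error.

## Query semantics

The five manager operations produce flat tables with one row per
(query, iteration, subject), summarised by the subject's **best HSP**:
minimal e-value, ties broken by maximal bit score, then report order
(`best_hsp()`). One row per subject is what the classic table output
prints even when an alignment holds several HSPs, and predicates evaluate
the same representative row that is displayed. The per-HSP view is
available as `tidy()` on a store or a single result.

* `select_where_evalue_lower_than()` and
  `select_where_identity_pct_higher_than()` are *strict* inequalities
  ("lower than" / "higher than"); boundary values are excluded, and the
  tests pin this at the boundary. Thresholds outside their domain
  (negative e-values, percentages outside [0, 100]) are rejected.
* `sort_by_identity_pct()` keeps queries in stored order and sorts
  descending by identity within each query, ties by ascending e-value
  then original subject order (stable).
* `select_by_query_id()` errors on unknown ids (`blastr_missing_query`);
  `select_by_subject_id()` returns an empty table for absent subjects —
  an absent hit is an answer, an absent query is a mistake.

Exported tables print percent columns with one decimal (`95.0`), e-values
as their stored tokens, tab separators, and a
`retrieved N results; query time: S seconds` trailer. The timed quantity
is predicate evaluation and row assembly, not store I/O or export. The
`descr` column of the by-query schema is printed empty: the classic
format reserves the column but its rows show no value, so emitting the
empty string keeps the column count stable. A `no_timing` flag zeroes the
elapsed field so outputs can be compared byte-for-byte.

## The synthetic-report generator

`generator_spec()` + `generate_model()` + `render_report()` produce
reports with exact ground truth, and `parse(render(model)) == model` —
checked with `identical()`, not numeric tolerance — is the package's
central oracle, exercised over seeded models spanning all four program
families and both length-line dialects.

What the generator emulates: multi-query reports; PSI-BLAST rounds with
`CONVERGED!`; one-line summary sections; wrapped subject descriptions;
gapped alignments wrapped at 60 columns (the standard layout; tunable);
midlines built by the letter/`+`/space convention for proteins and
`|`/space for nucleotides; truncated percentages; minus-strand and
negative-frame coordinates; comma-grouped number formatting; both length
dialects. Defaults — up to a few subjects per query, 1–2 HSPs per
subject, 30–90 alignment columns, 8% gap columns, 45% identity — are
ordinary mid-range protein-search values.

What it deliberately does not emulate: scores, e-values and sequences are
arbitrary self-consistent draws, not Karlin–Altschul statistics; residues
come from a reduced alphabet with a fixed toy similarity rule (fixed
residue groups, positives = same group) so the positives count is
well-defined without a real substitution matrix; bit scores do not
correlate with e-values. Passing round-trip tests therefore demonstrates
format coverage and losslessness, not statistical realism, and version-
specific quirks of real BLAST builds outside the emulated layout (e.g.
tblastn/tblastx output, XML or tabular modes) are out of scope and are
surfaced as diagnostics rather than guessed at.

Two generator details exist purely to keep models renderable: every
60-column wrap window must retain at least one residue on each sequence
(gap placement is re-rolled otherwise, since an all-gap segment has no
printable coordinates), and percentages/counts are drawn first with
strings constructed to match, never the reverse.

`corrupt_report()` derives robustness fixtures deterministically:
truncation inside the final block, a mangled `Score =` line, or a deleted
subject length declaration.

## Problem sizes in the test suite

The acceptance-grade checks run at: 100 seeded models for render→parse
identity; 100 stores for store/load identity plus a 1000-query store for
the random-access count; a 200-query, 2-round PSI-BLAST store with 3–4
HSPs per subject for manager/oracle agreement; 30 corruption runs; and a
10,000-query report (~340k lines) for the parse-and-store scalability
smoke test, which completes in well under its 15-minute budget on one
CPU. These sizes keep the full suite in the low minutes while still
exercising every format feature.

## Known limitations

* Only the pairwise text layout is read: no XML (`-m 7`), tabular
  (`-m 8/9`) or archive formats, and no tblastn/tblastx.
* BLAST+ textual deviations beyond the `Length=` dialect are not
  specially handled; unrecognized sections end up in diagnostics or in
  the retained verbatim blocks.
* The store has a single writer and no incremental append; rebuilding
  from the report is the supported path.
* One `Iteration` per report round means classic programs always show
  round 0; code that assumes PSI-BLAST semantics elsewhere should check
  `program_name`.
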