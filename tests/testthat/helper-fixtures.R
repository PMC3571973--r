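# Shared fixtures and independent oracles. Everything is built in code;
# the two grades blocks below are the classic worked example this package's
# formatting is checked against.

GRADES_BLOCK_1 <- c(
  "Score = 166 bits (419), Expect = 3e-39",
  "Identities = 168/468 (35%), Positives = 184/468 (39%), Gaps = 69/468 (14%)"
)
GRADES_BLOCK_2 <- c(
  "Score = 157 bits (397), Expect = 1e-36",
  "Identities = 165/474 (34%), Positives = 180/474 (37%), Gaps = 79/474 (16%)"
)

quick_spec <- function(seed, ...) {
  args <- list(...)
  defaults <- list(seed = seed, num_queries = 3L,
                   subjects_per_query = c(1L, 3L),
                   hsps_per_subject = c(1L, 2L),
                   alignment_length = c(30L, 80L))
  do.call(generator_spec, utils::modifyList(defaults, args))
}

family_for_seed <- function(s) {
  c("blastp", "blastn", "blastx", "psiblast")[(s %% 4) + 1]
}
style_for_seed <- function(s) {
  c("parenthetical", "keyword")[(s %% 2) + 1]
}

roundtrip_spec <- function(s, num_queries = 2L) {
  fam <- family_for_seed(s)
  quick_spec(s, num_queries = num_queries, program_family = fam,
             rounds_per_query = if (fam == "psiblast") 2L else 1L,
             subjects_per_query = c(0L, 3L),
             length_line_style = style_for_seed(s))
}

# Independent best-HSP oracle: exhaustive scan, no ordering tricks.
oracle_best_hsp <- function(alignment) {
  best <- NULL
  for (h in alignment$hsps) {
    if (is.null(best) ||
        h$stats$evalue < best$stats$evalue ||
        (h$stats$evalue == best$stats$evalue &&
         h$stats$bit_score > best$stats$bit_score)) {
      best <- h
    }
  }
  best
}

# Independent flat view of a model: plain loops over the hierarchy, one row
# per (query, iteration, subject) via the oracle best HSP.
oracle_rows <- function(results) {
  out <- list()
  for (qr in results) {
    for (it in qr$iterations) {
      j <- 0L
      for (al in it$alignments) {
        j <- j + 1L
        b <- oracle_best_hsp(al)
        out[[length(out) + 1L]] <- data.frame(
          query_id = qr$query_id, query_length = qr$query_length,
          round_index = it$round_index, subject_order = j,
          subject_id = al$subject_id, evalue = b$stats$evalue,
          evalue_token = b$stats$evalue_token,
          align_length = b$stats$alignment_length,
          identity_pct = b$stats$identity_pct,
          num_gaps = b$stats$num_gaps,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_id = character(), round_index = integer(),
                      subject_id = character(), evalue = numeric(),
                      identity_pct = integer()))
  }
  do.call(rbind, out)
}

# A tiny model built entirely by hand (no RNG), with hand-computed
# statistics, used for golden-output checks. One query, one subject, one
# HSP of 10 columns: 7 identities, 1 extra positive, 1 mismatch, 1 query
# gap, so 70% / 80% / 10% by truncation.
make_tiny_model <- function() {
  info <- general_info(
    program_name = "BLASTP", program_version = "2.2.26",
    database_name = "uniref100",
    database_posted_date = "May 30, 2007 11:40 PM",
    database_num_sequences = 1000L, database_num_letters = 500000
  )
  info$raw_header <- paste(blastr:::render_general_header(info),
                           collapse = "\n")
  st <- hsp_stats(
    bit_score = 25.5, raw_score = 55, evalue = 2e-05,
    evalue_token = "2e-05", num_identities = 7L, num_positives = 8L,
    num_gaps = 1L, alignment_length = 10L
  )
  h <- hsp(
    stats = st, query_start = 1L, query_end = 9L,
    subject_start = 11L, subject_end = 20L,
    aligned_query = "ACDEFGHKI-",
    midline = "ACDEFGH+  ",
    aligned_subject = "ACDEFGHRWL"
  )
  al <- subject_alignment("SUBJ1", "synthetic test subject protein", 40L,
                          list(h))
  fs <- footer_stats(0.318, 0.135, 0.401, 0.267, 0.041, 0.14,
                     "BLOSUM62", 11L, 1L)
  fs$raw_footer <- paste(blastr:::render_footer_block(fs, info),
                         collapse = "\n")
  it <- iteration(0L, FALSE, list(al))
  qr <- query_result("QTEST", "QTEST alpha", 50L, list(it),
                     summary_text = paste(
                       blastr:::render_summary_block(list(al)),
                       collapse = "\n"),
                     footer = fs)
  list(info = info, results = list(qr))
}

write_report <- function(lines) {
  path <- tempfile(fileext = ".blast")
  writeLines(lines, path)
  path
}
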