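test_that("query blocks stream one per anchor and conserve the input", {
  spec <- quick_spec(21, num_queries = 3L)
  lines <- generate_report(spec)
  it <- scan_query_blocks(lines)
  blocks <- list()
  repeat {
    b <- it$next_block()
    if (is.null(b)) break
    blocks[[length(blocks) + 1L]] <- b
  }
  expect_length(blocks, 3)
  expect_identical(unlist(lapply(blocks, `[[`, "lines")), lines)
  starts <- vapply(blocks, `[[`, integer(1), "start_line")
  expect_identical(starts[1], 1L)
  expect_true(all(diff(starts) > 0))

  expect_error(parse_report(character()), class = "blastr_not_blast_report")
  expect_error(parse_report(c("not", "a", "blast", "file")),
               class = "blastr_not_blast_report")
})

test_that("streaming also works from a file connection", {
  spec <- quick_spec(22, num_queries = 4L)
  lines <- generate_report(spec)
  path <- write_report(lines)
  p <- parse_report(path)
  expect_length(p$results, 4)
  expect_identical(p$results, parse_report(lines)$results)
})

test_that("query block parsing recovers id, title and no-hit rounds", {
  m <- make_tiny_model()
  txt <- render_report(m$info, m$results)
  p <- parse_report(txt)
  expect_identical(p$results[[1]]$query_id, "QTEST")
  expect_identical(p$results[[1]]$query_title, "QTEST alpha")
  expect_identical(p$results[[1]]$query_length, 50L)

  nohit <- quick_spec(30, num_queries = 1L, subjects_per_query = c(0L, 0L))
  pn <- parse_report(generate_report(nohit))
  expect_length(pn$results, 1)
  expect_length(pn$results[[1]]$iterations, 1)
  expect_identical(pn$results[[1]]$iterations[[1]]$round_index, 0L)
  expect_length(pn$results[[1]]$iterations[[1]]$alignments, 0)
  expect_identical(nrow(pn$diagnostics$warnings), 0L)
})

test_that("psiblast rounds open consecutive iterations and record convergence", {
  spec <- quick_spec(31, num_queries = 2L, program_family = "psiblast",
                     rounds_per_query = 3L)
  m <- generate_model(spec)
  p <- parse_report(render_report(m$info, m$results))
  for (qr in p$results) {
    expect_identical(vapply(qr$iterations, `[[`, integer(1), "round_index"),
                     0:2)
  }
  expect_identical(
    lapply(p$results, function(q) vapply(q$iterations, `[[`, logical(1),
                                         "converged")),
    lapply(m$results, function(q) vapply(q$iterations, `[[`, logical(1),
                                         "converged"))
  )
})

test_that("subject blocks join wrapped descriptions and split HSPs on Score anchors", {
  block <- c(
    ">UniRef100_Q2IMJ3 putative uncharacterized protein of",
    "          considerable length wrapped over three report",
    "          lines entirely",
    "          Length = 40",
    "",
    " Score = 25.5 bits (55), Expect = 2e-05",
    " Identities = 6/6 (100%), Positives = 6/6 (100%)",
    "",
    "Query: 1      ACDEFG  6",
    "              ACDEFG",
    "Sbjct: 11     ACDEFG  16",
    "",
    " Score = 20.1 bits (41), Expect = 0.004",
    " Identities = 6/6 (100%), Positives = 6/6 (100%)",
    "",
    "Query: 7      GFEDCA  12",
    "              GFEDCA",
    "Sbjct: 21     GFEDCA  26",
    ""
  )
  al <- parse_subject_block(block)
  expect_identical(al$subject_id, "UniRef100_Q2IMJ3")
  expect_identical(
    al$subject_description,
    "putative uncharacterized protein of considerable length wrapped over three report lines entirely"
  )
  expect_identical(al$subject_length, 40L)
  expect_length(al$hsps, 2)
  expect_identical(al$hsps[[2]]$stats$evalue_token, "0.004")

  expect_error(parse_subject_block(block[-4]), class = "blastr_corrupt_block")
  expect_error(parse_subject_block(block[1:5]), class = "blastr_corrupt_block")
})

test_that("stats blocks expose defaults for missing Gaps and Positives clauses", {
  st <- parse_stats_block(GRADES_BLOCK_1)
  expect_identical(st$stats$bit_score, 166)
  expect_identical(st$stats$raw_score, 419L)
  expect_equal(st$stats$evalue, 3e-39)
  expect_identical(st$stats$num_identities, 168L)
  nogaps <- parse_stats_block(c(
    "Score = 50 bits (120), Expect = 1e-10",
    "Identities = 30/30 (100%), Positives = 30/30 (100%)"
  ))
  expect_identical(nogaps$stats$num_gaps, 0L)
  expect_identical(nogaps$stats$gap_pct, 0L)
  nuc <- parse_stats_block(c(
    "Score = 50 bits (120), Expect = 1e-10",
    "Identities = 28/30 (93%)",
    "Strand = Plus / Minus"
  ))
  expect_identical(nuc$stats$num_positives, NA_integer_)
  expect_identical(nuc$query_strand, "plus")
  expect_identical(nuc$subject_strand, "minus")
  expect_error(parse_stats_block("Score = garbage"),
               class = "blastr_corrupt_block")
})

test_that("alignment rows concatenate across triplets and keep leading-space midlines", {
  seg <- strrep("K", 60)
  one <- c(
    paste0("Query: 1      ", seg, "  60"),
    paste0(strrep(" ", 14), seg),
    paste0("Sbjct: 1      ", seg, "  60")
  )
  got <- parse_alignment_rows(one)
  expect_identical(nchar(got$aligned_query), 60L)
  expect_identical(got$query_end, 60L)
  expect_identical(got$subject_end, 60L)

  two <- c(
    "Query: 1      AC-DEF  5",
    paste0(strrep(" ", 14), "  +DEF"),
    "Sbjct: 11     GCADEF  16",
    "",
    "Query: 6      HIKL  9",
    paste0(strrep(" ", 14), " IKL"),
    "Sbjct: 17     AIKL  20"
  )
  got2 <- parse_alignment_rows(two)
  expect_identical(got2$aligned_query, "AC-DEFHIKL")
  expect_identical(got2$midline, "  +DEF IKL")
  expect_identical(got2$query_start, 1L)
  expect_identical(got2$query_end, 9L)
  expect_identical(got2$subject_end, 20L)

  discontinuous <- two
  discontinuous[5] <- "Query: 8      HIKL  11"
  expect_error(parse_alignment_rows(discontinuous),
               class = "blastr_corrupt_block")
  mismatched <- two
  mismatched[7] <- "Sbjct: 17     AIKLM  21"
  expect_error(parse_alignment_rows(mismatched),
               class = "blastr_corrupt_block")
})

test_that("render-parse is the identity on seeded models", {
  for (s in 101:112) {
    spec <- roundtrip_spec(s)
    m <- generate_model(spec)
    txt <- render_report(m$info, m$results, dialect = spec$length_line_style)
    p <- parse_report(txt)
    expect_identical(p$results, m$results, label = sprintf("seed %d", s))
    expect_identical(p$info, m$info, label = sprintf("seed %d info", s))
    expect_identical(nrow(p$diagnostics$warnings), 0L)
  }
})

test_that("verbatim header, summaries and footer are substrings of the input", {
  spec <- quick_spec(33, num_queries = 2L, program_family = "psiblast",
                     rounds_per_query = 2L)
  m <- generate_model(spec)
  txt <- paste(render_report(m$info, m$results), collapse = "\n")
  p <- parse_report(generate_report(spec))
  expect_true(grepl(p$info$raw_header, txt, fixed = TRUE))
  for (qr in p$results) {
    for (s in qr$summary_text) expect_true(grepl(s, txt, fixed = TRUE))
    expect_true(grepl(qr$footer$raw_footer, txt, fixed = TRUE))
  }
})

test_that("corrupt blocks are skipped with diagnostics; strict mode aborts", {
  spec <- quick_spec(34, num_queries = 5L)
  lines <- generate_report(spec)
  mangled <- corrupt_report(lines, seed = 2, mode = "mangle_score_line")
  p <- parse_report(mangled)
  expect_identical(length(p$results), 4L)
  expect_identical(nrow(p$diagnostics$warnings), 1L)
  expect_match(p$diagnostics$warnings$message, "Score")
  expect_error(parse_report(mangled, strict = TRUE),
               class = "blastr_corrupt_block")
})

test_that("truncating the final block never fails and flags truncation", {
  spec <- quick_spec(35, num_queries = 4L)
  lines <- generate_report(spec)
  m <- generate_model(spec)
  anchors <- grep("^Query=", lines)
  last <- anchors[length(anchors)]
  for (cut in seq(last + 1, length(lines), by = 7)) {
    p <- parse_report(lines[seq_len(cut)])
    expect_gte(length(p$results), 3)
    expect_identical(p$results[1:3], m$results[1:3])
    if (length(p$results) == 3) expect_true(p$diagnostics$truncated)
  }
})
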