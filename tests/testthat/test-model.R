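test_that("percentages are truncated, never rounded", {
  # the three discriminating pairs: 14.74, 34.81 and 16.66 all floor
  expect_identical(compute_truncated_pct(168, 468), 35L)
  expect_identical(compute_truncated_pct(184, 468), 39L)
  expect_identical(compute_truncated_pct(69, 468), 14L)
  expect_identical(compute_truncated_pct(165, 474), 34L)
  expect_identical(compute_truncated_pct(180, 474), 37L)
  expect_identical(compute_truncated_pct(79, 474), 16L)
  expect_identical(compute_truncated_pct(0, 468), 0L)
  expect_identical(compute_truncated_pct(c(168, 184), c(468, 468)), c(35L, 39L))
  expect_error(compute_truncated_pct(1, 0), class = "blastr_invalid_denominator")
})

test_that("grades lines format exactly and round-trip through the parser", {
  s1 <- hsp_stats(166, 419, 3e-39, evalue_token = "3e-39",
                  num_identities = 168L, num_positives = 184L,
                  num_gaps = 69L, alignment_length = 468L)
  expect_identical(format_hsp_stats(s1), GRADES_BLOCK_1)
  s2 <- hsp_stats(157, 397, 1e-36, evalue_token = "1e-36",
                  num_identities = 165L, num_positives = 180L,
                  num_gaps = 79L, alignment_length = 474L)
  expect_identical(format_hsp_stats(s2), GRADES_BLOCK_2)

  # format o parse is the identity on well-formed blocks, 120 generated ones
  blastr:::with_seed(404, {
    for (k in 1:120) {
      L <- sample(20:500, 1)
      g <- sample(0:round(L / 4), 1)
      i <- sample(0:(L - g), 1)
      p <- sample(i:(L - g), 1)
      nucleotide <- runif(1) < 0.3
      st <- hsp_stats(
        bit_score = sample(200:5000, 1) / 10,
        raw_score = sample(50:9000, 1),
        evalue = 0, # overwritten below through the token
        evalue_token = "0.0",
        num_identities = i,
        num_positives = if (nucleotide) NA_integer_ else p,
        num_gaps = g, alignment_length = L
      )
      st$evalue_token <- blastr:::sample_evalue_token()
      st$evalue <- parse_evalue_token(st$evalue_token)
      block <- format_hsp_stats(st)
      reparsed <- parse_stats_block(block)
      expect_identical(format_hsp_stats(reparsed$stats), block)
      expect_identical(reparsed$stats, st)
    }
  })
})

test_that("e-value tokens parse across decimal, scientific and bare-exponent forms", {
  expect_equal(parse_evalue_token("3e-39"), 3e-39)
  expect_identical(parse_evalue_token("0.0"), 0)
  expect_equal(parse_evalue_token("e-104"), 1e-104) # implicit mantissa 1
  expect_equal(parse_evalue_token("0.001"), 0.001)
  expect_equal(parse_evalue_token("2.5"), 2.5)
  expect_error(parse_evalue_token("fast"), class = "blastr_corrupt_block")
})

test_that("best_hsp follows min-evalue, max-bits, first-occurrence order", {
  mk <- function(ev, bits) {
    hsp(stats = hsp_stats(bits, round(bits * 2), ev, num_identities = 5L,
                          num_positives = 6L, num_gaps = 0L,
                          alignment_length = 10L),
        query_start = 1L, query_end = 10L, subject_start = 1L,
        subject_end = 10L, aligned_query = "AAAAAAAAAA",
        midline = "AAAAAAAAAA", aligned_subject = "AAAAAAAAAA")
  }
  al <- subject_alignment("S", "d", 20L,
                          list(mk(1e-5, 30), mk(1e-9, 50), mk(1e-9, 40)))
  expect_identical(best_hsp(al), al$hsps[[2]])
  single <- subject_alignment("S", "d", 20L, list(mk(1, 10)))
  expect_identical(best_hsp(single), single$hsps[[1]])

  # brute-force agreement on 100 generated alignments
  blastr:::with_seed(77, {
    for (k in 1:100) {
      n <- sample(1:6, 1)
      hs <- lapply(seq_len(n), function(x) {
        mk(sample(c(0, 10^-sample(1:50, 1)), 1), sample(10:100, 1))
      })
      al <- subject_alignment("S", "d", 20L, hs)
      expect_identical(best_hsp(al), oracle_best_hsp(al))
    }
  })
})

test_that("model constructors enforce core invariants", {
  expect_error(general_info("TBLASTN", "2.2.26"),
               class = "blastr_not_blast_report")
  expect_error(subject_alignment("S", "d", 10L, list()),
               class = "blastr_corrupt_model")
  tiny <- make_tiny_model()
  expect_silent(blastr:::validate_model(tiny$info, tiny$results))
  broken <- tiny$results[[1]]
  broken$iterations[[1]]$alignments[[1]]$hsps[[1]]$stats$identity_pct <- 99L
  expect_error(blastr:::validate_model(tiny$info, list(broken)),
               class = "blastr_invalid_model")
})
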