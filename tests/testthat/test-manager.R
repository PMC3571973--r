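local_store <- function(spec, env = parent.frame()) {
  path <- write_report(generate_report(spec))
  db <- tempfile(fileext = ".db")
  h <- build_store(db, path)$handle
  withr::defer(close_store(h), envir = env)
  h
}

test_that("the e-value filter is strict and matches a brute-force scan", {
  spec <- quick_spec(60, num_queries = 20L, program_family = "psiblast",
                     rounds_per_query = 2L, hsps_per_subject = c(1L, 3L))
  m <- generate_model(spec)
  h <- local_store(spec)
  want <- oracle_rows(m$results)
  for (thr in c(0, 1e-50, 1e-10, 0.001, 10)) {
    got <- select_where_evalue_lower_than(h, thr)
    keep <- want[want$evalue < thr, ]
    expect_identical(got$subject_id, keep$subject_id)
    expect_identical(got$evalue, keep$evalue)
    expect_identical(attr(got, "retrieved_count"), nrow(got))
  }
  # boundary: a threshold equal to an existing e-value excludes that row
  ev <- sort(unique(want$evalue[want$evalue > 0]))[1]
  at <- select_where_evalue_lower_than(h, ev)
  expect_false(any(at$evalue == ev))
  expect_identical(nrow(select_where_evalue_lower_than(h, 0)), 0L)
  expect_error(select_where_evalue_lower_than(h, -1),
               class = "blastr_invalid_threshold")
  expect_identical(attr(select_where_evalue_lower_than(h, 1, TRUE),
                        "header_line"),
                   "##query | iter | subject | e-value")
})

test_that("the identity filter is strict at the boundary and oracle-exact", {
  spec <- quick_spec(61, num_queries = 20L, hsps_per_subject = c(2L, 3L))
  m <- generate_model(spec)
  h <- local_store(spec)
  want <- oracle_rows(m$results)
  for (thr in c(0, 30, 45, 99)) {
    got <- select_where_identity_pct_higher_than(h, thr)
    keep <- want[want$identity_pct > thr, ]
    expect_identical(got$subject_id, keep$subject_id)
    expect_identical(got$identity_pct, keep$identity_pct)
  }
  boundary <- sort(unique(want$identity_pct))[1]
  at <- select_where_identity_pct_higher_than(h, boundary)
  expect_false(any(at$identity_pct == boundary))
  expect_identical(nrow(select_where_identity_pct_higher_than(h, 100)), 0L)
  expect_error(select_where_identity_pct_higher_than(h, 101),
               class = "blastr_invalid_threshold")
  expect_identical(attr(select_where_identity_pct_higher_than(h, 1, TRUE),
                        "header_line"),
                   "##query | iter | subject | Ident.%")
})

test_that("identity sort descends within each query and is stable on ties", {
  spec <- quick_spec(62, num_queries = 10L, subjects_per_query = c(2L, 5L))
  m <- generate_model(spec)
  h <- local_store(spec)
  got <- sort_by_identity_pct(h)
  want <- oracle_rows(m$results)
  expect_identical(nrow(got), nrow(want))
  # queries appear in stored order; within each query pct runs descend
  runs <- split(seq_len(nrow(got)), match(got$query_id, unique(got$query_id)))
  expect_identical(unique(got$query_id), unique(want$query_id))
  for (idx in runs) {
    pct <- got$identity_pct[idx]
    expect_true(all(diff(pct) <= 0))
    # first row of each run carries that query's maximum
    qid <- got$query_id[idx[1]]
    expect_identical(pct[1], max(want$identity_pct[want$query_id == qid]))
    # ties broken by ascending e-value
    ev <- got$evalue[idx]
    for (p in unique(pct)) {
      expect_true(all(diff(ev[pct == p]) >= 0))
    }
  }
  # all-equal percentages keep original subject order (stable sort)
  tiny <- make_tiny_model()
  tiny$results[[1]]$iterations[[1]]$alignments <- rep(
    tiny$results[[1]]$iterations[[1]]$alignments, 3)
  for (j in 1:3) {
    tiny$results[[1]]$iterations[[1]]$alignments[[j]]$subject_id <-
      paste0("SUBJ", j)
  }
  db <- tempfile(fileext = ".db")
  h2 <- build_store(db, write_report(render_report(tiny$info, tiny$results)))$handle
  sorted <- sort_by_identity_pct(h2)
  expect_identical(sorted$subject_id, c("SUBJ1", "SUBJ2", "SUBJ3"))
  close_store(h2)
})

test_that("query and subject lookups reproduce best-HSP fields", {
  planted <- "UniRef100_G5BKD1"
  spec <- quick_spec(63, num_queries = 15L, hsps_per_subject = c(1L, 3L),
                     planted_subject_ids = planted)
  m <- generate_model(spec)
  h <- local_store(spec)
  want <- oracle_rows(m$results)

  qid <- m$results[[7]]$query_id
  got <- select_by_query_id(h, qid, with_header = TRUE)
  keep <- want[want$query_id == qid, ]
  expect_identical(attr(got, "header_line"),
                   "##queryid len descr round subjectid eval align ident. Pos. gaps")
  expect_identical(got$subject_id, keep$subject_id)
  expect_identical(got$evalue_token, keep$evalue_token)
  expect_identical(got$align_length, keep$align_length)
  expect_identical(got$num_gaps, keep$num_gaps)
  expect_identical(unique(got$query_length), m$results[[7]]$query_length)
  expect_error(select_by_query_id(h, "UNKNOWN"),
               class = "blastr_missing_query")

  bys <- select_by_subject_id(h, planted, with_header = TRUE)
  expect_identical(attr(bys, "header_line"),
                   "##queryid round subjectid eval align ident. Pos. gaps")
  expect_identical(nrow(bys), 1L)
  expect_identical(bys$query_id, m$results[[1]]$query_id)
  absent <- select_by_subject_id(h, "UniRef100_ABSENT")
  expect_identical(nrow(absent), 0L)
  expect_identical(attr(absent, "retrieved_count"), 0L)
})

test_that("exported tables are byte-stable with timing zeroed", {
  tiny <- make_tiny_model()
  db <- tempfile(fileext = ".db")
  h <- build_store(db, write_report(render_report(tiny$info, tiny$results)))$handle
  tab <- select_by_query_id(h, "QTEST", with_header = TRUE)
  out <- tempfile()
  export_table(tab, out, no_timing = TRUE)
  expect_identical(readLines(out), c(
    "##queryid len descr round subjectid eval align ident. Pos. gaps",
    "QTEST\t50\t\t0\tSUBJ1\t2e-05\t10\t70.0\t80.0\t1",
    "retrieved 1 results; query time: 0 seconds"
  ))
  empty <- select_where_evalue_lower_than(h, 0, with_header = TRUE)
  export_table(empty, out, no_timing = TRUE)
  expect_identical(readLines(out), c(
    "##query | iter | subject | e-value",
    "retrieved 0 results; query time: 0 seconds"
  ))
  # written-then-reread row count equals retrieved_count
  export_table(tab, out)
  body <- readLines(out)
  expect_identical(length(body) - 2L, attr(tab, "retrieved_count"))
  close_store(h)
})

test_that("tidy and glance give flat per-HSP views of a store", {
  spec <- quick_spec(64, num_queries = 4L, hsps_per_subject = c(2L, 2L))
  m <- generate_model(spec)
  h <- local_store(spec)
  flat <- tidy(h)
  n_hsp <- sum(vapply(m$results, function(q) {
    sum(vapply(q$iterations, function(it) {
      sum(vapply(it$alignments, function(al) length(al$hsps), integer(1)))
    }, integer(1)))
  }, integer(1)))
  expect_identical(nrow(flat), n_hsp)
  g <- glance(h)
  expect_identical(g$n_queries, 4L)
  expect_identical(g$n_hsps, n_hsp)
  p <- ggplot2::ggplot_build(autoplot(select_where_identity_pct_higher_than(h, 0)))
  expect_s3_class(p$plot, "ggplot")
})
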