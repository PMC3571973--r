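# Streaming parser for legacy BLAST pairwise text. Section anchors are
# simple line-anchored regular expressions: program header line, "Query=",
# "Results from round", line-initial '>', "Score =", and the footer's
# indented "Database:" block. Blocks are processed one at a time, so peak
# memory is bounded by the largest single query block.

RE_QUERY_ANCHOR <- "^Query="
RE_ROUND_ANCHOR <- "^Results from round ([0-9]+)"
RE_SUBJECT_ANCHOR <- "^>"
RE_SCORE_ANCHOR <- "^\\s*Score\\s*="
RE_FOOTER_ANCHOR <- "^  Database:"
RE_LEN_PAREN <- "^\\s+\\(([0-9,]+) letters\\)\\s*$"
RE_LEN_KEYWORD <- "^Length=([0-9]+)\\s*$"
RE_SUBJ_LEN_PAREN <- "^\\s+Length = ([0-9,]+)\\s*$"

strip_commas <- function(x) as.numeric(gsub(",", "", x, fixed = TRUE))

last_nonempty <- function(lines, upto = length(lines)) {
  idx <- which(nzchar(trimws(lines[seq_len(upto)])))
  if (length(idx) == 0) 0L else idx[length(idx)]
}

#' Stream a report as query blocks
#'
#' Splits a BLAST plain-text report at its `Query=` anchors without loading
#' the whole file. Header text before the first anchor is attached to the
#' first block, so concatenating all blocks reproduces the input exactly.
#' Memory use is bounded by the largest single block.
#'
#' @param source A file path, a readable text connection, or a character
#'   vector of report lines.
#' @return An iterator object of class `blast_block_iterator`. Call
#'   `$next_block()` repeatedly; it returns `list(lines, start_line)` per
#'   block and `NULL` after the last one.
#' @export
scan_query_blocks <- function(source) {
  env <- new.env(parent = emptyenv())
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    env$con <- file(source, open = "r")
    env$own_con <- TRUE
    env$lines <- NULL
  } else if (inherits(source, "connection")) {
    env$con <- source
    if (!isOpen(env$con)) {
      open(env$con, open = "r")
      env$own_con <- TRUE
    } else {
      env$own_con <- FALSE
    }
    env$lines <- NULL
  } else if (is.character(source)) {
    env$con <- NULL
    env$lines <- source
    env$cursor <- 1L
  } else {
    stop_storage_io("source must be a file path, connection or character vector")
  }
  env$pending <- character()
  env$pending_start <- 1L
  env$eof <- FALSE
  env$seen_anchor <- FALSE
  env$done <- FALSE

  read_chunk <- function(n = 4096L) {
    if (!is.null(env$con)) {
      chunk <- readLines(env$con, n = n, warn = FALSE)
      if (length(chunk) == 0) env$eof <- TRUE
      chunk
    } else {
      if (env$cursor > length(env$lines)) {
        env$eof <- TRUE
        character()
      } else {
        hi <- min(env$cursor + n - 1L, length(env$lines))
        chunk <- env$lines[env$cursor:hi]
        env$cursor <- hi + 1L
        chunk
      }
    }
  }
  finish <- function() {
    if (!is.null(env$con) && isTRUE(env$own_con)) {
      try(close(env$con), silent = TRUE)
      env$con <- NULL
    }
  }

  next_block <- function() {
    if (env$done) return(NULL)
    repeat {
      anchors <- grep(RE_QUERY_ANCHOR, env$pending)
      if (length(anchors) > 0) env$seen_anchor <- TRUE
      cut <- if (length(anchors) > 0) {
        after <- anchors[anchors > anchors[1]]
        if (length(after) > 0) after[1] else NA_integer_
      } else {
        NA_integer_
      }
      if (!is.na(cut)) {
        block <- env$pending[seq_len(cut - 1L)]
        start <- env$pending_start
        env$pending <- env$pending[cut:length(env$pending)]
        env$pending_start <- start + cut - 1L
        return(list(lines = block, start_line = start))
      }
      if (env$eof) {
        env$done <- TRUE
        finish()
        if (!env$seen_anchor) {
          stop_not_blast_report("no 'Query=' anchor found: not a BLAST plain-text report")
        }
        if (length(env$pending) == 0) return(NULL)
        block <- env$pending
        env$pending <- character()
        return(list(lines = block, start_line = env$pending_start))
      }
      env$pending <- c(env$pending, read_chunk())
    }
  }

  structure(list(next_block = next_block), class = "blast_block_iterator")
}

parse_general_header <- function(lines) {
  keep <- seq_len(last_nonempty(lines))
  if (length(keep) == 0 || keep[1] == 0) return(NULL)
  lines <- lines[keep]
  first <- lines[which(nzchar(trimws(lines)))[1]]
  m <- regmatches(first, regexec("^(\\S+)\\s+(\\S+)", first))[[1]]
  if (length(m) < 3) return(NULL)
  program <- toupper(m[2])
  if (!program %in% c("BLASTP", "BLASTN", "BLASTX", "PSIBLAST")) return(NULL)
  db_line <- grep("^Database:", lines, value = TRUE)
  db_name <- if (length(db_line)) sub("^Database:\\s*", "", db_line[1]) else NA_character_
  stat <- regmatches(lines, regexec("^\\s+([0-9,]+) sequences; ([0-9,]+) total letters",
                                    lines))
  stat <- Filter(function(x) length(x) == 3, stat)
  n_seq <- if (length(stat)) as.integer(strip_commas(stat[[1]][2])) else NA_integer_
  n_let <- if (length(stat)) strip_commas(stat[[1]][3]) else NA_real_
  general_info(
    program_name = program,
    program_version = m[3],
    database_name = db_name,
    database_num_sequences = n_seq,
    database_num_letters = n_let,
    raw_header = paste(lines, collapse = "\n")
  )
}

parse_footer_block <- function(lines) {
  keep <- seq_len(last_nonempty(lines))
  lines <- lines[keep]
  grab1 <- function(pattern) {
    hit <- regmatches(lines, regexec(pattern, lines))
    hit <- Filter(function(x) length(x) >= 2, hit)
    if (length(hit)) hit[[1]][2] else NA_character_
  }
  posted <- grab1("^\\s+Posted date:\\s+(.+?)\\s*$")
  n_let <- grab1("^\\s*Number of letters in database:\\s+([0-9,]+)")
  n_seq <- grab1("^\\s*Number of sequences in database:\\s+([0-9,]+)")
  lam_idx <- grep("^Lambda\\s+K\\s+H", lines)
  triples <- lapply(lam_idx, function(i) {
    j <- i + 1L
    while (j <= length(lines) && !nzchar(trimws(lines[j]))) j <- j + 1L
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
    if (length(vals) != 3 || any(is.na(vals))) NULL else vals
  })
  triples <- Filter(Negate(is.null), triples)
  if (length(triples) == 0) return(NULL)
  ungapped <- triples[[1]]
  gapped <- if (length(triples) >= 2 && any(grepl("^Gapped", lines))) {
    triples[[2]]
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  matrix_name <- grab1("^Matrix: (.+?)\\s*$")
  pen <- regmatches(lines, regexec(
    "^Gap Penalties: Existence: ([0-9]+), Extension: ([0-9]+)", lines))
  pen <- Filter(function(x) length(x) == 3, pen)
  fs <- footer_stats(
    lambda_ungapped = ungapped[1], k_ungapped = ungapped[2],
    h_ungapped = ungapped[3],
    lambda_gapped = gapped[1], k_gapped = gapped[2], h_gapped = gapped[3],
    matrix_name = matrix_name,
    gap_open = if (length(pen)) as.integer(pen[[1]][2]) else NA_integer_,
    gap_extend = if (length(pen)) as.integer(pen[[1]][3]) else NA_integer_,
    raw_footer = paste(lines, collapse = "\n")
  )
  list(
    footer = fs,
    posted_date = posted,
    num_letters = if (is.na(n_let)) NA_real_ else strip_commas(n_let),
    num_sequences = if (is.na(n_seq)) NA_integer_ else as.integer(strip_commas(n_seq))
  )
}

#' Parse an HSP statistics block
#'
#' Reads the `Score =` line and the Identities/Positives/Gaps line of one
#' HSP, plus any `Strand =`, `Frame =` or `Method:` annotations. A missing
#' Gaps clause means zero gaps; a missing Positives clause (nucleotide
#' output) leaves the positives fields `NA`.
#'
#' @param lines Character vector starting at a `Score =` line (a single
#'   string is split on newlines).
#' @return A list with elements `stats` ([hsp_stats()]), `query_frame`,
#'   `query_strand`, `subject_strand`, `method`.
#' @export
parse_stats_block <- function(lines) {
  if (length(lines) == 1 && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  score_line <- lines[grep(RE_SCORE_ANCHOR, lines)[1]]
  if (is.na(score_line)) stop_corrupt_block("no Score line in HSP block")
  m <- regmatches(score_line, regexec(
    "^\\s*Score\\s*=\\s*([0-9.eE+]+) bits \\(([0-9]+)\\), Expect(?:\\([0-9]+\\))? = ([^,[:space:]]+)",
    score_line))[[1]]
  if (length(m) != 4) {
    stop_corrupt_block(sprintf("malformed Score line: '%s'", trimws(score_line)))
  }
  bit_score <- suppressWarnings(as.numeric(m[2]))
  if (is.na(bit_score)) stop_corrupt_block("unparseable bit score")
  evalue_token <- m[4]
  method <- NA_character_
  mm <- regmatches(score_line, regexec(",\\s*Method:\\s*(.+?)\\s*$", score_line))[[1]]
  if (length(mm) == 2) method <- mm[2]
  for (ln in lines) {
    mm <- regmatches(ln, regexec("^\\s*Method:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(mm) == 2) method <- mm[2]
  }

  ident_line <- lines[grep("Identities = ", lines, fixed = TRUE)[1]]
  if (is.na(ident_line)) stop_corrupt_block("no Identities line in HSP block")
  pick <- function(pattern) {
    m <- regmatches(ident_line, regexec(pattern, ident_line))[[1]]
    if (length(m) == 4) as.integer(m[2:4]) else NULL
  }
  ident <- pick("Identities = ([0-9]+)/([0-9]+) \\(([0-9]+)%\\)")
  if (is.null(ident)) stop_corrupt_block("malformed Identities clause")
  pos <- pick("Positives = ([0-9]+)/([0-9]+) \\(([0-9]+)%\\)")
  gaps <- pick("Gaps = ([0-9]+)/([0-9]+) \\(([0-9]+)%\\)")
  L <- ident[2]

  frame <- NA_integer_
  qstrand <- sstrand <- NA_character_
  fm <- regmatches(lines, regexec("^\\s*Frame = ([+-][0-9])\\s*$", lines))
  fm <- Filter(function(x) length(x) == 2, fm)
  if (length(fm)) frame <- as.integer(fm[[1]][2])
  sm <- regmatches(lines, regexec("^\\s*Strand = (Plus|Minus) / (Plus|Minus)\\s*$",
                                  lines))
  sm <- Filter(function(x) length(x) == 3, sm)
  if (length(sm)) {
    qstrand <- tolower(sm[[1]][2])
    sstrand <- tolower(sm[[1]][3])
  }

  stats <- hsp_stats(
    bit_score = bit_score,
    raw_score = as.integer(m[3]),
    evalue = parse_evalue_token(evalue_token),
    evalue_token = evalue_token,
    num_identities = ident[1],
    num_positives = if (is.null(pos)) NA_integer_ else pos[1],
    num_gaps = if (is.null(gaps)) 0L else gaps[1],
    alignment_length = L,
    identity_pct = ident[3],
    positive_pct = if (is.null(pos)) NA_integer_ else pos[3],
    gap_pct = if (is.null(gaps)) 0L else gaps[3]
  )
  list(stats = stats, query_frame = frame, query_strand = qstrand,
       subject_strand = sstrand, method = method)
}

#' Parse a run of Query/midline/Sbjct triplets
#'
#' Concatenates the wrapped alignment rows of one HSP. Start coordinates
#' come from the first triplet and end coordinates from the last; the
#' midline is extracted by the column offset of the sequence field in its
#' flanking Query line, so leading spaces (mismatch columns) are preserved.
#' Segment-length mismatches and coordinate discontinuities between
#' consecutive triplets signal a corrupt block.
#'
#' @param lines Character vector covering the triplets.
#' @param step_query Query coordinate step per residue: 3 for translated
#'   (blastx) queries, 1 otherwise.
#' @return A list with `query_start`, `query_end`, `subject_start`,
#'   `subject_end`, `aligned_query`, `midline`, `aligned_subject`.
#' @export
parse_alignment_rows <- function(lines, step_query = 1L) {
  qidx <- grep("^Query:", lines)
  if (length(qidx) == 0) stop_corrupt_block("no alignment rows in HSP block")
  segs_q <- segs_m <- segs_s <- character(length(qidx))
  qcoord <- scoord <- matrix(0L, nrow = length(qidx), ncol = 2)
  for (t in seq_along(qidx)) {
    i <- qidx[t]
    if (i + 2 > length(lines)) stop_corrupt_block("incomplete alignment triplet")
    qm <- regmatches(lines[i], regexec(
      "^(Query:\\s+([0-9]+)\\s+)(\\S+)\\s+([0-9]+)\\s*$", lines[i]))[[1]]
    if (length(qm) != 5) {
      stop_corrupt_block(sprintf("malformed Query row: '%s'", lines[i]))
    }
    sm <- regmatches(lines[i + 2], regexec(
      "^Sbjct:\\s+([0-9]+)\\s+(\\S+)\\s+([0-9]+)\\s*$", lines[i + 2]))[[1]]
    if (length(sm) != 4) {
      stop_corrupt_block(sprintf("malformed Sbjct row: '%s'", lines[i + 2]))
    }
    seg <- qm[4]
    if (nchar(sm[3]) != nchar(seg)) {
      stop_corrupt_block("alignment triplet segment lengths differ")
    }
    off <- nchar(qm[2])
    mseg <- substr(lines[i + 1], off + 1L, off + nchar(seg))
    mseg <- formatC(mseg, width = -nchar(seg)) # right-pad to segment length
    segs_q[t] <- seg
    segs_m[t] <- mseg
    segs_s[t] <- sm[3]
    qcoord[t, ] <- as.integer(c(qm[3], qm[5]))
    scoord[t, ] <- as.integer(c(sm[2], sm[4]))
  }
  n <- length(qidx)
  dir_of <- function(coord) {
    d <- sign(coord[n, 2] - coord[1, 1])
    if (d == 0) 1L else as.integer(d)
  }
  dq <- dir_of(qcoord)
  ds <- dir_of(scoord)
  for (t in seq_len(n)) {
    rq <- count_non_gap(segs_q[t])
    rs <- count_non_gap(segs_s[t])
    if (abs(qcoord[t, 2] - qcoord[t, 1]) + 1L != step_query * rq ||
        abs(scoord[t, 2] - scoord[t, 1]) + 1L != rs) {
      stop_corrupt_block("alignment row coordinates do not match residue count")
    }
    if (t > 1) {
      if (qcoord[t, 1] != qcoord[t - 1, 2] + dq ||
          scoord[t, 1] != scoord[t - 1, 2] + ds) {
        stop_corrupt_block("coordinate discontinuity between alignment rows")
      }
    }
  }
  list(
    query_start = qcoord[1, 1], query_end = qcoord[n, 2],
    subject_start = scoord[1, 1], subject_end = scoord[n, 2],
    aligned_query = paste(segs_q, collapse = ""),
    midline = paste(segs_m, collapse = ""),
    aligned_subject = paste(segs_s, collapse = "")
  )
}

#' Parse one subject block
#'
#' @param lines Character vector beginning at the `>` subject anchor.
#' @return A [subject_alignment()] object.
#' @export
parse_subject_block <- function(lines) {
  m <- regmatches(lines[1], regexec("^>(\\S+)\\s*(.*)$", lines[1]))[[1]]
  if (length(m) != 3) stop_corrupt_block("malformed subject anchor line")
  subject_id <- m[2]
  desc_parts <- if (nzchar(m[3])) trimws(m[3]) else character()
  i <- 2L
  slen <- NA_integer_
  while (i <= length(lines)) {
    ln <- lines[i]
    lm <- regmatches(ln, regexec(RE_SUBJ_LEN_PAREN, ln))[[1]]
    if (length(lm) == 2) {
      slen <- as.integer(strip_commas(lm[2])); i <- i + 1L; break
    }
    lm <- regmatches(ln, regexec(RE_LEN_KEYWORD, ln))[[1]]
    if (length(lm) == 2) {
      slen <- as.integer(lm[2]); i <- i + 1L; break
    }
    if (grepl(RE_SCORE_ANCHOR, ln)) break
    if (nzchar(trimws(ln))) desc_parts <- c(desc_parts, trimws(ln))
    i <- i + 1L
  }
  if (is.na(slen)) {
    stop_corrupt_block(sprintf("subject '%s' has no Length declaration", subject_id))
  }
  body <- lines[seq.int(i, length.out = max(0L, length(lines) - i + 1L))]
  hidx <- grep(RE_SCORE_ANCHOR, body)
  if (length(hidx) == 0) {
    stop_corrupt_block(sprintf("subject '%s' has no HSP", subject_id))
  }
  ends <- c(hidx[-1] - 1L, length(body))
  hsps <- vector("list", length(hidx))
  for (k in seq_along(hidx)) {
    chunk <- body[hidx[k]:ends[k]]
    first_row <- grep("^Query:", chunk)[1]
    stat_lines <- if (is.na(first_row)) chunk else chunk[seq_len(first_row - 1L)]
    st <- parse_stats_block(stat_lines)
    if (is.na(first_row)) stop_corrupt_block("HSP block has no alignment rows")
    step_q <- if (!is.na(st$query_frame)) 3L else 1L
    rows <- parse_alignment_rows(chunk[first_row:length(chunk)], step_q)
    if (nchar(rows$aligned_query) != st$stats$alignment_length) {
      stop_corrupt_block("alignment rows do not match stated alignment length")
    }
    hsps[[k]] <- hsp(
      stats = st$stats,
      query_start = rows$query_start, query_end = rows$query_end,
      subject_start = rows$subject_start, subject_end = rows$subject_end,
      query_frame = st$query_frame,
      query_strand = st$query_strand, subject_strand = st$subject_strand,
      aligned_query = rows$aligned_query,
      midline = rows$midline,
      aligned_subject = rows$aligned_subject,
      method = st$method
    )
  }
  subject_alignment(
    subject_id = subject_id,
    subject_description = paste(desc_parts, collapse = " "),
    subject_length = slen,
    hsps = hsps
  )
}

# Parse one iteration region (lines between round anchors) into an
# iteration object plus its verbatim summary block (or NA).
parse_iteration_region <- function(rlines, round_index) {
  converged <- any(grepl("^CONVERGED!", rlines))
  keep <- !grepl("^CONVERGED!", rlines)
  rlines <- rlines[keep]
  sidx <- grep(RE_SUBJECT_ANCHOR, rlines)
  summary_txt <- NA_character_
  s0 <- grep("^Sequences producing significant alignments:", rlines)
  if (length(s0)) {
    s0 <- s0[1]
    start <- if (s0 > 1 && grepl("Score\\s+E\\s*$", rlines[s0 - 1])) s0 - 1L else s0
    limit <- if (length(sidx)) sidx[1] - 1L else length(rlines)
    end <- last_nonempty(rlines, limit)
    if (end >= start) {
      summary_txt <- paste(rlines[start:end], collapse = "\n")
    }
  }
  alignments <- list()
  if (length(sidx)) {
    ends <- c(sidx[-1] - 1L, length(rlines))
    alignments <- lapply(seq_along(sidx), function(j) {
      parse_subject_block(rlines[sidx[j]:ends[j]])
    })
  }
  list(
    iteration = iteration(round_index = round_index, converged = converged,
                          alignments = alignments),
    summary = summary_txt
  )
}

#' Parse one query block
#'
#' @param lines Character vector beginning at a `Query=` anchor (a single
#'   string is split on newlines).
#' @return A [query_result()] object.
#' @export
parse_query_block <- function(lines) {
  if (length(lines) == 1 && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  }
  m <- regmatches(lines[1], regexec("^Query=\\s*(.*)$", lines[1]))[[1]]
  if (length(m) != 2) stop_corrupt_block("block does not start at a Query= anchor")
  title_parts <- trimws(m[2])
  i <- 2L
  qlen <- NA_integer_
  while (i <= length(lines)) {
    ln <- lines[i]
    lm <- regmatches(ln, regexec(RE_LEN_PAREN, ln))[[1]]
    if (length(lm) == 2) {
      qlen <- as.integer(strip_commas(lm[2])); i <- i + 1L; break
    }
    lm <- regmatches(ln, regexec(RE_LEN_KEYWORD, ln))[[1]]
    if (length(lm) == 2) {
      qlen <- as.integer(lm[2]); i <- i + 1L; break
    }
    if (!nzchar(trimws(ln)) || grepl(RE_SUBJECT_ANCHOR, ln) ||
        grepl(RE_ROUND_ANCHOR, ln) || grepl(RE_SCORE_ANCHOR, ln)) break
    title_parts <- c(title_parts, trimws(ln))
    i <- i + 1L
  }
  if (is.na(qlen)) stop_corrupt_block("query block has no length declaration")
  title <- paste(title_parts, collapse = " ")
  query_id <- sub("\\s.*$", "", title)

  body <- lines[seq.int(i, length.out = max(0L, length(lines) - i + 1L))]
  fidx <- grep(RE_FOOTER_ANCHOR, body)[1]
  footer <- NULL
  posted <- NULL
  if (!is.na(fidx)) {
    parsed <- parse_footer_block(body[fidx:length(body)])
    if (!is.null(parsed)) {
      footer <- parsed$footer
      posted <- parsed
    }
    body <- body[seq_len(fidx - 1L)]
  }

  ridx <- grep(RE_ROUND_ANCHOR, body)
  regions <- if (length(ridx) == 0) {
    list(list(round = 0L, lines = body))
  } else {
    printed <- as.integer(sub(RE_ROUND_ANCHOR, "\\1",
                              grep(RE_ROUND_ANCHOR, body, value = TRUE)))
    ends <- c(ridx[-1] - 1L, length(body))
    lapply(seq_along(ridx), function(j) {
      list(round = printed[j] - 1L,
           lines = body[seq.int(ridx[j] + 1L,
                                length.out = max(0L, ends[j] - ridx[j]))])
    })
  }
  rounds <- vapply(regions, `[[`, integer(1), "round")
  if (!identical(rounds, seq_along(rounds) - 1L)) {
    stop_corrupt_block("round indices are not consecutive from 0")
  }
  iters <- vector("list", length(regions))
  summaries <- character()
  for (j in seq_along(regions)) {
    parsed <- parse_iteration_region(regions[[j]]$lines, regions[[j]]$round)
    iters[[j]] <- parsed$iteration
    if (!is.na(parsed$summary)) summaries <- c(summaries, parsed$summary)
  }
  qr <- query_result(
    query_id = query_id,
    query_title = title,
    query_length = qlen,
    iterations = iters,
    summary_text = summaries,
    footer = footer
  )
  attr(qr, "footer_meta") <- posted
  qr
}

new_diagnostics <- function(warnings = list(), truncated = FALSE) {
  tbl <- if (length(warnings)) {
    tibble::tibble(
      line = vapply(warnings, function(w) as.integer(w$line), integer(1)),
      message = vapply(warnings, function(w) as.character(w$message), character(1))
    )
  } else {
    tibble::tibble(line = integer(), message = character())
  }
  list(warnings = tbl, truncated = truncated)
}

# Shared streaming core: parse blocks one at a time, hand each result to
# `on_result`, and return general info + diagnostics. Corrupt blocks are
# skipped with a diagnostic unless strict = TRUE.
parse_stream <- function(source, on_result, strict = FALSE) {
  it <- scan_query_blocks(source)
  info <- NULL
  warnings <- list()
  last_failed <- FALSE
  first <- TRUE
  n_blocks <- 0L
  repeat {
    blk <- it$next_block()
    if (is.null(blk)) break
    n_blocks <- n_blocks + 1L
    lines <- blk$lines
    offset <- 0L
    if (first) {
      first <- FALSE
      a <- grep(RE_QUERY_ANCHOR, lines)[1]
      if (a > 1) {
        info <- parse_general_header(lines[seq_len(a - 1L)])
        offset <- a - 1L
        lines <- lines[a:length(lines)]
      }
    }
    res <- tryCatch(parse_query_block(lines), error = function(e) e)
    if (inherits(res, "condition")) {
      if (strict) rlang::cnd_signal(res)
      warnings[[length(warnings) + 1L]] <- list(
        line = blk$start_line + offset,
        message = sprintf("skipped corrupt query block at line %d: %s",
                          blk$start_line + offset, conditionMessage(res))
      )
      last_failed <- TRUE
      next
    }
    last_failed <- FALSE
    meta <- attr(res, "footer_meta")
    attr(res, "footer_meta") <- NULL
    if (!is.null(info) && !is.null(meta) && is.na(info$database_posted_date) &&
        !is.null(meta$posted_date) && !is.na(meta$posted_date)) {
      info$database_posted_date <- meta$posted_date
      if (is.na(info$database_num_letters)) {
        info$database_num_letters <- meta$num_letters
      }
      if (is.na(info$database_num_sequences)) {
        info$database_num_sequences <- meta$num_sequences
      }
    }
    on_result(res)
  }
  list(info = info, diagnostics = new_diagnostics(warnings, truncated = last_failed))
}

#' Parse a BLAST plain-text report
#'
#' Streams over the report one query block at a time and builds the full
#' lossless model. Corrupt blocks are skipped with a diagnostic by default
#' (`strict = TRUE` aborts on the first one); a corrupt final block
#' additionally flags the report as truncated.
#'
#' @param source A file path, readable text connection, or character vector
#'   of report lines.
#' @param strict Abort on the first corrupt block instead of skipping it.
#' @return A list with `info` ([general_info()]), `results` (list of
#'   [query_result()] in input order) and `diagnostics` (a list with a
#'   `warnings` tibble of `line`/`message` and a `truncated` flag).
#' @export
parse_report <- function(source, strict = FALSE) {
  results <- list()
  out <- parse_stream(source, function(qr) {
    results[[length(results) + 1L]] <<- qr
  }, strict = strict)
  list(info = out$info, results = results, diagnostics = out$diagnostics)
}
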