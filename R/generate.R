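# Synthetic-report generator: deterministic models with exact ground truth,
# rendered in the legacy BLAST pairwise text layout. Render->parse identity
# is the package's central oracle, so the renderer and parser share their
# format knowledge (anchors, wrapping, grades lines) exactly.

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

fmt_comma <- function(n) formatC(n, format = "d", big.mark = ",")

PROTEIN_GROUPS <- list(
  c("A", "G"), c("D", "E"), c("K", "R"), c("F", "Y"),
  c("I", "L", "V"), c("S", "T"), c("N", "Q"), c("H", "W"), c("M", "C")
)
DNA_LETTERS <- c("A", "C", "G", "T")

#' Specification for the synthetic-report generator
#'
#' Describes one deterministic synthetic BLAST report: how many queries,
#' which program family, how many psiblast rounds, and the shape of the
#' alignments. Counts given as a two-element range are sampled uniformly
#' per draw. All randomness derives from `seed`, so equal specs produce
#' byte-identical reports.
#'
#' @param seed Integer RNG seed.
#' @param num_queries Number of queries in the report.
#' @param program_family One of `"blastp"`, `"blastn"`, `"blastx"`,
#'   `"psiblast"`.
#' @param rounds_per_query Number of psiblast rounds (must be 1 for other
#'   programs).
#' @param subjects_per_query Range `c(min, max)` of subjects per round
#'   (min may be 0 to allow "No hits found" rounds).
#' @param hsps_per_subject Range of HSPs per subject.
#' @param alignment_length Range of alignment columns per HSP.
#' @param gap_rate Expected fraction of gap columns, in `[0, 0.4]`.
#' @param identity_rate Expected fraction of identical columns among
#'   non-gap columns, in `[0, 1]`.
#' @param length_line_style `"parenthetical"` for the legacy
#'   `"(N letters)"` / `"Length = N"` declarations, `"keyword"` for the
#'   later `"Length=N"` form.
#' @param wrap_width Alignment wrap width in columns (default 60, the
#'   standard BLAST layout).
#' @param planted_subject_ids Optional character vector; element `i`
#'   replaces the id of the first subject of query `i`, guaranteeing a
#'   known subject placement for lookup tests.
#' @param database_name Database name printed in header and footer.
#' @return An object of class `blast_generator_spec`.
#' @export
generator_spec <- function(seed = 1L, num_queries = 10L,
                           program_family = "blastp",
                           rounds_per_query = 1L,
                           subjects_per_query = c(1L, 4L),
                           hsps_per_subject = c(1L, 2L),
                           alignment_length = c(30L, 90L),
                           gap_rate = 0.08, identity_rate = 0.45,
                           length_line_style = "parenthetical",
                           wrap_width = 60L,
                           planted_subject_ids = NULL,
                           database_name = "uniref100") {
  program_family <- match.arg(program_family,
                              c("blastp", "blastn", "blastx", "psiblast"))
  length_line_style <- match.arg(length_line_style,
                                 c("parenthetical", "keyword"))
  chk_range <- function(r, name, lo_min = 1L) {
    if (length(r) == 1) r <- c(r, r)
    r <- as.integer(r)
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < lo_min) {
      stop_invalid_spec(sprintf("invalid range for %s", name))
    }
    r
  }
  if (is.na(num_queries) || num_queries < 1) {
    stop_invalid_spec("num_queries must be >= 1")
  }
  if (program_family != "psiblast" && rounds_per_query != 1) {
    stop_invalid_spec("rounds_per_query > 1 requires program_family 'psiblast'")
  }
  if (rounds_per_query < 1) stop_invalid_spec("rounds_per_query must be >= 1")
  if (is.na(gap_rate) || gap_rate < 0 || gap_rate > 0.4) {
    stop_invalid_spec("gap_rate must be in [0, 0.4]")
  }
  if (is.na(identity_rate) || identity_rate < 0 || identity_rate > 1) {
    stop_invalid_spec("identity_rate must be in [0, 1]")
  }
  if (wrap_width < 20) stop_invalid_spec("wrap_width must be >= 20")
  structure(
    list(
      seed = as.integer(seed),
      num_queries = as.integer(num_queries),
      program_family = program_family,
      rounds_per_query = as.integer(rounds_per_query),
      subjects_per_query = chk_range(subjects_per_query, "subjects_per_query", 0L),
      hsps_per_subject = chk_range(hsps_per_subject, "hsps_per_subject", 1L),
      alignment_length = chk_range(alignment_length, "alignment_length", 10L),
      gap_rate = gap_rate,
      identity_rate = identity_rate,
      length_line_style = length_line_style,
      wrap_width = as.integer(wrap_width),
      planted_subject_ids = planted_subject_ids,
      database_name = database_name
    ),
    class = "blast_generator_spec"
  )
}

random_token <- function(n = 6L) {
  paste(sample(c(LETTERS, 0:9), n, replace = TRUE), collapse = "")
}

word_pool <- c(
  "putative", "uncharacterized", "protein", "kinase", "domain",
  "containing", "transcription", "factor", "membrane", "receptor",
  "hypothetical", "synthetic", "fragment", "homolog", "precursor",
  "binding", "transferase", "ribosomal", "subunit", "mitochondrial"
)

random_description <- function() {
  paste(sample(word_pool, sample(3:10, 1), replace = TRUE), collapse = " ")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1)

sample_evalue_token <- function() {
  if (runif(1) < 0.1) return("0.0")
  mant <- sample(1:9, 1)
  expo <- sample(1:170, 1)
  if (expo >= 100) {
    if (mant == 1L) sprintf("e-%d", expo) else sprintf("%de-%d", mant, expo)
  } else if (expo >= 4) {
    sprintf("%de-%02d", mant, expo)
  } else {
    format(mant * 10^-expo, scientific = FALSE)
  }
}

# Build one HSP with self-consistent strings, counts and coordinates.
build_hsp <- function(family, len_range, gap_rate, identity_rate, qlen,
                      wrap_width = 60L) {
  L <- sample_range(len_range)
  g <- min(round(gap_rate * L), max(L - 2L, 0L))
  if (g > 0 && runif(1) < 0.2) g <- 0L # some gap-free HSPs even at gap_rate > 0
  n <- L - g
  protein <- family != "blastn"
  i <- min(n, round(identity_rate * n))
  pos_extra <- if (protein) round(0.3 * (n - i)) else 0L
  # Every wrap window must keep at least one residue on each sequence or
  # the rendered triplet would have no coordinates; re-roll gap placement
  # until that holds (short tail windows make all-gap windows possible).
  window <- ceiling(seq_len(L) / wrap_width)
  repeat {
    cols <- sample.int(L) # random assignment of column classes
    gap_cols <- if (g > 0) cols[seq_len(g)] else integer()
    gq_n <- if (g > 0) sample(0:g, 1) else 0L
    q_gap <- gap_cols[seq_len(gq_n)]
    s_gap <- setdiff(gap_cols, q_gap)
    ok <- TRUE
    for (w in unique(window)) {
      idx <- which(window == w)
      if (all(idx %in% q_gap) || all(idx %in% s_gap)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  nongap <- cols[setdiff(seq_len(L), seq_len(g))]
  id_cols <- nongap[seq_len(i)]
  pos_cols <- if (pos_extra > 0) nongap[i + seq_len(pos_extra)] else integer()
  mis_cols <- setdiff(nongap, c(id_cols, pos_cols))

  qc <- sc <- mc <- character(L)
  alphabet <- if (protein) unlist(PROTEIN_GROUPS) else DNA_LETTERS
  for (col in q_gap) {
    qc[col] <- "-"; sc[col] <- sample(alphabet, 1); mc[col] <- " "
  }
  for (col in s_gap) {
    sc[col] <- "-"; qc[col] <- sample(alphabet, 1); mc[col] <- " "
  }
  for (col in id_cols) {
    a <- sample(alphabet, 1)
    qc[col] <- a; sc[col] <- a
    mc[col] <- if (protein) a else "|"
  }
  for (col in pos_cols) {
    grp <- PROTEIN_GROUPS[[sample(length(PROTEIN_GROUPS), 1)]]
    pair <- sample(grp, 2)
    qc[col] <- pair[1]; sc[col] <- pair[2]; mc[col] <- "+"
  }
  for (col in mis_cols) {
    if (protein) {
      gi <- sample(length(PROTEIN_GROUPS), 2)
      qc[col] <- sample(PROTEIN_GROUPS[[gi[1]]], 1)
      sc[col] <- sample(PROTEIN_GROUPS[[gi[2]]], 1)
    } else {
      pair <- sample(DNA_LETTERS, 2)
      qc[col] <- pair[1]; sc[col] <- pair[2]
    }
    mc[col] <- " "
  }

  bits <- sample(250:4000, 1) / 10
  token <- sample_evalue_token()
  stats <- hsp_stats(
    bit_score = bits,
    raw_score = round(bits * 2.2),
    evalue = parse_evalue_token(token),
    evalue_token = token,
    num_identities = i,
    num_positives = if (protein) i + pos_extra else NA_integer_,
    num_gaps = g,
    alignment_length = L
  )

  step_q <- if (family == "blastx") 3L else 1L
  frame <- if (family == "blastx") sample(c(-3:-1, 1:3), 1) else NA_integer_
  dir_q <- if (!is.na(frame) && frame < 0) -1L else 1L
  sstrand <- if (family == "blastn") sample(c("plus", "minus"), 1) else NA_character_
  dir_s <- if (identical(sstrand, "minus")) -1L else 1L
  nq <- L - length(q_gap)
  ns <- L - length(s_gap)
  qspan <- step_q * nq
  if (dir_q > 0) {
    qs <- sample.int(qlen - qspan + 1L, 1)
    qe <- qs + qspan - 1L
  } else {
    qs <- sample(qspan:qlen, 1)
    qe <- qs - qspan + 1L
  }
  slack <- sample(10:200, 1)
  slen <- ns + slack
  if (dir_s > 0) {
    ss <- sample.int(slen - ns + 1L, 1)
    se <- ss + ns - 1L
  } else {
    ss <- sample(ns:slen, 1)
    se <- ss - ns + 1L
  }

  list(
    hsp = hsp(
      stats = stats,
      query_start = qs, query_end = qe,
      subject_start = ss, subject_end = se,
      query_frame = frame,
      query_strand = if (family == "blastn") "plus" else NA_character_,
      subject_strand = sstrand,
      aligned_query = paste(qc, collapse = ""),
      midline = paste(mc, collapse = ""),
      aligned_subject = paste(sc, collapse = "")
    ),
    subject_len_floor = slen
  )
}

#' Generate a ground-truth result model
#'
#' Draws a complete hierarchical model (general info, query results with
#' iterations, subject alignments and HSPs) from a [generator_spec()]. All
#' model invariants hold by construction: printed percentages are the
#' truncated percentages of the drawn counts, coordinates are derived from
#' the gap placements (with the 3x nucleotide step for blastx queries), and
#' the midline follows the letter/`+`/space convention (`|`/space for
#' blastn). Deterministic given `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A list with elements `info` ([general_info()]) and `results`
#'   (list of [query_result()]).
#' @export
generate_model <- function(spec) {
  if (!inherits(spec, "blast_generator_spec")) {
    stop_invalid_spec("spec must be created by generator_spec()")
  }
  with_seed(spec$seed, {
    family <- spec$program_family
    program <- toupper(family)
    info <- general_info(
      program_name = program,
      program_version = "2.2.26",
      database_name = spec$database_name,
      database_posted_date = "May 30, 2007 11:40 PM",
      database_num_sequences = sample(1000:999999, 1),
      database_num_letters = sample(1000000:99999999, 1)
    )
    info$raw_header <- paste(render_general_header(info), collapse = "\n")

    step_q <- if (family == "blastx") 3L else 1L
    results <- vector("list", spec$num_queries)
    for (k in seq_len(spec$num_queries)) {
      qid <- sprintf("SYNQ%05d.Contig%d", k, sample(1:99, 1))
      qtitle <- paste(c(qid, sample(word_pool, sample(0:4, 1))), collapse = " ")
      qlen <- step_q * spec$alignment_length[2] + sample(50:150, 1)
      iters <- vector("list", spec$rounds_per_query)
      for (r in seq_len(spec$rounds_per_query)) {
        n_sub <- sample_range(spec$subjects_per_query)
        aligns <- vector("list", n_sub)
        for (j in seq_along(aligns)) {
          sid <- paste0("UniRef100_", random_token())
          if (r == 1L && j == 1L && !is.null(spec$planted_subject_ids) &&
              k <= length(spec$planted_subject_ids)) {
            sid <- spec$planted_subject_ids[[k]]
          }
          n_hsp <- sample_range(spec$hsps_per_subject)
          built <- lapply(seq_len(n_hsp), function(x) {
            build_hsp(family, spec$alignment_length, spec$gap_rate,
                      spec$identity_rate, qlen, spec$wrap_width)
          })
          slen <- max(vapply(built, function(b) as.numeric(b$subject_len_floor),
                             numeric(1)))
          aligns[[j]] <- subject_alignment(
            subject_id = sid,
            subject_description = random_description(),
            subject_length = slen,
            hsps = lapply(built, `[[`, "hsp")
          )
        }
        converged <- family == "psiblast" && r == spec$rounds_per_query &&
          runif(1) < 0.5
        iters[[r]] <- iteration(round_index = r - 1L, converged = converged,
                                alignments = aligns)
      }
      fs <- footer_stats(
        lambda_ungapped = sample(c(0.318, 0.305, 0.267), 1),
        k_ungapped = sample(c(0.135, 0.046, 0.041), 1),
        h_ungapped = sample(c(0.401, 0.21, 0.14), 1),
        lambda_gapped = 0.267, k_gapped = 0.041, h_gapped = 0.14,
        matrix_name = if (family == "blastn") NA_character_ else "BLOSUM62",
        gap_open = if (family == "blastn") NA_integer_ else 11L,
        gap_extend = if (family == "blastn") NA_integer_ else 1L
      )
      fs$raw_footer <- paste(render_footer_block(fs, info), collapse = "\n")
      summaries <- vapply(
        iters,
        function(it) {
          if (length(it$alignments) == 0) NA_character_ else
            paste(render_summary_block(it$alignments), collapse = "\n")
        },
        character(1)
      )
      results[[k]] <- query_result(
        query_id = qid,
        query_title = qtitle,
        query_length = qlen,
        iterations = iters,
        summary_text = summaries[!is.na(summaries)],
        footer = fs
      )
    }
    list(info = info, results = results)
  })
}

#' Generate a rendered synthetic report
#'
#' Convenience wrapper: [generate_model()] then [render_report()] with the
#' spec's dialect and wrap width.
#'
#' @param spec A [generator_spec()].
#' @return Character vector of report lines.
#' @export
generate_report <- function(spec) {
  m <- generate_model(spec)
  render_report(m$info, m$results, dialect = spec$length_line_style,
                wrap_width = spec$wrap_width)
}

#' Deterministically corrupt a report for robustness tests
#'
#' @param lines Report text as a character vector of lines.
#' @param seed Integer seed controlling where the corruption lands.
#' @param mode `"truncate_tail"` cuts the report at a random offset inside
#'   the final query block; `"mangle_score_line"` rewrites one random
#'   `Score =` line to garbage; `"drop_length_line"` deletes one subject
#'   Length declaration; `"none"` returns the input unchanged.
#' @return Character vector of corrupted report lines.
#' @export
corrupt_report <- function(lines, seed = 1L,
                           mode = c("truncate_tail", "mangle_score_line",
                                    "drop_length_line", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(lines)
  with_seed(seed, {
    switch(mode,
      truncate_tail = {
        anchors <- grep("^Query=", lines)
        last <- anchors[length(anchors)]
        if (last + 2 > length(lines)) return(lines[seq_len(last)])
        cut <- sample((last + 2):length(lines), 1)
        lines[seq_len(cut - 1)]
      },
      mangle_score_line = {
        scores <- grep("^\\s*Score =", lines)
        if (length(scores) == 0) return(lines)
        pick <- scores[sample(length(scores), 1)]
        lines[pick] <- " Score = ### corrupted ###"
        lines
      },
      drop_length_line = {
        lens <- grep("^(\\s+Length = [0-9,]+\\s*|Length=[0-9]+)$", lines)
        # only subject declarations: keep those preceded by a '>' block,
        # i.e. drop query-level declarations right after a Query= line
        qanchors <- grep("^Query=", lines)
        lens <- lens[!(lens %in% (qanchors + 1))]
        if (length(lens) == 0) return(lines)
        pick <- lens[sample(length(lens), 1)]
        lines[-pick]
      }
    )
  })
}
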