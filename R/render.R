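# Rendering a model back to legacy BLAST pairwise text. The layout mirrors
# NCBI BLAST <= 2.2.26: a program header, per-query blocks with one-line
# summaries, '>' subject blocks with wrapped descriptions, Score/Identities
# grades lines, Query/midline/Sbjct triplets at a fixed wrap width, and the
# Karlin-Altschul footer.

render_general_header <- function(info) {
  c(
    sprintf("%s %s [Sep-21-2011]", info$program_name, info$program_version),
    "",
    "Reference: Altschul, Stephen F., Thomas L. Madden, Alejandro A. Schaffer,",
    "Jinghui Zhang, Zheng Zhang, Webb Miller, and David J. Lipman (1997),",
    "\"Gapped BLAST and PSI-BLAST: a new generation of protein database search",
    "programs\", Nucleic Acids Res. 25:3389-3402.",
    "",
    sprintf("Database: %s", info$database_name),
    sprintf("           %s sequences; %s total letters",
            fmt_comma(info$database_num_sequences),
            fmt_comma(info$database_num_letters))
  )
}

render_footer_block <- function(fs, info) {
  lines <- c(
    sprintf("  Database: %s", info$database_name),
    sprintf("    Posted date:  %s", info$database_posted_date),
    sprintf("  Number of letters in database: %s",
            fmt_comma(info$database_num_letters)),
    sprintf("  Number of sequences in database:  %s",
            fmt_comma(info$database_num_sequences)),
    "",
    "Lambda     K      H",
    sprintf("   %.3f   %.4f    %.3f", fs$lambda_ungapped, fs$k_ungapped,
            fs$h_ungapped)
  )
  if (!is.na(fs$lambda_gapped)) {
    lines <- c(lines,
      "",
      "Gapped",
      "Lambda     K      H",
      sprintf("   %.3f   %.4f    %.3f", fs$lambda_gapped, fs$k_gapped,
              fs$h_gapped)
    )
  }
  if (!is.na(fs$matrix_name)) {
    lines <- c(lines, "", sprintf("Matrix: %s", fs$matrix_name))
  }
  if (!is.na(fs$gap_open)) {
    lines <- c(lines, sprintf("Gap Penalties: Existence: %d, Extension: %d",
                              fs$gap_open, fs$gap_extend))
  }
  lines
}

render_summary_block <- function(alignments) {
  rows <- vapply(alignments, function(al) {
    b <- best_hsp(al)
    label <- paste(al$subject_id, al$subject_description)
    if (nchar(label) > 63) label <- substr(label, 1, 63)
    sprintf("%-63s %5s  %s", label,
            format(b$stats$bit_score, trim = TRUE, digits = 7),
            b$stats$evalue_token)
  }, character(1))
  c(
    "                                                                 Score    E",
    "Sequences producing significant alignments:                      (bits) Value",
    "",
    rows
  )
}

wrap_subject_header <- function(subject_id, description, wrap_width) {
  words <- strsplit(description, " ", fixed = TRUE)[[1]]
  first <- paste0(">", subject_id)
  lines <- character()
  cur <- first
  for (w in words) {
    cand <- paste(cur, w)
    if (nchar(cand) > wrap_width && cur != first && !identical(cur, "         ")) {
      lines <- c(lines, cur)
      cur <- paste("         ", w)
    } else if (nchar(cand) > wrap_width && cur == first) {
      # always keep at least one word on the anchor line
      lines <- c(lines, cand)
      cur <- "         "
    } else {
      cur <- cand
    }
  }
  if (!identical(cur, "         ")) lines <- c(lines, cur)
  lines
}

render_alignment_rows <- function(h, wrap_width) {
  L <- h$stats$alignment_length
  step_q <- if (!is.na(h$query_frame)) 3L else 1L
  dir_q <- if (h$query_end >= h$query_start) 1L else -1L
  dir_s <- if (h$subject_end >= h$subject_start) 1L else -1L
  cur_q <- h$query_start
  cur_s <- h$subject_start
  out <- character()
  starts <- seq(1L, L, by = wrap_width)
  for (st in starts) {
    en <- min(st + wrap_width - 1L, L)
    qseg <- substr(h$aligned_query, st, en)
    mseg <- substr(h$midline, st, en)
    sseg <- substr(h$aligned_subject, st, en)
    rq <- count_non_gap(qseg)
    rs <- count_non_gap(sseg)
    if (rq == 0 || rs == 0) {
      stop_invalid_model("alignment segment with no residues cannot be rendered")
    }
    q_end <- cur_q + dir_q * (step_q * rq - 1L)
    s_end <- cur_s + dir_s * (rs - 1L)
    prefix <- sprintf("Query: %-6d ", cur_q)
    out <- c(out,
             paste0(prefix, qseg, "  ", q_end),
             paste0(strrep(" ", nchar(prefix)), mseg),
             sprintf("Sbjct: %-6d %s  %d", cur_s, sseg, s_end),
             "")
    cur_q <- q_end + dir_q
    cur_s <- s_end + dir_s
  }
  out
}

cap_strand <- function(s) if (s == "plus") "Plus" else "Minus"

render_hsp_block <- function(h, wrap_width) {
  grades <- format_hsp_stats(h$stats)
  lines <- paste0(" ", grades)
  if (!is.na(h$query_frame)) {
    lines <- c(lines, sprintf(" Frame = %+d", h$query_frame))
  }
  if (!is.na(h$query_strand)) {
    lines <- c(lines, sprintf(" Strand = %s / %s", cap_strand(h$query_strand),
                              cap_strand(h$subject_strand)))
  }
  c(lines, "", render_alignment_rows(h, wrap_width))
}

render_subject_block <- function(al, dialect, wrap_width) {
  lines <- wrap_subject_header(al$subject_id, al$subject_description,
                               wrap_width)
  if (dialect == "parenthetical") {
    lines <- c(lines, sprintf("          Length = %s",
                              fmt_comma(al$subject_length)))
  } else {
    lines <- c(lines, sprintf("Length=%d", al$subject_length))
  }
  lines <- c(lines, "")
  for (h in al$hsps) {
    lines <- c(lines, render_hsp_block(h, wrap_width))
  }
  lines
}

render_query_block <- function(qr, family, dialect, wrap_width) {
  lines <- sprintf("Query= %s", qr$query_title)
  if (dialect == "parenthetical") {
    lines <- c(lines, sprintf("         (%s letters)",
                              fmt_comma(qr$query_length)))
  } else {
    lines <- c(lines, sprintf("Length=%d", qr$query_length))
  }
  lines <- c(lines, "")
  n_iter <- length(qr$iterations)
  for (it in qr$iterations) {
    if (family == "psiblast") {
      lines <- c(lines, sprintf("Results from round %d", it$round_index + 1L),
                 "")
    }
    if (length(it$alignments) == 0) {
      lines <- c(lines, " ***** No hits found ******", "")
    } else {
      lines <- c(lines, render_summary_block(it$alignments), "")
      for (al in it$alignments) {
        lines <- c(lines, render_subject_block(al, dialect, wrap_width))
      }
    }
    if (it$converged) lines <- c(lines, "CONVERGED!", "")
  }
  if (!is.null(qr$footer)) {
    lines <- c(lines, strsplit(qr$footer$raw_footer, "\n", fixed = TRUE)[[1]])
  }
  c(lines, "")
}

#' Render a result model as a BLAST plain-text report
#'
#' Inverse of [parse_report()]: emits the legacy pairwise layout (header,
#' `Query=` blocks, one-line summaries, `>` subject blocks, grades lines
#' built by [format_hsp_stats()], Query/midline/Sbjct triplets, and the
#' Karlin-Altschul footer; `Results from round N` separators for psiblast).
#' Parsing the rendered text reproduces the model exactly.
#'
#' @param info A [general_info()] object.
#' @param results List of [query_result()] objects.
#' @param dialect Length-line style: `"parenthetical"` (legacy
#'   `"(N letters)"`) or `"keyword"` (`"Length=N"`).
#' @param wrap_width Alignment wrap width in columns.
#' @return Character vector of report lines.
#' @export
render_report <- function(info, results, dialect = c("parenthetical", "keyword"),
                          wrap_width = 60L) {
  dialect <- match.arg(dialect)
  family <- tolower(info$program_name)
  lines <- c(strsplit(info$raw_header, "\n", fixed = TRUE)[[1]], "")
  for (qr in results) {
    lines <- c(lines, render_query_block(qr, family, dialect, wrap_width))
  }
  lines
}
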