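#' Report-level metadata for a BLAST run
#'
#' Holds the program identity, the database the queries were searched
#' against, and the verbatim report header block. Every field other than
#' `raw_header` is parsed out of that block (or out of the first per-query
#' footer, for the posted date), so the object is lossless: the raw text can
#' always be re-emitted.
#'
#' @param program_name Program token as printed in the report header, one of
#'   `"BLASTP"`, `"BLASTN"`, `"BLASTX"`, `"PSIBLAST"` (case-insensitive).
#' @param program_version Version token, e.g. `"2.2.26"`.
#' @param database_name Database name as printed.
#' @param database_posted_date Posted-date string, verbatim (e.g.
#'   `"May 30, 2007 11:40 PM"`), or `NA`.
#' @param database_num_sequences Number of sequences in the database, or `NA`.
#' @param database_num_letters Number of letters in the database, or `NA`.
#' @param raw_header The verbatim header block (lines joined with `"\n"`).
#' @return An object of class `blast_general_info`.
#' @export
general_info <- function(program_name, program_version,
                         database_name = NA_character_,
                         database_posted_date = NA_character_,
                         database_num_sequences = NA_integer_,
                         database_num_letters = NA_real_,
                         raw_header = "") {
  program_name <- toupper(program_name)
  if (!program_name %in% c("BLASTP", "BLASTN", "BLASTX", "PSIBLAST")) {
    stop_not_blast_report(sprintf("unsupported program '%s'", program_name))
  }
  structure(
    list(
      program_name = program_name,
      program_version = as.character(program_version),
      database_name = as.character(database_name),
      database_posted_date = as.character(database_posted_date),
      database_num_sequences = as.integer(database_num_sequences),
      database_num_letters = as.numeric(database_num_letters),
      raw_header = as.character(raw_header)
    ),
    class = "blast_general_info"
  )
}

#' One query's full result
#'
#' @param query_id First whitespace-delimited token of the `Query=` line.
#' @param query_title Full query title as printed.
#' @param query_length Query length in letters (nucleotides for blastn and
#'   blastx, residues otherwise).
#' @param iterations List of [iteration()] objects, one per search round
#'   (always exactly one for non-psiblast programs).
#' @param summary_text Character vector of verbatim one-line-summary blocks,
#'   one element per round that printed one (may be empty).
#' @param footer A [footer_stats()] object or `NULL`.
#' @return An object of class `blast_query_result`.
#' @export
query_result <- function(query_id, query_title, query_length,
                         iterations, summary_text = character(),
                         footer = NULL) {
  stopifnot(length(iterations) >= 1)
  structure(
    list(
      query_id = as.character(query_id),
      query_title = as.character(query_title),
      query_length = as.integer(query_length),
      iterations = iterations,
      summary_text = as.character(summary_text),
      footer = footer
    ),
    class = "blast_query_result"
  )
}

#' One search round (psiblast iteration)
#'
#' Non-psiblast programs have a single implicit round with `round_index = 0`.
#'
#' @param round_index 0-based round index.
#' @param converged `TRUE` if the report printed `CONVERGED!` for this round.
#' @param alignments List of [subject_alignment()] objects, in report order
#'   (empty for a "No hits found" round).
#' @return An object of class `blast_iteration`.
#' @export
iteration <- function(round_index, converged = FALSE, alignments = list()) {
  structure(
    list(
      round_index = as.integer(round_index),
      converged = isTRUE(converged),
      alignments = alignments
    ),
    class = "blast_iteration"
  )
}

#' One subject hit with its HSPs
#'
#' @param subject_id Token following the `>` anchor.
#' @param subject_description Description, with wrapped lines joined by
#'   single spaces.
#' @param subject_length Subject sequence length.
#' @param hsps Non-empty list of [hsp()] objects in report order.
#' @return An object of class `blast_subject_alignment`.
#' @export
subject_alignment <- function(subject_id, subject_description,
                              subject_length, hsps) {
  if (length(hsps) < 1) stop_corrupt_model("subject alignment with no HSP")
  structure(
    list(
      subject_id = as.character(subject_id),
      subject_description = as.character(subject_description),
      subject_length = as.integer(subject_length),
      hsps = hsps
    ),
    class = "blast_subject_alignment"
  )
}

#' Per-HSP statistics, exactly as printed
#'
#' Counts and their printed truncated percentages are both stored; scores
#' and e-values are parsed, never recomputed. `evalue_token` keeps the
#' e-value exactly as the report printed it, so the grades line round-trips
#' byte-for-byte.
#'
#' @param bit_score Bit score.
#' @param raw_score Raw (matrix-level) score.
#' @param evalue Numeric e-value.
#' @param evalue_token The e-value as printed (defaults to a canonical
#'   rendering of `evalue`).
#' @param num_identities,num_positives,num_gaps Column counts over the
#'   alignment; `num_positives` is `NA` for nucleotide output.
#' @param alignment_length Number of alignment columns.
#' @param identity_pct,positive_pct,gap_pct Printed integer percentages;
#'   default to the truncated percentage of the corresponding count.
#' @return An object of class `blast_hsp_stats`.
#' @export
hsp_stats <- function(bit_score, raw_score, evalue,
                      evalue_token = format_evalue_token(evalue),
                      num_identities, num_positives = NA_integer_,
                      num_gaps = 0L, alignment_length,
                      identity_pct = compute_truncated_pct(num_identities, alignment_length),
                      positive_pct = if (is.na(num_positives)) NA_integer_ else
                        compute_truncated_pct(num_positives, alignment_length),
                      gap_pct = compute_truncated_pct(num_gaps, alignment_length)) {
  structure(
    list(
      bit_score = as.numeric(bit_score),
      raw_score = as.integer(raw_score),
      evalue = as.numeric(evalue),
      evalue_token = as.character(evalue_token),
      num_identities = as.integer(num_identities),
      num_positives = as.integer(num_positives),
      num_gaps = as.integer(num_gaps),
      alignment_length = as.integer(alignment_length),
      identity_pct = as.integer(identity_pct),
      positive_pct = as.integer(positive_pct),
      gap_pct = as.integer(gap_pct)
    ),
    class = "blast_hsp_stats"
  )
}

#' One high-scoring segment pair
#'
#' Coordinates are stored exactly as printed: 1-based, inclusive, and
#' descending for minus-strand or negative-frame segments. Strand and frame
#' are explicit; coordinates are never silently swapped.
#'
#' @param stats A [hsp_stats()] object.
#' @param query_start,query_end,subject_start,subject_end Printed coordinates.
#' @param query_frame Signed frame for blastx, else `NA`.
#' @param query_strand,subject_strand `"plus"`/`"minus"` for blastn, else `NA`.
#' @param aligned_query,midline,aligned_subject The three alignment strings,
#'   all of length `stats$alignment_length`; `'-'` is the gap symbol.
#' @param method Verbatim `Method:` annotation if the Score line carried one.
#' @return An object of class `blast_hsp`.
#' @export
hsp <- function(stats, query_start, query_end, subject_start, subject_end,
                query_frame = NA_integer_, query_strand = NA_character_,
                subject_strand = NA_character_,
                aligned_query, midline, aligned_subject,
                method = NA_character_) {
  structure(
    list(
      stats = stats,
      query_start = as.integer(query_start),
      query_end = as.integer(query_end),
      subject_start = as.integer(subject_start),
      subject_end = as.integer(subject_end),
      query_frame = as.integer(query_frame),
      query_strand = as.character(query_strand),
      subject_strand = as.character(subject_strand),
      aligned_query = as.character(aligned_query),
      midline = as.character(midline),
      aligned_subject = as.character(aligned_subject),
      method = as.character(method)
    ),
    class = "blast_hsp"
  )
}

#' Karlin-Altschul footer statistics
#'
#' The report footer's Lambda/K/H blocks (ungapped and, when printed,
#' gapped), scoring matrix and gap penalties, with the whole footer retained
#' verbatim.
#'
#' @param lambda_ungapped,k_ungapped,h_ungapped Ungapped Karlin-Altschul
#'   parameters.
#' @param lambda_gapped,k_gapped,h_gapped Gapped parameters, or `NA`.
#' @param matrix_name Scoring matrix name, or `NA`.
#' @param gap_open,gap_extend Gap penalties, or `NA`.
#' @param raw_footer Verbatim footer block.
#' @return An object of class `blast_footer_stats`.
#' @export
footer_stats <- function(lambda_ungapped, k_ungapped, h_ungapped,
                         lambda_gapped = NA_real_, k_gapped = NA_real_,
                         h_gapped = NA_real_, matrix_name = NA_character_,
                         gap_open = NA_integer_, gap_extend = NA_integer_,
                         raw_footer = "") {
  structure(
    list(
      lambda_ungapped = as.numeric(lambda_ungapped),
      k_ungapped = as.numeric(k_ungapped),
      h_ungapped = as.numeric(h_ungapped),
      lambda_gapped = as.numeric(lambda_gapped),
      k_gapped = as.numeric(k_gapped),
      h_gapped = as.numeric(h_gapped),
      matrix_name = as.character(matrix_name),
      gap_open = as.integer(gap_open),
      gap_extend = as.integer(gap_extend),
      raw_footer = as.character(raw_footer)
    ),
    class = "blast_footer_stats"
  )
}

#' Truncated percentage, as BLAST prints it
#'
#' BLAST truncates (floors) the percentages on the Identities line rather
#' than rounding: 69/468 prints as 14%, not 15%. Computed in exact integer
#' arithmetic.
#'
#' @param count Numerator count(s), `0 <= count <= total`.
#' @param total Denominator(s), `>= 1`.
#' @return Integer percentage(s), `floor(100 * count / total)`.
#' @examples
#' compute_truncated_pct(168, 468) # 35
#' compute_truncated_pct(165, 474) # 34, not 35
#' @export
compute_truncated_pct <- function(count, total) {
  count <- as.numeric(count)
  total <- as.numeric(total)
  if (any(is.na(total)) || any(total < 1)) {
    stop_invalid_denominator("percentage denominator must be >= 1")
  }
  if (any(is.na(count)) || any(count < 0) || any(count > total)) {
    stop_invalid_denominator("count must satisfy 0 <= count <= total")
  }
  as.integer((100 * count) %/% total)
}

#' Canonical e-value token
#'
#' Renders a numeric e-value the way legacy BLAST prints it: `"0.0"` for
#' zero, plain decimals down to 1e-3, scientific `"3e-39"` below that, and
#' the bare-exponent form `"e-104"` (implicit mantissa 1) once the exponent
#' reaches three digits.
#'
#' @param evalue Non-negative numeric e-value.
#' @return A single character token.
#' @export
format_evalue_token <- function(evalue) {
  stopifnot(length(evalue) == 1, !is.na(evalue), evalue >= 0)
  if (evalue == 0) return("0.0")
  if (evalue >= 1e-3) {
    tok <- format(evalue, scientific = FALSE, trim = TRUE, digits = 7)
    return(tok)
  }
  tok <- sprintf("%.0e", evalue)
  tok <- sub("e-0*(\\d)", "e-\\1", tok) # strip exponent zero-padding
  if (grepl("^1e-\\d{3,}$", tok)) tok <- sub("^1", "", tok)
  tok
}

#' Parse an e-value token
#'
#' Accepts decimal (`"0.001"`), scientific (`"3e-39"`) and bare-exponent
#' (`"e-104"`, read as 1e-104) forms; `"0.0"` parses to exactly 0.
#'
#' @param token Character token from an `Expect =` field.
#' @return A single non-negative numeric value.
#' @export
parse_evalue_token <- function(token) {
  token <- trimws(token)
  if (grepl("^e-?\\d+$", token)) token <- paste0("1", token)
  value <- suppressWarnings(as.numeric(token))
  if (is.na(value) || value < 0) {
    stop_corrupt_block(sprintf("unparseable e-value token '%s'", token))
  }
  value
}

#' Format an HSP's grades lines
#'
#' Reproduces the two statistics lines of an HSP block ("Score = ..." and
#' "Identities = ...") from parsed statistics, byte-for-byte when the stats
#' were themselves parsed from a report. Clauses follow the legacy layout:
#' the Positives clause is omitted for nucleotide output and the Gaps clause
#' is omitted when the HSP has no gaps.
#'
#' @param stats A [hsp_stats()] object.
#' @return Character vector of two lines.
#' @examples
#' s <- hsp_stats(166, 419, 3e-39, num_identities = 168, num_positives = 184,
#'                num_gaps = 69, alignment_length = 468)
#' format_hsp_stats(s)
#' @export
format_hsp_stats <- function(stats) {
  line1 <- sprintf("Score = %s bits (%d), Expect = %s",
                   format(stats$bit_score, trim = TRUE, digits = 7),
                   stats$raw_score, stats$evalue_token)
  line2 <- sprintf("Identities = %d/%d (%d%%)",
                   stats$num_identities, stats$alignment_length,
                   stats$identity_pct)
  if (!is.na(stats$num_positives)) {
    line2 <- sprintf("%s, Positives = %d/%d (%d%%)", line2,
                     stats$num_positives, stats$alignment_length,
                     stats$positive_pct)
  }
  if (stats$num_gaps > 0L) {
    line2 <- sprintf("%s, Gaps = %d/%d (%d%%)", line2,
                     stats$num_gaps, stats$alignment_length, stats$gap_pct)
  }
  c(line1, line2)
}

#' Best HSP of a subject alignment
#'
#' The representative HSP used for one-row-per-subject tables: minimal
#' e-value, ties broken by maximal bit score, then by report order.
#'
#' @param alignment A [subject_alignment()] object.
#' @return The winning [hsp()] object.
#' @export
best_hsp <- function(alignment) {
  hsps <- alignment$hsps
  if (length(hsps) == 0) stop_corrupt_model("alignment has no HSPs")
  ev <- vapply(hsps, function(h) h$stats$evalue, numeric(1))
  bits <- vapply(hsps, function(h) h$stats$bit_score, numeric(1))
  hsps[[order(ev, -bits)[1]]]
}

# ---- validation -----------------------------------------------------------

count_non_gap <- function(s) nchar(gsub("-", "", s, fixed = TRUE))

validate_hsp <- function(h, program_family = "blastp") {
  st <- h$stats
  L <- st$alignment_length
  if (nchar(h$aligned_query) != L || nchar(h$midline) != L ||
      nchar(h$aligned_subject) != L) {
    stop_invalid_model("aligned strings must all have length alignment_length")
  }
  q <- strsplit(h$aligned_query, "")[[1]]
  s <- strsplit(h$aligned_subject, "")[[1]]
  if (any(q == "-" & s == "-")) {
    stop_invalid_model("gap in both sequences at the same column")
  }
  if (st$num_gaps != sum(q == "-") + sum(s == "-")) {
    stop_invalid_model("num_gaps does not match gap symbols")
  }
  if (!is.na(st$num_positives) &&
      !(st$num_identities <= st$num_positives &&
        st$num_positives <= L)) {
    stop_invalid_model("identities <= positives <= alignment_length violated")
  }
  if (st$identity_pct != compute_truncated_pct(st$num_identities, L) ||
      st$gap_pct != compute_truncated_pct(st$num_gaps, L)) {
    stop_invalid_model("printed percentage is not the truncated percentage")
  }
  step_q <- if (!is.na(h$query_frame)) 3L else 1L
  nq <- count_non_gap(h$aligned_query)
  ns <- count_non_gap(h$aligned_subject)
  if (abs(h$query_end - h$query_start) + 1L != step_q * nq) {
    stop_invalid_model("query coordinate span does not match residue count")
  }
  if (abs(h$subject_end - h$subject_start) + 1L != ns) {
    stop_invalid_model("subject coordinate span does not match residue count")
  }
  invisible(h)
}

validate_model <- function(info, results) {
  for (qr in results) {
    idx <- vapply(qr$iterations, function(it) it$round_index, integer(1))
    if (!identical(idx, seq_along(idx) - 1L)) {
      stop_invalid_model("round indices must be 0,1,2,... consecutive")
    }
    for (it in qr$iterations) {
      for (al in it$alignments) {
        for (h in al$hsps) validate_hsp(h)
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.blast_general_info <- function(x, ...) {
  cat(sprintf("<%s %s> database: %s\n", x$program_name, x$program_version,
              x$database_name))
  if (!is.na(x$database_posted_date)) {
    cat("  Posted date:", x$database_posted_date, "\n")
  }
  invisible(x)
}

#' @export
print.blast_query_result <- function(x, ...) {
  n_al <- sum(vapply(x$iterations, function(it) length(it$alignments),
                     integer(1)))
  cat(sprintf("<blast_query_result> %s (%d letters), %d iteration(s), %d alignment(s)\n",
              x$query_id, x$query_length, length(x$iterations), n_al))
  invisible(x)
}

#' @export
print.blast_hsp <- function(x, ...) {
  cat(format_hsp_stats(x$stats), sep = "\n")
  invisible(x)
}
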