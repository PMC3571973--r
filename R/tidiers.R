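# broom-style views of stores and results, and quick-look plots.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

hsp_row <- function(qr, it, al, h, hsp_index) {
  tibble::tibble(
    query_id = qr$query_id,
    round_index = it$round_index,
    subject_id = al$subject_id,
    hsp_index = hsp_index,
    bit_score = h$stats$bit_score,
    raw_score = h$stats$raw_score,
    evalue = h$stats$evalue,
    alignment_length = h$stats$alignment_length,
    num_identities = h$stats$num_identities,
    num_positives = h$stats$num_positives,
    num_gaps = h$stats$num_gaps,
    identity_pct = h$stats$identity_pct,
    query_start = h$query_start, query_end = h$query_end,
    subject_start = h$subject_start, subject_end = h$subject_end
  )
}

#' @rdname tidy.blast_store
#' @exportS3Method generics::tidy
tidy.blast_query_result <- function(x, ...) {
  chunks <- list()
  for (it in x$iterations) {
    for (al in it$alignments) {
      for (k in seq_along(al$hsps)) {
        chunks[[length(chunks) + 1L]] <- hsp_row(x, it, al, al$hsps[[k]], k)
      }
    }
  }
  if (length(chunks)) dplyr::bind_rows(chunks) else hsp_row_empty()
}

hsp_row_empty <- function() {
  tibble::tibble(
    query_id = character(), round_index = integer(), subject_id = character(),
    hsp_index = integer(), bit_score = numeric(), raw_score = integer(),
    evalue = numeric(), alignment_length = integer(),
    num_identities = integer(), num_positives = integer(),
    num_gaps = integer(), identity_pct = integer(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer()
  )
}

#' Tidy a result store into per-HSP rows
#'
#' One row per HSP across every stored query, with scores, e-values,
#' counts and coordinates — the flat view suited to dplyr/ggplot2 work.
#' `glance()` gives a one-row summary of the store.
#'
#' @param x A [blast_store] handle (or a [query_result()] for the
#'   single-query method).
#' @param ... Unused.
#' @return A tibble with one row per HSP.
#' @exportS3Method generics::tidy
tidy.blast_store <- function(x, ...) {
  check_open(x)
  nxt <- iter_results(x)
  chunks <- list()
  repeat {
    qr <- nxt()
    if (is.null(qr)) break
    chunks[[length(chunks) + 1L]] <- tidy(qr)
  }
  if (length(chunks)) dplyr::bind_rows(chunks) else hsp_row_empty()
}

#' @rdname tidy.blast_store
#' @exportS3Method generics::glance
glance.blast_store <- function(x, ...) {
  check_open(x)
  hits <- tidy(x)
  info <- get_general_info(x)
  tibble::tibble(
    program = if (is.null(info)) NA_character_ else info$program_name,
    database = if (is.null(info)) NA_character_ else info$database_name,
    n_queries = length(list_query_ids(x)),
    n_alignments = nrow(dplyr::distinct(
      hits, .data$query_id, .data$round_index, .data$subject_id)),
    n_hsps = nrow(hits),
    min_evalue = if (nrow(hits)) min(hits$evalue) else NA_real_,
    median_identity_pct = if (nrow(hits)) stats::median(hits$identity_pct)
      else NA_real_
  )
}

#' Plot a result table
#'
#' Identity-schema tables get a histogram of identity percentages; other
#' schemas a histogram of -log10 e-values (zero e-values are dropped with
#' a message).
#'
#' @param object A `blast_result_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.blast_result_table <- function(object, ...) {
  schema <- attr(object, "schema")
  df <- tibble::as_tibble(object)
  if (schema == "IDENTITY" || "identity_pct" %in% names(df) &&
      !"evalue" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$identity_pct)) +
      ggplot2::geom_histogram(binwidth = 5, boundary = 0,
                              fill = "steelblue", colour = "white") +
      ggplot2::labs(x = "best-HSP identity (%)", y = "subjects",
                    title = "Identity distribution")
  } else {
    pos <- df[df$evalue > 0, , drop = FALSE]
    if (nrow(pos) < nrow(df)) {
      message(sprintf("dropping %d zero e-value row(s) from the plot",
                      nrow(df) - nrow(pos)))
    }
    ggplot2::ggplot(pos, ggplot2::aes(x = -log10(.data$evalue))) +
      ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                              colour = "white") +
      ggplot2::labs(x = expression(-log[10] ~ "e-value"), y = "subjects",
                    title = "E-value distribution")
  }
}

#' @importFrom rlang .data
NULL
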