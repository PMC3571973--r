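# Single-file result store. Layout: an 8-byte magic, then one serialized
# record per query result, then a serialized metadata block (format-version
# tag, general info, query order, per-record offsets/lengths, parse
# diagnostics), and a 16-byte trailer holding the metadata offset and
# length. Random access seeks straight to a record; nothing else is read.

STORE_MAGIC <- "BLSTRDB1"
STORE_FORMAT_VERSION <- 1L

new_store_handle <- function(path, con, meta) {
  env <- new.env(parent = emptyenv())
  env$db_path <- path
  env$con <- con
  env$mode <- "reading"
  env$meta <- meta
  env$record_reads <- 0L
  class(env) <- "blast_store"
  env
}

check_open <- function(handle) {
  if (!inherits(handle, "blast_store")) {
    stop_storage_io("not a store handle")
  }
  if (handle$mode == "closed") stop_closed_store()
  invisible(handle)
}

#' Build a result store from a BLAST report
#'
#' Parses the report in streaming fashion and writes one record per query
#' result, keyed by query id, plus a metadata record (general info, query
#' order, format-version tag) to a single database file. Each result is
#' written as soon as its block has been parsed, so memory stays bounded.
#' Duplicate query ids keep the first position in the stored order but the
#' later record wins, with a diagnostic warning.
#'
#' @param db_path Destination file path.
#' @param report A report file path, connection, or character vector of
#'   lines.
#' @param strict Abort on the first corrupt block instead of skipping it.
#' @return A list with `handle` (an open read-mode [blast_store] handle for
#'   `db_path`) and `diagnostics` (as in [parse_report()]).
#' @export
build_store <- function(db_path, report, strict = FALSE) {
  if (!is.character(db_path) || length(db_path) != 1 || !nzchar(db_path)) {
    stop_storage_io("db_path must be a non-empty file path")
  }
  dir <- dirname(db_path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    stop_storage_io(sprintf("destination '%s' is not writable", db_path))
  }
  con <- file(db_path, open = "wb")
  ok <- FALSE
  on.exit({
    try(close(con), silent = TRUE)
    if (!ok) unlink(db_path)
  })
  writeBin(charToRaw(STORE_MAGIC), con)
  offsets <- numeric()
  lengths <- numeric()
  order_ids <- character()
  dup_warnings <- list()
  write_record <- function(qr) {
    id <- qr$query_id
    raw <- serialize(qr, NULL, xdr = FALSE)
    pos <- seek(con, where = NA)
    writeBin(raw, con)
    if (id %in% order_ids) {
      dup_warnings[[length(dup_warnings) + 1L]] <<- list(
        line = NA_integer_,
        message = sprintf("duplicate query id '%s': later record wins", id)
      )
    } else {
      order_ids <<- c(order_ids, id)
    }
    offsets[id] <<- pos
    lengths[id] <<- length(raw)
  }
  parsed <- parse_stream(report, write_record, strict = strict)
  diagnostics <- parsed$diagnostics
  if (length(dup_warnings)) {
    extra <- new_diagnostics(dup_warnings)$warnings
    diagnostics$warnings <- dplyr::bind_rows(diagnostics$warnings, extra)
  }
  meta <- list(
    format_version = STORE_FORMAT_VERSION,
    general_info = parsed$info,
    query_order = order_ids,
    offsets = offsets,
    lengths = lengths,
    diagnostics = diagnostics
  )
  mraw <- serialize(meta, NULL, xdr = FALSE)
  mpos <- seek(con, where = NA)
  writeBin(mraw, con)
  writeBin(as.numeric(c(mpos, length(mraw))), con, size = 8)
  close(con)
  on.exit(NULL)
  ok <- TRUE
  list(handle = open_store(db_path), diagnostics = diagnostics)
}

#' Open an existing result store
#'
#' Opens a database file written by [build_store()] for random access. The
#' original report file is never touched; a wrong magic or an unknown
#' format-version tag signals an incompatible store.
#'
#' @param db_path Path to a store file.
#' @return A read-mode handle of class `blast_store`.
#' @export
open_store <- function(db_path) {
  if (!file.exists(db_path)) {
    stop_storage_io(sprintf("store file '%s' does not exist", db_path))
  }
  size <- file.info(db_path)$size
  if (is.na(size) || size < nchar(STORE_MAGIC) + 16) {
    stop_incompatible_store("file is too small to be a result store")
  }
  con <- file(db_path, open = "rb")
  magic <- rawToChar(readBin(con, "raw", n = nchar(STORE_MAGIC)))
  if (!identical(magic, STORE_MAGIC)) {
    close(con)
    stop_incompatible_store("file is not a blastr result store (bad magic)")
  }
  seek(con, where = size - 16)
  trailer <- readBin(con, "numeric", n = 2, size = 8)
  meta <- tryCatch({
    seek(con, where = trailer[1])
    unserialize(readBin(con, "raw", n = trailer[2]))
  }, error = function(e) NULL)
  if (is.null(meta) || !identical(meta$format_version, STORE_FORMAT_VERSION)) {
    close(con)
    stop_incompatible_store("missing or incompatible store format version")
  }
  new_store_handle(db_path, con, meta)
}

#' Fetch one stored result by query id
#'
#' Seeks directly to the record; no other record is read.
#'
#' @param handle An open [blast_store] handle.
#' @param query_id A stored query id.
#' @return The [query_result()] for that id.
#' @export
get_result <- function(handle, query_id) {
  check_open(handle)
  off <- handle$meta$offsets[query_id]
  if (is.na(off)) stop_missing_query(query_id)
  seek(handle$con, where = off)
  raw <- readBin(handle$con, "raw", n = handle$meta$lengths[[query_id]])
  handle$record_reads <- handle$record_reads + 1L
  unserialize(raw)
}

#' Iterate stored results lazily
#'
#' @param handle An open [blast_store] handle.
#' @return A function that returns the next [query_result()] in stored
#'   (input) order on each call, and `NULL` after the last one.
#' @export
iter_results <- function(handle) {
  check_open(handle)
  ids <- handle$meta$query_order
  i <- 0L
  function() {
    if (handle$mode == "closed") stop_closed_store()
    i <<- i + 1L
    if (i > length(ids)) return(NULL)
    get_result(handle, ids[i])
  }
}

#' Read all stored results
#'
#' @param handle An open [blast_store] handle.
#' @return A named list of [query_result()] objects in stored order.
#' @export
read_all_results <- function(handle) {
  check_open(handle)
  ids <- handle$meta$query_order
  out <- lapply(ids, function(id) get_result(handle, id))
  names(out) <- ids
  out
}

#' Stored report metadata
#'
#' @param handle An open [blast_store] handle.
#' @return The stored [general_info()] object.
#' @export
get_general_info <- function(handle) {
  check_open(handle)
  handle$meta$general_info
}

#' Stored query ids in input order
#'
#' @param handle An open [blast_store] handle.
#' @return Character vector of query ids.
#' @export
list_query_ids <- function(handle) {
  check_open(handle)
  handle$meta$query_order
}

#' Diagnostics recorded while the store was built
#'
#' @param handle An open [blast_store] handle.
#' @return The diagnostics list stored by [build_store()].
#' @export
store_diagnostics <- function(handle) {
  check_open(handle)
  handle$meta$diagnostics
}

#' Close a store handle
#'
#' Idempotent: closing an already-closed handle is a no-op.
#'
#' @param handle A [blast_store] handle.
#' @return The handle, invisibly.
#' @export
close_store <- function(handle) {
  if (inherits(handle, "blast_store") && handle$mode != "closed") {
    try(close(handle$con), silent = TRUE)
    handle$con <- NULL
    handle$mode <- "closed"
  }
  invisible(handle)
}

#' @export
print.blast_store <- function(x, ...) {
  if (x$mode == "closed") {
    cat(sprintf("<blast_store> %s (closed)\n", x$db_path))
  } else {
    cat(sprintf("<blast_store> %s: %d quer%s\n", x$db_path,
                length(x$meta$query_order),
                if (length(x$meta$query_order) == 1) "y" else "ies"))
  }
  invisible(x)
}
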