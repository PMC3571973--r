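# Classed conditions shared across the package. Every user-facing failure
# carries a class so callers (and the CLI) can dispatch on it.

abort_blastr <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "blastr_error"), ...)
}

stop_invalid_denominator <- function(msg) abort_blastr("blastr_invalid_denominator", msg)
stop_corrupt_block <- function(msg, line = NA_integer_) {
  abort_blastr("blastr_corrupt_block", msg, line = line)
}
stop_not_blast_report <- function(msg) abort_blastr("blastr_not_blast_report", msg)
stop_corrupt_model <- function(msg) abort_blastr("blastr_corrupt_model", msg)
stop_storage_io <- function(msg) abort_blastr("blastr_storage_io", msg)
stop_missing_query <- function(id) {
  abort_blastr("blastr_missing_query", sprintf("no result stored for query id '%s'", id))
}
stop_closed_store <- function() abort_blastr("blastr_closed_store", "store handle is closed")
stop_incompatible_store <- function(msg) abort_blastr("blastr_incompatible_store", msg)
stop_invalid_threshold <- function(msg) abort_blastr("blastr_invalid_threshold", msg)
stop_invalid_spec <- function(msg) abort_blastr("blastr_invalid_spec", msg)
stop_invalid_model <- function(msg) abort_blastr("blastr_invalid_model", msg)
stop_usage <- function(msg) abort_blastr("blastr_usage", msg)
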