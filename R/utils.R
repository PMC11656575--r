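# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
.assert <- function(cond, msg, class = "medewas_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

# Deterministic child seed derived from one global seed. Offsets keep the
# stages' streams distinct while a single integer reproduces the whole run.
# Kept below 2^31 - 1 so the value is always a valid R integer seed.
#' @keywords internal
#' @noRd
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% 2147483647)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all pipeline outputs (no quoting, no row
#' names), so every artifact stays diff-able text.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
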