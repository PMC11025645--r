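# Plain-text serialization: TSV for word streams and matrices, YAML for
# ground-truth sidecars and configuration. Everything round-trips.

#' Write a word stream as TSV (word, onset, offset)
#' @param stream A `word_stream`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_word_stream <- function(stream, path) {
  df <- data.frame(word = stream$word_ids,
                   onset = sprintf("%.9f", stream$onsets),
                   offset = sprintf("%.9f", stream$offsets))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a word stream written by [write_word_stream()]
#'
#' The transition matrix and entropy rate are not stored in the TSV; if
#' needed they travel in the ground-truth YAML sidecar.
#'
#' @param path TSV path.
#' @param vocab Vocabulary size (defaults to `max(word)`).
#' @return A `word_stream` (without `transition_matrix`/`entropy_rate`).
#' @export
read_word_stream <- function(path, vocab = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(word_ids = as.integer(df$word), onsets = df$onset,
                 offsets = df$offset, transition_matrix = NULL,
                 entropy_rate = NA_real_,
                 vocab = as.integer(vocab %||% max(df$word))),
            class = "word_stream")
}

#' Write a numeric matrix as TSV with a one-line header of attributes
#' @param x Numeric matrix.
#' @param path Output path.
#' @param attrs Named list of scalar attributes stored on a `#` header line.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, attrs = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(attrs)) {
    writeLines(paste0("# ", paste(names(attrs), unlist(attrs), sep = "=",
                                  collapse = "\t")), con)
  }
  utils::write.table(as.matrix(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return Numeric matrix with an `attrs` attribute (named character).
#' @export
read_matrix_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  attrs <- character(0)
  if (startsWith(first, "# ")) {
    skip <- 1L
    fields <- strsplit(sub("^# ", "", first), "\t")[[1]]
    kv <- strsplit(fields, "=")
    attrs <- vapply(kv, `[`, character(1), 2)
    names(attrs) <- vapply(kv, `[`, character(1), 1)
  }
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = skip,
                                   header = FALSE))
  dimnames(m) <- NULL
  attr(m, "attrs") <- attrs
  m
}

#' Write a BOLD run as TSV with tr/run_id recorded in the header
#' @param run A `bold_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  write_matrix_tsv(run$data, path, attrs = list(tr = run$tr,
                                                run_id = run$run_id))
}

#' Read a BOLD run written by [write_bold_run()]
#' @param path TSV path.
#' @return A `bold_run`.
#' @export
read_bold_run <- function(path) {
  m <- read_matrix_tsv(path)
  a <- attr(m, "attrs")
  attr(m, "attrs") <- NULL
  bold_run(m, tr = as.numeric(a[["tr"]]), run_id = a[["run_id"]])
}

#' Write the synthetic ground truth as a YAML sidecar
#' @param truth Named list (entropy rate, noise levels, factor usage, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' Read a ground-truth YAML sidecar
#' @param path YAML path.
#' @return Named list.
#' @export
read_ground_truth <- function(path) {
  yaml::read_yaml(path)
}
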