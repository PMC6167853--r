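#' Read FASTA text
#'
#' @param text a single string, a character vector of lines, or a file path.
#' @return a data.frame with columns `header` (without the leading `>`) and
#'   `sequence`; records appear in file order, multi-line sequences are
#'   concatenated and whitespace-only lines are ignored.
#' @examples
#' read_fasta(">a\nACGT\n>b\nGG\n")
#' @export
read_fasta <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(header = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  is_header <- startsWith(lines, ">")
  if (!is_header[1L])
    stop("FASTA: sequence data before the first '>' header")
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(seq_along(headers), function(k) {
    body <- lines[rec == k & !is_header]
    paste(gsub("\\s", "", body), collapse = "")
  }, character(1))
  data.frame(header = headers, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write FASTA text
#'
#' @param records data.frame with `header` and `sequence` columns (as
#'   returned by [read_fasta()]).
#' @param line_width wrap sequence lines at this many symbols.
#' @param path optional file to write to.
#' @return the FASTA text (one string), invisibly when `path` is given.
#'   `read_fasta(write_fasta(x))` is the identity.
#' @export
write_fasta <- function(records, line_width = 80L, path = NULL) {
  stopifnot(is.data.frame(records),
            all(c("header", "sequence") %in% names(records)),
            line_width >= 1L)
  if (any(grepl("[\r\n]", records$header)))
    stop("FASTA headers must not contain line breaks")
  out <- character(0)
  for (k in seq_len(nrow(records))) {
    s <- records$sequence[k]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = line_width)
    body <- if (n == 0L) character(0)
            else substring(s, starts, pmin(starts + line_width - 1L, n))
    out <- c(out, paste0(">", records$header[k]), body)
  }
  text <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
  else as.character(text)
}
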