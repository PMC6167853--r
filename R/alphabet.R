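#' Create an alphabet
#'
#' An alphabet is an ordered collection of distinct symbols.  The *symbol
#' code* of a symbol is its 0-based position in this order; sequences store
#' codes, not symbols, so every downstream operation (alignment, searching)
#' works on integer arrays and is independent of the symbol type.  Symbols
#' may be single characters, multi-character strings, numbers or any other
#' value with a well-defined identity.
#'
#' @param symbols an atomic vector or list of distinct symbols.
#' @return An object of class `"alphabet"`.
#' @examples
#' dna <- alphabet(c("A", "C", "G", "T"))
#' encode_symbols("G", dna)  # 2
#' @export
alphabet <- function(symbols) {
  if (is.factor(symbols)) symbols <- as.character(symbols)
  syms <- if (is.list(symbols)) symbols else as.list(symbols)
  if (length(syms) < 1L) stop("an alphabet needs at least one symbol")
  keys <- vapply(syms, symbol_key, character(1))
  if (anyDuplicated(keys)) {
    dup <- keys[duplicated(keys)][1L]
    stop("duplicate symbol in alphabet: ", dup)
  }
  lookup <- new.env(parent = emptyenv(), size = length(syms))
  for (i in seq_along(keys)) assign(keys[[i]], i - 1L, envir = lookup)
  structure(
    list(symbols = syms, lookup = lookup),
    class = "alphabet"
  )
}

# Stable identity key for a symbol; character symbols map to themselves so
# lookups stay cheap for the common case.
symbol_key <- function(s) {
  if (is.character(s) && length(s) == 1L) s
  else paste(deparse(s), collapse = "")
}

#' @export
length.alphabet <- function(x) length(x$symbols)

#' @export
print.alphabet <- function(x, ...) {
  shown <- vapply(utils::head(x$symbols, 12L), symbol_key, character(1))
  cat("<alphabet> size", length(x), ":",
      paste(shown, collapse = ","),
      if (length(x) > 12L) "..." else "", "\n")
  invisible(x)
}

#' @export
`==.alphabet` <- function(e1, e2) {
  length(e1) == length(e2) &&
    all(vapply(e1$symbols, symbol_key, character(1)) ==
        vapply(e2$symbols, symbol_key, character(1)))
}

#' Test whether one alphabet extends another
#'
#' An alphabet `big` *fits* `small` when its symbol order starts with the
#' symbols of `small` in the same order (equal alphabets trivially fit).
#' A substitution matrix whose alphabets fit the aligned sequences'
#' alphabets can score them by code without any translation.
#'
#' @param big,small alphabets.
#' @return `TRUE` or `FALSE`.
#' @export
alphabet_extends <- function(big, small) {
  if (length(big) < length(small)) return(FALSE)
  all(vapply(big$symbols[seq_along(small$symbols)], symbol_key, character(1)) ==
      vapply(small$symbols, symbol_key, character(1)))
}

#' Encode symbols to symbol codes
#'
#' @param symbols vector/list of symbols (a single string is split into
#'   characters when the alphabet's symbols are single characters).
#' @param alph an [alphabet()].
#' @return integer vector of 0-based symbol codes.
#' @export
encode_symbols <- function(symbols, alph) {
  stopifnot(inherits(alph, "alphabet"))
  symbols <- split_symbols(symbols, alph)
  if (length(symbols) == 0L) return(integer(0))
  keys <- vapply(symbols, symbol_key, character(1))
  codes <- vapply(keys, function(k) {
    v <- get0(k, envir = alph$lookup, inherits = FALSE)
    if (is.null(v)) NA_integer_ else v
  }, integer(1), USE.NAMES = FALSE)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop("symbol '", keys[[bad]], "' at position ", bad,
         " is not in the alphabet")
  }
  codes
}

#' Decode symbol codes to symbols
#'
#' @param codes integer vector of 0-based codes.
#' @param alph an [alphabet()].
#' @param as_string collapse single-character symbols into one string.
#' @return list of symbols, a character vector, or a single string.
#' @export
decode_codes <- function(codes, alph, as_string = FALSE) {
  stopifnot(inherits(alph, "alphabet"))
  codes <- as.integer(codes)
  if (length(codes) && (min(codes) < 0L || max(codes) >= length(alph)))
    stop("symbol code out of range [0, ", length(alph) - 1L, "]")
  syms <- alph$symbols[codes + 1L]
  if (all(vapply(syms, function(s) is.character(s) && length(s) == 1L,
                 logical(1)))) {
    out <- unlist(syms, use.names = FALSE)
    if (is.null(out)) out <- character(0)
    if (as_string) paste(out, collapse = "") else out
  } else {
    syms
  }
}

# A single string over a single-character alphabet is treated as its
# character sequence; everything else is taken element-wise.
split_symbols <- function(symbols, alph) {
  single_char <- all(vapply(alph$symbols, function(s)
    is.character(s) && length(s) == 1L && nchar(s) == 1L, logical(1)))
  if (is.character(symbols) && length(symbols) == 1L && single_char &&
      nchar(symbols) != 1L) {
    symbols <- strsplit(symbols, "", fixed = TRUE)[[1]]
  }
  if (is.list(symbols)) symbols else as.list(symbols)
}

#' Bytes needed per symbol code
#'
#' The smallest of 1, 2, 4 or 8 bytes whose unsigned range covers the
#' alphabet size; alphabets are not limited to 256 symbols.
#'
#' @param alphabet_size number of symbols (>= 1).
#' @return integer number of bytes.
#' @examples
#' code_width(4)    # 1
#' code_width(257)  # 2
#' @export
code_width <- function(alphabet_size) {
  stopifnot(alphabet_size >= 1)
  if (alphabet_size <= 2^8) 1L
  else if (alphabet_size <= 2^16) 2L
  else if (alphabet_size <= 2^32) 4L
  else 8L
}
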