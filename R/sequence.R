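#' Sequences as coded integer arrays
#'
#' A sequence stores an [alphabet()] plus the integer code array obtained by
#' encoding its symbols.  All operations act on the code array.
#'
#' @param symbols symbols to encode (string, vector or list).
#' @param alph the alphabet the symbols are drawn from.
#' @return An object of class `"bioseq"` with fields `alphabet`, `code`
#'   (0-based integer codes) and `code_width` (bytes per code element that a
#'   packed binary representation would need).
#' @export
new_sequence <- function(symbols, alph) {
  code <- encode_symbols(symbols, alph)
  sequence_from_code(code, alph)
}

#' @rdname new_sequence
#' @param code integer vector of 0-based symbol codes.
#' @export
sequence_from_code <- function(code, alph) {
  code <- as.integer(code)
  if (length(code) && (min(code) < 0L || max(code) >= length(alph)))
    stop("symbol code out of range for alphabet of size ", length(alph))
  structure(
    list(alphabet = alph, code = code, code_width = code_width(length(alph))),
    class = "bioseq"
  )
}

#' @export
length.bioseq <- function(x) length(x$code)

#' @export
as.character.bioseq <- function(x, ...) {
  decode_codes(x$code, x$alphabet, as_string = TRUE)
}

#' @export
print.bioseq <- function(x, ...) {
  cat("<", paste(class(x), collapse = "/"), "> length ", length(x), "\n",
      sep = "")
  s <- as.character(x)
  if (is.character(s) && length(s) == 1L)
    cat(substr(s, 1, 70), if (nchar(s) > 70) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.bioseq` <- function(x, i) {
  out <- x
  out$code <- x$code[i]
  out
}

#' Symbols of a sequence
#' @param x a sequence.
#' @return list or character vector of symbols.
#' @export
sequence_symbols <- function(x) decode_codes(x$code, x$alphabet)

# --- nucleotide sequences ---------------------------------------------------

#' Nucleotide alphabets
#'
#' The unambiguous DNA alphabet (A, C, G, T) and the IUPAC-ambiguous
#' extension.  T is the canonical internal symbol; U on input is mapped to T.
#'
#' @name dna_alphabets
NULL

DNA_SYMBOLS <- c("A", "C", "G", "T")
DNA_AMBIGUOUS_SYMBOLS <- c("A", "C", "G", "T",
                           "R", "Y", "S", "W", "K", "M",
                           "B", "D", "H", "V", "N")
# IUPAC base-pairing partners, index-aligned with DNA_AMBIGUOUS_SYMBOLS
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                    B = "V", D = "H", H = "D", V = "B", N = "N")

#' @rdname dna_alphabets
#' @export
dna_alphabet <- function() alphabet(DNA_SYMBOLS)

#' @rdname dna_alphabets
#' @export
dna_ambiguous_alphabet <- function() alphabet(DNA_AMBIGUOUS_SYMBOLS)

#' Protein alphabet: 20 canonical amino acids, X (unknown), * (stop)
#' @export
protein_alphabet <- function() alphabet(PROTEIN_SYMBOLS)

PROTEIN_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                     "X", "*")

#' Create a nucleotide sequence
#'
#' @param x string or character vector of bases; `U` is accepted and stored
#'   as `T`; lower case is accepted.
#' @param ambiguous use the IUPAC-ambiguous alphabet.  With the default
#'   `FALSE` the alphabet is the unambiguous A/C/G/T set and ambiguity codes
#'   are rejected.
#' @return a `"nucleotide_sequence"` (also `"bioseq"`).
#' @export
nucleotide_sequence <- function(x, ambiguous = FALSE) {
  chars <- toupper(if (length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1]]
                   else as.character(x))
  chars[chars == "U"] <- "T"
  alph <- if (ambiguous) dna_ambiguous_alphabet() else dna_alphabet()
  s <- new_sequence(chars, alph)
  class(s) <- c("nucleotide_sequence", class(s))
  s
}

#' Create a protein sequence
#'
#' @param x string or character vector of one-letter amino-acid symbols
#'   (20 canonical plus `X` and `*`).
#' @return a `"protein_sequence"` (also `"bioseq"`).
#' @export
protein_sequence <- function(x) {
  chars <- toupper(if (length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1]]
                   else as.character(x))
  s <- new_sequence(chars, protein_alphabet())
  class(s) <- c("protein_sequence", class(s))
  s
}

#' Complement and reverse complement
#'
#' The complement follows IUPAC base pairing (also for ambiguity codes);
#' both operations are involutions.
#'
#' @param x a nucleotide sequence.
#' @return a nucleotide sequence over the same alphabet.
#' @export
complement <- function(x) {
  stopifnot(inherits(x, "nucleotide_sequence"))
  chars <- decode_codes(x$code, x$alphabet)
  out <- new_sequence(unname(DNA_COMPLEMENT[chars]), x$alphabet)
  class(out) <- class(x)
  out
}

#' @rdname complement
#' @export
reverse_complement <- function(x) {
  out <- complement(x)
  out$code <- rev(out$code)
  out
}

# --- translation ------------------------------------------------------------

# Standard genetic code, written per codon (TTT, TTC, ... in T/C/A/G order).
STANDARD_CODE_STRING <- paste0(
  "FFLLSSSSYY**CC*W",   # TTT..TGG
  "LLLLPPPPHHQQRRRR",   # CTT..CGG
  "IIIMTTTTNNKKSSRR",   # ATT..AGG
  "VVVVAAAADDEEGGGG"    # GTT..GGG
)

#' Codon tables
#'
#' A codon table maps all 64 codons to amino-acid symbols and records the
#' start codons used for open-reading-frame extraction.  The default is the
#' standard genetic code with `ATG` as start codon.
#'
#' @param starts character vector of start codons.
#' @return an object of class `"codon_table"` with fields `forward` (named
#'   character vector of 64 codon -> amino acid entries) and `starts`.
#' @export
default_codon_table <- function(starts = "ATG") {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  # codons enumerates TTT,TTC,TTA,TTG,TCT,... matching STANDARD_CODE_STRING
  aa <- strsplit(STANDARD_CODE_STRING, "", fixed = TRUE)[[1]]
  stopifnot(length(codons) == 64L, length(aa) == 64L)
  tab <- stats::setNames(aa, codons)
  structure(list(forward = tab, starts = toupper(starts)),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("<codon_table> 64 codons, starts:",
      paste(x$starts, collapse = ","), "\n")
  invisible(x)
}

translate_codon <- function(codon, table) {
  aa <- table$forward[codon]
  if (is.na(aa)) "X" else unname(aa)   # ambiguity codes in codon -> X
}

#' Translate a nucleotide sequence
#'
#' In `complete` mode the whole sequence is translated codon by codon in
#' frame 0 (stop codons rendered as `*`); the length must be divisible by 3.
#' Otherwise all open reading frames on the given strand are extracted: each
#' start codon opens a frame that runs to the first in-frame stop codon
#' (excluded from the protein); a start codon with no downstream in-frame
#' stop yields a protein truncated at the sequence end.  Callers wanting the
#' minus strand pass the [reverse_complement()].
#'
#' @param x a nucleotide sequence.
#' @param table a [default_codon_table()].
#' @param complete translate the full sequence instead of extracting ORFs.
#' @return a single protein sequence (`complete = TRUE`) or a list of
#'   protein sequences, one per ORF in order of start position.
#' @export
translate_sequence <- function(x, table = default_codon_table(),
                               complete = FALSE) {
  stopifnot(inherits(x, "nucleotide_sequence"), inherits(table, "codon_table"))
  chars <- decode_codes(x$code, x$alphabet)
  n <- length(chars)
  codon_at <- function(i) paste(chars[i:(i + 2L)], collapse = "")
  if (complete) {
    if (n %% 3L != 0L)
      stop("complete translation needs a length divisible by 3, got ", n)
    if (n == 0L) return(protein_sequence(character(0)))
    aas <- vapply(seq(1L, n, by = 3L),
                  function(i) translate_codon(codon_at(i), table),
                  character(1))
    return(protein_sequence(paste(aas, collapse = "")))
  }
  orfs <- list()
  if (n >= 3L) {
    for (start in seq_len(n - 2L)) {
      if (!codon_at(start) %in% table$starts) next
      aas <- character(0)
      i <- start
      while (i + 2L <= n) {
        aa <- translate_codon(codon_at(i), table)
        if (aa == "*") break
        aas <- c(aas, aa)
        i <- i + 3L
      }
      orfs[[length(orfs) + 1L]] <- protein_sequence(paste(aas, collapse = ""))
    }
  }
  orfs
}
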