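#' Substitution matrices
#'
#' A substitution matrix holds two alphabets and a score table of shape
#' (|alphabet1|, |alphabet2|).  The score of two symbols with codes m and n
#' is `scores[m + 1, n + 1]` — symbol codes are direct indices, so scoring
#' needs no symbol lookup and two sequences of *different* types can be
#' aligned as long as a matrix over both alphabets is supplied.
#'
#' @param alphabet1,alphabet2 alphabets for the first/second sequence.
#' @param scores integer matrix of dimension `length(alphabet1)` x
#'   `length(alphabet2)`.
#' @return an object of class `"substitution_matrix"`.
#' @export
substitution_matrix <- function(alphabet1, alphabet2, scores) {
  stopifnot(inherits(alphabet1, "alphabet"), inherits(alphabet2, "alphabet"))
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(length(alphabet1), length(alphabet2))))
    stop("score table must be ", length(alphabet1), " x ", length(alphabet2),
         ", got ", nrow(scores), " x ", ncol(scores))
  storage.mode(scores) <- "double"
  structure(list(alphabet1 = alphabet1, alphabet2 = alphabet2,
                 scores = scores),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", length(x$alphabet1), " x ",
      length(x$alphabet2), "\n", sep = "")
  invisible(x)
}

#' An identity-style matrix over one alphabet
#'
#' @param alph an alphabet.
#' @param match,mismatch scores on/off the diagonal.
#' @export
identity_matrix <- function(alph, match = 1, mismatch = 0) {
  n <- length(alph)
  m <- matrix(mismatch, n, n)
  diag(m) <- match
  substitution_matrix(alph, alph, m)
}

bundled_matrix_dir <- function() {
  system.file("extdata", "matrices", package = "atomseq")
}

bundled_matrix_names <- function() {
  sub("\\.mat$", "", list.files(bundled_matrix_dir(), pattern = "\\.mat$"))
}

#' Load a substitution matrix
#'
#' Loads one of the bundled NCBI score tables (by name, e.g. `"BLOSUM62"`)
#' or parses raw NCBI-format matrix text (a `#`-commented header, a row of
#' column symbols, then one labelled score row per symbol).  Bundled
#' matrices are re-indexed onto the canonical protein alphabet
#' (20 amino acids, X, *) extended by the ambiguity symbols B and Z, so
#' they directly fit [protein_sequence()] objects.
#'
#' @param name_or_text a bundled matrix name, a path to an NCBI-format
#'   file, or the matrix text itself (must contain a newline).
#' @return a [substitution_matrix()].
#' @examples
#' m <- load_substitution_matrix("BLOSUM62")
#' @export
load_substitution_matrix <- function(name_or_text) {
  stopifnot(is.character(name_or_text), length(name_or_text) == 1L)
  if (!grepl("\n", name_or_text) && !file.exists(name_or_text)) {
    path <- file.path(bundled_matrix_dir(), paste0(name_or_text, ".mat"))
    if (!file.exists(path))
      stop("unknown substitution matrix '", name_or_text, "'; bundled: ",
           paste(bundled_matrix_names(), collapse = ", "))
    mat <- parse_ncbi_matrix(readLines(path))
    return(reindex_protein_matrix(mat))
  }
  lines <- if (grepl("\n", name_or_text))
    strsplit(name_or_text, "\n", fixed = TRUE)[[1]]
  else readLines(name_or_text)
  parse_ncbi_matrix(lines)
}

# NCBI matrix text: '#' comments, header row of symbols, then one score row
# per symbol, each prefixed by its row symbol.
parse_ncbi_matrix <- function(lines) {
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) < 2L) stop("malformed matrix text: no header/data rows")
  header <- strsplit(trimws(lines[keep[1L]]), "\\s+")[[1]]
  ncolms <- length(header)
  n <- length(keep) - 1L
  scores <- matrix(NA_real_, n, ncolms)
  row_syms <- character(n)
  for (k in seq_len(n)) {
    ln <- keep[k + 1L]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != ncolms + 1L)
      stop("malformed matrix row at line ", ln, ": expected ",
           ncolms + 1L, " fields, got ", length(fields))
    row_syms[k] <- fields[1L]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) stop("non-numeric score at line ", ln)
    scores[k, ] <- vals
  }
  substitution_matrix(alphabet(row_syms), alphabet(header), scores)
}

# Reorder a parsed NCBI protein matrix onto protein_alphabet() + (B, Z),
# an ordered extension of the protein alphabet.
reindex_protein_matrix <- function(mat) {
  target <- c(PROTEIN_SYMBOLS, "B", "Z")
  src <- vapply(mat$alphabet1$symbols, symbol_key, character(1))
  target <- target[target %in% src]
  idx <- match(target, src)
  alph <- alphabet(target)
  substitution_matrix(alph, alph, mat$scores[idx, idx, drop = FALSE])
}

matrix_fits <- function(mat, seq1, seq2) {
  alphabet_extends(mat$alphabet1, seq1$alphabet) &&
    alphabet_extends(mat$alphabet2, seq2$alphabet)
}

# --- gap penalties ----------------------------------------------------------

# A gap penalty is one non-positive number (linear) or c(open, extend):
# the first column of a gap run contributes `open`, each further column
# `extend`.
normalize_gap <- function(gap_penalty) {
  gap_penalty <- as.numeric(gap_penalty)
  if (length(gap_penalty) == 1L) gap_penalty <- c(gap_penalty, gap_penalty)
  if (length(gap_penalty) != 2L)
    stop("gap penalty must be one value (linear) or c(open, extend)")
  if (any(gap_penalty > 0))
    stop("gap penalties are non-positive score contributions")
  gap_penalty
}

# --- alignment object -------------------------------------------------------

#' Alignment objects
#'
#' An alignment stores the two aligned sequences, an L x 2 integer *trace*
#' whose entry is the 0-based index of the aligned symbol in its source
#' sequence (-1 for a gap) and the optimal score.
#'
#' @param seq1,seq2 the aligned sequences.
#' @param trace L x 2 integer matrix.
#' @param score alignment score.
#' @export
new_alignment <- function(seq1, seq2, trace, score) {
  trace <- matrix(as.integer(trace), ncol = 2L)
  validate_trace(trace, length(seq1), length(seq2))
  structure(list(sequences = list(seq1, seq2), trace = trace,
                 score = score),
            class = "alignment")
}

validate_trace <- function(trace, n1, n2) {
  if (any(rowSums(trace == -1L) > 1L))
    stop("invalid trace: a column may hold at most one gap")
  for (k in 1:2) {
    v <- trace[trace[, k] >= 0L, k]
    if (length(v) && (any(diff(v) <= 0L) || any(v >= c(n1, n2)[k])))
      stop("invalid trace: indices of sequence ", k,
           " must be strictly increasing and < its length")
  }
  invisible(trace)
}

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> score ", x$score, ", length ", nrow(x$trace), "\n",
      sep = "")
  cat(render_alignment(x), sep = "\n")
  invisible(x)
}

#' Render an alignment as gapped text
#'
#' @param aln an alignment; gaps are drawn as `-`.
#' @return character vector of two lines.
#' @export
render_alignment <- function(aln) {
  vapply(1:2, function(k) {
    syms <- decode_codes(aln$sequences[[k]]$code, aln$sequences[[k]]$alphabet)
    idx <- aln$trace[, k]
    chars <- ifelse(idx >= 0L,
                    vapply(idx + 1L, function(i)
                      symbol_key(if (is.list(syms)) syms[[i]] else syms[i]),
                      character(1)),
                    "-")
    paste(chars, collapse = "")
  }, character(1))
}

pair_score <- function(mat, code1, code2) mat$scores[code1 + 1L, code2 + 1L]

#' Recompute an alignment score from its trace
#'
#' Sums substitution scores over non-gap columns and adds gap penalties:
#' the first column of each gap run contributes the open penalty, every
#' further column the extend penalty.
#'
#' @param aln an alignment.
#' @param mat the substitution matrix used for scoring.
#' @param gap_penalty linear value or `c(open, extend)`.
#' @return numeric score.
#' @export
score_of <- function(aln, mat, gap_penalty) {
  gp <- normalize_gap(gap_penalty)
  trace <- aln$trace
  validate_trace(trace, length(aln$sequences[[1]]), length(aln$sequences[[2]]))
  total <- 0
  for (k in 1:2) {
    gap <- trace[, k] == -1L
    if (!any(gap)) next
    runs <- rle(gap)
    glens <- runs$lengths[runs$values]
    total <- total + sum(gp[1] + (glens - 1) * gp[2])
  }
  both <- trace[, 1] >= 0L & trace[, 2] >= 0L
  if (any(both)) {
    c1 <- aln$sequences[[1]]$code[trace[both, 1] + 1L]
    c2 <- aln$sequences[[2]]$code[trace[both, 2] + 1L]
    total <- total + sum(mat$scores[cbind(c1 + 1L, c2 + 1L)])
  }
  total
}

# --- dynamic programming ----------------------------------------------------

NEG_INF <- -1e18

#' Optimal pairwise alignment
#'
#' `align_global()` computes a Needleman-Wunsch global alignment (terminal
#' gaps penalized), `align_local()` a Smith-Waterman local alignment.  With
#' `open != extend` the three-state Gotoh recursion is used, so a gap run
#' of length g scores `open + (g - 1) * extend`.  One optimal alignment is
#' returned; ties are broken deterministically with priority diagonal >
#' gap in the second sequence (vertical) > gap in the first (horizontal).
#' Time and memory are proportional to the product of the two lengths.
#'
#' @param seq1,seq2 sequences whose alphabets the matrix must fit.
#' @param mat a [substitution_matrix()].
#' @param gap_penalty a single non-positive value (linear) or
#'   `c(open, extend)`.
#' @return an [new_alignment()] object.
#' @examples
#' m <- identity_matrix(dna_alphabet())
#' align_global(nucleotide_sequence("ACGT"), nucleotide_sequence("AGT"),
#'              m, gap_penalty = -1)
#' @export
align_global <- function(seq1, seq2, mat, gap_penalty) {
  align_pair(seq1, seq2, mat, gap_penalty, local = FALSE)
}

#' @rdname align_global
#' @export
align_local <- function(seq1, seq2, mat, gap_penalty) {
  align_pair(seq1, seq2, mat, gap_penalty, local = TRUE)
}

align_pair <- function(seq1, seq2, mat, gap_penalty, local) {
  stopifnot(inherits(mat, "substitution_matrix"))
  if (!matrix_fits(mat, seq1, seq2))
    stop("substitution matrix alphabets do not fit the sequence alphabets")
  gp <- normalize_gap(gap_penalty)
  open <- gp[1]; extend <- gp[2]
  c1 <- seq1$code; c2 <- seq2$code
  n1 <- length(c1); n2 <- length(c2)

  # state matrices: M = column with both symbols, V = gap in seq2
  # (consumes seq1), H = gap in seq1 (consumes seq2); (n1+1) x (n2+1)
  M <- matrix(NEG_INF, n1 + 1L, n2 + 1L)
  V <- matrix(NEG_INF, n1 + 1L, n2 + 1L)
  H <- matrix(NEG_INF, n1 + 1L, n2 + 1L)
  # predecessor state per cell/state: 0 none, 1 M, 2 V, 3 H
  pM <- matrix(0L, n1 + 1L, n2 + 1L)
  pV <- matrix(0L, n1 + 1L, n2 + 1L)
  pH <- matrix(0L, n1 + 1L, n2 + 1L)

  M[1, 1] <- 0
  if (!local) {
    if (n1 > 0) {
      V[2:(n1 + 1L), 1] <- open + (0:(n1 - 1L)) * extend
      pV[2, 1] <- 1L
      if (n1 > 1) pV[3:(n1 + 1L), 1] <- 2L
    }
    if (n2 > 0) {
      H[1, 2:(n2 + 1L)] <- open + (0:(n2 - 1L)) * extend
      pH[1, 2] <- 1L
      if (n2 > 1) pH[1, 3:(n2 + 1L)] <- 3L
    }
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }

  # pick with fixed priority (first maximal option wins): M > V > H
  best3 <- function(m, v, h) {
    if (m >= v && m >= h) c(m, 1L)
    else if (v >= h) c(v, 2L)
    else c(h, 3L)
  }

  for (i in seq_len(n1)) {
    srow <- mat$scores[c1[i] + 1L, c2 + 1L]
    for (j in seq_len(n2)) {
      # M: diagonal step from any state
      b <- best3(M[i, j], V[i, j], H[i, j])
      m_val <- b[1] + srow[j]
      m_ptr <- b[2]
      if (local && m_val < 0) { m_val <- 0; m_ptr <- 0L }
      M[i + 1L, j + 1L] <- m_val
      pM[i + 1L, j + 1L] <- as.integer(m_ptr)
      # V: vertical step (gap in seq2); opening from M/H, extending from V
      b <- best3(M[i, j + 1L] + open, V[i, j + 1L] + extend,
                 H[i, j + 1L] + open)
      V[i + 1L, j + 1L] <- b[1]
      pV[i + 1L, j + 1L] <- as.integer(b[2])
      # H: horizontal step (gap in seq1)
      b <- best3(M[i + 1L, j] + open, V[i + 1L, j] + open,
                 H[i + 1L, j] + extend)
      H[i + 1L, j + 1L] <- b[1]
      pH[i + 1L, j + 1L] <- as.integer(b[2])
    }
  }

  if (local) {
    # best M cell; ties resolved to the smallest i, then smallest j
    best <- which(M == max(M), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    score <- M[best[1], best[2]]
    if (score <= 0)
      return(new_alignment(seq1, seq2, matrix(integer(0), ncol = 2), 0))
    state <- 1L; i <- best[1] - 1L; j <- best[2] - 1L
  } else {
    b <- best3(M[n1 + 1L, n2 + 1L], V[n1 + 1L, n2 + 1L], H[n1 + 1L, n2 + 1L])
    score <- b[1]; state <- b[2]
    i <- n1; j <- n2
  }

  cols1 <- integer(0); cols2 <- integer(0)
  repeat {
    if (local && state == 1L && M[i + 1L, j + 1L] == 0 && pM[i + 1L, j + 1L] == 0L)
      break
    if (!local && i == 0L && j == 0L) break
    if (state == 1L) {
      prev <- pM[i + 1L, j + 1L]
      cols1 <- c(i - 1L, cols1); cols2 <- c(j - 1L, cols2)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- pV[i + 1L, j + 1L]
      cols1 <- c(i - 1L, cols1); cols2 <- c(-1L, cols2)
      i <- i - 1L
    } else {
      prev <- pH[i + 1L, j + 1L]
      cols1 <- c(-1L, cols1); cols2 <- c(j - 1L, cols2)
      j <- j - 1L
    }
    state <- prev
    if (state == 0L) break
  }
  new_alignment(seq1, seq2, cbind(cols1, cols2), score)
}
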