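random_case <- function(seed, max_len = 5L, alph_size = 4L) {
  set.seed(seed)
  alph <- random_alphabet(alph_size)
  n1 <- sample(0:max_len, 1L); n2 <- sample(0:max_len, 1L)
  list(
    alph = alph,
    s1 = sequence_from_code(
      if (n1) sample.int(alph_size, n1, TRUE) - 1L else integer(0), alph),
    s2 = sequence_from_code(
      if (n2) sample.int(alph_size, n2, TRUE) - 1L else integer(0), alph),
    mat = substitution_matrix(alph, alph,
      matrix(sample(-4:4, alph_size^2, TRUE), alph_size, alph_size)),
    open = -sample(1:6, 1L),
    ext = -sample(1:3, 1L)
  )
}

test_that("trivial global alignments are exact", {
  m <- identity_matrix(dna_alphabet())
  aln <- align_global(nucleotide_sequence("ACGT"), nucleotide_sequence("ACGT"),
                      m, -1)
  expect_equal(aln$score, 4)
  expect_true(all(aln$trace != -1L))
  aln2 <- align_global(nucleotide_sequence(""), nucleotide_sequence("ACG"),
                       m, -2)
  expect_equal(aln2$score, -6)
  expect_equal(nrow(aln2$trace), 3L)
  expect_true(all(aln2$trace[, 1] == -1L))
})

test_that("global DP score equals exhaustive enumeration (linear and affine)", {
  for (seed in 1:40) {
    cs <- random_case(seed)
    for (gap in list(c(cs$open, cs$open), c(cs$open, cs$ext))) {
      aln <- align_global(cs$s1, cs$s2, cs$mat, gap)
      want <- oracle_global_score(cs$s1$code, cs$s2$code, cs$mat$scores,
                                  gap[1], gap[2])
      expect_equal(aln$score, want,
                   label = sprintf("seed %d gap (%d,%d)", seed, gap[1],
                                   gap[2]))
      # the returned trace must reproduce the reported score
      expect_equal(score_of(aln, cs$mat, gap), aln$score)
    }
  }
})

test_that("local DP score equals exhaustive enumeration and floors at zero", {
  for (seed in 1:12) {
    cs <- random_case(seed, max_len = 4L, alph_size = 3L)
    for (gap in list(c(cs$open, cs$open), c(cs$open, cs$ext))) {
      aln <- align_local(cs$s1, cs$s2, cs$mat, gap)
      want <- oracle_local_score(cs$s1$code, cs$s2$code, cs$mat$scores,
                                 gap[1], gap[2])
      expect_equal(aln$score, want,
                   label = sprintf("seed %d gap (%d,%d)", seed, gap[1],
                                   gap[2]))
      expect_gte(aln$score, 0)
    }
  }
  # all-negative scores give the empty alignment
  alph <- dna_alphabet()
  neg <- substitution_matrix(alph, alph, matrix(-2, 4, 4))
  aln <- align_local(nucleotide_sequence("ACG"), nucleotide_sequence("TTT"),
                     neg, -5)
  expect_equal(aln$score, 0)
  expect_equal(nrow(aln$trace), 0L)
})

test_that("local alignment recovers an embedded exact match", {
  alph <- dna_alphabet()
  m <- identity_matrix(alph, match = 2, mismatch = -3)
  aln <- align_local(nucleotide_sequence("TTACGTGG"),
                     nucleotide_sequence("ACGT"), m, -5)
  expect_equal(aln$score, 8)
  expect_equal(nrow(aln$trace), 4L)
  expect_identical(aln$trace[, 1], 2:5)
  expect_identical(aln$trace[, 2], 0:3)
})

test_that("affine with open == extend reproduces the linear-gap score", {
  for (seed in 41:80) {
    cs <- random_case(seed)
    lin <- align_global(cs$s1, cs$s2, cs$mat, cs$open)
    aff <- align_global(cs$s1, cs$s2, cs$mat, c(cs$open, cs$open))
    expect_equal(aff$score, lin$score, label = paste("seed", seed))
  }
})

test_that("score is symmetric under sequence swap for symmetric matrices", {
  for (seed in 1:15) {
    set.seed(seed)
    alph <- random_alphabet(4L)
    raw <- matrix(sample(-4:4, 16, TRUE), 4, 4)
    m <- substitution_matrix(alph, alph, raw + t(raw))
    s1 <- sequence_from_code(sample(0:3, 5, TRUE), alph)
    s2 <- sequence_from_code(sample(0:3, 4, TRUE), alph)
    g <- c(-4, -1)
    expect_equal(align_global(s1, s2, m, g)$score,
                 align_global(s2, s1, m, g)$score)
  }
})

test_that("more negative gap penalties never increase the optimal score", {
  for (seed in 1:10) {
    cs <- random_case(seed)
    base <- align_global(cs$s1, cs$s2, cs$mat, c(cs$open, cs$ext))$score
    worse_open <- align_global(cs$s1, cs$s2, cs$mat,
                               c(cs$open - 2, cs$ext))$score
    worse_ext <- align_global(cs$s1, cs$s2, cs$mat,
                              c(cs$open, cs$ext - 2))$score
    expect_lte(worse_open, base)
    expect_lte(worse_ext, base)
  }
})

test_that("alignment scores depend only on code arrays, not symbol types", {
  # same codes over two alphabets with entirely different symbols
  a1 <- alphabet(c("A", "C", "G", "T"))
  a2 <- alphabet(list("His", "Ala", 7L, "Gly"))
  scores <- matrix(sample(-3:3, 16, TRUE), 4, 4)
  m1 <- substitution_matrix(a1, a1, scores)
  m2 <- substitution_matrix(a2, a2, scores)
  codes1 <- c(0L, 2L, 3L, 1L); codes2 <- c(0L, 3L, 1L)
  aln1 <- align_global(sequence_from_code(codes1, a1),
                       sequence_from_code(codes2, a1), m1, c(-5, -1))
  aln2 <- align_global(sequence_from_code(codes1, a2),
                       sequence_from_code(codes2, a2), m2, c(-5, -1))
  expect_equal(aln1$score, aln2$score)
  expect_identical(aln1$trace, aln2$trace)
})

test_that("cross-alphabet matrices align sequences of different types", {
  dna <- dna_alphabet()
  tri <- alphabet(c("one", "two", "three"))
  m <- substitution_matrix(dna, tri, matrix(1, 4, 3))
  s1 <- nucleotide_sequence("ACG")
  s2 <- new_sequence(list("one", "three"), tri)
  aln <- align_global(s1, s2, m, -1)
  expect_s3_class(aln, "alignment")
  expect_equal(aln$score, 2 - 1)  # two matches, one gap
  # mismatching alphabets error
  expect_error(align_global(s2, s1, m, -1), "do not fit")
})

test_that("bundled NCBI matrices load, are symmetric, and score by code", {
  b62 <- load_substitution_matrix("BLOSUM62")
  w <- encode_symbols("W", b62$alphabet1)
  expect_equal(b62$scores[w + 1L, w + 1L], 11)
  for (nm in c("BLOSUM45", "BLOSUM62", "PAM250")) {
    m <- load_substitution_matrix(nm)
    expect_true(isSymmetric(unname(m$scores)))
  }
  expect_error(load_substitution_matrix("NOSUCH"), "BLOSUM62")
  # the matrices fit protein sequences directly
  s <- protein_sequence("WW")
  aln <- align_global(s, s, b62, c(-10, -1))
  expect_equal(aln$score, 22)
})

test_that("NCBI-format text parses and malformed text reports the line", {
  txt <- "# comment\n   A  B\nA  1 -1\nB -1  2\n"
  m <- load_substitution_matrix(txt)
  expect_equal(dim(m$scores), c(2L, 2L))
  expect_equal(m$scores[1, 2], -1)
  bad <- "   A  B\nA  1\nB -1  2\n"
  expect_error(load_substitution_matrix(bad), "line 2")
})

test_that("score_of applies affine gap runs as open plus extends", {
  alph <- dna_alphabet()
  m <- identity_matrix(alph)
  s1 <- nucleotide_sequence("AAAA")
  s2 <- nucleotide_sequence("A")
  trace <- cbind(0:3, c(0L, -1L, -1L, -1L))
  aln <- new_alignment(s1, s2, trace, 0)
  expect_equal(score_of(aln, m, c(-10, -1)), 1 - 10 - 1 - 1)
  expect_error(new_alignment(s1, s2, cbind(c(0L, 2L, 1L), c(0L, 1L, -1L)),
                             0),
               "strictly increasing")
  expect_error(new_alignment(s1, s2, cbind(-1L, -1L), 0), "at most one gap")
})
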