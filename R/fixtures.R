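#' Deterministic fixture generation
#'
#' Generates the synthetic inputs every algorithm in the package can be
#' exercised on without downloads: random sequences, ideal secondary
#' structure CA traces, ideal trans-peptide backbones, random coils,
#' random structures/stacks and the same toy structure written in PDB,
#' mmCIF and MMTF.  All randomness flows through the explicit `seed`;
#' identical parameters and seed give identical output.
#'
#' Geometry of the ideal elements: the alpha-helix CA trace uses a rise of
#' 1.5 Angstrom per residue, 3.6 residues per turn and a helix radius of
#' 2.3 Angstrom; the ideal strand is a zigzag CA trace with 3.8 Angstrom
#' between consecutive CA atoms and an alternating pleat chosen so the
#' i, i+2 distance is 6.7 Angstrom.
#'
#' @name fixtures
NULL

#' @rdname fixtures
#' @param n_res number of residues.
#' @param chain_id chain identifier.
#' @export
ideal_helix_ca <- function(n_res, chain_id = "A") {
  rise <- 1.5; per_turn <- 3.6; radius <- 2.3
  i <- seq_len(n_res) - 1L
  theta <- 2 * pi * i / per_turn
  coord <- cbind(radius * cos(theta), radius * sin(theta), rise * i)
  atom_array(coord, chain_id = chain_id, res_id = seq_len(n_res),
             res_name = "ALA", atom_name = "CA", element = "C",
             hetero = FALSE)
}

#' @rdname fixtures
#' @export
ideal_strand_ca <- function(n_res, chain_id = "A") {
  spacing <- 3.8
  half_d2 <- 6.7 / 2                       # target |CA(i-1), CA(i+1)| = 6.7
  pleat <- sqrt(spacing^2 - half_d2^2)
  i <- seq_len(n_res) - 1L
  coord <- cbind(half_d2 * i, pleat * (i %% 2L), 0)
  atom_array(coord, chain_id = chain_id, res_id = seq_len(n_res),
             res_name = "VAL", atom_name = "CA", element = "C",
             hetero = FALSE)
}

#' @rdname fixtures
#' @details `ideal_trans_backbone()` builds an N/CA/C backbone with ideal
#' bond lengths (N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom), tetrahedral
#' backbone angles and all-trans torsions (phi = psi = omega = pi), i.e. a
#' fully extended chain.
#' @export
ideal_trans_backbone <- function(n_res, chain_id = "A") {
  bonds <- c(N_CA = 1.46, CA_C = 1.52, C_N = 1.33)
  ang <- 111 * pi / 180   # backbone bond angle
  # place atoms in the xy plane: all torsions are exactly pi (trans)
  n_atoms_total <- n_res * 3L
  coord <- matrix(0, n_atoms_total, 3L)
  lengths <- rep(c(bonds[["N_CA"]], bonds[["CA_C"]], bonds[["C_N"]]),
                 n_res)[seq_len(n_atoms_total - 1L)]
  dirs <- rep(c(1, -1), length.out = n_atoms_total - 1L)
  pos <- c(0, 0, 0)
  step_angle <- (pi - ang) / 2
  for (k in seq_len(n_atoms_total - 1L)) {
    dir <- c(cos(step_angle * dirs[k]), sin(step_angle * dirs[k]), 0)
    pos <- pos + lengths[k] * dir
    coord[k + 1L, ] <- pos
  }
  atom_array(coord, chain_id = chain_id,
             res_id = rep(seq_len(n_res), each = 3L),
             res_name = "GLY",
             atom_name = rep(c("N", "CA", "C"), n_res),
             element = rep(c("N", "C", "C"), n_res),
             hetero = FALSE)
}

#' @rdname fixtures
#' @param n number of atoms / sequence length.
#' @param seed integer seed.
#' @param spread coordinate spread in Angstrom.
#' @export
random_structure <- function(n, seed = 1L, spread = 10) {
  set.seed(seed)
  res_id <- sort(sample.int(max(1L, n %/% 3L), n, replace = TRUE))
  res_names <- sample(c("ALA", "GLY", "SER", "HOH"), max(res_id),
                      replace = TRUE)
  atom_array(
    coord = matrix(stats::runif(n * 3L, -spread, spread), n, 3L),
    chain_id = "A",
    res_id = res_id,
    res_name = res_names[res_id],
    atom_name = sprintf("X%d", seq_len(n) %% 9L + 1L),
    element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    hetero = FALSE,
    b_factor = round(stats::runif(n, 0, 99), 2),
    occupancy = round(stats::runif(n, 0.5, 1), 2)
  )
}

#' @rdname fixtures
#' @param m number of models.
#' @param noise per-model coordinate jitter (Angstrom).
#' @export
random_stack <- function(n, m, seed = 1L, spread = 10, noise = 0.5) {
  base <- random_structure(n, seed = seed, spread = spread)
  set.seed(seed + 1L)
  arrays <- lapply(seq_len(m), function(k) {
    out <- base
    out$coord <- base$coord + matrix(stats::rnorm(n * 3L, sd = noise), n, 3L)
    out
  })
  stack_atom_arrays(arrays)
}

#' @rdname fixtures
#' @param length sequence length.
#' @param alph alphabet to draw symbols from.
#' @export
random_sequence <- function(length, seed = 1L, alph = dna_alphabet()) {
  set.seed(seed)
  sequence_from_code(sample.int(length(alph), length, replace = TRUE) - 1L,
                     alph)
}

#' @rdname fixtures
#' @param kind one of `random_sequence`, `ideal_helix`, `ideal_strand`,
#'   `random_coil`, `toy_structure_files`.
#' @param dir output directory for `toy_structure_files`.
#' @param ... size parameters passed to the specific generator.
#' @return the generated object, or (for `toy_structure_files`) the named
#'   vector of written file paths.
#' @export
generate_fixture <- function(kind, seed = 1L, dir = tempdir(), ...) {
  switch(kind,
    random_sequence = random_sequence(seed = seed, ...),
    ideal_helix = ideal_helix_ca(...),
    ideal_strand = ideal_strand_ca(...),
    random_coil = random_structure(seed = seed, ...),
    toy_structure_files = {
      arr <- random_structure(seed = seed, ...)
      paths <- c(pdb = file.path(dir, "toy.pdb"),
                 cif = file.path(dir, "toy.cif"),
                 mmtf = file.path(dir, "toy.mmtf"))
      arr$coord <- round(arr$coord, 3)   # identical across the 3 formats
      write_pdb(arr, paths[["pdb"]])
      write_mmcif(arr, paths[["cif"]])
      write_mmtf(arr, paths[["mmtf"]])
      paths
    },
    stop("unknown fixture kind '", kind, "'")
  )
}
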