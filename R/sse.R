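#' P-SEA secondary-structure assignment
#'
#' Assigns one label per residue — `a` (alpha-helix), `b` (beta-strand) or
#' `c` (coil) — from CA geometry only.  For each residue i the criteria
#' use the inter-CA distances d2 = |CA(i-1), CA(i+1)|, d3 = |CA(i-1),
#' CA(i+2)| and d4 = |CA(i-1), CA(i+3)|, the bond angle at (i-1, i, i+1)
#' and the torsion over (i-1, i, i+1, i+2).  Residues pass a *strict*
#' helix/strand criterion (distances, or angle plus torsion, inside the
#' windows below); runs of at least 5 (helix) or 4 (strand) strict
#' residues seed a segment, a strand seed of 3 also qualifies when it has
#' at least 5 CA contacts at 4.2-5.2 A to other strand candidates, and
#' segments are then extended outwards over residues passing the *relaxed*
#' criterion.  Residues whose measurement window crosses a chain end stay
#' coil, and chains with fewer than 5 CA atoms are entirely coil.
#'
#' @section Criteria windows:
#' Helix: d3 in `[4.8, 5.8]` and d4 in `[5.8, 7.0]`, or angle in
#' `[77, 101]` degrees and torsion in `[30, 70]` degrees; relaxed: d3 in
#' window or angle in window.  Strand: d2 in `[6.1, 7.3]`, d3 in
#' `[9.0, 10.8]` and d4 in `[11.3, 13.5]`, or angle in `[110, 138]`
#' degrees and torsion in `[-180, -125]` or `[145, 180]` degrees;
#' relaxed: d3 in window.
#'
#' @param array an atom array containing CA atoms.
#' @param chain chain to annotate; default: first chain in the array.
#' @return character vector with one `a`/`b`/`c` label per residue of the
#'   chain, in file order.
#' @export
annotate_sse <- function(array, chain = NULL) {
  stopifnot(inherits(array, "atom_array"))
  if (is.null(chain)) chain <- array$chain_id[1]
  sel <- array[array$chain_id == chain & !array$hetero &
                 array$atom_name == "CA"]
  ca <- sel$coord
  k <- nrow(ca)
  if (k == 0L) return(character(0))
  if (k < 5L) return(rep("c", k))

  d2 <- d3 <- d4 <- r <- a <- rep(NaN, k)
  idx <- seq_len(k)
  ok <- function(lo, hi) idx >= lo & idx <= hi
  d2[2:(k - 1)] <- distance(ca[1:(k - 2), , drop = FALSE],
                            ca[3:k, , drop = FALSE])
  d3[2:(k - 2)] <- distance(ca[1:(k - 3), , drop = FALSE],
                            ca[4:k, , drop = FALSE])
  if (k >= 5) d4[2:(k - 3)] <- distance(ca[1:(k - 4), , drop = FALSE],
                                        ca[5:k, , drop = FALSE])
  r[2:(k - 1)] <- angle(ca[1:(k - 2), , drop = FALSE],
                        ca[2:(k - 1), , drop = FALSE],
                        ca[3:k, , drop = FALSE])
  a[2:(k - 2)] <- dihedral(ca[1:(k - 3), , drop = FALSE],
                           ca[2:(k - 2), , drop = FALSE],
                           ca[3:(k - 1), , drop = FALSE],
                           ca[4:k, , drop = FALSE])

  p <- PSEA_PARAMS
  inw <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  relaxed_helix <- inw(d3, p$d3_helix) | inw(r, p$r_helix)
  strict_helix <- (inw(d3, p$d3_helix) & inw(d4, p$d4_helix)) |
    (inw(r, p$r_helix) & inw(a, p$a_helix))
  relaxed_strand <- inw(d3, p$d3_strand)
  strict_strand <- (inw(d2, p$d2_strand) & inw(d3, p$d3_strand) &
                      inw(d4, p$d4_strand)) |
    (inw(r, p$r_strand) &
       (inw(a, p$a_strand_neg) | inw(a, p$a_strand_pos)))

  helix <- extend_region(mask_consecutive(strict_helix, p$helix_min_run),
                         relaxed_helix)
  strand_seed <- mask_consecutive(strict_strand, p$strand_min_run)
  short_seed <- mask_with_contacts(ca, mask_consecutive(strict_strand, 3L),
                                   p$contact_min, p$contact_window)
  strand <- extend_region(strand_seed | short_seed, relaxed_strand)

  out <- rep("c", k)
  out[helix] <- "a"
  out[strand] <- "b"
  out
}

# Numeric thresholds of the CA-geometry criteria (distances in Angstrom,
# angles in radians), one block for auditability:
PSEA_PARAMS <- list(
  d3_helix = c(5.3 - 0.5, 5.3 + 0.5),       # CA(i-1)..CA(i+2) in a helix
  d4_helix = c(6.4 - 0.6, 6.4 + 0.6),       # CA(i-1)..CA(i+3)
  r_helix  = (89 + c(-12, 12)) * pi / 180,  # CA bond angle
  a_helix  = (50 + c(-20, 20)) * pi / 180,  # CA torsion
  d2_strand = c(6.7 - 0.6, 6.7 + 0.6),      # CA(i-1)..CA(i+1) in a strand
  d3_strand = c(9.9 - 0.9, 9.9 + 0.9),
  d4_strand = c(12.4 - 1.1, 12.4 + 1.1),
  r_strand  = (124 + c(-14, 14)) * pi / 180,
  a_strand_neg = c(-180, -125) * pi / 180,  # torsion near +/-180 (trans),
  a_strand_pos = c(145, 180) * pi / 180,    # split at the periodic boundary
  helix_min_run = 5L,                       # minimum strict helix seed
  strand_min_run = 4L,                      # minimum strict strand seed
  contact_min = 5L,            # contacts needed by a 3-residue strand seed
  contact_window = c(4.2, 5.2) # CA-CA contact distance window (sheet pairing)
)

# TRUE for every index inside a run of >= len consecutive TRUEs
mask_consecutive <- function(mask, len) {
  out <- rep(FALSE, length(mask))
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values & runs$lengths >= len))
    out[starts[j]:ends[j]] <- TRUE
  out
}

# grow seed regions outwards while the relaxed criterion holds
extend_region <- function(seed, relaxed) {
  repeat {
    grown <- seed |
      (c(FALSE, seed[-length(seed)]) & relaxed) |
      (c(seed[-1], FALSE) & relaxed)
    if (identical(grown, seed)) return(seed)
    seed <- grown
  }
}

# keep short-seed regions only if their residues have enough CA contacts
# (within the distance window) to residues of other candidate regions
mask_with_contacts <- function(ca, seed, min_contacts, window) {
  if (!any(seed)) return(seed)
  out <- rep(FALSE, length(seed))
  runs <- rle(seed)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(seed)
  for (j in which(runs$values)) {
    region <- starts[j]:ends[j]
    others <- setdiff(cand, region)
    if (length(others) == 0L) next
    d <- as.matrix(stats::dist(ca))[region, others, drop = FALSE]
    contacts <- sum(d >= window[1] & d <= window[2])
    if (contacts >= min_contacts) out[region] <- TRUE
  }
  out
}
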