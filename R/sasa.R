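#' Van der Waals radius sets
#'
#' Two radius sets are shipped: `"single"` assigns one van der Waals radius
#' per element (Bondi/Mantina consensus values; appropriate when hydrogens
#' are present), `"protor"` assigns ProtOr-style group radii to the heavy
#' atoms of the standard amino acids, in which each heavy atom's radius
#' accounts for its bonded hydrogens — the right choice for X-ray
#' structures without hydrogens.
#'
#' @name radius_sets
NULL

ELEMENT_VDW_RADII <- c(
  H = 1.10, HE = 1.40, LI = 1.81, BE = 1.53, B = 1.92, C = 1.70, N = 1.55,
  O = 1.52, F = 1.47, NE = 1.54, "NA" = 2.27, MG = 1.73, AL = 1.84,
  SI = 2.10, P = 1.80, S = 1.80, CL = 1.75, AR = 1.88, K = 2.75,
  CA = 2.31, MN = 2.05, FE = 2.05, CO = 2.00, NI = 2.00, CU = 2.00,
  ZN = 2.10, AS = 1.85, SE = 1.90, BR = 1.83, SR = 2.49, MO = 2.10,
  I = 1.98, CS = 3.43, BA = 2.68, W = 2.10, PT = 2.05, AU = 2.10
)

# ProtOr united-atom group radii (Tsai/Taylor/Chothia/Gerstein classes):
# trigonal C without H 1.61, trigonal C-H 1.76, tetrahedral C(Hn) 1.88,
# any N 1.64, carbonyl/carboxyl O 1.42, hydroxyl O-H 1.46, S 1.77.
PROTOR_CLASS_RADII <- c(C3H0 = 1.61, C3H1 = 1.76, C4 = 1.88,
                        N = 1.64, O1 = 1.42, O2H1 = 1.46, S = 1.77)

# Heavy side-chain atoms that are trigonal carbons without hydrogen; all
# other side-chain carbons are either trigonal C-H (aromatic CH) or
# tetrahedral.
PROTOR_C3H0 <- list(
  ARG = "CZ", ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD",
  HIS = "CG", PHE = "CG", TRP = c("CG", "CD2", "CE2"),
  TYR = c("CG", "CZ")
)
PROTOR_C3H1 <- list(
  HIS = c("CD2", "CE1"), PHE = c("CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD1", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CD1", "CD2", "CE1", "CE2")
)
PROTOR_HYDROXYL <- list(SER = "OG", THR = "OG1", TYR = "OH")

protor_radius <- function(res_name, atom_name) {
  r <- PROTOR_CLASS_RADII
  if (atom_name %in% c("N",  "NE", "NH1", "NH2", "ND1", "ND2", "NE1",
                       "NE2", "NZ", "ND", "NT")) return(r[["N"]])
  if (startsWith(atom_name, "N")) return(r[["N"]])
  if (atom_name %in% c("O", "OXT", "OD1", "OD2", "OE1", "OE2"))
    return(r[["O1"]])
  if (atom_name %in% PROTOR_HYDROXYL[[res_name]] %||% character(0))
    return(r[["O2H1"]])
  if (startsWith(atom_name, "O")) return(r[["O1"]])
  if (startsWith(atom_name, "S")) return(r[["S"]])
  if (atom_name == "C") return(r[["C3H0"]])      # backbone carbonyl C
  if (atom_name %in% PROTOR_C3H0[[res_name]] %||% character(0))
    return(r[["C3H0"]])
  if (atom_name %in% PROTOR_C3H1[[res_name]] %||% character(0))
    return(r[["C3H1"]])
  if (startsWith(atom_name, "C")) return(r[["C4"]])  # CA, CB, aliphatic
  NA_real_
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_radii <- function(array, radius_set) {
  if (is.numeric(radius_set)) {
    if (length(radius_set) != n_atoms(array))
      stop("numeric radius set must have one radius per atom")
    return(radius_set)
  }
  n <- n_atoms(array)
  radii <- numeric(n)
  for (i in seq_len(n)) {
    r <- if (radius_set == "single") {
      unname(ELEMENT_VDW_RADII[toupper(array$element[i])])
    } else if (radius_set == "protor") {
      protor_radius(array$res_name[i], array$atom_name[i])
    } else stop("unknown radius set '", radius_set, "'")
    if (is.null(r) || is.na(r))
      stop("no ", radius_set, " radius for atom ", i, " (",
           array$res_name[i], " ", array$atom_name[i], ", element ",
           array$element[i], ")")
    radii[i] <- r
  }
  radii
}

#' Quasi-uniform points on the unit sphere
#'
#' Golden-section (Fibonacci) spiral lattice; deterministic.
#'
#' @param n number of points.
#' @return (n x 3) matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Estimates the atom-wise SASA by placing `point_count` quasi-uniform
#' points on each atom's probe-inflated sphere (radius `r_atom + probe`)
#' and counting the points not buried inside any neighbour's inflated
#' sphere:  `SASA_i = exposed_i / point_count * 4 * pi * (r_i + probe)^2`.
#' Neighbour candidates come from a uniform cell grid with edge
#' `2 * (max radius + probe)`, so results are exact while the search stays
#' near-linear in the atom count.
#'
#' @param array an atom array.
#' @param probe_radius solvent probe radius in Angstrom (1.4 for water).
#' @param point_count sphere points per atom.
#' @param radius_set `"protor"` (heavy-atom group radii), `"single"`
#'   (per-element radii) or a numeric vector with one radius per atom.
#' @param atom_mask optional logical mask: atoms outside the mask get `NA`
#'   SASA and do not occlude others (use it to drop waters/het atoms).
#' @return numeric vector of per-atom areas in Angstrom^2.
#' @export
sasa <- function(array, probe_radius = 1.4, point_count = 1000L,
                 radius_set = "protor", atom_mask = NULL) {
  stopifnot(probe_radius >= 0, point_count >= 1)
  n <- n_atoms(array)
  keep <- if (is.null(atom_mask)) rep(TRUE, n) else as.logical(atom_mask)
  if (length(keep) != n) stop("atom_mask length must equal atom count")
  idx <- which(keep)
  radii <- rep(NA_real_, n)
  radii[idx] <- atom_radii(array[keep], radius_set)
  pts <- sphere_points(point_count)
  xyz <- coords(array)
  out <- rep(NA_real_, n)
  if (length(idx) == 0L) return(out)

  infl <- radii + probe_radius
  cell_edge <- 2 * (max(radii[idx]) + probe_radius)
  key <- function(c3) paste(c3[, 1], c3[, 2], c3[, 3])
  cell_of <- floor(xyz[idx, , drop = FALSE] / cell_edge)
  grid <- split(idx, key(cell_of))

  for (a in idx) {
    center <- xyz[a, ]
    ca <- floor(center / cell_edge)
    neigh <- integer(0)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k <- paste(ca[1] + dx, ca[2] + dy, ca[3] + dz)
      neigh <- c(neigh, grid[[k]])
    }
    neigh <- neigh[neigh != a]
    if (length(neigh)) {
      d2 <- rowSums((xyz[neigh, , drop = FALSE] -
                       matrix(center, length(neigh), 3, byrow = TRUE))^2)
      neigh <- neigh[d2 < (infl[a] + infl[neigh])^2]
    }
    surf <- pts * infl[a] + matrix(center, point_count, 3, byrow = TRUE)
    exposed <- rep(TRUE, point_count)
    for (b in neigh) {
      if (!any(exposed)) break
      db <- surf[exposed, , drop = FALSE] -
        matrix(xyz[b, ], sum(exposed), 3, byrow = TRUE)
      exposed[exposed] <- rowSums(db^2) >= infl[b]^2
    }
    out[a] <- sum(exposed) / point_count * 4 * pi * infl[a]^2
  }
  out
}
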