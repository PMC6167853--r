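#' Geometric measurements
#'
#' Distances, bond angles and dihedral (torsion) angles between atoms,
#' atom arrays and stacks.  Operands broadcast over their leading
#' dimensions like numeric arrays: an (n x 3) set against an (m x n x 3)
#' stack yields an (m x n) result, a single atom against an array yields a
#' length-n vector.  Angles are in radians; undefined results (zero-length
#' bond vectors, collinear torsion axes) are quiet `NaN`s, never errors.
#'
#' @param a,b,c,d coordinate operands: atom arrays, stacks, length-3
#'   vectors, (n x 3) matrices or (m x n x 3) arrays.
#' @return numeric scalar, length-n vector or (m x n) matrix.
#' @name geometry
NULL

# Broadcast coordinate operands to a common (m x n x 3) shape.
broadcast_coords <- function(...) {
  ops <- lapply(list(...), coords)
  ops <- lapply(ops, function(x) {
    if (is.null(dim(x)))
      stop("coordinate operand must be a length-3 vector, (n x 3) matrix, ",
           "(m x n x 3) array, atom array or stack")
    if (length(dim(x)) == 2L) array(x, c(1L, dim(x))) else x
  })
  ms <- vapply(ops, function(x) dim(x)[1], integer(1))
  ns <- vapply(ops, function(x) dim(x)[2], integer(1))
  m <- max(ms); n <- max(ns)
  if (any(!(ms %in% c(1L, m))) || any(!(ns %in% c(1L, n))))
    stop("coordinate operands have incompatible shapes")
  ops <- lapply(ops, function(x) {
    if (dim(x)[2] == 1L && n > 1L) x <- x[, rep(1L, n), , drop = FALSE]
    if (dim(x)[1] == 1L && m > 1L) x <- x[rep(1L, m), , , drop = FALSE]
    x
  })
  attr(ops, "shape") <- c(m, n)
  ops
}

shape_result <- function(v, shape) {
  m <- shape[1]; n <- shape[2]
  if (m == 1L) as.numeric(v) else matrix(v, m, n)
}

#' @rdname geometry
#' @export
distance <- function(a, b) {
  ops <- broadcast_coords(a, b)
  d <- matrix(ops[[1]] - ops[[2]], ncol = 3L)
  shape_result(sqrt(rowSums(d^2)), attr(ops, "shape"))
}

#' @rdname geometry
#' @export
angle <- function(a, b, c) {
  ops <- broadcast_coords(a, b, c)
  shp <- attr(ops, "shape")
  v1 <- matrix(ops[[1]] - ops[[2]], ncol = 3L)
  v2 <- matrix(ops[[3]] - ops[[2]], ncol = 3L)
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  cosv <- rowSums(v1 * v2) / (n1 * n2)   # 0/0 -> NaN for degenerate input
  cosv <- pmin(1, pmax(-1, cosv))
  shape_result(acos(cosv), shp)
}

#' @rdname geometry
#' @details
#' The dihedral follows the IUPAC convention: 0 for the cis (eclipsed)
#' arrangement, sign by the right-hand rule looking from `b` to `c`,
#' range (-pi, pi].
#' @export
dihedral <- function(a, b, c, d) {
  ops <- broadcast_coords(a, b, c, d)
  shp <- attr(ops, "shape")
  b1 <- matrix(ops[[2]] - ops[[1]], ncol = 3L)
  b2 <- matrix(ops[[3]] - ops[[2]], ncol = 3L)
  b3 <- matrix(ops[[4]] - ops[[3]], ncol = 3L)
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  ang <- atan2(y, x)
  # degenerate (collinear) input: zero normal vectors -> NaN
  bad <- rowSums(n1^2) == 0 | rowSums(n2^2) == 0
  ang[bad] <- NaN
  # atan2 maps trans to pi or -pi depending on rounding; canonicalize to pi
  ang[!is.nan(ang) & ang <= -pi + 1e-12] <- pi
  shape_result(ang, shp)
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Backbone dihedral angles of a peptide chain
#'
#' Computes per-residue phi, psi and omega torsions from the N, CA and C
#' backbone atoms: phi(i) = C(i-1)-N(i)-CA(i)-C(i), psi(i) =
#' N(i)-CA(i)-C(i)-N(i+1), omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1).  Angles
#' whose atoms cross the chain termini are `NaN`; a residue missing a
#' backbone atom yields `NaN` for the affected angles without aborting.
#' Residues are taken in file order, identified by `(chain_id, res_id)`.
#'
#' @param array an atom array.
#' @param chain chain identifier; default: the first chain in the array.
#' @return data.frame with columns `res_id`, `phi`, `psi`, `omega`
#'   (radians).
#' @export
backbone_dihedrals <- function(array, chain = NULL) {
  stopifnot(inherits(array, "atom_array"))
  if (is.null(chain)) chain <- array$chain_id[1]
  sel <- array[array$chain_id == chain & !array$hetero]
  res_ids <- unique(sel$res_id)
  k <- length(res_ids)
  pick <- function(rid, name) {
    idx <- which(sel$res_id == rid & sel$atom_name == name)
    if (length(idx) == 0L) rep(NaN, 3L) else as.numeric(sel$coord[idx[1L], ])
  }
  N  <- t(vapply(res_ids, pick, numeric(3), name = "N"))
  CA <- t(vapply(res_ids, pick, numeric(3), name = "CA"))
  C  <- t(vapply(res_ids, pick, numeric(3), name = "C"))
  phi <- psi <- omega <- rep(NaN, k)
  for (i in seq_len(k)) {
    if (i > 1L)
      phi[i] <- dihedral(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (i < k) {
      psi[i] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- dihedral(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  data.frame(res_id = res_ids, phi = phi, psi = psi, omega = omega)
}
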