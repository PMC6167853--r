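#' Kabsch superimposition
#'
#' Finds the proper rigid transform (rotation + translation) that minimizes
#' the RMSD of `mobile` onto `fixed` over all rotations and translations:
#' both coordinate sets are centered, the rotation is taken from the SVD of
#' the covariance matrix, and a reflection (negative determinant) is
#' corrected by sign-flipping the singular direction with the smallest
#' singular value.  The transform is stored as "subtract the mobile
#' centroid, rotate, add the fixed centroid".
#'
#' @param fixed reference atom array (or (n x 3) matrix).
#' @param mobile structure to superimpose; same atom count as `fixed`,
#'   n >= 3 and not all collinear.
#' @return list with `fitted` (the transformed mobile structure) and
#'   `transform`, a `"rigid_transform"` with fields `rotation` (3 x 3,
#'   determinant +1), `center_translation` (minus the mobile centroid) and
#'   `final_translation` (the fixed centroid).
#' @export
superimpose <- function(fixed, mobile) {
  P <- coords(fixed)   # target
  Q <- coords(mobile)  # to move
  if (length(dim(P)) != 2L || length(dim(Q)) != 2L)
    stop("superimpose expects single-model structures")
  if (nrow(P) != nrow(Q))
    stop("atom counts differ: ", nrow(P), " vs ", nrow(Q))
  if (nrow(P) < 3L) stop("superimposition needs at least 3 atoms")
  cP <- colMeans(P); cQ <- colMeans(Q)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  H <- t(Q0) %*% P0          # covariance of mobile against fixed
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))      # reflection correction on the smallest
  R <- sv$v %*% D %*% t(sv$u)  # singular direction (svd orders decreasing)
  tr <- structure(list(rotation = R,
                       center_translation = -cQ,
                       final_translation = cP),
                  class = "rigid_transform")
  fitted <- apply_transform(mobile, tr)
  list(fitted = fitted, transform = tr)
}

#' Apply a rigid transform
#'
#' @param x atom array, stack or coordinate matrix.
#' @param transform a `"rigid_transform"` from [superimpose()].
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  f <- function(m) {
    m <- sweep(m, 2, -transform$center_translation)
    m <- m %*% t(transform$rotation)
    sweep(m, 2, transform$final_translation, FUN = "+")
  }
  if (inherits(x, "atom_array_stack")) {
    out <- x
    for (k in seq_len(n_models(x))) out$coord[k, , ] <- f(x$coord[k, , ])
    out
  } else if (inherits(x, "atom_array")) {
    out <- x
    out$coord <- f(x$coord)
    out
  } else f(coords(x))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> det(R) =", round(det(x$rotation), 6), "\n")
  invisible(x)
}

#' Root-mean-square deviation
#'
#' `sqrt(mean(|r_ref - r_sub|^2))` over atoms.  If `subject` is a stack the
#' result is one value per model.
#'
#' @param reference atom array or (n x 3) matrix.
#' @param subject atom array, stack, or matching coordinates.
#' @return numeric scalar or length-m vector.
#' @export
rmsd <- function(reference, subject) {
  ref <- coords(reference)
  sub <- coords(subject)
  if (length(dim(sub)) == 3L) {
    if (dim(sub)[2] != nrow(ref))
      stop("atom counts differ: ", nrow(ref), " vs ", dim(sub)[2])
    return(vapply(seq_len(dim(sub)[1]), function(k)
      sqrt(mean(rowSums((sub[k, , ] - ref)^2))), numeric(1)))
  }
  if (nrow(sub) != nrow(ref))
    stop("atom counts differ: ", nrow(ref), " vs ", nrow(sub))
  sqrt(mean(rowSums((sub - ref)^2)))
}

#' Root-mean-square fluctuation
#'
#' Per atom: `sqrt(mean_m(|r_m - r_ref|^2))` over the m models of a stack.
#' The reference defaults to the coordinate mean over models.
#'
#' @param stack an atom array stack with at least 2 models.
#' @param reference optional reference coordinates ((n x 3) or atom array).
#' @return numeric vector of length n.
#' @export
rmsf <- function(stack, reference = NULL) {
  cs <- coords(stack)
  if (length(dim(cs)) != 3L || dim(cs)[1] < 2L)
    stop("rmsf needs a stack with at least 2 models")
  m <- dim(cs)[1]; n <- dim(cs)[2]
  ref <- if (is.null(reference)) apply(cs, c(2, 3), mean)
         else coords(reference)
  if (nrow(ref) != n) stop("reference atom count differs")
  acc <- matrix(0, m, n)
  for (k in seq_len(m)) acc[k, ] <- rowSums((cs[k, , ] - ref)^2)
  sqrt(colMeans(acc))
}
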