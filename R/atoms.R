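#' Columnar atomic structure model
#'
#' A structure with n atoms is stored column-wise: one annotation vector of
#' length n per category (`chain_id`, `res_id`, `res_name`, `atom_name`,
#' `element`, `hetero`, optionally `b_factor`, `occupancy`, `altloc`, ...)
#' plus an (n x 3) coordinate matrix in Angstrom.  A multi-model structure
#' (NMR ensemble, trajectory) shares one set of annotations and holds an
#' (m x n x 3) coordinate array.  Both behave like arrays under indexing
#' with integers, index vectors or boolean masks, so structures are
#' filtered by masks over annotations.
#'
#' @param coord (n x 3) numeric matrix.
#' @param chain_id,res_id,res_name,atom_name,element annotation vectors of
#'   length n (scalars are recycled).
#' @param hetero logical length-n vector: `TRUE` for HETATM-origin atoms.
#' @param ... further annotation categories (length n each), e.g.
#'   `b_factor`, `occupancy`.
#' @return an object of class `"atom_array"`.
#' @export
atom_array <- function(coord, chain_id = "A", res_id = 1L, res_name = "UNK",
                       atom_name = "X", element = "C", hetero = FALSE, ...) {
  coord <- as.matrix(coord)
  if (ncol(coord) != 3L) stop("coord must be an (n x 3) matrix")
  storage.mode(coord) <- "double"
  dimnames(coord) <- NULL
  n <- nrow(coord)
  ann <- list(chain_id = as.character(chain_id),
              res_id = as.integer(res_id),
              res_name = as.character(res_name),
              atom_name = as.character(atom_name),
              element = as.character(element),
              hetero = as.logical(hetero))
  extra <- list(...)
  ann <- c(ann, extra)
  ann <- lapply(ann, function(a) if (length(a) == 1L) rep(a, n) else a)
  bad <- names(ann)[vapply(ann, length, integer(1)) != n]
  if (length(bad))
    stop("annotation arrays must have length n = ", n, ": ",
         paste(bad, collapse = ", "))
  structure(c(list(coord = coord), ann), class = "atom_array")
}

#' @rdname atom_array
#' @param coord_stack (m x n x 3) numeric array.
#' @export
atom_array_stack <- function(coord_stack, chain_id = "A", res_id = 1L,
                             res_name = "UNK", atom_name = "X",
                             element = "C", hetero = FALSE, ...) {
  coord_stack <- as_coord_stack(coord_stack)
  n <- dim(coord_stack)[2]
  template <- atom_array(matrix(0, n, 3), chain_id, res_id, res_name,
                         atom_name, element, hetero, ...)
  template$coord <- coord_stack
  class(template) <- "atom_array_stack"
  template
}

as_coord_stack <- function(x) {
  x <- if (is.matrix(x)) array(x, c(1L, dim(x))) else as.array(x)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("stack coordinates must be an (m x n x 3) array")
  storage.mode(x) <- "double"
  x
}

#' Build a stack from atom arrays with identical annotations
#' @param arrays list of atom arrays (same n and annotations).
#' @return an `"atom_array_stack"` with m = `length(arrays)`.
#' @export
stack_atom_arrays <- function(arrays) {
  stopifnot(length(arrays) >= 1L)
  ref <- arrays[[1]]
  for (a in arrays[-1]) {
    if (n_atoms(a) != n_atoms(ref))
      stop("all models must have the same atom count")
    for (cat in annotation_names(ref))
      if (!identical(a[[cat]], ref[[cat]]))
        stop("models differ in annotation '", cat, "'")
  }
  m <- length(arrays)
  n <- n_atoms(ref)
  coord <- array(0, c(m, n, 3L))
  for (k in seq_len(m)) coord[k, , ] <- arrays[[k]]$coord
  out <- ref
  out$coord <- coord
  class(out) <- "atom_array_stack"
  out
}

#' Number of atoms / models
#' @param x atom array or stack.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "atom_array_stack")) dim(x$coord)[2] else nrow(x$coord)
}

#' @rdname n_atoms
#' @export
n_models <- function(x) {
  if (inherits(x, "atom_array_stack")) dim(x$coord)[1] else 1L
}

#' Annotation category names
#' @param x atom array or stack.
#' @export
annotation_names <- function(x) setdiff(names(x), "coord")

#' Coordinates of an array, stack or plain matrix
#' @param x atom array, stack, numeric vector of length 3, or matrix/array.
#' @return (n x 3) matrix or (m x n x 3) array.
#' @export
coords <- function(x) {
  if (inherits(x, c("atom_array", "atom_array_stack"))) x$coord
  else if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L)
    matrix(x, 1L, 3L)
  else x
}

#' @export
print.atom_array <- function(x, ...) {
  cat("<atom_array> ", n_atoms(x), " atoms\n", sep = "")
  print(utils::head(as.data.frame(x), 8L))
  if (n_atoms(x) > 8L) cat("...\n")
  invisible(x)
}

#' @export
print.atom_array_stack <- function(x, ...) {
  cat("<atom_array_stack> ", n_models(x), " models x ", n_atoms(x),
      " atoms\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.atom_array <- function(x, ...) {
  df <- data.frame(x[annotation_names(x)], stringsAsFactors = FALSE)
  df$x <- x$coord[, 1]; df$y <- x$coord[, 2]; df$z <- x$coord[, 3]
  df
}

check_atom_selector <- function(i, n) {
  if (is.logical(i)) {
    if (length(i) != n)
      stop("boolean mask length ", length(i), " does not match atom count ",
           n)
  } else if (is.numeric(i)) {
    if (any(i > n) || any(i == 0))
      stop("atom index out of range (n = ", n, ")")
  }
  i
}

#' @export
`[.atom_array` <- function(x, i) {
  if (missing(i)) return(x)
  i <- check_atom_selector(i, n_atoms(x))
  out <- x
  for (cat in annotation_names(x)) out[[cat]] <- x[[cat]][i]
  out$coord <- x$coord[i, , drop = FALSE]
  out
}

#' @export
`[.atom_array_stack` <- function(x, i, j) {
  has_i <- !missing(i); has_j <- !missing(j)
  if (has_j) j <- check_atom_selector(j, n_atoms(x))
  if (has_i && is.numeric(i) && any(abs(i) > n_models(x)))
    stop("model index out of range (m = ", n_models(x), ")")
  # single model selection collapses to an atom_array
  if (has_i && is.numeric(i) && length(i) == 1L && i > 0) {
    out <- x
    out$coord <- x$coord[i, , , drop = TRUE]
    if (is.null(dim(out$coord))) out$coord <- matrix(out$coord, ncol = 3L)
    class(out) <- "atom_array"
    if (has_j) out <- out[j]
    return(out)
  }
  out <- x
  if (has_i) out$coord <- x$coord[i, , , drop = FALSE]
  if (has_j) {
    for (cat in annotation_names(x)) out[[cat]] <- x[[cat]][j]
    out$coord <- out$coord[, j, , drop = FALSE]
  }
  out
}

#' Concatenate two atom arrays
#'
#' @param x,y atom arrays; annotation categories are unioned (categories
#'   absent on one side are filled with `NA`).
#' @return atom array with `n_atoms(x) + n_atoms(y)` atoms, annotations in
#'   order.
#' @export
concat_atom_arrays <- function(x, y) {
  stopifnot(inherits(x, "atom_array"), inherits(y, "atom_array"))
  cats <- union(annotation_names(x), annotation_names(y))
  ann <- lapply(cats, function(cat) {
    a <- if (!is.null(x[[cat]])) x[[cat]] else rep(NA, n_atoms(x))
    b <- if (!is.null(y[[cat]])) y[[cat]] else rep(NA, n_atoms(y))
    c(a, b)
  })
  names(ann) <- cats
  out <- c(list(coord = rbind(x$coord, y$coord)), ann)
  structure(out, class = "atom_array")
}

#' Extract one atom
#' @param x atom array.
#' @param i atom index (1-based).
#' @return a list with `coord` (length-3 vector) and scalar annotations.
#' @export
get_atom <- function(x, i) {
  stopifnot(i >= 1L, i <= n_atoms(x))
  out <- lapply(annotation_names(x), function(cat) x[[cat]][i])
  names(out) <- annotation_names(x)
  out$coord <- as.numeric(x$coord[i, ])
  structure(out, class = "atom")
}
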