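#' Read PDB coordinate records
#'
#' Parses only the ATOM and HETATM records (plus MODEL/ENDMDL block
#' structure) of a PDB file into an atom array; files with two or more
#' MODEL blocks yield an atom array stack (all models must agree in atom
#' count and annotations).  The `hetero` flag is `TRUE` exactly for
#' HETATM records.  Coordinates are fixed-point with 3 decimals, i.e.
#' exact to 0.001 Angstrom.  A blank element column is inferred from the
#' atom-name columns (left-justification rule).  When a position carries
#' alternate locations, the first-listed altloc is kept and the others
#' dropped unless `keep_altloc = TRUE`, in which case the altloc
#' identifier becomes an annotation.
#'
#' @param text PDB text: a string, vector of lines, or file path.
#' @param keep_altloc keep all alternate locations as an `altloc`
#'   annotation instead of keeping only the first.
#' @return an `"atom_array"` or `"atom_array_stack"`.
#' @export
read_pdb <- function(text, keep_altloc = FALSE) {
  lines <- as_lines(text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_no <- cumsum(rec == "MODEL ")
  models <- unique(model_no[is_atom])
  arrays <- lapply(models, function(mn)
    parse_pdb_block(lines[is_atom & model_no == mn],
                    which(is_atom & model_no == mn), keep_altloc))
  if (length(arrays) == 0L)
    stop("no ATOM/HETATM records found")
  if (length(arrays) == 1L) return(arrays[[1]])
  counts <- vapply(arrays, n_atoms, integer(1))
  if (length(unique(counts)) != 1L)
    stop("MODEL blocks differ in atom count: ",
         paste(counts, collapse = ", "))
  stack_atom_arrays(arrays)
}

parse_pdb_block <- function(lines, line_numbers, keep_altloc) {
  short <- which(nchar(lines) < 54L)
  if (length(short))
    stop("PDB line ", line_numbers[short[1]],
         " is shorter than 54 columns")
  field <- function(from, to) substr(lines, from, to)
  numfield <- function(from, to, what) {
    s <- field(from, to)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad))
      stop("unparseable ", what, " at PDB line ", line_numbers[bad[1]],
           ": '", s[bad[1]], "'")
    v
  }
  x <- numfield(31, 38, "x coordinate")
  y <- numfield(39, 46, "y coordinate")
  z <- numfield(47, 54, "z coordinate")
  if (anyNA(c(x, y, z)))
    stop("blank coordinate field at PDB line ",
         line_numbers[which(is.na(x + y + z))[1]])
  atom_name <- trimws(field(13, 16))
  element <- trimws(field(77, 78))
  # legacy files leave the element blank; columns 13-14 carry it,
  # left-padded for one-letter elements
  guess <- trimws(substr(lines, 13, 14))
  guess <- ifelse(grepl("^[0-9]", guess) | substr(lines, 13, 13) == " ",
                  substr(guess, nchar(guess), nchar(guess)), guess)
  element <- ifelse(nzchar(element), element, toupper(gsub("[0-9]", "", guess)))
  altloc <- field(17, 17)
  occ <- numfield(55, 60, "occupancy")
  bf <- numfield(61, 66, "B-factor")
  arr <- atom_array(
    coord = cbind(x, y, z),
    chain_id = field(22, 22),
    res_id = as.integer(numfield(23, 26, "residue number")),
    res_name = trimws(field(18, 20)),
    atom_name = atom_name,
    element = element,
    hetero = substr(lines, 1, 6) == "HETATM",
    b_factor = ifelse(is.na(bf), 0, bf),
    occupancy = ifelse(is.na(occ), 1, occ),
    altloc = altloc
  )
  if (keep_altloc) return(arr)
  drop_altlocs(arr)
}

# keep the first-listed altloc of each (chain, res, atom name) position
drop_altlocs <- function(arr) {
  al <- arr$altloc
  key <- paste(arr$chain_id, arr$res_id, arr$res_name, arr$atom_name)
  keep <- al == " " | al == "" | !duplicated(key)
  # a duplicated key with blank altloc is a genuine duplicate atom; only
  # non-blank altlocs after the first of their position are dropped
  keep[al != " " & al != "" & duplicated(key)] <- FALSE
  out <- arr[keep]
  out$altloc <- NULL
  out
}

#' Write PDB coordinate records
#'
#' `read_pdb(write_pdb(x))` reproduces all annotations and the coordinates
#' to 0.001 Angstrom.  Stacks produce one MODEL/ENDMDL block per model.
#' Annotations must fit the fixed columns: chain id 1 character, residue
#' number at most 4 digits, serial at most 5 digits.
#'
#' @param x atom array or stack.
#' @param path optional output file.
#' @return the PDB text as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_pdb <- function(x, path = NULL) {
  if (inherits(x, "atom_array_stack")) {
    out <- character(0)
    for (k in seq_len(n_models(x))) {
      out <- c(out, sprintf("MODEL     %4d", k),
               format_pdb_lines(x[k, ]), "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    out <- c(format_pdb_lines(x), "END")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

format_pdb_lines <- function(arr) {
  n <- n_atoms(arr)
  bad <- which(nchar(arr$chain_id) > 1L)
  if (length(bad))
    stop("atom ", bad[1], ": chain id '", arr$chain_id[bad[1]],
         "' exceeds 1 character")
  bad <- which(arr$res_id > 9999L | arr$res_id < -999L)
  if (length(bad))
    stop("atom ", bad[1], ": residue number ", arr$res_id[bad[1]],
         " exceeds 4 digits")
  if (n > 99999L) stop("atom serial exceeds 5 digits (n = ", n, ")")
  bad <- which(abs(arr$coord) >= 10000)
  if (length(bad))
    stop("coordinate out of the PDB fixed-column range at atom ",
         ((bad[1] - 1L) %% n) + 1L)
  # standard alignment: element part of the atom name starts at column 14;
  # names of up to 3 characters with a 1-letter element are left-padded
  names4 <- ifelse(nchar(arr$atom_name) <= 3L &
                     nchar(arr$element) == 1L,
                   sprintf(" %-3s", arr$atom_name),
                   sprintf("%-4s", arr$atom_name))
  bf <- if (!is.null(arr$b_factor)) arr$b_factor else rep(0, n)
  occ <- if (!is.null(arr$occupancy)) arr$occupancy else rep(1, n)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(arr$hetero, "HETATM", "ATOM"),
          seq_len(n), names4, " ", arr$res_name, arr$chain_id,
          arr$res_id, " ",
          arr$coord[, 1], arr$coord[, 2], arr$coord[, 3],
          occ, bf, toupper(arr$element))
}
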