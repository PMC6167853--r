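#' Read PDBx/mmCIF text into category tables
#'
#' Parses the generic category model of the PDBx/mmCIF syntax: a `data_`
#' block with `_category.item value` pairs and `loop_` constructs, with
#' quoted values and semicolon-delimited multi-line values.  Every
#' category becomes a named list of equal-length character columns
#' (length 1 for key-value style categories, row count for loops).
#'
#' @param text mmCIF text: a string, vector of lines, or a file path.
#' @return named list of category tables (`name -> list of columns`).
#' @export
read_mmcif <- function(text) {
  lines <- as_lines(text)
  tokens <- cif_tokenize(lines)
  categories <- list()
  i <- 1L
  n <- length(tokens$value)
  tokval <- tokens$value; toktype <- tokens$type
  add_value <- function(tag, value) {
    parts <- strsplit(sub("^_", "", tag), ".", fixed = TRUE)[[1]]
    cat_name <- parts[1]; item <- paste(parts[-1], collapse = ".")
    categories[[cat_name]][[item]] <<- value
  }
  while (i <= n) {
    tok <- tokval[i]; type <- toktype[i]
    if (type == "tag" && startsWith(tok, "data_")) { i <- i + 1L; next }
    if (type == "tag" && tolower(tok) == "loop_") {
      i <- i + 1L
      cols <- character(0)
      while (i <= n && toktype[i] == "tag" && startsWith(tokval[i], "_")) {
        cols <- c(cols, tokval[i]); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n && !(toktype[i] == "tag")) {
        vals <- c(vals, tokval[i]); i <- i + 1L
      }
      if (length(cols) == 0L) stop("mmCIF: loop_ without item tags")
      if (length(vals) %% length(cols) != 0L)
        stop("mmCIF: loop_ body of ", length(vals),
             " values is not divisible by ", length(cols), " columns")
      nr <- length(vals) %/% length(cols)
      mat <- matrix(vals, nrow = nr, byrow = TRUE)
      for (k in seq_along(cols)) add_value(cols[k], mat[, k])
      next
    }
    if (type == "tag" && startsWith(tok, "_")) {
      if (i + 1L > n || toktype[i + 1L] == "tag")
        stop("mmCIF: item ", tok, " has no value")
      add_value(tok, tokval[i + 1L])
      i <- i + 2L
      next
    }
    stop("mmCIF: unexpected token '", tok, "'")
  }
  categories
}

# Split mmCIF text into tokens; type "tag" marks data_/loop_/_item tokens,
# type "value" quoted/unquoted/multiline values.
cif_tokenize <- function(lines) {
  values <- character(0); types <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (startsWith(line, ";")) {       # semicolon-delimited multi-line value
      body <- substring(line, 2)
      i <- i + 1L
      while (i <= length(lines) && !startsWith(lines[i], ";")) {
        body <- paste(body, lines[i], sep = "\n")
        i <- i + 1L
      }
      if (i > length(lines)) stop("mmCIF: unterminated multi-line value")
      values <- c(values, body); types <- c(types, "value")
      i <- i + 1L
      next
    }
    line <- sub("^\\s+", "", line)
    if (!nzchar(line) || startsWith(line, "#")) { i <- i + 1L; next }
    while (nzchar(line)) {
      line <- sub("^\\s+", "", line)
      if (!nzchar(line) || startsWith(line, "#")) break
      ch <- substr(line, 1, 1)
      if (ch == "'" || ch == "\"") {
        m <- regexpr(paste0(ch, "(\\s|$)"), substring(line, 2))
        if (m < 0) stop("mmCIF: unterminated quoted value in: ", line)
        values <- c(values, substr(line, 2, m))
        types <- c(types, "value")
        line <- substring(line, m + 2L)
      } else {
        m <- regexpr("\\s", line)
        tok <- if (m < 0) line else substr(line, 1, m - 1L)
        line <- if (m < 0) "" else substring(line, m)
        is_tag <- startsWith(tok, "_") || tolower(tok) == "loop_" ||
          startsWith(tolower(tok), "data_")
        values <- c(values, tok)
        types <- c(types, if (is_tag) "tag" else "value")
      }
    }
    i <- i + 1L
  }
  list(value = values, type = types)
}

MANDATORY_ATOM_SITE <- c("group_PDB", "id", "label_atom_id",
                         "label_comp_id", "auth_asym_id", "auth_seq_id",
                         "Cartn_x", "Cartn_y", "Cartn_z", "type_symbol")

#' Convert between category tables and atom arrays
#'
#' `mmcif_to_atoms()` builds an atom array (or stack, when the model
#' number item has several values) from the `atom_site` category;
#' `atoms_to_mmcif()` produces category tables holding an `atom_site`
#' category.  `group_PDB` maps to the `hetero` flag (`HETATM` vs `ATOM`).
#'
#' @param tables category tables from [read_mmcif()].
#' @param keep_altloc keep alternate locations (annotation `altloc`)
#'   instead of the first-listed one per atom position.
#' @return an atom array or stack / a category-table list.
#' @export
mmcif_to_atoms <- function(tables, keep_altloc = FALSE) {
  as_ <- tables$atom_site
  if (is.null(as_)) stop("no atom_site category in the mmCIF tables")
  miss <- setdiff(MANDATORY_ATOM_SITE, names(as_))
  # auth_* items may fall back to label_*
  if ("auth_asym_id" %in% miss && "label_asym_id" %in% names(as_)) {
    as_$auth_asym_id <- as_$label_asym_id
    miss <- setdiff(miss, "auth_asym_id")
  }
  if ("auth_seq_id" %in% miss && "label_seq_id" %in% names(as_)) {
    as_$auth_seq_id <- as_$label_seq_id
    miss <- setdiff(miss, "auth_seq_id")
  }
  if (length(miss))
    stop("atom_site lacks mandatory items: ", paste(miss, collapse = ", "))
  model <- if (!is.null(as_$pdbx_PDB_model_num)) as_$pdbx_PDB_model_num
           else rep("1", length(as_$id))
  build <- function(ix) {
    arr <- atom_array(
      coord = cbind(as.numeric(as_$Cartn_x[ix]),
                    as.numeric(as_$Cartn_y[ix]),
                    as.numeric(as_$Cartn_z[ix])),
      chain_id = as_$auth_asym_id[ix],
      res_id = as.integer(as_$auth_seq_id[ix]),
      res_name = as_$label_comp_id[ix],
      atom_name = as_$label_atom_id[ix],
      element = as_$type_symbol[ix],
      hetero = as_$group_PDB[ix] == "HETATM",
      b_factor = if (!is.null(as_$B_iso_or_equiv))
        as.numeric(as_$B_iso_or_equiv[ix]) else rep(0, length(ix)),
      occupancy = if (!is.null(as_$occupancy))
        as.numeric(as_$occupancy[ix]) else rep(1, length(ix)),
      altloc = if (!is.null(as_$label_alt_id))
        ifelse(as_$label_alt_id[ix] %in% c(".", "?"), " ",
               as_$label_alt_id[ix])
        else rep(" ", length(ix))
    )
    if (keep_altloc) arr else drop_altlocs(arr)
  }
  model_levels <- unique(model)
  arrays <- lapply(model_levels, function(mv) build(which(model == mv)))
  if (length(arrays) == 1L) arrays[[1]] else stack_atom_arrays(arrays)
}

#' @rdname mmcif_to_atoms
#' @param x atom array or stack.
#' @param data_name name for the `data_` block.
#' @export
atoms_to_mmcif <- function(x, data_name = "structure") {
  models <- if (inherits(x, "atom_array_stack"))
    lapply(seq_len(n_models(x)), function(k) x[k, ]) else list(x)
  n <- n_atoms(models[[1]])
  m <- length(models)
  rep_ann <- function(f, default) {
    v <- if (!is.null(models[[1]][[f]])) models[[1]][[f]] else
      rep(default, n)
    rep(v, m)
  }
  coord <- do.call(rbind, lapply(models, coords))
  list(atom_site = list(
    group_PDB = ifelse(rep_ann("hetero", FALSE), "HETATM", "ATOM"),
    id = as.character(seq_len(n * m)),
    label_atom_id = rep_ann("atom_name", "X"),
    label_alt_id = {
      al <- rep_ann("altloc", ".")
      ifelse(al %in% c(" ", ""), ".", al)
    },
    label_comp_id = rep_ann("res_name", "UNK"),
    auth_asym_id = rep_ann("chain_id", "A"),
    auth_seq_id = as.character(rep_ann("res_id", 1L)),
    type_symbol = rep_ann("element", "C"),
    Cartn_x = sprintf("%.3f", coord[, 1]),
    Cartn_y = sprintf("%.3f", coord[, 2]),
    Cartn_z = sprintf("%.3f", coord[, 3]),
    occupancy = sprintf("%.2f", rep_ann("occupancy", 1)),
    B_iso_or_equiv = sprintf("%.2f", rep_ann("b_factor", 0)),
    pdbx_PDB_model_num = as.character(rep(seq_len(m), each = n))
  ), `_data_name` = data_name)
}

#' Write category tables (or a structure) as mmCIF text
#'
#' @param x atom array, stack, or category tables.
#' @param path optional output file.
#' @return character vector of mmCIF lines.
#' @export
write_mmcif <- function(x, path = NULL) {
  tables <- if (inherits(x, c("atom_array", "atom_array_stack")))
    atoms_to_mmcif(x) else x
  data_name <- tables$`_data_name` %||% "structure"
  tables$`_data_name` <- NULL
  out <- paste0("data_", data_name)
  quote_val <- function(v) {
    v[!nzchar(v)] <- "."
    needs <- grepl("\\s|^_|^'|^\"", v)
    v[needs] <- paste0("'", v[needs], "'")
    v
  }
  for (cat_name in names(tables)) {
    tab <- tables[[cat_name]]
    len <- unique(vapply(tab, length, integer(1)))
    if (length(len) != 1L)
      stop("category ", cat_name, " has columns of unequal length")
    out <- c(out, "#")
    if (len == 1L) {
      for (item in names(tab))
        out <- c(out, sprintf("_%s.%s %s", cat_name, item,
                              quote_val(as.character(tab[[item]]))))
    } else {
      out <- c(out, "loop_",
               sprintf("_%s.%s", cat_name, names(tab)))
      cols <- lapply(tab, function(cl) quote_val(as.character(cl)))
      rows <- do.call(paste, cols)
      out <- c(out, rows)
    }
  }
  out <- c(out, "#")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
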