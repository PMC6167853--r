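#' MMTF structure encoding and decoding
#'
#' MMTF stores a structure as a MessagePack map of typed fields; the
#' chain -> residue (group) -> atom hierarchy is flattened onto the
#' per-atom annotation arrays of an atom array and back.  Coordinates are
#' quantized at 1/1000 Angstrom (divisor 1000), B-factors at 1/100,
#' occupancies at 1/100, matching the format's conventions.  The encoder
#' emits the mandatory fields of the v1.0 format (plus B-factor/occupancy/
#' altloc fields when the structure carries those annotations); the
#' decoder accepts any conformant document restricted to codecs 1-10 and
#' reads optional fields when present (bonds are kept as an opaque pair
#' list attribute, not a topology model).
#'
#' @param x an atom array or atom array stack.
#' @return `encode_mmtf()`: raw vector with the MessagePack document;
#'   `decode_mmtf()`: an atom array (single model) or stack.
#' @export
encode_mmtf <- function(x) {
  models <- if (inherits(x, "atom_array_stack"))
    lapply(seq_len(n_models(x)), function(k) x[k, ]) else list(x)
  m <- length(models)
  n <- n_atoms(models[[1]])

  group_keys <- character(0)
  group_list <- list()
  group_type <- integer(0)   # 0-based index into group_list, per group
  group_id <- integer(0)     # res_id per group
  chain_ids <- character(0)
  groups_per_chain <- integer(0)
  chains_per_model <- integer(0)

  for (mod in models) {
    chain_run <- run_starts(mod$chain_id)
    chains_per_model <- c(chains_per_model, length(chain_run$starts))
    for (ci in seq_along(chain_run$starts)) {
      lo <- chain_run$starts[ci]; hi <- chain_run$ends[ci]
      chain_ids <- c(chain_ids, mod$chain_id[lo])
      rid <- mod$res_id[lo:hi]
      grp <- run_starts(paste(rid, mod$res_name[lo:hi],
                              mod$hetero[lo:hi]))
      groups_per_chain <- c(groups_per_chain, length(grp$starts))
      for (gi in seq_along(grp$starts)) {
        glo <- lo + grp$starts[gi] - 1L; ghi <- lo + grp$ends[gi] - 1L
        atoms <- glo:ghi
        key <- paste(mod$res_name[glo], mod$hetero[glo],
                     paste(mod$atom_name[atoms], collapse = ","),
                     paste(mod$element[atoms], collapse = ","), sep = "|")
        pos <- match(key, group_keys)
        if (is.na(pos)) {
          group_keys <- c(group_keys, key)
          group_list[[length(group_list) + 1L]] <- list(
            formalChargeList = as_msgpack_array(
              rep(0L, length(atoms))),
            atomNameList = as_msgpack_array(mod$atom_name[atoms]),
            elementList = as_msgpack_array(mod$element[atoms]),
            bondAtomList = as_msgpack_array(integer(0)),
            bondOrderList = as_msgpack_array(integer(0)),
            groupName = mod$res_name[glo],
            singleLetterCode = "?",
            chemCompType = if (mod$hetero[glo]) "NON-POLYMER"
                           else "PEPTIDE LINKING"
          )
          pos <- length(group_list)
        }
        group_type <- c(group_type, pos - 1L)
        group_id <- c(group_id, rid[grp$starts[gi]])
      }
    }
  }

  flat <- function(field) do.call(c, lapply(models, `[[`, field))
  all_coord <- do.call(rbind, lapply(models, coords))
  doc <- list(
    mmtfVersion = "1.0.0",
    mmtfProducer = "atomseq",
    numBonds = 0L,
    numAtoms = as.integer(m * n),
    numGroups = length(group_type),
    numChains = length(chain_ids),
    numModels = m,
    groupList = group_list,
    xCoordList = mmtf_encode_field(all_coord[, 1], 10L, 1000L),
    yCoordList = mmtf_encode_field(all_coord[, 2], 10L, 1000L),
    zCoordList = mmtf_encode_field(all_coord[, 3], 10L, 1000L),
    groupIdList = mmtf_encode_field(group_id, 8L),
    groupTypeList = mmtf_encode_field(group_type, 4L),
    chainIdList = mmtf_encode_field(chain_ids, 5L, 4L),
    chainNameList = mmtf_encode_field(chain_ids, 5L, 4L),
    groupsPerChain = as_msgpack_array(groups_per_chain),
    chainsPerModel = as_msgpack_array(chains_per_model),
    atomIdList = mmtf_encode_field(seq_len(m * n), 8L)
  )
  if (!is.null(models[[1]]$b_factor))
    doc$bFactorList <- mmtf_encode_field(flat("b_factor"), 10L, 100L)
  if (!is.null(models[[1]]$occupancy))
    doc$occupancyList <- mmtf_encode_field(flat("occupancy"), 9L, 100L)
  if (!is.null(models[[1]]$altloc))
    doc$altLocList <- mmtf_encode_field(flat("altloc"), 6L)
  msgpack_pack(doc)
}

run_starts <- function(v) {
  if (length(v) == 0L) return(list(starts = integer(0), ends = integer(0)))
  changed <- c(TRUE, v[-1] != v[-length(v)])
  starts <- which(changed)
  list(starts = starts, ends = c(starts[-1] - 1L, length(v)))
}

POLYMER_TYPES <- c("PEPTIDE LINKING", "L-PEPTIDE LINKING",
                   "D-PEPTIDE LINKING", "DNA LINKING", "RNA LINKING",
                   "SACCHARIDE", "PEPTIDE-LIKE")

#' @rdname encode_mmtf
#' @param bytes raw vector holding an MMTF document.
#' @export
decode_mmtf <- function(bytes) {
  doc <- msgpack_unpack(bytes)
  need <- c("numAtoms", "numGroups", "numChains", "numModels", "groupList",
            "xCoordList", "yCoordList", "zCoordList", "groupIdList",
            "groupTypeList", "chainIdList", "groupsPerChain",
            "chainsPerModel")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("MMTF document lacks mandatory fields: ",
         paste(missing, collapse = ", "))
  num <- function(f) as.numeric(unlist(doc[[f]]))
  x <- mmtf_decode_field(doc$xCoordList)
  y <- mmtf_decode_field(doc$yCoordList)
  z <- mmtf_decode_field(doc$zCoordList)
  group_type <- mmtf_decode_field(doc$groupTypeList)
  group_id <- mmtf_decode_field(doc$groupIdList)
  chain_ids <- mmtf_decode_field(doc$chainIdList)
  groups_per_chain <- num("groupsPerChain")
  chains_per_model <- num("chainsPerModel")
  groups <- doc$groupList
  b_factor <- if (!is.null(doc$bFactorList))
    mmtf_decode_field(doc$bFactorList)
  occupancy <- if (!is.null(doc$occupancyList))
    mmtf_decode_field(doc$occupancyList)
  altloc <- if (!is.null(doc$altLocList)) mmtf_decode_field(doc$altLocList)

  n_total <- length(x)
  chain_of_group <- rep(seq_along(groups_per_chain), groups_per_chain)
  atoms_per_group <- vapply(group_type, function(g)
    length(groups[[g + 1L]]$atomNameList), numeric(1))
  group_of_atom <- rep(seq_along(group_type), atoms_per_group)
  if (length(group_of_atom) != n_total)
    stop("MMTF: group atom counts do not match coordinate count")

  gi <- group_of_atom
  ann <- list(
    chain_id = chain_ids[chain_of_group[gi]],
    res_id = as.integer(group_id[gi]),
    res_name = vapply(group_type[gi], function(g)
      groups[[g + 1L]]$groupName, character(1)),
    atom_name = unlist(lapply(group_type + 1L, function(g)
      unlist(groups[[g]]$atomNameList))),
    element = unlist(lapply(group_type + 1L, function(g)
      unlist(groups[[g]]$elementList))),
    hetero = vapply(group_type[gi], function(g)
      !(toupper(groups[[g + 1L]]$chemCompType) %in% POLYMER_TYPES),
      logical(1))
  )
  if (!is.null(b_factor)) ann$b_factor <- b_factor
  if (!is.null(occupancy)) ann$occupancy <- occupancy
  if (!is.null(altloc)) ann$altloc <- altloc

  m <- max(1, length(chains_per_model))
  if (m == 1L) {
    return(do.call(atom_array, c(list(coord = cbind(x, y, z)), ann)))
  }
  # split atoms by model via per-model chain/group spans
  model_of_chain <- rep(seq_along(chains_per_model), chains_per_model)
  model_of_atom <- model_of_chain[chain_of_group[gi]]
  per_model <- split(seq_len(n_total), model_of_atom)
  sizes <- vapply(per_model, length, integer(1))
  if (length(unique(sizes)) != 1L)
    stop("MMTF: models differ in atom count; cannot build a stack")
  arrays <- lapply(per_model, function(ix)
    do.call(atom_array, c(list(coord = cbind(x[ix], y[ix], z[ix])),
                          lapply(ann, function(a) a[ix]))))
  stack_atom_arrays(arrays)
}

#' Read / write MMTF files
#' @param path file path.
#' @export
read_mmtf <- function(path) {
  decode_mmtf(readBin(path, "raw", file.size(path)))
}

#' @rdname read_mmtf
#' @param x atom array or stack.
#' @export
write_mmtf <- function(x, path) {
  writeBin(encode_mmtf(x), path)
  invisible(path)
}
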