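# structure_io: coordinate file handling, the in-memory structure
# container, the domain-architecture map and residue-numbering schemes.
#
# A structure is stored as a flat atom table (one row per atom) in the
# style of bio3d's pdb$atom, wrapped in an S3 class carrying the model
# identity and the physiologic condition the coordinates represent
# ("extracellular" vs "endosomal" for LDLR).

DOMAIN_CLASSES <- c("classA", "EGF", "classB", "O-linked", "TM", "cytoplasmic")

#' Construct a structure object from an atom table
#'
#' @param id character model identifier
#' @param atoms data.frame with columns record ("ATOM"/"HETATM"), atom_name,
#'   element, chain_id, res_name, res_seq, ins_code, x, y, z, occupancy,
#'   b_factor
#' @param condition_label free-text physiologic condition
#'   (e.g. "extracellular", "endosomal")
#' @return an object of class `ldlr_structure`
#' @export
new_structure <- function(id, atoms, condition_label = "") {
  needed <- c("record", "atom_name", "element", "chain_id", "res_name",
              "res_seq", "ins_code", "x", "y", "z", "occupancy", "b_factor")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in atom table")
  atoms$is_hetero <- atoms$record == "HETATM"
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, condition_label = condition_label),
            class = "ldlr_structure")
}

#' @export
print.ldlr_structure <- function(x, ...) {
  res <- structure_residues(x)
  cat(sprintf("<ldlr_structure> %s [%s]: %d residues, %d atoms, %d ion(s)\n",
              x$id, x$condition_label, nrow(res), sum(!x$atoms$is_hetero),
              nrow(structure_ions(x))))
  invisible(x)
}

#' Residue-level view of a structure
#'
#' One row per protein residue, in file order.
#'
#' @param structure an `ldlr_structure`
#' @return data.frame with chain_id, res_seq, ins_code, res_name, aa
#'   (one-letter), n_atoms
#' @export
structure_residues <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  if (!nrow(a)) {
    return(data.frame(chain_id = character(), res_seq = integer(),
                      ins_code = character(), res_name = character(),
                      aa = character(), n_atoms = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(a$chain_id, a$res_seq, a$ins_code)
  first <- !duplicated(key)
  out <- data.frame(chain_id = a$chain_id[first], res_seq = a$res_seq[first],
                    ins_code = a$ins_code[first], res_name = a$res_name[first],
                    stringsAsFactors = FALSE)
  out$aa <- aa3_to_1(out$res_name)
  out$n_atoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
}

#' Hetero ion records of a structure (calcium)
#'
#' @param structure an `ldlr_structure`
#' @return data.frame of ion atoms (element Ca)
#' @export
structure_ions <- function(structure) {
  a <- structure$atoms
  a[a$is_hetero & toupper(a$element) == "CA", , drop = FALSE]
}

#' Read a PDB coordinate file into a structure object
#'
#' Parsing is delegated to [bio3d::read.pdb()]. All `ATOM` records become
#' protein residues (common modified residues are mapped to their parent
#' amino acid); `HETATM` calcium records are collected as ions; alternate
#' locations are resolved to the highest-occupancy conformer (ties broken
#' by altloc label order). Only the first model of multi-model files is
#' used.
#'
#' @param path PDB file path
#' @param condition_label condition tag stored on the structure
#' @return an `ldlr_structure`
#' @export
read_structure <- function(path, condition_label = "") {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!nrow(at)) stop("no coordinate records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(elem)
  elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)
  at$elesy <- toupper(elem)

  # altloc: keep the highest-occupancy conformer per atom position
  key <- paste(at$chain, at$resno, at$insert, at$elety, at$type)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(at$eleno), , drop = FALSE]

  res_name <- toupper(at$resid)
  mapped <- NONSTANDARD_PARENT[res_name]
  res_name[!is.na(mapped)] <- mapped[!is.na(mapped)]
  record <- ifelse(at$type == "ATOM" & is_standard_aa3(res_name),
                   "ATOM", "HETATM")
  if (!any(record == "ATOM"))
    stop("no protein ATOM records in ", path, " (format error)")

  keep <- record == "ATOM" |
    (record == "HETATM" & toupper(at$elesy) == "CA" & at$type == "HETATM")
  atoms <- data.frame(record = record[keep],
                      atom_name = at$elety[keep],
                      element = at$elesy[keep],
                      chain_id = ifelse(is.na(at$chain[keep]), "A", at$chain[keep]),
                      res_name = res_name[keep],
                      res_seq = at$resno[keep],
                      ins_code = at$insert[keep],
                      x = at$x[keep], y = at$y[keep], z = at$z[keep],
                      occupancy = at$o[keep], b_factor = at$b[keep],
                      stringsAsFactors = FALSE)
  new_structure(id = tools::file_path_sans_ext(basename(path)),
                atoms = atoms, condition_label = condition_label)
}

#' Write a structure object to a PDB file
#'
#' Emits ATOM records for protein residues and HETATM records for ions via
#' [bio3d::write.pdb()]. Coordinates survive a round trip to within the PDB
#' fixed-format precision (1e-3 angstrom).
#'
#' @param structure an `ldlr_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$record,
                   resno = a$res_seq, resid = a$res_name,
                   eleno = seq_len(nrow(a)), elety = a$atom_name,
                   chain = a$chain_id, insert = ifelse(nzchar(a$ins_code),
                                                      a$ins_code, NA),
                   o = a$occupancy, b = a$b_factor, elesy = a$element)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Domain map

#' Construct and validate a domain-architecture map
#'
#' Encodes the modular architecture of the receptor (seven cysteine-rich
#' class-A repeats, EGF-like domains, the class-B beta-propeller, the
#' O-linked sugar region, transmembrane and cytoplasmic segments) as
#' inclusive 1-based precursor-coordinate spans.
#'
#' @param entries data.frame with columns domain_name, class, start, end
#' @param numbering_offset signal-peptide length used for legacy-mature to
#'   precursor conversion (21 for LDLR P01130-1)
#' @return an object of class `ldlr_domain_map` (a validated data.frame)
#' @export
domain_map <- function(entries, numbering_offset = 21L) {
  needed <- c("domain_name", "class", "start", "end")
  if (!all(needed %in% names(entries)))
    stop("domain map needs columns: ", paste(needed, collapse = ", "))
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (any(is.na(entries$start) | is.na(entries$end)))
    stop("non-integer domain span")
  if (any(entries$start > entries$end))
    stop("domain span with start > end: ",
         paste(entries$domain_name[entries$start > entries$end], collapse = ", "))
  bad_class <- setdiff(unique(entries$class), DOMAIN_CLASSES)
  if (length(bad_class))
    stop("unknown domain class label(s): ", paste(bad_class, collapse = ", "))
  for (cl in unique(entries$class)) {
    e <- entries[entries$class == cl, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop("overlapping entries within class track: ", cl)
  }
  span <- entries$end - entries$start + 1L
  odd <- entries$class == "classA" & (span < 30 | span > 50)
  if (any(odd))
    warning("class-A entries with atypical span (expected ~40 aa): ",
            paste(entries$domain_name[odd], collapse = ", "))
  entries <- entries[order(entries$start), , drop = FALSE]
  rownames(entries) <- NULL
  attr(entries, "numbering_offset") <- as.integer(numbering_offset)
  class(entries) <- c("ldlr_domain_map", "data.frame")
  entries
}

#' Load a domain map from a tab-delimited file
#'
#' @param path TSV with header domain_name, class, start, end; lines starting
#'   with `#` are ignored
#' @param numbering_offset see [domain_map()]
#' @return an `ldlr_domain_map`
#' @export
load_domain_map <- function(path, numbering_offset = 21L) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  domain_map(tab, numbering_offset = numbering_offset)
}

#' Look up the domain containing each position
#'
#' @param position integer vector of precursor positions
#' @param map an `ldlr_domain_map`
#' @param class_filter optional domain class; only entries of that class are
#'   searched
#' @return character vector of domain names (first containing entry), `NA`
#'   for positions outside all entries
#' @export
domain_of <- function(position, map, class_filter = NULL) {
  entries <- map
  if (!is.null(class_filter))
    entries <- entries[entries$class %in% class_filter, , drop = FALSE]
  vapply(position, function(p) {
    hit <- which(entries$start <= p & p <= entries$end)
    if (length(hit)) entries$domain_name[hit[1]] else NA_character_
  }, character(1))
}

#' Convert residue numbering between mature and precursor frames
#'
#' LDLR literature mixes mature-protein numbering (signal peptide removed)
#' with precursor numbering (UniProt P01130-1 frame). The package stores all
#' positions in the precursor frame.
#'
#' @param position integer vector (>= 1)
#' @param direction `"mature_to_precursor"` (adds `offset`) or
#'   `"precursor_to_mature"` (subtracts it)
#' @param offset signal-peptide length (default 21)
#' @return converted integer positions
#' @export
convert_numbering <- function(position,
                              direction = c("mature_to_precursor",
                                            "precursor_to_mature"),
                              offset = 21L) {
  direction <- match.arg(direction)
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L))
    stop("positions must be integers >= 1")
  out <- if (direction == "mature_to_precursor") position + offset
         else position - offset
  if (any(out < 1L))
    stop("converted position below 1 (position precedes the mature start)")
  out
}
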