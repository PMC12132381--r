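#' Construct an atomic model object
#'
#' A thin, typed container for atoms from a PDB/mmCIF structure: one row
#' per atom with element, atom name, residue identity, chain, coordinates
#' (Angstrom) and alternate-location code. Residue identity for fibril
#' work is the (residue_name, residue_number) pair: deposited fibril
#' models repeat the same residue across stacked chains, and coordination
#' is counted over residue identities, not chain copies.
#'
#' @param atoms data.frame with columns `element`, `atom_name`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`,
#'   `alt_loc`, `insert`, `occupancy` (missing optional columns are
#'   filled with defaults).
#' @param source_label free-text provenance label (e.g. "PDB 6xyo").
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms = empty_atoms(), source_label = "") {
  need <- c("element", "atom_name", "residue_name", "residue_number",
            "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"alt_loc" %in% names(atoms)) atoms$alt_loc <- ""
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  atoms$alt_loc[is.na(atoms$alt_loc)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (nrow(atoms)) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
      stop("atom coordinates must be finite")
    }
    key <- paste(atoms$chain_id, atoms$residue_number, atoms$insert,
                 atoms$atom_name, atoms$alt_loc)
    if (anyDuplicated(key)) {
      stop("duplicate (chain, residue, atom, alt_loc) atom records")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_label = source_label),
            class = "atomic_model")
}

empty_atoms <- function() {
  data.frame(element = character(), atom_name = character(),
             residue_name = character(), residue_number = integer(),
             chain_id = character(), x = numeric(), y = numeric(),
             z = numeric(), alt_loc = character(), insert = character(),
             occupancy = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat("atomic_model", if (nzchar(x$source_label)) x$source_label else "",
      "\n  ", nrow(a), " atoms, ",
      length(unique(paste(a$chain_id, a$residue_number, a$insert))),
      " residues, ", length(unique(a$chain_id)), " chains\n", sep = "")
  invisible(x)
}

# nx3 coordinate matrix of a model (or an atom subset data.frame).
atom_xyz <- function(x) {
  a <- if (inherits(x, "atomic_model")) x$atoms else x
  cbind(a$x, a$y, a$z)
}

element_from_name <- function(atom_name) {
  el <- sub("^([0-9 ]*)([A-Za-z]).*$", "\\2", atom_name)
  toupper(el)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Wraps bio3d's parsers and normalizes the result: every ATOM/HETATM
#' record becomes one atom row; when alternate locations are present only
#' the highest-occupancy conformer of each atom is kept (with a message);
#' insertion codes are kept in a separate column so that inserted residues
#' remain distinguishable. Residue names not covered by the polarity
#' taxonomy are accepted and simply classed "unknown" downstream.
#'
#' @param path file path; format chosen by extension (`.cif`/`.mmcif`
#'   versus PDB) unless `format` is given.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return An [atomic_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "cif"
    } else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path, rm.alt = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE),
    error = function(e) e)
  if (inherits(parsed, "error")) {
    # an empty model (no coordinate records) is valid input
    txt <- readLines(path, warn = FALSE)
    if (!any(grepl("^(ATOM|HETATM)", txt))) {
      return(atomic_model(empty_atoms(), source_label = basename(path)))
    }
    stop("failed to parse ", path, ": ", conditionMessage(parsed))
  }
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) {
    return(atomic_model(empty_atoms(), source_label = basename(path)))
  }
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    stop("model has missing or non-finite coordinates: ", path)
  }
  alt <- a$alt
  alt[is.na(alt)] <- ""
  ins <- a$insert
  ins[is.na(ins)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- element_from_name(a$elety[bad])
  atoms <- data.frame(element = trimws(toupper(elem)),
                      atom_name = trimws(a$elety),
                      residue_name = trimws(a$resid),
                      residue_number = as.integer(a$resno),
                      chain_id = ifelse(is.na(a$chain), "", a$chain),
                      x = a$x, y = a$y, z = a$z,
                      alt_loc = trimws(alt), insert = trimws(ins),
                      occupancy = occ, stringsAsFactors = FALSE)
  # collapse alternate locations: keep the highest-occupancy conformer
  if (any(nzchar(atoms$alt_loc))) {
    key <- paste(atoms$chain_id, atoms$residue_number, atoms$insert,
                 atoms$atom_name)
    ord <- order(key, -atoms$occupancy,  atoms$alt_loc)
    atoms <- atoms[ord, ]
    dup <- duplicated(paste(atoms$chain_id, atoms$residue_number,
                            atoms$insert, atoms$atom_name))
    if (any(dup)) {
      message("read_model: dropped ", sum(dup),
              " alternate-location atom(s), keeping highest occupancy")
      atoms <- atoms[!dup, ]
    }
    atoms$alt_loc <- ""
    atoms <- atoms[order(atoms$chain_id, atoms$residue_number,
                         atoms$insert, atoms$atom_name), ]
  }
  atomic_model(atoms, source_label = basename(path))
}

#' Write an atomic model to a PDB file
#'
#' @param model an [atomic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  if (nrow(a) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(atom_xyz(a))),
                   resno = a$residue_number,
                   resid = a$residue_name,
                   eleno = seq_len(nrow(a)),
                   elety = a$atom_name,
                   chain = a$chain_id,
                   insert = ifelse(nzchar(a$insert), a$insert, NA),
                   o = a$occupancy,
                   elesy = a$element)
  invisible(path)
}

# Subset helper: atoms of a model matching predicates.
select_atoms <- function(model, atom_name = NULL, residue_name = NULL,
                         residue_number = NULL, chain_id = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (!is.null(residue_name)) keep <- keep & a$residue_name %in% residue_name
  if (!is.null(residue_number)) {
    keep <- keep & a$residue_number %in% residue_number
  }
  if (!is.null(chain_id)) keep <- keep & a$chain_id %in% chain_id
  a[keep, , drop = FALSE]
}
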