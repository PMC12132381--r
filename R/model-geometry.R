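#' Van der Waals radii table
#'
#' @param path optional path to an alternative radii JSON.
#' @return named numeric vector of radii (Angstrom) by element symbol.
#' @export
vdw_radii <- function(path = NULL) {
  path <- path %||% system.file("extdata", "vdw_radii.json",
                                package = "lcedscan")
  unlist(jsonlite::read_json(path, simplifyVector = TRUE)$radii)
}

#' Ideal covalent geometry dictionary
#'
#' @param path optional path to an alternative dictionary JSON.
#' @return list with `bonds` and `angles` entries keyed by sorted
#'   element composition (e.g. `"C-C"`, `"C-C-O"` with the vertex
#'   element in the middle).
#' @export
geometry_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "geometry_dictionary.json",
                                package = "lcedscan")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Distance-based covalent bond inference: atoms i, j are bonded when
# d < 0.55 * (0.6 + r_i + r_j), a scaled van der Waals heuristic that
# accepts covalent bonds (C-C 1.53 < 2.2) while excluding 1-3 ring
# diagonals (~2.35 in a furanose). Returns a 2-column index matrix.
infer_bonds <- function(model, radii = vdw_radii()) {
  a <- model$atoms
  n <- nrow(a)
  if (n < 2L) return(matrix(integer(), 0, 2))
  heavy <- a$element != "H"
  xyz <- atom_xyz(a)
  r <- radii[a$element]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(a$element[is.na(r)]), collapse = ", "))
  }
  out <- list()
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    cutoff <- 0.55 * (0.6 + r[i] + r[j])
    hit <- j[d < cutoff & d > 1e-6]
    if (length(hit)) out[[length(out) + 1L]] <- cbind(i, hit)
  }
  bonds <- if (length(out)) do.call(rbind, out) else matrix(integer(), 0, 2)
  attr(bonds, "heavy") <- heavy
  bonds
}

#' Clash score of an atomic model
#'
#' Counts nonbonded heavy-atom pairs whose van der Waals envelopes
#' overlap by at least `overlap_threshold` (default 0.4 Angstrom) and
#' reports the count per 1000 atoms. Covalent bonds are inferred by
#' distance; bonded (1-2) and angle (1-3) pairs are excluded. Hydrogens
#' are not placed, so the score is a heavy-atom approximation: a model
#' with score zero is clash-free at the heavy-atom level.
#'
#' @param model an [atomic_model()].
#' @param radii element radii (Angstrom); see [vdw_radii()].
#' @param overlap_threshold minimum vdW overlap counted as a clash.
#' @return list with `clash_count`, `clash_score` (per 1000 atoms),
#'   `clashes` (data.frame of offending pairs) and `n_atoms`.
#' @export
clash_score <- function(model, radii = vdw_radii(),
                        overlap_threshold = 0.4) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  n <- nrow(a)
  if (n == 0L) {
    return(list(clash_count = 0L, clash_score = 0, clashes = NULL,
                n_atoms = 0L))
  }
  r <- radii[a$element]
  if (anyNA(r)) {
    stop("unknown element(s): ",
         paste(unique(a$element[is.na(r)]), collapse = ", "))
  }
  bonds <- infer_bonds(model, radii)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, as.vector(t(bonds)))
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  # exclude 1-2 and 1-3 pairs
  excl <- adj + adj %*% adj
  xyz <- atom_xyz(a)
  heavy <- which(a$element != "H")
  clashes <- list()
  for (ii in seq_along(heavy)) {
    i <- heavy[ii]
    if (ii == length(heavy)) break
    j <- heavy[(ii + 1L):length(heavy)]
    d <- sqrt(colSums((t(xyz[j, , drop = FALSE]) - xyz[i, ])^2))
    overlap <- (r[i] + r[j]) - d
    hit <- which(overlap >= overlap_threshold)
    for (h in hit) {
      jj <- j[h]
      if (excl[i, jj] > 0) next
      clashes[[length(clashes) + 1L]] <- data.frame(
        i = i, j = jj,
        atom_i = paste0(a$residue_name[i], a$residue_number[i], ":",
                        a$atom_name[i]),
        atom_j = paste0(a$residue_name[jj], a$residue_number[jj], ":",
                        a$atom_name[jj]),
        distance = d[h], overlap = overlap[h])
    }
  }
  clashes <- if (length(clashes)) do.call(rbind, clashes) else NULL
  cnt <- if (is.null(clashes)) 0L else nrow(clashes)
  list(clash_count = cnt, clash_score = 1000 * cnt / n,
       clashes = clashes, n_atoms = n)
}

#' Bond and angle deviations from ideal geometry
#'
#' Measures every inferred covalent bond and every bonded angle against
#' the geometry dictionary and reports observed, ideal and z-score
#' (dictionary sigma). Bond/angle types missing from the dictionary are
#' skipped with a warning.
#'
#' @param model an [atomic_model()].
#' @param dictionary see [geometry_dictionary()].
#' @param radii element radii used for bond inference.
#' @return list with data.frames `bonds` (atoms, observed, ideal, z) and
#'   `angles`, and `skipped` (types not in the dictionary).
#' @export
bond_geometry <- function(model, dictionary = geometry_dictionary(),
                          radii = vdw_radii()) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  xyz <- atom_xyz(a)
  bonds <- infer_bonds(model, radii)
  skipped <- character()
  bond_rows <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    key <- paste(sort(c(a$element[i], a$element[j])), collapse = "-")
    e <- dictionary$bonds[[key]]
    if (is.null(e)) { skipped <- c(skipped, key); next }
    d <- vec_norm(xyz[j, ] - xyz[i, ])
    bond_rows[[length(bond_rows) + 1L]] <- data.frame(
      atoms = paste(a$atom_name[i], a$atom_name[j], sep = "-"),
      observed = d, ideal = e$ideal, z = (d - e$ideal) / e$sigma)
  }
  nb <- vector("list", nrow(a))
  for (k in seq_len(nrow(bonds))) {
    nb[[bonds[k, 1]]] <- c(nb[[bonds[k, 1]]], bonds[k, 2])
    nb[[bonds[k, 2]]] <- c(nb[[bonds[k, 2]]], bonds[k, 1])
  }
  angle_rows <- list()
  for (v in seq_len(nrow(a))) {
    nbs <- if (v <= length(nb)) nb[[v]] else NULL
    if (length(nbs) < 2L) next
    prs <- utils::combn(sort(nbs), 2)
    for (p in seq_len(ncol(prs))) {
      i <- prs[1, p]; j <- prs[2, p]
      ends <- sort(c(a$element[i], a$element[j]))
      key <- paste(ends[1], a$element[v], ends[2], sep = "-")
      e <- dictionary$angles[[key]]
      if (is.null(e)) { skipped <- c(skipped, key); next }
      ang <- angle_deg(xyz[i, ], xyz[v, ], xyz[j, ])
      angle_rows[[length(angle_rows) + 1L]] <- data.frame(
        atoms = paste(a$atom_name[i], a$atom_name[v], a$atom_name[j],
                      sep = "-"),
        observed = ang, ideal = e$ideal, z = (ang - e$ideal) / e$sigma)
    }
  }
  skipped <- unique(skipped)
  if (length(skipped)) {
    warning("geometry types not in dictionary, skipped: ",
            paste(skipped, collapse = ", "))
  }
  list(bonds = if (length(bond_rows)) do.call(rbind, bond_rows)
       else data.frame(atoms = character(), observed = numeric(),
                       ideal = numeric(), z = numeric()),
       angles = if (length(angle_rows)) do.call(rbind, angle_rows)
       else data.frame(atoms = character(), observed = numeric(),
                       ideal = numeric(), z = numeric()),
       skipped = skipped)
}

.pucker_classes <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo",
                     "C2'-endo", "C3'-exo", "C4'-endo", "O4'-exo",
                     "C1'-endo", "C2'-exo")

#' Ribose sugar pucker from the five furanose ring atoms
#'
#' Computes the five endocyclic torsions nu0..nu4 of the furanose ring
#' (O4'-C1'-C2'-C3'-C4') and derives the pseudorotation phase P and
#' amplitude via the standard relation
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' `amplitude = nu2 / cos P`. The named pucker class is read from
#' 36-degree bins of P (C3'-endo for P in \[0, 36), C2'-endo for
#' \[144, 180), and so on). A planar ring has amplitude zero and an
#' undefined phase (flagged).
#'
#' @param ring an [atomic_model()] (or atom data.frame) containing the
#'   atoms O4', C1', C2', C3', C4' of one ring, or a 5x3 coordinate
#'   matrix in that order.
#' @return list with `phase` (degrees in \[0, 360) or `NA`),
#'   `amplitude` (degrees), `class`, `nu` (the five torsions) and
#'   `planar` flag.
#' @export
sugar_pucker <- function(ring) {
  names_ord <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  if (is.matrix(ring)) {
    if (!all(dim(ring) == c(5, 3))) stop("ring matrix must be 5x3")
    xyz <- ring
  } else {
    a <- if (inherits(ring, "atomic_model")) ring$atoms else ring
    xyz <- matrix(NA_real_, 5, 3)
    for (i in seq_along(names_ord)) {
      hit <- which(a$atom_name == names_ord[i])
      if (length(hit) == 0L) stop("ring atom missing: ", names_ord[i])
      xyz[i, ] <- c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
    }
  }
  ring5 <- function(i) xyz[((i - 1) %% 5) + 1, ]
  # nu_i is the torsion about the bond between ring atoms i+2 and i+3
  # in the standard numbering: nu0 = C4'-O4'-C1'-C2', etc.
  nu <- vapply(0:4, function(i) {
    dihedral_deg(ring5(i + 5), ring5(i + 6), ring5(i + 7), ring5(i + 8))
  }, numeric(1))
  names(nu) <- paste0("nu", 0:4)
  if (max(abs(nu)) < 1e-6) {
    return(list(phase = NA_real_, amplitude = 0, class = "planar",
                nu = nu, planar = TRUE))
  }
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  p <- rad2deg(atan2(num, den)) %% 360
  amp <- abs(nu[3] / cos(deg2rad(p)))
  cls <- .pucker_classes[floor(p / 36) + 1]
  list(phase = as.numeric(p), amplitude = as.numeric(amp), class = cls,
       nu = nu, planar = FALSE)
}

#' Full geometry report of an atomic model
#'
#' Combines [clash_score()], [bond_geometry()] and, for every residue
#' carrying a complete furanose ring, [sugar_pucker()].
#'
#' @param model an [atomic_model()].
#' @param radii,dictionary resource tables.
#' @param overlap_threshold clash overlap threshold, Angstrom.
#' @return object of class `geometry_report`.
#' @export
geometry_report <- function(model, radii = vdw_radii(),
                            dictionary = geometry_dictionary(),
                            overlap_threshold = 0.4) {
  cs <- clash_score(model, radii, overlap_threshold)
  bg <- bond_geometry(model, dictionary, radii)
  a <- model$atoms
  ring_names <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  key <- paste(a$chain_id, a$residue_number, a$insert)
  puckers <- list()
  for (res in unique(key[a$atom_name %in% ring_names])) {
    sub <- a[key == res, , drop = FALSE]
    if (!all(ring_names %in% sub$atom_name)) next
    pk <- sugar_pucker(sub)
    puckers[[length(puckers) + 1L]] <- data.frame(
      residue = paste0(sub$residue_name[1], sub$residue_number[1]),
      chain = sub$chain_id[1], phase = pk$phase,
      amplitude = pk$amplitude, class = pk$class)
  }
  structure(list(clash_count = cs$clash_count,
                 clash_score = cs$clash_score,
                 clashes = cs$clashes,
                 bond_deviations = bg$bonds,
                 angle_deviations = bg$angles,
                 skipped_types = bg$skipped,
                 puckers = if (length(puckers)) do.call(rbind, puckers)
                 else NULL,
                 n_atoms = cs$n_atoms),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf(
    "geometry_report: %d atoms, %d clashes (score %.1f/1000 atoms)\n",
    x$n_atoms, x$clash_count, x$clash_score))
  if (nrow(x$bond_deviations)) {
    cat(sprintf("  bonds: max |z| = %.2f over %d\n",
                max(abs(x$bond_deviations$z)), nrow(x$bond_deviations)))
  }
  if (nrow(x$angle_deviations)) {
    cat(sprintf("  angles: max |z| = %.2f over %d\n",
                max(abs(x$angle_deviations$z)), nrow(x$angle_deviations)))
  }
  if (!is.null(x$puckers)) {
    cat("  sugar puckers:", paste(x$puckers$class, collapse = ", "), "\n")
  }
  invisible(x)
}
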