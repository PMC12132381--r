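#' Hydrogen-bond polarity taxonomy
#'
#' Loads the residue polarity taxonomy shipped with the package (or a
#' user-edited copy): for each residue name, its hydrogen-bonding class
#' (`donor_only`, `mixed`, `acceptor_only`, `nonpolar`) and its side-chain
#' donor and acceptor heavy atoms. Lysine and arginine side chains are
#' pure donors; histidine, the hydroxyl and amide residues are mixed;
#' aspartate and glutamate are pure acceptors. Backbone amide/carbonyl
#' atoms are excluded by default. Nucleotides (A, C, G, U) are included
#' for ligand-model hydrogen-bond analysis. Unknown residue names class
#' as `"unknown"` downstream.
#'
#' @param path optional path to an alternative taxonomy JSON.
#' @return named list of residue entries, class `polarity_taxonomy`.
#' @export
polarity_taxonomy <- function(path = NULL) {
  path <- path %||% system.file("extdata", "polarity_taxonomy.json",
                                package = "lcedscan")
  tx <- jsonlite::read_json(path, simplifyVector = TRUE)$residues
  structure(tx, class = "polarity_taxonomy")
}

.residue_class <- function(taxonomy, residue_name) {
  e <- taxonomy[[residue_name]]
  if (is.null(e)) "unknown" else e$class
}

.polar_atoms <- function(taxonomy, residue_name) {
  e <- taxonomy[[residue_name]]
  if (is.null(e)) return(character())
  unique(c(e$donor_atoms, e$acceptor_atoms))
}

#' Find residues coordinating an extra density
#'
#' A residue coordinates the region when any of its taxonomy donor or
#' acceptor atoms lies within `cutoff` of the region's density surface
#' (voxel centers at or above the contour level). Residue identity is the
#' (residue name, residue number) pair, so the same residue repeated
#' across the stacked chains of a fibril model counts once; the reported
#' distance and atom are those of the closest copy.
#'
#' @param model an [atomic_model()].
#' @param region an `ed_region`.
#' @param cutoff coordination distance cutoff in Angstrom, within
#'   hydrogen-bonding range (2.5 to 6.0).
#' @param taxonomy a [polarity_taxonomy()].
#' @param level contour level (default: the region's extraction level).
#' @return object of class `coordination_set`: data.frame `entries`
#'   (chain, residue_number, residue_name, atom_name, min_distance,
#'   atom coordinates; sorted by residue number) plus the `cutoff` used.
#' @export
find_coordinating_residues <- function(model, region, cutoff = 4.8,
                                       taxonomy = polarity_taxonomy(),
                                       level = NULL) {
  stopifnot(inherits(model, "atomic_model"), inherits(region, "ed_region"))
  if (cutoff < 2.5 || cutoff > 6.0) {
    stop("cutoff must be within hydrogen-bonding range [2.5, 6.0]")
  }
  a <- model$atoms
  keep <- logical(nrow(a))
  for (rn in unique(a$residue_name)) {
    pa <- .polar_atoms(taxonomy, rn)
    if (length(pa)) {
      keep <- keep | (a$residue_name == rn & a$atom_name %in% pa)
    }
  }
  cand <- a[keep, , drop = FALSE]
  empty <- data.frame(chain = character(), residue_number = integer(),
                      residue_name = character(), atom_name = character(),
                      min_distance = numeric(), atom_x = numeric(),
                      atom_y = numeric(), atom_z = numeric())
  if (nrow(cand) == 0L) {
    return(structure(list(entries = empty, cutoff = cutoff),
                     class = "coordination_set"))
  }
  d <- proximity_to_region(cand, region, level = level)
  hit <- d <= cutoff
  if (!any(hit)) {
    return(structure(list(entries = empty, cutoff = cutoff),
                     class = "coordination_set"))
  }
  cand <- cand[hit, , drop = FALSE]
  d <- d[hit]
  id <- paste(cand$residue_name, cand$residue_number)
  best <- tapply(seq_along(d), id, function(ii) ii[which.min(d[ii])])
  best <- as.integer(best)
  entries <- data.frame(chain = cand$chain_id[best],
                        residue_number = cand$residue_number[best],
                        residue_name = cand$residue_name[best],
                        atom_name = cand$atom_name[best],
                        min_distance = d[best],
                        atom_x = cand$x[best], atom_y = cand$y[best],
                        atom_z = cand$z[best])
  entries <- entries[order(entries$residue_number), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, cutoff = cutoff),
            class = "coordination_set")
}

#' @export
print.coordination_set <- function(x, ...) {
  cat("coordination_set (cutoff", x$cutoff, "A):",
      nrow(x$entries), "residues\n")
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Donor/mixed environment code of a coordination set
#'
#' The chemical environment of an extra density is coded `D` (pure
#' donor) when every coordinating residue is donor-only, otherwise `M`
#' (mixed donor and acceptor; acceptor-only residues such as glutamate
#' also land in `M`), together with the count of coordinating residues
#' (reported clamped at 6).
#'
#' @param coordination a `coordination_set` with at least one entry.
#' @param taxonomy a [polarity_taxonomy()].
#' @return object of class `environment_code`: `class` (`"D"`/`"M"`),
#'   `count`, `code` (e.g. `"D2"`), `clamped`.
#' @export
classify_environment <- function(coordination,
                                 taxonomy = polarity_taxonomy()) {
  stopifnot(inherits(coordination, "coordination_set"))
  ent <- coordination$entries
  if (nrow(ent) == 0L) stop("coordination set is empty")
  cls <- vapply(ent$residue_name,
                function(rn) .residue_class(taxonomy, rn), character(1))
  if (all(cls == "nonpolar")) {
    stop("all coordinating residues are nonpolar; check the taxonomy")
  }
  class <- if (all(cls == "donor_only")) "D" else "M"
  n <- nrow(ent)
  count <- min(n, 6L)
  structure(list(class = class, count = count,
                 code = paste0(class, count), clamped = n > 6L),
            class = "environment_code")
}

#' @export
print.environment_code <- function(x, ...) {
  cat("environment_code:", x$code,
      if (x$clamped) "(count clamped at 6)" else "", "\n")
  invisible(x)
}

#' Name an extra density after its map and first coordinating residue
#'
#' Extra densities are named `<EMDB numeric id>-<lowest coordinating
#' residue number>`; for a doublet, the protofilament letter (`a` left,
#' `b` right) is appended. An accession without a numeric id is used
#' verbatim.
#'
#' @param map_accession accession text, e.g. `"EMD-10650"`.
#' @param coordination a nonempty `coordination_set`.
#' @param protofilament optional protofilament letter to append.
#' @return character label, e.g. `"10650-43"`.
#' @export
label_ed <- function(map_accession, coordination, protofilament = NA) {
  stopifnot(inherits(coordination, "coordination_set"))
  ent <- coordination$entries
  if (nrow(ent) == 0L) stop("coordination set is empty")
  m <- regmatches(map_accession, regexpr("[0-9]+", map_accession))
  id <- if (length(m) && nzchar(m)) m else map_accession
  lab <- paste0(id, "-", min(ent$residue_number))
  if (!is.na(protofilament)) lab <- paste0(lab, protofilament)
  lab
}

#' Detect hydrogen bonds between two models (heavy-atom criteria)
#'
#' Reports donor/acceptor heavy-atom pairs compatible with a hydrogen
#' bond under relaxed criteria suited to models without hydrogens:
#' donor-to-acceptor distance at most `2.9 + dist_tol + slack` Angstrom,
#' and the antecedent-donor-acceptor angle at least `90 - (angle_tol -
#' 20)` degrees (the heavy-atom proxy for near-linear D-H...A geometry;
#' donors without a detectable antecedent pass the angle test). Donor
#' atoms are drawn from `model_a`, acceptor atoms from `model_b`,
#' according to the taxonomy.
#'
#' @param model_a donor-side [atomic_model()].
#' @param model_b acceptor-side [atomic_model()].
#' @param dist_tol distance tolerance added to the 2.9 Angstrom ideal.
#' @param angle_tol angle tolerance in degrees.
#' @param slack additional heavy-atom slack on the distance, Angstrom.
#' @param taxonomy a [polarity_taxonomy()].
#' @return data.frame of bonds: donor and acceptor identities, distance,
#'   antecedent-donor-acceptor angle (`NA` when no antecedent).
#' @export
detect_hbonds <- function(model_a, model_b, dist_tol = 0.4,
                          angle_tol = 20, slack = 0.5,
                          taxonomy = polarity_taxonomy()) {
  stopifnot(inherits(model_a, "atomic_model"),
            inherits(model_b, "atomic_model"))
  pick <- function(model, which_set) {
    a <- model$atoms
    keep <- logical(nrow(a))
    for (rn in unique(a$residue_name)) {
      e <- taxonomy[[rn]]
      if (is.null(e)) next
      atoms <- if (which_set == "donor") e$donor_atoms else e$acceptor_atoms
      if (length(atoms)) {
        keep <- keep | (a$residue_name == rn & a$atom_name %in% atoms)
      }
    }
    a[keep, , drop = FALSE]
  }
  donors <- pick(model_a, "donor")
  acceptors <- pick(model_b, "acceptor")
  empty <- data.frame(donor_chain = character(),
                      donor_residue = character(),
                      donor_number = integer(), donor_atom = character(),
                      acceptor_chain = character(),
                      acceptor_residue = character(),
                      acceptor_number = integer(),
                      acceptor_atom = character(),
                      distance = numeric(), angle = numeric())
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(empty)
  max_d <- 2.9 + dist_tol + slack
  min_angle <- 90 - (angle_tol - 20)
  all_a <- model_a$atoms
  axyz <- atom_xyz(all_a)
  out <- list()
  for (i in seq_len(nrow(donors))) {
    dp <- c(donors$x[i], donors$y[i], donors$z[i])
    # antecedent: nearest covalently bonded heavy atom in the same residue
    same <- all_a$chain_id == donors$chain_id[i] &
      all_a$residue_number == donors$residue_number[i] &
      all_a$insert == donors$insert[i] &
      !(all_a$atom_name == donors$atom_name[i])
    ante <- NULL
    if (any(same)) {
      dd <- sqrt(rowSums(sweep(axyz[same, , drop = FALSE], 2, dp)^2))
      if (min(dd) < 1.8) {
        ante <- axyz[same, , drop = FALSE][which.min(dd), ]
      }
    }
    dv <- sweep(atom_xyz(acceptors), 2, dp)
    dist <- sqrt(rowSums(dv^2))
    hit <- which(dist <= max_d & dist > 1e-6)
    for (j in hit) {
      ap <- c(acceptors$x[j], acceptors$y[j], acceptors$z[j])
      ang <- if (is.null(ante)) NA_real_ else angle_deg(ante, dp, ap)
      if (!is.na(ang) && ang < min_angle) next
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = donors$chain_id[i],
        donor_residue = donors$residue_name[i],
        donor_number = donors$residue_number[i],
        donor_atom = donors$atom_name[i],
        acceptor_chain = acceptors$chain_id[j],
        acceptor_residue = acceptors$residue_name[j],
        acceptor_number = acceptors$residue_number[j],
        acceptor_atom = acceptors$atom_name[j],
        distance = dist[j], angle = ang)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
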