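#' Specify a synthetic extra density (ligand rod)
#'
#' Describes one rod-like extra density to be placed in a synthetic
#' fibril: its cross-section code, occupancy/strength scenario, binding
#' pose and the pseudo-lysine NZ positions that coordinate it. The
#' cross-section codes follow the morphology taxonomy: `y` (asymmetric
#' hump-middle-peg triplet), `x` (superposition of a Y and its mirrored
#' pose), `v` (truncated Y without the peg), `b` (bulky duplex of two Y
#' chains plus a bridging density) and `t` (three-fold symmetric).
#'
#' @param code one of `"y"`, `"x"`, `"v"`, `"b"`, `"t"`.
#' @param center in-plane (u, v) offset of the rod axis in Angstrom.
#' @param strength `"strong"`, `"moderate"` or `"weak"`: realized by axial
#'   amplitude modulation so that a strong rod is continuous at the
#'   display level, a moderate one only at sub-display ladder levels, and
#'   a weak one is a stack of uniform per-rung beads.
#' @param occupancy peak amplitude as a fraction of the protein amplitude,
#'   in (0, 1]; `NULL` uses the calibrated default of the strength
#'   scenario.
#' @param pose_rotation in-plane rotation of the cross-section, degrees.
#' @param pose_flip logical; flips the rod end-over-end (hump and peg
#'   swap in-plane and the axial peg offset reverses sign).
#' @param duplex_antiparallel for code `"b"`: run the second chain in the
#'   opposite axial direction.
#' @param coordinating_offsets list of in-plane NZ positions (Angstrom,
#'   relative to `center`); defaults place a lysine pair on the protein
#'   side of the rod within hydrogen-bonding distance of its surface.
#' @param residue_numbers residue numbers of the coordinating lysines.
#' @param rise optional axial repeat of the rod, Angstrom; defaults to the
#'   fibril rise (in-register rod).
#' @return An object of class `lced_spec`.
#' @export
lced_spec <- function(code = c("y", "x", "v", "b", "t"),
                      center = c(0, 0),
                      strength = c("strong", "moderate", "weak"),
                      occupancy = NULL,
                      pose_rotation = 0, pose_flip = FALSE,
                      duplex_antiparallel = FALSE,
                      coordinating_offsets = NULL,
                      residue_numbers = c(43L, 47L),
                      rise = NULL) {
  code <- match.arg(code)
  strength <- match.arg(strength)
  if (!is.null(occupancy) && (occupancy <= 0 || occupancy > 1)) {
    stop("occupancy must be in (0, 1]")
  }
  if (is.null(coordinating_offsets)) {
    coordinating_offsets <- switch(code,
      b = list(c(-7.5, 1.2), c(-7.5, -1.2)),
      t = list(c(-6.4, 1.4), c(-6.4, -1.4)),
      list(c(-4.2, 1.4), c(-4.2, -1.4)))
  }
  structure(list(code = code, center = as.numeric(center),
                 strength = strength, occupancy = occupancy,
                 pose_rotation = pose_rotation, pose_flip = pose_flip,
                 duplex_antiparallel = duplex_antiparallel,
                 coordinating_offsets = coordinating_offsets,
                 residue_numbers = as.integer(residue_numbers),
                 rise = rise),
            class = "lced_spec")
}

# Calibrated axial-width / amplitude pairs realizing the three occupancy
# scenarios against the default display level (0.35 x protein amplitude):
# strong rods stay above it between rungs, moderate rods bridge rungs only
# at the two sub-display ladder levels, weak rods never bridge.
.strength_params <- list(
  strong   = list(sigma_z = 1.6,  occupancy = 0.80),
  moderate = list(sigma_z = 1.3,  occupancy = 0.82),
  weak     = list(sigma_z = 0.9,  occupancy = 0.55))

.default_authors_level <- 0.35
.protein_sigma_z <- 1.7

#' Default protein rung cross-section
#'
#' Five in-plane Gaussian blobs forming a compact protein cross-section
#' offset from the extra-density site, roughly mimicking a segment of a
#' misfolded protein rung.
#'
#' @return data.frame with columns `du`, `dv`, `sigma`, `amp`.
#' @export
default_protein_blobs <- function() {
  data.frame(du = c(-7, -8.5, -8.5, -10, -8.5),
             dv = c(0, 2, -2, 0, 0),
             sigma = 1.1,
             amp = c(1, 1, 1, 1, 0.9))
}

# In-plane blob triplets per cross-section code, before pose transforms.
# Columns: du, dv (A), dz axial offset within the rung (A), sigma
# (in-plane), amp (relative), role.
lced_blob_table <- function(code, duplex_antiparallel = FALSE) {
  y <- data.frame(du = 0, dv = c(2.8, 0, -2.8), dz = c(0, 0, 1.2),
                  sigma = c(1.1, 0.8, 0.7), amp = c(1, 0.85, 0.7),
                  role = c("hump", "middle", "peg"))
  flip <- function(b) { b$dv <- -b$dv; b$dz <- -b$dz; b }
  shift <- function(b, du) { b$du <- b$du + du; b }
  half <- function(b) { b$amp <- b$amp / 2; b }
  switch(code,
    y = y,
    v = y[y$role != "peg", ],
    x = {
      xb <- rbind(half(y), half(flip(y)))
      xb$role <- paste0(xb$role, rep(c("", "2"), each = 3))
      xb
    },
    b = {
      c2 <- if (duplex_antiparallel) flip(y) else y
      out <- rbind(shift(y, -3), shift(c2, 3),
                   data.frame(du = 0, dv = 0, dz = 0, sigma = 1.5,
                              amp = 0.35, role = "bridge"))
      out$role <- paste0(out$role, rep(c(".1", ".2", ""), c(3, 3, 1)))
      out
    },
    t = {
      ang <- deg2rad(c(90, 210, 330))
      rbind(data.frame(du = 0, dv = 0, dz = 0, sigma = 0.8, amp = 0.85,
                       role = "middle"),
            data.frame(du = 2.8 * cos(ang), dv = 2.8 * sin(ang), dz = 0,
                       sigma = 1.1, amp = 0.9,
                       role = paste0("arm", 1:3)))
    },
    stop("unknown cross-section code: ", code))
}

# Realized blob table of one lced spec: pose transforms applied, amplitude
# scaled by occupancy, axial sigma attached.
realize_lced_blobs <- function(ls) {
  b <- lced_blob_table(ls$code, ls$duplex_antiparallel)
  if (isTRUE(ls$pose_flip)) {
    b$dv <- -b$dv
    b$dz <- -b$dz
  }
  if (ls$pose_rotation != 0) {
    xy <- cbind(b$du, b$dv) %*% t(rot2(ls$pose_rotation))
    b$du <- xy[, 1]
    b$dv <- xy[, 2]
  }
  b$du <- b$du + ls$center[1]
  b$dv <- b$dv + ls$center[2]
  sp <- .strength_params[[ls$strength]]
  # normalize so the rod's 3D peak equals the occupancy fraction of the
  # protein amplitude regardless of cross-section code (codes built from
  # superposed half-amplitude chains would otherwise realize a lower
  # occupancy than specified)
  pk <- max(vapply(seq_len(nrow(b)), function(i) {
    d2 <- (b$du - b$du[i])^2 + (b$dv - b$dv[i])^2
    dz2 <- (b$dz - b$dz[i])^2
    sum(b$amp * exp(-d2 / (2 * b$sigma^2) - dz2 / (2 * 1.3^2)))
  }, numeric(1)))
  b$amp <- b$amp / pk * (ls$occupancy %||% sp$occupancy)
  b$sigma_z <- sp$sigma_z
  b
}

#' Specify a synthetic fibril
#'
#' Defines the study conditions of a simulated fibril map: stacked protein
#' rungs at the given rise and twist, zero or more extra-density rods with
#' coordinating pseudo-lysines, and i.i.d. Gaussian map noise. The default
#' geometry (rise 4.8 Angstrom, small negative twist, 20 rungs, 10% noise)
#' mirrors typical deposited fibril maps.
#'
#' @param n_rungs number of protein rungs (>= 3).
#' @param rise axial translation per rung, Angstrom.
#' @param twist rotation per rung about the fibril axis, degrees.
#' @param voxel_size cubic voxel edge, Angstrom; must satisfy the Nyquist
#'   bound `voxel_size <= rise / 2` for repeat recovery.
#' @param protein_blobs data.frame of in-plane protein Gaussian blobs
#'   (`du`, `dv`, `sigma`, `amp`); may have zero rows for ligand-only maps.
#' @param lceds list of [lced_spec()] objects.
#' @param noise_sigma standard deviation of the additive Gaussian noise,
#'   in units of the protein amplitude.
#' @param seed integer seed driving the noise.
#' @param padding Angstrom of empty margin around the structure.
#' @return An object of class `fibril_spec`.
#' @export
fibril_spec <- function(n_rungs = 20L, rise = 4.8, twist = -1.0,
                        voxel_size = 1.0,
                        protein_blobs = default_protein_blobs(),
                        lceds = list(lced_spec("y")),
                        noise_sigma = 0.1, seed = 1L, padding = 4.5) {
  n_rungs <- as.integer(n_rungs)
  if (n_rungs < 3L) stop("n_rungs must be at least 3")
  if (rise <= 0) stop("rise must be positive")
  if (voxel_size > rise / 2) {
    stop("voxel_size exceeds the Nyquist bound rise/2 for repeat recovery")
  }
  if (inherits(lceds, "lced_spec")) lceds <- list(lceds)
  structure(list(n_rungs = n_rungs, rise = rise, twist = twist,
                 voxel_size = voxel_size, protein_blobs = protein_blobs,
                 lceds = lceds, noise_sigma = noise_sigma,
                 seed = as.integer(seed), padding = padding),
            class = "fibril_spec")
}

# Add one 3D separable Gaussian to a grid in place (returns the grid).
.add_gaussian <- function(grid, voxel_size, origin, center, sigma_xy,
                          sigma_z, amp, cut = 4) {
  dims <- dim(grid)
  lo <- center - c(cut * sigma_xy, cut * sigma_xy, cut * sigma_z)
  hi <- center + c(cut * sigma_xy, cut * sigma_xy, cut * sigma_z)
  i0 <- pmax(1L, floor((lo - origin) / voxel_size) + 1L)
  i1 <- pmin(dims, ceiling((hi - origin) / voxel_size) + 1L)
  if (any(i0 > i1)) return(grid)
  ax <- origin[1] + (seq(i0[1], i1[1]) - 1) * voxel_size[1]
  ay <- origin[2] + (seq(i0[2], i1[2]) - 1) * voxel_size[2]
  az <- origin[3] + (seq(i0[3], i1[3]) - 1) * voxel_size[3]
  gx <- exp(-(ax - center[1])^2 / (2 * sigma_xy^2))
  gy <- exp(-(ay - center[2])^2 / (2 * sigma_xy^2))
  gz <- exp(-(az - center[3])^2 / (2 * sigma_z^2))
  blk <- array(outer(as.vector(outer(gx, gy)), gz),
               c(length(gx), length(gy), length(gz)))
  xr <- i0[1]:i1[1]; yr <- i0[2]:i1[2]; zr <- i0[3]:i1[3]
  grid[xr, yr, zr] <- grid[xr, yr, zr] + amp * blk
  grid
}

.chain_pool <- c(LETTERS, 0:9)

#' Generate a synthetic fibril map, model and ground truth
#'
#' Builds the density map (sum of per-rung protein and extra-density
#' Gaussian blobs, rotated by the cumulative twist and translated by the
#' rise, plus seeded Gaussian noise), a pseudo-atomic model (glycine CA
#' markers at the protein blobs and coordinating lysines with NZ at the
#' specified offsets, one chain per rung), and a ground-truth record per
#' extra density for recovery tests. The map's recommended contour level
#' is set so that the protein density is axially continuous.
#'
#' @param spec a [fibril_spec()].
#' @return list with elements `map` ([density_map()]), `model`
#'   ([atomic_model()]), `truth` (data.frame, one row per extra density)
#'   and `spec`.
#' @export
generate_fibril <- function(spec) {
  stopifnot(inherits(spec, "fibril_spec"))
  vs <- rep_len(spec$voxel_size, 3L)
  pb <- spec$protein_blobs
  # realized blob tables and atom offsets determine the grid extent
  lced_tabs <- lapply(spec$lceds, realize_lced_blobs)
  pts <- rbind(
    if (nrow(pb)) cbind(pb$du, pb$dv),
    do.call(rbind, lapply(lced_tabs, function(b) cbind(b$du, b$dv))),
    do.call(rbind, lapply(spec$lceds, function(ls) {
      off <- do.call(rbind, ls$coordinating_offsets)
      if (is.null(off)) return(NULL)
      sweep(off, 2, -ls$center)
    })))
  if (is.null(pts) || nrow(pts) == 0L) stop("spec describes an empty fibril")
  pad <- spec$padding
  rmax <- max(sqrt(rowSums(pts^2)))
  ur <- range(pts[, 1]); vr <- range(pts[, 2])
  # twist sweeps blobs along arcs; pad the in-plane box accordingly
  arc <- min(abs(spec$twist) * (spec$n_rungs - 1), 360)
  if (arc > 1) {
    ur <- c(-rmax, rmax); vr <- c(-rmax, rmax)
  }
  rises <- c(spec$rise, vapply(spec$lceds,
                               function(ls) ls$rise %||% spec$rise,
                               numeric(1)))
  zmax <- (spec$n_rungs - 1) * max(rises)
  # snap the origin to the voxel lattice so blob centers written at
  # round coordinates coincide with voxel centers
  origin <- floor(c(ur[1] - pad, vr[1] - pad, -pad) / vs) * vs
  dims <- ceiling((c(ur[2] + pad, vr[2] + pad, zmax + pad) - origin) / vs) + 1L
  grid <- array(0, dims)
  add_rod <- function(grid, blobs, sigma_z, rise) {
    n_copies <- floor((spec$n_rungs - 1) * spec$rise / rise) + 1L
    for (r in seq_len(n_copies) - 1L) {
      R <- rot2(spec$twist * r)
      for (i in seq_len(nrow(blobs))) {
        ctr2 <- R %*% c(blobs$du[i], blobs$dv[i])
        grid <- .add_gaussian(grid, vs, origin,
                              c(ctr2, r * rise + blobs$dz[i]),
                              blobs$sigma[i], sigma_z, blobs$amp[i])
      }
    }
    grid
  }
  if (nrow(pb)) {
    pbt <- data.frame(du = pb$du, dv = pb$dv, dz = 0, sigma = pb$sigma,
                      amp = pb$amp)
    grid <- add_rod(grid, pbt, .protein_sigma_z, spec$rise)
  }
  for (k in seq_along(spec$lceds)) {
    ls <- spec$lceds[[k]]
    grid <- add_rod(grid, lced_tabs[[k]],
                    .strength_params[[ls$strength]]$sigma_z,
                    ls$rise %||% spec$rise)
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    grid <- grid + stats::rnorm(length(grid), 0, spec$noise_sigma)
  }
  amp_ref <- if (nrow(pb)) max(pb$amp) else 1
  level <- .default_authors_level * amp_ref
  map <- density_map(grid, vs, origin, recommended_level = level,
                     accession_label = sprintf("SYN-%06d", spec$seed))
  # pseudo-atomic model: one chain per rung, extended one virtual rung
  # beyond each end so the model covers the axial tails of the finite
  # blob stack (a real fibril continues past the box)
  rows <- list()
  for (r in (-1L):spec$n_rungs) {
    ch <- .chain_pool[((r + 1L) %% length(.chain_pool)) + 1L]
    R <- rot2(spec$twist * r)
    z <- r * spec$rise
    if (nrow(pb)) {
      ca <- t(R %*% rbind(pb$du, pb$dv))
      rows[[length(rows) + 1L]] <- data.frame(
        element = "C", atom_name = "CA", residue_name = "GLY",
        residue_number = seq_len(nrow(pb)), chain_id = ch,
        x = ca[, 1], y = ca[, 2], z = z,
        alt_loc = "", insert = "", occupancy = 1)
    }
    for (k in seq_along(spec$lceds)) {
      ls <- spec$lceds[[k]]
      for (j in seq_along(ls$coordinating_offsets)) {
        off <- ls$coordinating_offsets[[j]]
        nz2 <- ls$center + off
        d <- vec_norm(off)
        ca2 <- ls$center + off * (d + 2.8) / d
        nz <- R %*% nz2
        ca <- R %*% ca2
        rows[[length(rows) + 1L]] <- data.frame(
          element = c("N", "C"), atom_name = c("NZ", "CA"),
          residue_name = "LYS",
          residue_number = ls$residue_numbers[j], chain_id = ch,
          x = c(nz[1], ca[1]), y = c(nz[2], ca[2]), z = z,
          alt_loc = "", insert = "", occupancy = 1)
      }
    }
  }
  atoms <- if (length(rows)) do.call(rbind, rows) else empty_atoms()
  model <- atomic_model(atoms, source_label = map$accession_label)
  truth <- do.call(rbind, lapply(seq_along(spec$lceds), function(k) {
    ls <- spec$lceds[[k]]
    data.frame(label = paste0("lced", k),
               code = ls$code,
               grade = substr(ls$strength, 1, 1),
               repeat_A = ls$rise %||% spec$rise,
               n_coordinating = length(ls$coordinating_offsets),
               residue_numbers = paste(ls$residue_numbers, collapse = ","),
               pose_rotation = ls$pose_rotation,
               pose_flip = ls$pose_flip,
               duplex = if (ls$code == "b") {
                 if (ls$duplex_antiparallel) "antiparallel" else "parallel"
               } else NA_character_,
               center_u = ls$center[1], center_v = ls$center[2],
               stringsAsFactors = FALSE)
  }))
  list(map = map, model = model, truth = truth, spec = spec)
}

#' Deterministic fixtures for geometry validation
#'
#' Small hand-constructed models used to exercise clash scoring, bond
#' geometry and sugar-pucker analysis: `ideal_chain` is a zig-zag carbon
#' chain with all bonds at 1.53 Angstrom and all angles at 111 degrees;
#' `clashing_pair` is two nonbonded carbons at a 2.8 Angstrom separation
#' (van der Waals overlap 0.6 Angstrom for 1.7 Angstrom radii);
#' `planar_ring` is a flat regular furanose ring (pucker amplitude zero);
#' `puckered_ring` is a furanose ring displaced out of plane to a
#' C3'-endo pucker.
#'
#' @param kind fixture name.
#' @return An [atomic_model()].
#' @export
generate_geometry_fixture <- function(kind = c("ideal_chain",
                                               "clashing_pair",
                                               "planar_ring",
                                               "puckered_ring")) {
  kind <- match.arg(kind)
  ring_names <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  ring_elements <- c("O", "C", "C", "C", "C")
  pent <- function(z) {
    ang <- deg2rad(90 + 72 * (0:4))
    data.frame(element = ring_elements, atom_name = ring_names,
               residue_name = "U", residue_number = 1L, chain_id = "A",
               x = 1.25 * cos(ang), y = 1.25 * sin(ang), z = z,
               alt_loc = "", insert = "", occupancy = 1)
  }
  atoms <- switch(kind,
    ideal_chain = {
      b <- 1.53
      alpha <- deg2rad((180 - 111) / 2)
      n <- 8L
      x <- cumsum(c(0, rep(b * cos(alpha), n - 1)))
      y <- cumsum(c(0, rep_len(c(b * sin(alpha), -b * sin(alpha)), n - 1)))
      data.frame(element = "C", atom_name = paste0("C", seq_len(n)),
                 residue_name = "UNL", residue_number = 1L, chain_id = "A",
                 x = x, y = y, z = 0, alt_loc = "", insert = "",
                 occupancy = 1)
    },
    clashing_pair = data.frame(
      element = "C", atom_name = c("C1", "C2"), residue_name = "UNL",
      residue_number = 1:2, chain_id = "A", x = c(0, 2.8), y = 0, z = 0,
      alt_loc = "", insert = "", occupancy = 1),
    planar_ring = pent(0),
    puckered_ring = {
      # Cremer-Pople out-of-plane displacements tuned to a C3'-endo
      # pucker (pseudorotation phase ~18 degrees)
      j <- 0:4
      pent(0.38 * sqrt(2 / 5) * cos(deg2rad(108) + 4 * pi * j / 5))
    })
  atomic_model(atoms, source_label = paste0("fixture:", kind))
}

#' Write a generated fibril to disk
#'
#' Writes the map (MRC), model (PDB) and ground truth (JSON) of a
#' [generate_fibril()] result into a directory.
#'
#' @param sim result of [generate_fibril()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_fibril <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, "map.mrc"),
             model = file.path(dir, "model.pdb"),
             truth = file.path(dir, "truth.json"))
  write_map(sim$map, paths[["map"]])
  write_model(sim$model, paths[["model"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
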