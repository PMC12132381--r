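# Shared fixtures and independent brute-force oracles for the test suite.
# Simulated fibrils are cached per parameter set: several test files probe
# the same standard conditions.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(code = "y", strength = "strong", flip = FALSE,
                       n_rungs = 12L, noise = 0, seed = 1L, twist = -1.0,
                       rise = 4.8, lced_rise = NULL) {
  key <- paste(code, strength, flip, n_rungs, noise, seed, twist, rise,
               lced_rise %||% "", sep = "|")
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  spec <- fibril_spec(n_rungs = n_rungs, rise = rise, twist = twist,
                      noise_sigma = noise, seed = seed,
                      lceds = list(lced_spec(code, strength = strength,
                                             pose_flip = flip,
                                             rise = lced_rise)))
  sim <- generate_fibril(spec)
  sim$frame <- estimate_fibril_frame(sim$map, estimate_twist = FALSE)
  sim$ladder <- make_contour_ladder(sim$map)
  sim$regions <- extract_extra_density(sim$map, sim$model,
                                       frame = sim$frame)
  .sim_cache[[key]] <- sim
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The region nearest the generator's rod site (extraction may also return
# candidate regions formed by map noise; those grade "none").
main_region <- function(sim) {
  stopifnot(length(sim$regions) > 0)
  d <- vapply(sim$regions, function(r) sqrt(sum(r$centroid_uv^2)),
              numeric(1))
  sim$regions[[which.min(d)]]
}

# Minimal atom data.frame builder.
atoms_df <- function(x, y, z, element = "C", atom_name = "CA",
                     residue_name = "GLY", residue_number = seq_along(x),
                     chain_id = "A") {
  data.frame(element = element, atom_name = atom_name,
             residue_name = residue_name, residue_number = residue_number,
             chain_id = chain_id, x = x, y = y, z = z,
             alt_loc = "", insert = "", occupancy = 1,
             stringsAsFactors = FALSE)
}

# Brute-force zone mask: O(voxels x atoms) all-pairs distance test.
oracle_zone_mask <- function(map, atoms, radius) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  dims <- dim(map$grid)
  out <- array(FALSE, dims)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) {
    for (i in seq_len(dims[1])) {
      p <- map$origin + (c(i, j, k) - 1) * map$voxel_size
      for (a in seq_len(nrow(xyz))) {
        if (sum((p - xyz[a, ])^2) <= radius^2) {
          out[i, j, k] <- TRUE
          break
        }
      }
    }
  }
  out
}

# Brute-force atom-to-region minimum distances.
oracle_proximity <- function(atoms, region, level = NULL) {
  level <- level %||% region$level
  idx <- which(region$mask & region$residual >= level)
  vox <- lcedscan:::map_voxel_coords(region$map, idx)
  hv <- region$map$voxel_size / 2
  vapply(seq_len(nrow(atoms)), function(a) {
    p <- c(atoms$x[a], atoms$y[a], atoms$z[a])
    best <- Inf
    inside <- FALSE
    for (v in seq_len(nrow(vox))) {
      d <- vox[v, ] - p
      if (all(abs(d) <= hv)) inside <- TRUE
      best <- min(best, sqrt(sum(d^2)))
    }
    if (inside) 0 else best
  }, numeric(1))
}

# Brute-force clash enumeration under the same published rules: nonbonded
# heavy-atom pairs (excluding inferred 1-2 and 1-3 paths) with vdW
# overlap >= threshold.
oracle_clashes <- function(model, radii = vdw_radii(), threshold = 0.4) {
  a <- model$atoms
  n <- nrow(a)
  xyz <- cbind(a$x, a$y, a$z)
  r <- radii[a$element]
  bonded <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 0.55 * (0.6 + r[i] + r[j])) bonded[i, j] <- TRUE
  }
  excluded <- bonded
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || excluded[i, j]) next
    for (k in seq_len(n)) {
      if (bonded[i, k] && bonded[k, j]) { excluded[i, j] <- TRUE; break }
    }
  }
  out <- 0L
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$element[i] == "H" || a$element[j] == "H") next
    if (excluded[i, j]) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if ((r[i] + r[j]) - d >= threshold) {
      out <- out + 1L
      pairs[[out]] <- c(i, j)
    }
  }
  list(count = out, pairs = pairs)
}

# Brute-force hydrogen-bond enumeration under the same rules as
# detect_hbonds (donor atoms of model_a vs acceptor atoms of model_b).
oracle_hbonds <- function(model_a, model_b, dist_tol = 0.4,
                          angle_tol = 20, slack = 0.5,
                          taxonomy = polarity_taxonomy()) {
  a <- model_a$atoms
  b <- model_b$atoms
  max_d <- 2.9 + dist_tol + slack
  min_ang <- 90 - (angle_tol - 20)
  hits <- 0L
  for (i in seq_len(nrow(a))) {
    ta <- taxonomy[[a$residue_name[i]]]
    if (is.null(ta) || !(a$atom_name[i] %in% ta$donor_atoms)) next
    dp <- c(a$x[i], a$y[i], a$z[i])
    # antecedent: nearest other atom of the same residue within 1.8 A
    same <- which(a$chain_id == a$chain_id[i] &
                    a$residue_number == a$residue_number[i] &
                    a$atom_name != a$atom_name[i])
    ante <- NULL
    if (length(same)) {
      dd <- vapply(same, function(s) {
        sqrt(sum((c(a$x[s], a$y[s], a$z[s]) - dp)^2))
      }, numeric(1))
      if (min(dd) < 1.8) {
        s <- same[which.min(dd)]
        ante <- c(a$x[s], a$y[s], a$z[s])
      }
    }
    for (j in seq_len(nrow(b))) {
      tb <- taxonomy[[b$residue_name[j]]]
      if (is.null(tb) || !(b$atom_name[j] %in% tb$acceptor_atoms)) next
      ap <- c(b$x[j], b$y[j], b$z[j])
      d <- sqrt(sum((ap - dp)^2))
      if (d > max_d || d < 1e-6) next
      if (!is.null(ante)) {
        v1 <- ante - dp; v2 <- ap - dp
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < min_ang) next
      }
      hits <- hits + 1L
    }
  }
  hits
}

# A bare cross-section object wrapping a pixel image, for classifier
# null tests on synthetic section images.
as_section <- function(img, px = 0.5) {
  n <- nrow(img)
  half <- (n - 1) / 2 * px
  structure(list(img = img, units = list(img), u = seq(-half, half, px),
                 v = seq(-half, half, px), px = px, n_units = 3L,
                 repeat_A = 4.8, max3d = max(img), scale = 1,
                 center_uv = c(0, 0)),
            class = "lced_section")
}

# Region built directly from a grid (value 1 inside features).
region_from_grid <- function(grid, level, voxel = 1, origin = c(0, 0, 0)) {
  m <- density_map(grid, voxel, origin, recommended_level = level)
  lcedscan:::new_ed_region(grid >= level, m, grid, level)
}

hand_records <- function() {
  # 10 extra densities: 6 y, 3 x, 1 b; 5 s, 2 m, 3 w
  data.frame(
    label = sprintf("m%02d-%d", 1:10, 1:10),
    map_accession = rep(c("EMD-1", "EMD-2"), each = 5),
    model_accession = "pdb",
    grade = c("s", "s", "s", "s", "s", "m", "m", "w", "w", "w"),
    morphology = c(rep("y", 6), rep("x", 3), "b"),
    repeat_A = 4.8, env_inner = "D2", env_outer = "D2",
    n_coordinating = 2L, min_proximity = 3.0,
    pose_alignment = "horizontal", pose_flip = "up",
    duplex = NA_character_, protofilament = NA_character_,
    boundary = FALSE, stringsAsFactors = FALSE)
}
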