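test_that("zone masks match the definition voxel by voxel", {
  g <- array(0, c(8, 8, 8))
  m <- density_map(g, 1, c(0, 0, 0))
  # single atom exactly on a voxel center, radius under half a voxel
  a1 <- atoms_df(3, 4, 5)
  zm <- zone_mask(m, a1, radius = 0.4)
  expect_identical(sum(zm), 1L)
  expect_true(zm[4, 5, 6])
  # 5-atom fixture against the brute-force all-pairs oracle
  set.seed(9)
  a5 <- atoms_df(runif(5, 0, 7), runif(5, 0, 7), runif(5, 0, 7))
  zm5 <- zone_mask(m, a5, radius = 2.5)
  expect_identical(unclass(zm5)[seq_along(zm5)],
                   as.vector(oracle_zone_mask(m, a5, 2.5)))
  # radius beyond the grid diagonal covers everything
  expect_true(all(zone_mask(m, a1, radius = 50)))
})

test_that("zone masks grow monotonically with radius", {
  g <- array(0, c(10, 10, 10))
  m <- density_map(g, 1, c(0, 0, 0))
  set.seed(4)
  at <- atoms_df(runif(4, 1, 8), runif(4, 1, 8), runif(4, 1, 8))
  prev <- NULL
  for (r in c(0.5, 1.2, 2.0, 3.5, 5.0)) {
    cur <- zone_mask(m, at, r)
    if (!is.null(prev)) expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("nanodissection recovers the generated rod as one region", {
  sim <- cached_sim(noise = 0)
  expect_length(sim$regions, 1L)
  r <- sim$regions[[1]]
  # oracle: analytic rod voxels above the level, outside the erase zone
  lb <- lcedscan:::realize_lced_blobs(sim$spec$lceds[[1]])
  lsig <- lb$sigma_z[1]
  map <- sim$map
  idx <- seq_along(map$grid)
  co <- lcedscan:::map_voxel_coords(map, idx)
  rod <- numeric(length(idx))
  for (rr in 0:(sim$spec$n_rungs - 1)) {
    R <- lcedscan:::rot2(sim$spec$twist * rr)
    for (i in seq_len(nrow(lb))) {
      ctr <- as.vector(R %*% c(lb$du[i], lb$dv[i]))
      d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2
      dz2 <- (co[, 3] - rr * 4.8 - lb$dz[i])^2
      rod <- rod + lb$amp[i] * exp(-d2 / (2 * lb$sigma[i]^2) -
                                     dz2 / (2 * lsig^2))
    }
  }
  zone <- zone_mask(map, sim$model, 3.0)
  rod_voxels <- rod >= map$recommended_level & !as.vector(zone)
  expect_gte(sum(r$mask[idx[rod_voxels]]) / sum(rod_voxels), 0.95)
  # the region never overlaps the protein zone
  expect_false(any(r$mask & zone))
})

test_that("a model zone covering the whole map leaves nothing to dissect", {
  g <- array(0, c(6, 6, 6))
  g[2:5, 2:5, 2:5] <- 1
  m <- density_map(g, 1, c(0, 0, 0), recommended_level = 0.5)
  mod <- atomic_model(atoms_df(2.5, 2.5, 2.5))
  expect_identical(extract_extra_density(m, mod, protein_radius = 20,
                                         level = 0.5), list())
})

test_that("doublet densities are split left/right with a, b letters", {
  spec <- fibril_spec(n_rungs = 12, noise_sigma = 0, seed = 1,
    lceds = list(lced_spec("y", strength = "strong"),
                 lced_spec("y", strength = "strong", center = c(0, 14),
                           residue_numbers = c(53L, 57L))))
  sim <- generate_fibril(spec)
  fr <- estimate_fibril_frame(sim$map, estimate_twist = FALSE)
  regions <- extract_extra_density(sim$map, sim$model, frame = fr)
  expect_length(regions, 2L)
  expect_identical(vapply(regions, function(r) r$protofilament,
                          character(1)), c("a", "b"))
  # ordered by in-plane coordinate, masks pairwise disjoint
  cu <- vapply(regions, function(r) r$centroid_uv[1], numeric(1))
  cv <- vapply(regions, function(r) r$centroid_uv[2], numeric(1))
  expect_true(cu[1] < cu[2] || (cu[1] == cu[2] && cv[1] < cv[2]))
  expect_false(any(regions[[1]]$mask & regions[[2]]$mask))
})

test_that("a rod reaching the map face is flagged as boundary-touching", {
  g <- array(0, c(12, 12, 24))
  for (k in seq(1, 24, by = 5)) g[6:7, 6:7, k] <- 1
  m <- density_map(g, 1, c(0, 0, 0), recommended_level = 0.5)
  mod <- atomic_model(atoms_df(0, 0, 0))
  regions <- extract_extra_density(m, mod, level = 0.5)
  expect_length(regions, 1L)
  expect_true(regions[[1]]$boundary)
})

test_that("atom-to-region distances match the exhaustive oracle", {
  sim <- cached_sim(noise = 0)
  r <- sim$regions[[1]]
  set.seed(5)
  at <- atoms_df(runif(10, -6, 4), runif(10, -6, 6), runif(10, 5, 40))
  expect_equal(proximity_to_region(at, r), oracle_proximity(at, r))
})

test_that("atoms at a constructed distance from the rod surface read back", {
  # flat-top rod: a 3x3 column of value 1 in z; an atom 3 A off the
  # surface voxel centers
  g <- array(0, c(21, 21, 40))
  g[10:12, 10:12, ] <- 1
  reg <- region_from_grid(g, 0.5)
  # nearest voxel center column at x index 10 -> x = 9; atom at x = 6
  at <- atoms_df(6, 10, 20)
  d <- proximity_to_region(at, reg)
  expect_equal(d, 3, tolerance = 0.5)
  inside <- atoms_df(10, 10, 20)
  expect_identical(proximity_to_region(inside, reg), 0)
})

test_that("proximity is invariant under a joint rigid transformation", {
  g <- array(0, c(16, 16, 30))
  g[7:9, 7:9, seq(2, 30, 5)] <- 1
  at <- atoms_df(c(2, 12), c(8, 3), c(10, 20))
  d0 <- proximity_to_region(at, region_from_grid(g, 0.5))
  # joint translation: shift the map origin and the atoms together
  shift <- c(5, -3, 2)
  m2 <- density_map(g, 1, shift, recommended_level = 0.5)
  reg2 <- lcedscan:::new_ed_region(g >= 0.5, m2, g, 0.5)
  at2 <- at
  at2$x <- at$x + shift[1]; at2$y <- at$y + shift[2]; at2$z <- at$z + shift[3]
  expect_equal(proximity_to_region(at2, reg2), d0)
  # joint 90-degree rotation via axis permutation (z -> x)
  g3 <- aperm(g, c(3, 1, 2))
  m3 <- density_map(g3, 1, c(0, 0, 0), recommended_level = 0.5)
  reg3 <- lcedscan:::new_ed_region(g3 >= 0.5, m3, g3, 0.5)
  at3 <- atoms_df(at$z, at$x, at$y)
  expect_equal(proximity_to_region(at3, reg3), d0)
})

test_that("axial slices of an untwisted fibril superpose near-perfectly", {
  blobs <- data.frame(du = c(0, 2.5, -1.5), dv = c(0, 0.5, 2),
                      sigma = 1.2, amp = c(1, 0.8, 0.9))
  spec <- fibril_spec(n_rungs = 23, twist = 0, noise_sigma = 0,
                      protein_blobs = blobs, lceds = list(), seed = 1)
  sim <- generate_fibril(spec)
  fr <- fibril_frame(c(0, 0, 1), rise = 4.8, twist = 0)
  cs <- compare_slices(sim$map, fr, thickness = 5, spacing = 100)
  expect_gte(min(cs$correlation), 0.99)
  expect_lt(max(abs(cs$rotation)), 1.5)
})

test_that("slice rotation accumulates the helical twist over the spacing", {
  blobs <- data.frame(du = c(0, 2.5, -1.5), dv = c(0, 0.5, 2),
                      sigma = 1.2, amp = c(1, 0.8, 0.9))
  spec <- fibril_spec(n_rungs = 23, twist = -1, noise_sigma = 0,
                      protein_blobs = blobs, lceds = list(), seed = 1)
  sim <- generate_fibril(spec)
  fr <- fibril_frame(c(0, 0, 1), rise = 4.8, twist = -1)
  cs <- compare_slices(sim$map, fr, thickness = 5, spacing = 100)
  # closed form: -1 deg/rung x 100 A / 4.8 A/rung = -20.8 deg
  expect_equal(cs$rotation[1], -1 * 100 / 4.8, tolerance = 1.5)
  expect_gte(cs$correlation[1], 0.95)
})

test_that("pure-noise maps do not fake slice similarity", {
  fr <- fibril_frame(c(0, 0, 1), rise = 4.8, twist = 0)
  cors <- vapply(1:20, function(sd) {
    set.seed(sd)
    g <- array(stats::rnorm(26 * 26 * 110), c(26, 26, 110))
    m <- density_map(g, 1, c(0, 0, 0), recommended_level = 1.5)
    mean(compare_slices(m, fr, 5, 100)$correlation)
  }, numeric(1))
  expect_lt(mean(cors), 0.2)
})

test_that("slice comparison refuses maps shorter than the spacing", {
  sim <- cached_sim(n_rungs = 6)
  fr <- fibril_frame(c(0, 0, 1), rise = 4.8)
  expect_error(compare_slices(sim$map, fr, thickness = 5, spacing = 100),
               "axial extent")
})

test_that("a rod sharing the protein rise is in register; one with its own
           rise is not", {
  sim <- cached_sim(n_rungs = 33)
  r <- main_region(sim)
  reg <- axial_registration(r, sim$map, sim$frame, n_repeats = 30)
  expect_equal(reg$ratio, 1, tolerance = 0.02)
  expect_true(reg$in_register)
  sim2 <- cached_sim(n_rungs = 33, lced_rise = 5.0)
  r2 <- main_region(sim2)
  reg2 <- axial_registration(r2, sim2$map, sim2$frame, n_repeats = 25)
  expect_equal(reg2$ratio, 5.0 / 4.8, tolerance = 0.01)
  expect_false(reg2$in_register)
  expect_error(axial_registration(r, sim$map, sim$frame, n_repeats = 100),
               "repeats")
})
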