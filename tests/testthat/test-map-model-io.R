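test_that("MRC maps round-trip through write and read", {
  set.seed(42)
  g <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  m <- density_map(g, c(1.1, 1.2, 0.9), c(-3, 2, 5),
                   recommended_level = 0.5, accession_label = "SYN-RT")
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, f)
  m2 <- read_map(f)
  # values pass through a float32 file; a second round trip is exact
  expect_lt(max(abs(m2$grid - g)), 1e-6)
  f2 <- withr::local_tempfile(fileext = ".mrc")
  write_map(m2, f2)
  expect_identical(read_map(f2)$grid, m2$grid)
  expect_equal(m2$voxel_size, c(1.1, 1.2, 0.9), tolerance = 1e-6)
  expect_equal(m2$origin, c(-3, 2, 5), tolerance = 1e-6)
  expect_equal(m2$recommended_level, 0.5, tolerance = 1e-6)
})

test_that("permuted-axis MRC files describe the same physical volume", {
  set.seed(7)
  g <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  m <- density_map(g, c(1, 1, 1), c(0, 0, 0))
  fa <- withr::local_tempfile(fileext = ".mrc")
  fb <- withr::local_tempfile(fileext = ".mrc")
  write_map(m, fa, axis_order = c(1, 2, 3))
  write_map(m, fb, axis_order = c(3, 1, 2))
  ma <- read_map(fa)
  mb <- read_map(fb)
  # per-voxel coordinate oracle: same value at the same physical point
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expect_identical(ma$grid[i, j, k], mb$grid[i, j, k])
  }
  expect_identical(ma$voxel_size, mb$voxel_size)
})

test_that("degenerate all-zero maps read back without a contour level", {
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(density_map(array(0, c(4, 4, 4))), f)
  m <- read_map(f)
  expect_identical(range(m$grid), c(0, 0))
  expect_null(m$recommended_level)
})

test_that("malformed map files are rejected", {
  f <- withr::local_tempfile(fileext = ".mrc")
  writeBin(raw(2048), f)
  expect_error(read_map(f), "MRC")
  expect_error(read_map(tempfile()), "no such file")
})

test_that("PDB and mmCIF encodings of a model parse identically", {
  p <- read_model(system.file("extdata", "tripeptide.pdb",
                              package = "lcedscan"))
  cif <- suppressWarnings(
    read_model(system.file("extdata", "tripeptide.cif",
                           package = "lcedscan")))
  expect_identical(nrow(p$atoms), 22L)
  expect_setequal(unique(p$atoms$residue_name), c("LYS", "GLY", "GLU"))
  expect_true(any(p$atoms$atom_name == "NZ" &
                    p$atoms$residue_name == "LYS"))
  key <- function(a) order(a$residue_number, a$atom_name)
  ap <- p$atoms[key(p$atoms), ]
  ac <- cif$atoms[key(cif$atoms), ]
  expect_equal(ap$atom_name, ac$atom_name)
  expect_equal(ap$residue_number, ac$residue_number)
  expect_equal(ap$element, ac$element)
  expect_equal(cbind(ap$x, ap$y, ap$z), cbind(ac$x, ac$y, ac$z),
               tolerance = 1e-6)
})

test_that("an empty model file yields an empty atom table, not an error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  m <- read_model(f)
  expect_identical(nrow(m$atoms), 0L)
})

test_that("alternate locations collapse to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  CA ALYS A   1       0.000   0.000   0.000",
           "  0.40 10.00           C"),
    paste0("ATOM      2  CA BLYS A   1       1.000   0.000   0.000",
           "  0.60 10.00           C"),
    "END"), f)
  expect_message(m <- read_model(f), "alternate")
  expect_identical(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 1.0)
})

test_that("contour ladders bracket the display level with even spacing", {
  l1 <- make_contour_ladder(n_levels = 5, spread = 0.5, level = 1.0)
  expect_equal(l1$levels, c(0.5, 0.75, 1.0, 1.25, 1.5))
  expect_identical(l1$authors_index, 3L)
  l2 <- make_contour_ladder(n_levels = 3, spread = 0.25, level = 2.0)
  expect_equal(l2$levels, c(1.5, 2.0, 2.5))
  expect_error(make_contour_ladder(level = 0), "zero")
  expect_error(make_contour_ladder(level = 1, n_levels = 4), "odd")
  # the display level itself is always a rung of the ladder
  for (lv in c(0.2, 1.7, 9)) {
    ld <- make_contour_ladder(n_levels = 7, spread = 0.3, level = lv)
    expect_true(any(abs(ld$levels - lv) < 1e-12))
  }
})

test_that("maps without a deposited level fall back to a flagged quantile", {
  sim <- cached_sim()
  lv <- fallback_level(sim$map, top_frac = 0.01)
  expect_true(isTRUE(attr(lv, "fallback")))
  expect_equal(mean(sim$map$grid > lv), 0.01, tolerance = 0.005)
})

test_that("the fibril frame recovers axis and rise of a synthetic fibril", {
  sim <- cached_sim(noise = 0)
  fr <- sim$frame
  expect_lt(acos(abs(sum(fr$axis_direction * c(0, 0, 1)))) * 180 / pi, 2)
  expect_lt(abs(fr$rise - 4.8), 0.1)
})

test_that("frame estimation follows a rigid rotation of the map", {
  sim <- cached_sim(noise = 0)
  # 90-degree rotation: permute grid axes so z becomes x
  gp <- aperm(sim$map$grid, c(3, 1, 2))
  mp <- density_map(gp, sim$map$voxel_size, c(0, 0, 0),
                    recommended_level = sim$map$recommended_level)
  frp <- estimate_fibril_frame(mp, estimate_twist = FALSE)
  expect_lt(acos(abs(sum(frp$axis_direction * c(1, 0, 0)))) * 180 / pi, 2)
  # the rise is invariant under the rotation
  expect_lt(abs(frp$rise - sim$frame$rise), 0.05)
})

test_that("an isotropic density cloud is rejected as degenerate", {
  g <- array(0, c(24, 24, 24))
  co <- as.matrix(expand.grid(1:24, 1:24, 1:24))
  d2 <- rowSums((co - 12.5)^2)
  g[co[d2 <= 64, ]] <- 1
  m <- density_map(g, 1, c(0, 0, 0), recommended_level = 0.5)
  expect_error(estimate_fibril_frame(m), "degenerate")
})

test_that("the estimated twist matches the generator's helical twist", {
  sim <- cached_sim(n_rungs = 16)
  fr <- estimate_fibril_frame(sim$map)
  expect_lt(abs(fr$twist - (-1.0)), 0.4)
})
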