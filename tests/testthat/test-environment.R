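test_that("coordination counts follow the distance cutoff", {
  # rod column plus NZ atoms at constructed distances from its surface
  g <- array(0, c(21, 21, 40))
  g[10:12, 10:12, ] <- 1
  reg <- region_from_grid(g, 0.5)
  # surface voxel centers at x = 9 (y,z inside); NZ at 3.0 and 5.5 A
  at <- atoms_df(x = c(6, 6, 3.5), y = c(10, 10, 10), z = c(10, 25, 18),
                 element = "N", atom_name = "NZ", residue_name = "LYS",
                 residue_number = c(317L, 321L, 350L))
  model <- atomic_model(at)
  cs35 <- find_coordinating_residues(model, reg, cutoff = 3.5)
  expect_identical(nrow(cs35$entries), 2L)
  expect_setequal(cs35$entries$residue_number, c(317L, 321L))
  cs48 <- find_coordinating_residues(model, reg, cutoff = 4.8)
  # widening the cutoff only ever adds residues
  expect_identical(nrow(cs48$entries), 2L)
  cs60 <- find_coordinating_residues(model, reg, cutoff = 6.0)
  expect_identical(nrow(cs60$entries), 3L)
  expect_true(all(cs35$entries$residue_number %in%
                    cs60$entries$residue_number))
  expect_error(find_coordinating_residues(model, reg, cutoff = 10),
               "cutoff")
})

test_that("repeated residues across fibril chains count once", {
  sim <- cached_sim()
  cs <- find_coordinating_residues(sim$model, main_region(sim),
                                   cutoff = 4.8)
  # one lysine pair coordinates each rung of the stack
  expect_identical(nrow(cs$entries), 2L)
  expect_setequal(cs$entries$residue_number, c(43L, 47L))
  expect_true(all(cs$entries$min_distance <= 4.8))
})

fake_coordination <- function(residue_names, residue_numbers) {
  structure(list(entries = data.frame(
    chain = "A", residue_number = residue_numbers,
    residue_name = residue_names, atom_name = "X",
    min_distance = seq_along(residue_names),
    atom_x = 0, atom_y = 0, atom_z = 0), cutoff = 4.8),
    class = "coordination_set")
}

test_that("environment codes separate pure-donor from mixed sets", {
  expect_identical(
    classify_environment(fake_coordination(c("LYS", "LYS"),
                                           c(317L, 321L)))$code, "D2")
  expect_identical(
    classify_environment(fake_coordination(c("LYS", "SER"),
                                           c(10L, 11L)))$code, "M2")
  # an acidic residue joining three lysines lands in M; without it, D
  expect_identical(
    classify_environment(fake_coordination(c("LYS", "LYS", "LYS", "GLU"),
                                           c(290L, 294L, 370L, 372L)))$code,
    "M4")
  expect_identical(
    classify_environment(fake_coordination(c("LYS", "LYS", "LYS"),
                                           c(290L, 294L, 370L)))$code, "D3")
})

test_that("environment codes ignore residue order and clamp the count", {
  a <- classify_environment(fake_coordination(c("LYS", "SER", "ARG"),
                                              c(1L, 2L, 3L)))
  b <- classify_environment(fake_coordination(c("ARG", "LYS", "SER"),
                                              c(3L, 1L, 2L)))
  expect_identical(a$code, b$code)
  big <- classify_environment(fake_coordination(rep("LYS", 8), 1:8))
  expect_identical(big$code, "D6")
  expect_true(big$clamped)
})

test_that("with a lysine-only taxonomy every nonempty code is pure donor", {
  tx <- structure(list(LYS = list(class = "donor_only",
                                  donor_atoms = "NZ",
                                  acceptor_atoms = character())),
                  class = "polarity_taxonomy")
  sim <- cached_sim()
  cs <- find_coordinating_residues(sim$model, main_region(sim),
                                   cutoff = 4.8, taxonomy = tx)
  expect_gt(nrow(cs$entries), 0L)
  expect_identical(substr(classify_environment(cs, tx)$code, 1, 1), "D")
})

test_that("a growing cutoff can only move the class from D to M", {
  g <- array(0, c(21, 21, 40))
  g[10:12, 10:12, ] <- 1
  reg <- region_from_grid(g, 0.5)
  set.seed(21)
  for (trial in 1:10) {
    n <- sample(2:5, 1)
    at <- atoms_df(x = runif(n, 3, 7), y = runif(n, 6, 14),
                   z = runif(n, 5, 35),
                   element = "N", atom_name = "NZ",
                   residue_name = sample(c("LYS", "ARG"), n, TRUE),
                   residue_number = seq_len(n) * 10L)
    ser <- atoms_df(x = runif(2, 3, 7), y = runif(2, 6, 14),
                    z = runif(2, 5, 35),
                    element = "O", atom_name = "OG", residue_name = "SER",
                    residue_number = c(100L, 110L))
    model <- atomic_model(rbind(at, ser))
    prev <- NULL
    for (ct in c(2.5, 3.5, 4.8, 6.0)) {
      cs <- find_coordinating_residues(model, reg, cutoff = ct)
      if (nrow(cs$entries) == 0) next
      cls <- classify_environment(cs)$class
      if (!is.null(prev) && prev == "M") expect_identical(cls, "M")
      prev <- cls
    }
  }
})

test_that("extra densities are named by map id and first residue", {
  cs <- fake_coordination(c("LYS", "LYS"), c(43L, 47L))
  expect_identical(label_ed("EMD-10650", cs), "10650-43")
  expect_identical(label_ed("EMD-10650", cs, protofilament = "a"),
                   "10650-43a")
  expect_identical(label_ed("mysample", cs), "mysample-43")
})

test_that("hydrogen bonds obey the relaxed heavy-atom criteria", {
  donor <- atomic_model(atoms_df(
    x = c(0, -1.2), y = c(0, 0.9), z = 0,
    element = c("N", "C"), atom_name = c("NZ", "CE"),
    residue_name = "LYS", residue_number = 1L))
  acc <- function(x) atomic_model(atoms_df(
    x = x, y = 0, z = 0, element = "O", atom_name = "OE1",
    residue_name = "GLN", residue_number = 2L, chain_id = "B"))
  expect_identical(nrow(detect_hbonds(donor, acc(3.1))), 1L)
  expect_identical(nrow(detect_hbonds(donor, acc(4.5))), 0L)
  # an acceptor tucked behind the antecedent fails the angle test
  behind <- atomic_model(atoms_df(
    x = -2.8, y = 2.1, z = 0, element = "O", atom_name = "OE1",
    residue_name = "GLN", residue_number = 2L, chain_id = "B"))
  expect_identical(nrow(detect_hbonds(donor, behind)), 0L)
})

test_that("hydrogen-bond detection matches the exhaustive oracle", {
  set.seed(12)
  n <- 10
  mk <- function(seed_off) {
    set.seed(12 + seed_off)
    resn <- sample(c("LYS", "SER", "GLN", "ASP", "ARG"), n, TRUE)
    atn <- vapply(resn, function(rn) switch(rn, LYS = "NZ", SER = "OG",
                                            GLN = sample(c("NE2", "OE1"), 1),
                                            ASP = "OD1", ARG = "NH1"),
                  character(1))
    atomic_model(atoms_df(
      x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8),
      element = substr(atn, 1, 1), atom_name = atn, residue_name = resn,
      residue_number = seq_len(n)))
  }
  a <- mk(0); b <- mk(1)
  expect_identical(nrow(detect_hbonds(a, b)), oracle_hbonds(a, b))
  expect_identical(nrow(detect_hbonds(b, a)), oracle_hbonds(b, a))
})
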