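# Structure reading, methyl proton building, and geometric primitives

test_that("PDB read-back reproduces hand-written coordinates and applies altloc policy", {
  f <- write_pdb_fixture(c(
    pdb_atom_line(1, "N", "TRP", "A", 59, c(11.104, 22.200, 3.300)),
    pdb_atom_line(2, "CA", "TRP", "A", 59, c(12.000, 21.500, 2.250)),
    pdb_atom_line(3, "C", "TRP", "A", 59, c(13.350, 22.150, 2.000))))
  st <- read_structure(f)
  expect_s3_class(st, "noemix_structure")
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$x, c(11.104, 12.000, 13.350), tolerance = 1e-3)
  expect_equal(st$atoms$elety, c("N", "CA", "C"))

  # dual conformer at occupancies 0.71 / 0.29: highest-occupancy policy keeps A
  f2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "CA", "TRP", "A", 59, c(0, 0, 0)),
    pdb_atom_line(2, "CD1", "TRP", "A", 59, c(1.000, 0, 0), occ = 0.71, alt = "A"),
    pdb_atom_line(3, "CD1", "TRP", "A", 59, c(2.000, 0, 0), occ = 0.29, alt = "B")))
  st2 <- read_structure(f2, altloc = "highest")
  cd1 <- st2$atoms[st2$atoms$elety == "CD1", ]
  expect_equal(nrow(cd1), 1)
  expect_equal(cd1$x, 1.000, tolerance = 1e-3)
  expect_error(read_structure(f2, altloc = "error"), "alternate locations")

  # degenerate input
  fe <- tempfile(fileext = ".pdb"); file.create(fe)
  expect_error(read_structure(fe), "empty")
})

test_that("structure round-trips through PDB text within format precision", {
  sc <- make_scene(seed = 11)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(sc$structure_a, f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), nrow(sc$structure_a$atoms))
  m0 <- as.matrix(sc$structure_a$atoms[, c("x", "y", "z")])
  m1 <- as.matrix(st$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(m0 - m1)), 1e-3 + 1e-9)
})

test_that("ideal methyl protons have textbook geometry and staggered phase", {
  vf <- valine_fragment()
  mg <- build_methyl_protons(vf)
  expect_length(mg, 2)  # CG1 and CG2
  m <- mg[[which(vapply(mg, `[[`, "", "carbon_name") == "CG1")]]
  ch <- sqrt(rowSums(sweep(m$protons, 2, m$carbon)^2))
  expect_equal(ch, rep(1.09, 3), tolerance = 1e-9)
  hh <- as.numeric(dist(m$protons))
  expect_equal(hh, rep(1.780, 3), tolerance = 1e-3)
  # all three H-C-antecedent angles equal the tetrahedral angle
  ang <- apply(m$protons, 1, function(h) {
    u <- h - m$carbon; v <- m$antecedent - m$carbon
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  })
  expect_equal(ang, rep(109.47, 3), tolerance = 1e-4)

  # staggered rotor phase: dihedrals H-CG1-CB-CA at 180 / +-60, and the
  # phase agrees with a brute-force scan minimizing the worst eclipse with
  # all three CB substituents (CA, CG2, and the implicit third position)
  a <- vf$atoms
  CA <- as.numeric(a[a$elety == "CA", c("x", "y", "z")])
  CB <- as.numeric(a[a$elety == "CB", c("x", "y", "z")])
  dih <- sort(abs(apply(m$protons, 1, dihedral, b = m$carbon, c = CB, d = CA)))
  expect_equal(dih, c(60, 60, 180), tolerance = 1e-3)

  sub_az <- c(0, 120, -120)  # CB substituent azimuths in the ideal fragment
  eclipse <- function(phi) {
    haz <- (phi + c(0, 120, 240)) %% 360
    max(vapply(haz, function(h) max(cos((h - sub_az) * pi / 180)), 1))
  }
  grid <- seq(0, 120, by = 0.01)
  phi_star <- grid[which.min(vapply(grid, eclipse, 1))] %% 120
  expect_equal(phi_star, 60, tolerance = 0.01)  # anti phase, as built
})

test_that("methyl building is rotation-equivariant and idempotent via use_explicit", {
  vf <- valine_fragment()
  set.seed(7)
  R <- random_rotation(); tr <- rnorm(3, sd = 5)
  vf_rot <- apply_rigid(vf, R, tr)
  H0 <- build_methyl_protons(vf)[[1]]$protons
  H_rot <- build_methyl_protons(vf_rot)[[1]]$protons
  H0_then_rot <- H0 %*% t(R) + matrix(tr, 3, 3, byrow = TRUE)
  expect_lt(sqrt(mean((H_rot - H0_then_rot)^2)), 1e-9)

  # write built protons into the structure, re-build with use_explicit
  mg <- build_methyl_protons(vf)[[1]]
  hn <- paste0("HG1", 1:3)
  extra <- data.frame(chain = "A", resno = 30L, resid = "VAL", elety = hn,
                      x = mg$protons[, 1], y = mg$protons[, 2],
                      z = mg$protons[, 3], stringsAsFactors = FALSE)
  vf2 <- new_structure(rbind(vf$atoms[, names(extra)], extra), label = "withH")
  mg2 <- build_methyl_protons(vf2, selection = "A:30:CG1", use_explicit = TRUE)[[1]]
  expect_equal(mg2$provenance, "read-from-file")
  expect_lt(max(abs(mg2$protons - mg$protons)), 1e-9)

  # missing antecedent is a topology error naming the residue
  vf3 <- vf; vf3$atoms <- vf3$atoms[vf3$atoms$elety != "CB", ]
  expect_error(build_methyl_protons(vf3), "antecedent")
})

test_that("methyl-probe geometry is symmetric, matches a dot-product oracle, and is rigid-body invariant", {
  vf <- valine_fragment()
  m <- build_methyl_protons(vf, selection = "A:30:CG1")[[1]]
  # probe on the methyl 3-fold axis: equal distances, equal angles
  axis <- (m$carbon - m$antecedent) / sqrt(sum((m$carbon - m$antecedent)^2))
  probe <- m$carbon + 4 * axis
  g <- methyl_probe_geometry(m, probe)
  expect_equal(diff(range(g$r)), 0, tolerance = 1e-9)
  off <- g$theta[upper.tri(g$theta)]
  expect_equal(diff(range(off)), 0, tolerance = 1e-6)
  expect_true(isSymmetric(g$theta))
  expect_equal(diag(g$theta), rep(0, 3))

  # right-angle construction: two points at unit distance, 90 degrees apart
  mg_fake <- m
  mg_fake$protons <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  g2 <- methyl_probe_geometry(mg_fake, c(0, 0, 0))
  expect_equal(g2$theta[1, 2], 90, tolerance = 1e-9)

  # independent acos/dot-product oracle on a toy geometry
  set.seed(21)
  for (rep in 1:20) {
    P <- matrix(rnorm(9, sd = 2), 3, 3) + 4
    probe <- rnorm(3)
    mg_fake$protons <- P
    g3 <- methyl_probe_geometry(mg_fake, probe)
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      u <- P[i, ] - probe; v <- P[j, ] - probe
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      expect_equal(g3$theta[i, j], ang, tolerance = 1e-9)
    }
    # rigid-body invariance of r and theta
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    mg_rot <- mg_fake
    mg_rot$protons <- P %*% t(R) + matrix(tr, 3, 3, byrow = TRUE)
    g4 <- methyl_probe_geometry(mg_rot, as.numeric(R %*% probe + tr))
    expect_lt(max(abs(g4$r - g3$r)), 1e-9)
    expect_lt(max(abs(g4$theta - g3$theta)), 1e-7)
  }
})

test_that("bond vector angle recovers identity, right angles, and the built flip", {
  mk <- function(hpos) {
    new_structure(data.frame(
      chain = "A", resno = c(1L, 2L, 3L, 4L, 59L, 59L),
      resid = c(rep("GLY", 4), "TRP", "TRP"),
      elety = c(rep("CA", 4), "NE1", "HE1"),
      x = c(5, -5, 0, 0, 0, hpos[1]), y = c(0, 0, 5, -5, 0, hpos[2]),
      z = c(0, 0, 0, 3, 0, hpos[3]), stringsAsFactors = FALSE), label = "bv")
  }
  a <- mk(c(0, 0, 1.01))
  expect_equal(bond_vector_angle(a, a, "A:59:HE1"), 0, tolerance = 1e-9)
  b <- mk(c(1.01, 0, 0))  # rotated 90 degrees about y
  expect_equal(bond_vector_angle(a, b, "A:59:HE1"), 90, tolerance = 1e-9)

  # synthetic conformer pair built with a known 83-degree flip; superpose on
  # the undisplaced methyl residues
  sc <- make_scene(seed = 3)
  ref <- sprintf("A:%d:CA", setdiff(10L + seq_len(sc$config$n_methyl), sc$displaced))
  expect_equal(bond_vector_angle(sc$structure_a, sc$structure_b,
                                 sc$probe_sel, ref), 83, tolerance = 0.1)

  # mismatched reference sets are a mapping error
  expect_error(bond_vector_angle(a, b, "A:59:HE1", c("A:1:CA", "A:2:CA", "A:9:CA")),
               "mapping error")
})
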