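test_that("C-H unit vectors and distances are extracted in input order", {
  cf <- conformer(c("C1", "H1", "H2"),
                  coords = rbind(c(0, 0, 0), c(0, 0, 1.09), c(1.09, 0, 0)))
  v <- extractVectors(cf, data.frame(atom_c = c("C1", "C1"),
                                     atom_h = c("H1", "H2")))
  expect_equal(unlist(v[1, c("x", "y", "z")], use.names = FALSE), c(0, 0, 1))
  expect_equal(unlist(v[2, c("x", "y", "z")], use.names = FALSE), c(1, 0, 0))
  expect_equal(v$r, c(1.09, 1.09))
  expect_error(extractVectors(cf, data.frame(atom_c = "C1", atom_h = "H99")),
               "H99", class = "rdcrank_lookup")
  vfix <- extractVectors(cf, data.frame(atom_c = "C1", atom_h = "H1"),
                         effectiveR = 1.10)
  expect_equal(vfix$r, 1.10)
})

test_that("bond vectors are translation-invariant and rotation-covariant", {
  tmpl <- makeTemplate()
  pr <- chPairs(tmpl)
  v0 <- extractVectors(tmpl, pr)
  shifted <- conformer(atomLabels(tmpl), elements = tmpl@elements,
                       coords = sweep(atomCoords(tmpl), 2, c(3, -2, 7), "+"))
  expect_equal(extractVectors(shifted, pr), v0)
  set.seed(21)
  rot <- randomRotation()
  vr <- extractVectors(rotateConformer(tmpl, rot), pr)
  expect_equal(as.matrix(vr[, c("x", "y", "z")]),
               as.matrix(v0[, c("x", "y", "z")]) %*% t(rot),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(vr$r, v0$r, tolerance = 1e-9)
})

test_that("dihedral angles follow the IUPAC sign convention", {
  mk <- function(theta) conformer(paste0("A", 1:4), elements = rep("C", 4),
    coords = rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                   c(cos(theta * pi / 180), sin(theta * pi / 180), 1)))
  expect_equal(dihedralAngle(mk(0), "A1", "A2", "A3", "A4"), 0)
  expect_equal(dihedralAngle(mk(180), "A1", "A2", "A3", "A4"), 180)
  expect_equal(dihedralAngle(mk(60), "A1", "A2", "A3", "A4"), 60,
               tolerance = 1e-6)
  # reversal of the atom path leaves the torsion unchanged; mirroring the
  # coordinates negates it
  set.seed(5)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    cf <- conformer(paste0("A", 1:4), elements = rep("C", 4), coords = p)
    f <- dihedralAngle(cf, "A1", "A2", "A3", "A4")
    b <- dihedralAngle(cf, "A4", "A3", "A2", "A1")
    expect_equal(f, b, tolerance = 1e-9)
    mir <- conformer(paste0("A", 1:4), elements = rep("C", 4),
                     coords = p %*% diag(c(1, 1, -1)))
    m <- dihedralAngle(mir, "A1", "A2", "A3", "A4")
    if (abs(abs(f) - 180) > 1e-6) expect_equal(m, -f, tolerance = 1e-9)
  }
  lin <- conformer(paste0("A", 1:4), elements = rep("C", 4),
                   coords = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2),
                                  c(1, 0, 3)))
  expect_error(dihedralAngle(lin, "A1", "A2", "A3", "A4"),
               class = "rdcrank_undefined_torsion")
})

test_that("dihedral angles agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  set.seed(33)
  for (i in 1:10) {
    p <- matrix(rnorm(12), 4, 3)
    cf <- conformer(paste0("A", 1:4), elements = rep("C", 4), coords = p)
    expect_equal(dihedralAngle(cf, "A1", "A2", "A3", "A4"),
                 bio3d::torsion.xyz(as.vector(t(p))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("fast methyl rotation scales the axial RDC by P2(cos beta)", {
  mkMethyl <- function(beta) {
    b <- beta * pi / 180
    hs <- t(vapply(c(0, 120, 240), function(phi) {
      p <- phi * pi / 180
      1.09 * c(sin(b) * cos(p), sin(b) * sin(p), cos(b))
    }, numeric(3)))
    conformer(c("C0", "C1", "H1", "H2", "H3"),
              elements = c("C", "C", "H", "H", "H"),
              coords = rbind(c(0, 0, -1.5), c(0, 0, 0), hs))
  }
  tet <- methylEffectiveVector(mkMethyl(acos(-1 / 3) * 180 / pi), "C1", "C0")
  expect_equal(tet$scale, -1 / 3, tolerance = 1e-9)
  expect_equal(unlist(tet$vector[, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 1), tolerance = 1e-9)
  expect_equal(methylEffectiveVector(mkMethyl(1e-7), "C1", "C0")$scale, 1,
               tolerance = 1e-9)
  expect_equal(methylEffectiveVector(mkMethyl(90), "C1", "C0")$scale, -1 / 2,
               tolerance = 1e-9)
  expect_error(methylEffectiveVector(mkMethyl(90), "C9", "C0"),
               class = "rdcrank_lookup")
})

test_that("Kabsch superposition undoes a rigid-body motion", {
  tmpl <- makeTemplate()
  set.seed(9)
  rot <- randomRotation()
  moved <- conformer(atomLabels(tmpl), elements = tmpl@elements,
                     coords = sweep(atomCoords(tmpl) %*% t(rot), 2,
                                    c(5, 1, -3), "+"))
  sup <- superposeConformers(list(tmpl, moved))
  expect_equal(atomCoords(sup[[2]]), atomCoords(tmpl), tolerance = 1e-9)
})

test_that("XYZ files round-trip single conformers and trajectories", {
  tmpl <- makeTemplate()
  tmp <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(tmpl, tmp)
  back <- readXYZ(tmp)
  expect_s4_class(back, "Conformer")
  expect_equal(unname(atomCoords(back)), unname(atomCoords(tmpl)),
               tolerance = 1e-8)
  expect_equal(conformerEnergy(back), 0)

  traj <- trajectory(list(tmpl, rotateConformer(tmpl, randomRotation())))
  tmp2 <- withr::local_tempfile(fileext = ".xyz")
  writeXYZ(traj, tmp2)
  back2 <- readXYZ(tmp2)
  expect_s4_class(back2, "Trajectory")
  expect_equal(nFrames(back2), 2L)
  expect_equal(unname(atomCoords(frames(back2)[[2]])),
               unname(atomCoords(frames(traj)[[2]])), tolerance = 1e-8)
})

test_that("SDF atom blocks are read into conformers", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("probe", "  none", "",
               "  3  2  0  0  0  0  0  0  0  0999 V2000",
               paste0("    0.0000    0.0000    0.0000 C   0  0  0  0  0",
                      "  0  0  0  0  0  0  0"),
               paste0("    0.0000    0.0000    1.0900 H   0  0  0  0  0",
                      "  0  0  0  0  0  0  0"),
               paste0("    1.0900    0.0000    0.0000 H   0  0  0  0  0",
                      "  0  0  0  0  0  0  0"),
               "  1  2  1  0  0  0  0", "  1  3  1  0  0  0  0",
               "M  END", "$$$$"), tmp)
  cf <- readSDF(tmp)
  expect_equal(atomLabels(cf), c("C1", "H1", "H2"))
  v <- extractVectors(cf, data.frame(atom_c = "C1", atom_h = "H1"))
  expect_equal(v$r, 1.09, tolerance = 1e-9)
})
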