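test_that("reference builds place substituents per the registry pattern", {
  # axial/equatorial read-out: |z offset from the ring carbon| is large for
  # axial substituents and small for equatorial ones in the reference chair
  dz <- function(xyz, ring_atom, sub_atom) {
    abs(xyz$z[xyz$name == sub_atom] - xyz$z[xyz$name == ring_atom])
  }
  glc <- build_residue("Glc", "beta")
  for (p in list(c("C1", "O1"), c("C2", "O2"), c("C3", "O3"), c("C4", "O4"),
                 c("C5", "C6"))) {
    expect_lt(dz(glc, p[1], p[2]), 0.7)  # all equatorial
  }
  gal <- build_residue("Gal", "beta")
  expect_gt(dz(gal, "C4", "O4"), 0.9)    # C4 hydroxyl axial
  expect_lt(dz(gal, "C3", "O3"), 0.7)

  man <- build_residue("Man", "alpha")
  expect_gt(dz(man, "C2", "O2"), 0.9)    # C2 hydroxyl axial
  expect_gt(dz(man, "C1", "O1"), 0.9)    # alpha anomeric axial

  # the alpha/beta builds differ exactly at the anomeric oxygen
  glc_a <- build_residue("Glc", "alpha")
  expect_gt(dz(glc_a, "C1", "O1"), 0.9)
  same <- setdiff(glc$name, "O1")
  expect_equal(glc[glc$name %in% same, c("x", "y", "z")],
               glc_a[glc_a$name %in% same, c("x", "y", "z")])
})

test_that("boat and envelope builds show the expected displaced atoms", {
  # 3,OB boat: ring order (O5, C1, ..., C5); O5 and C3 above the plane of
  # the other four
  ring <- build_ring(6, 0.76, 90, 0)
  z <- ring[, 3]
  expect_true(all(z[c(1, 4)] > 0.2))
  expect_true(all(z[c(2, 3, 5, 6)] < 0))

  # furanose envelope at phi = 90
  r5 <- build_ring(5, 0.35, phi = 90)
  cp <- cremer_pople(r5)
  expect_equal(cp$Q, 0.35, tolerance = 1e-9)
  expect_equal(cp$phi, 90, tolerance = 1e-6)
})

test_that("assembled glycans are clean and geometrically bonded", {
  for (nm in c("LNnT", "G2S2", "coreM3")) {
    g <- template_glycan(nm)
    m <- build_glycan_coords(g)
    expect_identical(nrow(check_stereocenters(m, g)$findings), 0L,
                     label = paste("clean", nm))
    b <- infer_bonds(m)
    inter <- b[b$residue1 != b$residue2, , drop = FALSE]
    expect_identical(nrow(inter), length(g$linkages))
    expect_equal(unname(inter$dist), rep(1.43, nrow(inter)), tolerance = 1e-6)
  }
  # ribitol segment in core M3: placed, no ring, no pucker
  gm3 <- template_glycan("coreM3")
  sugars <- vapply(gm3$residues, `[[`, "", "sugar_name")
  ribo <- which(sugars == "Rib-ol")
  m3 <- build_glycan_coords(gm3)
  rep <- check_stereocenters(m3, gm3)
  expect_null(rep$entries[[ribo]]$pucker)
})

test_that("each corruption class injects exactly one detected defect", {
  g <- parse_iupac_condensed("Neu5Aca2-3Galb1-3GalNAca")
  m <- build_glycan_coords(g)
  expect_identical(nrow(check_stereocenters(m, g)$findings), 0L)

  cases <- list(
    list(residue = 2, class = "epimer-flip", center = "C4"),
    list(residue = 2, class = "epimer-flip", center = "C2"),
    list(residue = 3, class = "anomer-flip"),
    list(residue = 3, class = "retain-leaving-oxygen"))
  for (spec in cases) {
    f <- check_stereocenters(corrupt(m, spec), g)$findings
    expect_identical(nrow(f), 1L,
                     label = paste(spec$class, spec$residue,
                                   if (is.null(spec$center)) "" else spec$center))
    expect_identical(f$residue, as.integer(spec$residue))
  }

  # ring flatten is visible in the pucker report
  flat <- corrupt(m, list(residue = 2, class = "ring-flatten"))
  expect_identical(check_stereocenters(flat, g)$entries[[2]]$pucker$conformer,
                   "planar")

  expect_error(corrupt(m, list(residue = 1, class = "retain-leaving-oxygen")),
               "root")
  expect_error(corrupt(m, list(residue = 2, class = "no-such-class")),
               "unknown corruption class")
  expect_error(corrupt(m, list(residue = 9, class = "anomer-flip")),
               "does not exist")
  plain <- structure_model(m$atoms)
  expect_error(corrupt(plain, list(residue = 2, class = "anomer-flip")),
               "build_glycan_coords")
})

test_that("seeded generation is reproducible", {
  g <- template_glycan("G2")
  m1 <- build_glycan_coords(g)
  m2 <- build_glycan_coords(g)
  expect_identical(m1$atoms, m2$atoms)
  expect_identical(write_structure_mmcif(m1), write_structure_mmcif(m2))
})
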