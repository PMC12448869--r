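test_that("bond inference matches known connectivity", {
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue("Glc", "beta"))
  m <- build_glycan_coords(g)
  b <- infer_bonds(m)
  expect_identical(nrow(b), 12L)  # 6 ring + O1..O4, C6, O6

  far <- structure_model(data.frame(
    entity = "X", residue = 1L, code = "UNK", atom = c("O1", "O2"),
    element = "O", x = c(0, 5), y = 0, z = 0))
  expect_identical(nrow(infer_bonds(far)), 0L)

  lac <- build_glycan_coords(parse_iupac_condensed("Galb1-4Glc"))
  bl <- infer_bonds(lac)
  inter <- bl[bl$residue1 != bl$residue2, , drop = FALSE]
  expect_identical(nrow(inter), 1L)
  expect_setequal(c(inter$atom1, inter$atom2), c("O4", "C1"))
})

test_that("ring perception orders the cycle oxygen-first toward C1", {
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue("Man", "alpha"))
  m <- build_glycan_coords(g)
  ring <- perceive_ring(m, "NG", 1)
  expect_identical(ring, c("O5", "C1", "C2", "C3", "C4", "C5"))

  gf <- glycan_graph()
  gf <- add_residue(gf, monosaccharide_residue("Galf", "beta"))
  mf <- build_glycan_coords(gf)
  expect_identical(perceive_ring(mf, "NG", 1), c("O4", "C1", "C2", "C3", "C4"))

  # sialic ring starts at O6 and proceeds to the anomeric C2
  gs <- glycan_graph()
  gs <- add_residue(gs, monosaccharide_residue("Neu5Ac", "alpha"))
  ms <- build_glycan_coords(gs)
  expect_identical(perceive_ring(ms, "NG", 1)[1:2], c("O6", "C2"))

  # open-chain ribitol: indeterminate, skipped by pucker analysis
  gr <- glycan_graph()
  gr <- add_residue(gr, monosaccharide_residue("Rib-ol"))
  mr <- build_glycan_coords(gr)
  expect_null(perceive_ring(mr, "NG", 1))
  rep <- check_stereocenters(mr, gr)
  expect_identical(rep$entries[[1]]$anomeric_verdict, "not-applicable")
})

test_that("stereocenter checks reproduce the catalogued error classes", {
  g <- parse_iupac_condensed("Galb1-4GlcNAcb1-3Galb1-4Glc")
  m <- build_glycan_coords(g)
  expect_identical(nrow(check_stereocenters(m, g)$findings), 0L)

  # the Gal residue mis-modeled as Glc: C4 hydroxyl axial -> equatorial
  m_epi <- corrupt(m, list(residue = 2, class = "epimer-flip", center = "C4"))
  f <- check_stereocenters(m_epi, g)$findings
  expect_identical(nrow(f), 1L)
  expect_identical(f$residue, 2L)
  expect_identical(f$center, "C4")
  expect_identical(f$category, "epimer-flip")

  # an alpha- instead of beta-linkage
  m_ano <- corrupt(m, list(residue = 2, class = "anomer-flip"))
  rep <- check_stereocenters(m_ano, g)
  expect_identical(rep$entries[[2]]$anomeric_verdict, "flipped")
  expect_identical(nrow(rep$findings), 1L)

  # missing atoms give indeterminate, not an error
  m_missing <- m
  m_missing$atoms <- m_missing$atoms[!(m_missing$atoms$residue == 3 &
                                         m_missing$atoms$atom == "O5"), ]
  rep2 <- check_stereocenters(m_missing, g)
  expect_identical(rep2$entries[[3]]$anomeric_verdict, "indeterminate")
})

test_that("valence checks flag retained leaving oxygens", {
  lac <- parse_iupac_condensed("Galb1-4Glc")
  m <- build_glycan_coords(lac)
  expect_identical(nrow(check_valence(m)), 0L)

  m_keep <- corrupt(m, list(residue = 2, class = "retain-leaving-oxygen"))
  v <- check_valence(m_keep)
  expect_true("retained-leaving-oxygen" %in% v$flag)
  expect_true(any(v$atom == "C1" & v$residue == 2))

  # retained O2 at a sialyl junction flags C2
  sial <- parse_iupac_condensed("Neu5Aca2-6Gal")
  ms <- corrupt(build_glycan_coords(sial),
                list(residue = 2, class = "retain-leaving-oxygen"))
  vs <- check_valence(ms)
  expect_true(any(vs$atom == "C2" & vs$flag == "retained-leaving-oxygen"))
  f <- check_stereocenters(ms, sial)$findings
  expect_identical(nrow(f), 1L)
  expect_identical(f$center, "C2")
})

test_that("dihedral geometry is recovered from constructed coordinates", {
  # four points built with a known torsion angle
  make_dihedral <- function(ang_deg) {
    p1 <- c(1, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1.5, 0, 0)
    r <- ang_deg * pi / 180
    p4 <- p3 + c(0.5, cos(r), sin(r))
    glycobap:::.dihedral(p1, p2, p3, p4)
  }
  for (ang in c(-179, -120, -60, 0.5, 60, 120, 180)) {
    got <- make_dihedral(ang)
    # p1 sits at torsion 0 reference; angle measured relative to it
    expect_equal(got, if (ang == 180) 180 else ang, tolerance = 1e-6)
  }

  # omega present for 1->6, absent for 1->4
  g6 <- parse_iupac_condensed("Gala1-6Glc")
  m6 <- build_glycan_coords(g6)
  t6 <- glycosidic_torsions(m6, g6, g6$linkages[[1]])
  expect_false(is.null(t6$phi))
  expect_false(is.null(t6$psi))
  expect_false(is.null(t6$omega))
  expect_true(t6$phi > -180 && t6$phi <= 180)

  g4 <- parse_iupac_condensed("Galb1-4Glc")
  m4 <- build_glycan_coords(g4)
  t4 <- glycosidic_torsions(m4, g4, g4$linkages[[1]])
  expect_null(t4$omega)
})

test_that("confidence extraction passes values through with summaries", {
  g <- parse_iupac_condensed("Galb1-4Glc")
  m_const <- build_glycan_coords(g, confidence = 90)
  cc <- extract_confidence(m_const)
  expect_equal(cc$mean, 90)
  expect_equal(cc$min, 90)

  m_grad <- build_glycan_coords(template_glycan("LNnT"),
                                confidence = "gradient")
  cg <- extract_confidence(m_grad)
  terminal <- max(m_grad$atoms$residue)
  expect_identical(unique(cg$values$residue[cg$values$confidence == cg$min]),
                   terminal)

  empty <- extract_confidence(m_const, entity = "NOPE")
  expect_identical(nrow(empty$values), 0L)
  expect_true(is.na(empty$mean))

  m_na <- m_const
  m_na$atoms$confidence <- NA_real_
  expect_warning(extract_confidence(m_na), "no confidence")
})

test_that("structure files round-trip in both formats", {
  m <- build_glycan_coords(template_glycan("LNnT"), confidence = 77.5)
  cif <- write_structure_mmcif(m)
  pdb <- write_structure_pdb(m)
  m_cif <- read_structure(cif)
  m_pdb <- read_structure(pdb)
  expect_identical(nrow(m_cif$atoms), nrow(m$atoms))
  expect_identical(m_cif$atoms$atom, m$atoms$atom)
  expect_equal(m_cif$atoms$x, m$atoms$x, tolerance = 2e-3)
  expect_equal(m_cif$atoms$confidence, rep(77.5, nrow(m$atoms)))
  # both formats agree within format precision
  expect_equal(m_pdb$atoms$x, m_cif$atoms$x, tolerance = 2e-3)
  expect_identical(m_pdb$atoms$atom, m_cif$atoms$atom)

  f <- tempfile(fileext = ".cif")
  on.exit(unlink(f), add = TRUE)
  write_structure_mmcif(m, path = f)
  expect_identical(read_structure(f)$atoms$atom, m$atoms$atom)

  expect_error(read_structure("not a structure at all"), "ATOM|atom_site")
})
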