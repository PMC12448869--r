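test_that("residues are appended with stable indices and validated fields", {
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue("Glc", "beta"))
  expect_identical(attr(g, "index"), 1L)
  expect_identical(g$root_index, 1L)

  # LNnT built residue by residue carries four residues
  lnnt <- glycan_graph()
  for (s in c("Glc", "Gal", "GlcNAc", "Gal")) {
    lnnt <- add_residue(lnnt, monosaccharide_residue(s, "beta"))
  }
  expect_length(lnnt$residues, 4)

  expect_error(add_residue(glycan_graph(), "NotASugar"), "unsupported sugar")
  expect_error(monosaccharide_residue("Glc", "beta",
    modifications = list(list(position = 1, mod_name = "sulfate"))),
    "invalid modification position")
  expect_error(monosaccharide_residue("Glc", "none"), "open-chain")
})

test_that("linkages enforce tree topology and registry anomeric carbons", {
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue("GlcNAc", "beta"))
  g <- add_residue(g, monosaccharide_residue("GlcNAc", "beta"))
  g <- add_linkage(g, 2, 1, 4)
  expect_identical(attr(g, "linkage")$donor_anomeric_carbon, "C1")

  # sialic acid donates through C2
  s <- glycan_graph()
  s <- add_residue(s, monosaccharide_residue("Gal", "beta"))
  s <- add_residue(s, monosaccharide_residue("Neu5Ac", "alpha"))
  s <- add_linkage(s, 2, 1, 6)
  expect_identical(attr(s, "linkage")$donor_anomeric_carbon, "C2")

  g <- add_residue(g, monosaccharide_residue("Man", "beta"))
  expect_error(add_linkage(g, 3, 1, 4), "already occupied")
  expect_error(add_linkage(g, 2, 3, 4), "already a donor")
  g <- add_linkage(g, 3, 2, 4)
  expect_error(add_linkage(g, 1, 3, 2), "cycle|donor")
})

test_that("canonical numbering reproduces the published G2 and M9 numbers", {
  g2 <- template_glycan("G2")
  sugars <- vapply(g2$residues, `[[`, "", "sugar_name")
  expect_identical(which(sugars == "Gal"), c(8L, 9L))
  expect_identical(sugars[1:3], c("GlcNAc", "GlcNAc", "Man"))

  m9 <- template_glycan("M9")
  # the 3-arm: Man alpha1-3 on the core Man (residue 4) and its alpha1-2
  # extensions (residues 6 and 9)
  arm3 <- integer(0)
  stack <- 4L
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    arm3 <- c(arm3, cur)
    kids <- Filter(function(l) l$acceptor_index == cur, m9$linkages)
    stack <- c(stack, vapply(kids, `[[`, 0, "donor_index"))
  }
  link4 <- Filter(function(l) l$donor_index == 4L, m9$linkages)[[1]]
  expect_identical(link4$acceptor_index, 3L)
  expect_identical(link4$acceptor_position, 3L)
  expect_identical(sort(as.integer(arm3)), c(4L, 6L, 9L))

  # linear chains number identically
  lin <- parse_iupac_condensed("Galb1-4GlcNAcb1-3Galb1-4Glc")
  expect_identical(residue_numbering(lin), 1:4)
})

test_that("numbering is a root-first permutation, stable under growth", {
  set.seed(42)
  for (i in 1:10) {
    g <- random_glycan(sample(3:10, 1), NULL)
    ord <- residue_numbering(g)
    expect_setequal(ord, seq_along(g$residues))
    expect_identical(ord[1], g$root_index)
  }
  # growing the tree at a later branch position leaves the numbering of
  # the existing residues untouched
  g <- parse_iupac_condensed("Galb1-4Glc")
  before <- residue_numbering(g)
  g2 <- add_residue(g, monosaccharide_residue("Fuc", "alpha"))
  g2 <- add_linkage(g2, 3, 1, 6)
  after <- residue_numbering(g2)
  expect_identical(after[seq_along(before)], before)
})

test_that("validate_graph reports orphans and registry contradictions", {
  g2 <- template_glycan("G2")
  expect_length(validate_graph(g2), 0)

  orphan <- glycan_graph()
  orphan <- add_residue(orphan, monosaccharide_residue("Glc", "beta"))
  orphan <- add_residue(orphan, monosaccharide_residue("Gal", "beta"))
  iss <- validate_graph(orphan)
  expect_length(iss, 1)
  expect_identical(iss[[1]]$category, "orphan-residue")

  # a linkage claiming C1 on a sialic donor contradicts the registry
  s <- glycan_graph()
  s <- add_residue(s, monosaccharide_residue("Gal", "beta"))
  s <- add_residue(s, monosaccharide_residue("Neu5Ac", "alpha"))
  s <- add_linkage(s, 2, 1, 6)
  s$linkages[[1]]$donor_anomeric_carbon <- "C1"
  cats <- vapply(validate_graph(s), `[[`, "", "category")
  expect_true("anomeric-carbon-mismatch" %in% cats)
})

test_that("attachment kinds imply their default partner atoms", {
  expect_identical(attachment_spec("N-linked", "A", 24)$partner_atom, "ND2")
  expect_identical(attachment_spec("O-Ser", "A", 126)$partner_atom, "OG")
  expect_identical(attachment_spec("O-Thr", "A", 30)$partner_atom, "OG1")
  expect_identical(attachment_spec("lipid", "C", 1, "O1")$partner_atom, "O1")
  expect_error(attachment_spec("lipid", "C", 1), "explicit partner_atom")
})
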