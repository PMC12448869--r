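test_that("parser handles linear, branched, and single-residue inputs", {
  lnnt <- parse_iupac_condensed("Galb1-4GlcNAcb1-3Galb1-4Glc")
  expect_length(lnnt$residues, 4)
  expect_identical(vapply(lnnt$residues, `[[`, "", "sugar_name"),
                   c("Glc", "Gal", "GlcNAc", "Gal"))

  g2s2 <- parse_iupac_condensed(paste0(
    "Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
    "[Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3]Manb1-4GlcNAcb1-4GlcNAc"))
  expect_length(g2s2$residues, 11)
  expect_identical(sum(vapply(g2s2$residues, `[[`, "", "sugar_name") == "Neu5Ac"),
                   2L)

  single <- parse_iupac_condensed("Glc")
  expect_length(single$residues, 1)
  expect_length(single$linkages, 0)
})

test_that("parser accepts modifications, configs, and is whitespace-blind", {
  g <- parse_iupac_condensed("GlcNAc6Sb1-3Gal")
  don <- g$residues[[2]]
  expect_identical(don$sugar_name, "GlcNAc")
  expect_identical(don$modifications[[1]],
                   list(position = 6L, mod_name = "sulfate"))

  x <- parse_iupac_condensed("Xyl2Pb")
  expect_identical(x$residues[[1]]$modifications[[1]]$mod_name, "phosphate")

  spaced <- parse_iupac_condensed("Galb1-4 GlcNAcb1-3\tGalb1-4Glc")
  expect_identical(write_iupac_condensed(spaced),
                   "Galb1-4GlcNAcb1-3Galb1-4Glc")
  expect_false(grepl("[[:space:]]", write_iupac_condensed(spaced)))

  # explicit config prefix survives a round trip
  lf <- parse_iupac_condensed("D-Fucp a1-2Gal" ) |> write_iupac_condensed()
  expect_match(lf, "^D-Fuc")
})

test_that("syntax errors carry position information", {
  expect_error(parse_iupac_condensed("Galb1-4Qux"), "no sugar token")
  expect_error(parse_iupac_condensed("Galb1-4[GlcNAcb1-3Glc"), "unbalanced")
  expect_error(parse_iupac_condensed("Galb1-4Glcb1-2"), "root residue")
})

test_that("canonical serialization round-trips", {
  expect_identical(
    write_iupac_condensed(parse_iupac_condensed("Galb1-4GlcNAcb1-3Galb1-4Glc")),
    "Galb1-4GlcNAcb1-3Galb1-4Glc")
  expect_identical(write_iupac_condensed(parse_iupac_condensed("Neu5Ac")),
                   "Neu5Ac")

  graphs_equal <- function(a, b) {
    identical(lapply(a$residues, unclass), lapply(b$residues, unclass)) &&
      identical(lapply(a$linkages, unclass), lapply(b$linkages, unclass))
  }
  set.seed(7)
  for (i in 1:25) {
    g <- random_glycan(sample(2:12, 1), NULL)
    txt <- write_iupac_condensed(g)
    g2 <- parse_iupac_condensed(txt)
    expect_true(graphs_equal(g, g2), label = paste("round trip of", txt))
    # and text-level idempotence
    expect_identical(write_iupac_condensed(g2), txt)
  }
})
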