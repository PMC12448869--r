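test_that("glycosidic pairs follow the worked biantennary example", {
  g2 <- template_glycan("G2")
  pairs <- emit_glycan_bonds(g2, "NG")
  expect_length(pairs, 8)  # 9 residues, no modifications

  # the chitobiose->Man junction: O4 of residue 2 bonded to C1 of residue 3
  hit <- Filter(function(p) p$first$residue == 2 && p$second$residue == 3,
                pairs)
  expect_length(hit, 1)
  expect_identical(hit[[1]]$first,
                   list(entity = "NG", residue = 2L, atom = "O4"))
  expect_identical(hit[[1]]$second,
                   list(entity = "NG", residue = 3L, atom = "C1"))

  single <- parse_iupac_condensed("Glc")
  expect_length(emit_glycan_bonds(single, "NG"), 0)

  # G2S2: 10 pairs; donor atoms all C1 except the two sialic C2
  pairs2 <- emit_glycan_bonds(template_glycan("G2S2"), "NG")
  expect_length(pairs2, 10)
  don <- vapply(pairs2, function(p) p$second$atom, "")
  expect_identical(sum(don == "C1"), 8L)
  expect_identical(sum(don == "C2"), 2L)
})

test_that("bond-count law holds across the template catalog", {
  for (nm in template_catalog()) {
    job <- template(nm)
    glycans <- Filter(function(e) !is.null(e$graph), job$entities)
    expected_glyco <- sum(vapply(glycans, function(e) {
      length(e$graph$residues) - 1 + glycobap:::.graph_mod_count(e$graph)
    }, 0))
    # remaining pairs: attachments and inter-block lipid bonds
    extra <- length(job$bonded_atom_pairs) - expected_glyco
    expect_gte(extra, 0)
    cross <- Filter(function(p) p$first$entity != p$second$entity,
                    job$bonded_atom_pairs)
    intra_nonglycan <- Filter(function(p) {
      p$first$entity == p$second$entity &&
        !(p$first$entity %in% vapply(glycans, `[[`, "", "id"))
    }, job$bonded_atom_pairs)
    expect_identical(as.integer(extra),
                     length(cross) + length(intra_nonglycan))
    expect_length(validate_job(job), 0)
  }
})

test_that("attachments bond the root anomeric carbon to the partner atom", {
  job <- af3_job("epo-nglycan")
  job <- add_protein(job, "A", glycobap:::.protein_seq("EPO"))
  job <- add_glycan(job, "NG", template_glycan("M9"),
                    attachment = attachment_spec("N-linked", "A", 24))
  att <- job$bonded_atom_pairs[[length(job$bonded_atom_pairs)]]
  expect_identical(att$first, list(entity = "A", residue = 24L, atom = "ND2"))
  expect_identical(att$second, list(entity = "NG", residue = 1L, atom = "C1"))

  # O-Thr GalNAc uses OG1
  job2 <- af3_job("dag1")
  job2 <- add_protein(job2, "A", glycobap:::.protein_seq("DAG1"))
  job2 <- add_glycan(job2, "OG", template_glycan("O-core1"),
                     attachment = attachment_spec("O-Thr", "A", 30))
  att2 <- job2$bonded_atom_pairs[[length(job2$bonded_atom_pairs)]]
  expect_identical(att2$first$atom, "OG1")

  # ptm strategy records a protein modification instead of a pair
  job3 <- af3_job("ptm")
  job3 <- add_protein(job3, "A", glycobap:::.protein_seq("GPC1"))
  n_before <- length(job3$bonded_atom_pairs)
  job3 <- add_glycan(job3, "OG", template_glycan("O-core1"),
                     attachment = attachment_spec("O-Ser", "A", 40),
                     strategy = "ptm")
  expect_length(job3$bonded_atom_pairs,
                n_before + length(template_glycan("O-core1")$residues) - 1)
  expect_length(job3$entities[[1]]$ptms, 1)
  expect_identical(job3$entities[[1]]$ptms[[1]]$ptmPosition, 40)

  expect_error(
    attach_glycan(job, "NG", attachment_spec("free")), "nothing to attach")
})

test_that("job validation flags dangling pairs, bad atoms, missing userCCD", {
  job <- template("g2s2")
  expect_length(validate_job(job), 0)

  bad <- add_bond(job, "NG", 12L, "O4", "NG", 3L, "C1")
  cats <- vapply(validate_job(bad), `[[`, "", "category")
  expect_true("dangling-pair" %in% cats)

  bad2 <- add_bond(job, "NG", 2L, "OZZ", "NG", 3L, "C1")
  cats2 <- vapply(validate_job(bad2), `[[`, "", "category")
  expect_true("bad-atom-name" %in% cats2)

  # a sialylated glycan whose donor still uses unedited SIA
  hand <- af3_job("hand-built")
  gr <- parse_iupac_condensed("Neu5Aca2-6Gal")
  hand <- add_ligand_chain(hand, "NG", c("GAL", "SIA"))
  hand$entities[[1]]$graph <- glycobap:::.canonicalize_graph(gr)
  cats3 <- vapply(validate_job(hand), `[[`, "", "category")
  expect_identical(cats3, "missing-userCCD")

  expect_error(add_ligand_chain(job, "NG", "GAL"), "duplicate entity id")
})

test_that("ketose donors are auto-remediated during assembly", {
  job <- template("g2s2")
  codes <- job$entities[[1]]$ccd_codes
  expect_identical(codes[1:3], c("NAG", "NAG", "BMA"))
  expect_identical(codes[10:11], c("SIAX", "SIAX"))
  expect_named(job$user_ccd, "SIAX")
  edited <- load_component_cif(job$user_ccd$SIAX)
  expect_false("O2" %in% edited$atoms$name)
})

test_that("JSON serialization is canonical, byte-stable, and lossless", {
  job <- template("g2")
  txt <- write_af3_json(job)
  expect_identical(txt, write_af3_json(template("g2")))
  expect_match(txt, '"dialect": "alphafold3"')
  expect_match(txt, '"version": 2')

  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(unlist(parsed$sequences[[1]]$ligand$ccdCodes[1:3]),
                   c("NAG", "NAG", "BMA"))
  pair2 <- parsed$bondedAtomPairs[[2]]
  expect_identical(pair2[[1]], list("NG", 2L, "O4"))
  expect_identical(pair2[[2]], list("NG", 3L, "C1"))
  expect_identical(length(parsed$bondedAtomPairs),
                   length(job$bonded_atom_pairs))
  expect_identical(parsed$modelSeeds, list(1L))

  # write to file, byte-identical re-serialization
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  write_af3_json(job, path = f)
  expect_identical(readChar(f, file.info(f)$size), txt)
})

test_that("build_job assembles and aggregates part errors", {
  spec <- list(name = "man1a1-complex",
               proteins = list(list(id = "A",
                                    sequence = glycobap:::.protein_seq("MAN1A1"))),
               ions = list(list(id = "CA", code = "CA")),
               glycans = list(list(id = "NG", glycan = template_glycan("M9"))))
  job <- build_job(spec)
  expect_length(job$entities, 3)
  expect_length(job$bonded_atom_pairs, 10)

  spec$bonds <- list(list("A", 9999L, "ND2", "NG", 1L, "C1"))
  expect_error(build_job(spec), "dangling-pair")
})
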