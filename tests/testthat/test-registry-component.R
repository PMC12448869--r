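test_that("CCD resolution encodes anomericity purely by code choice", {
  expect_identical(resolve_ccd("Man", anomer = "beta")$ccd_code, "BMA")
  expect_identical(resolve_ccd("Man", anomer = "alpha")$ccd_code, "MAN")
  expect_identical(resolve_ccd("GlcNAc", anomer = "beta")$ccd_code, "NAG")

  sia <- resolve_ccd("Neu5Ac", anomer = "alpha")
  expect_identical(sia$ccd_code, "SIA")
  expect_identical(sia$anomeric_carbon, "C2")
  expect_identical(sia$leaving_atom, "O2")
  expect_false(sia$auto_removed)

  # aldoses: C1/O1, auto-removed
  glc <- resolve_ccd("Glc", anomer = "beta")
  expect_identical(glc$anomeric_carbon, "C1")
  expect_identical(glc$leaving_atom, "O1")
  expect_true(glc$auto_removed)

  expect_error(resolve_ccd("NotASugar"), "unsupported")
  expect_error(resolve_ccd("ManA", anomer = "alpha"), "no CCD code")
})

test_that("the packaged registry is total and well-formed", {
  reg <- ccd_registry()
  expect_gte(length(reg$sugars) + length(reg$blocks), 20)
  expect_true(all(c("SPH", "STE", "OTP", "GOL", "PL3", "IPD", "ETA", "PO4")
                  %in% names(reg$blocks)))
  codes <- unlist(lapply(reg$sugars, function(d) unlist(d$codes)))
  expect_true(all(grepl("^[A-Z0-9]{1,5}$", codes)))
  expect_false(anyDuplicated(codes) > 0)
  # every registered tuple resolves without error
  for (s in names(reg$sugars)) {
    for (key in names(reg$sugars[[s]]$codes)) {
      parts <- strsplit(key, ":")[[1]]
      expect_silent(resolve_ccd(s, parts[1], parts[2], parts[3]))
    }
  }
})

test_that("component cif text round-trips and rejects malformed input", {
  for (code in c("NAG", "SIA", "GOL", "PO4")) {
    comp <- ccd_component(code)
    rt <- load_component_cif(write_component_cif(comp))
    expect_identical(rt$code, comp$code)
    expect_identical(rt$atoms$name, comp$atoms$name)
    expect_identical(rt$atoms$leaving, comp$atoms$leaving)
    expect_identical(rt$bonds$atom1, comp$bonds$atom1)
    expect_equal(rt$atoms$x, comp$atoms$x, tolerance = 1e-3)
  }
  nag <- ccd_component("NAG")
  expect_true(all(c("C1", "O1", "O4") %in% nag$atoms$name))

  expect_error(load_component_cif("data_X\nloop_\nnonsense"), "loop")
  bad <- sub("_chem_comp_bond.atom_id_1", "", write_component_cif(nag))
  expect_error(load_component_cif(bad), "malformed|lacks")
})

test_that("leaving-atom remediation strips O2 and its hydroxyl hydrogen", {
  sia <- ccd_component("SIA")
  edited <- strip_leaving_atoms(sia, "O2")
  expect_identical(edited$code, "SIAX")
  expect_false("O2" %in% edited$atoms$name)
  expect_false("HO2" %in% edited$atoms$name)
  expect_identical(sum(sia$atoms$element != "H") -
                     sum(edited$atoms$element != "H"), 1L)
  expect_identical(nrow(sia$atoms) - nrow(edited$atoms), 2L)
  expect_false(any(edited$bonds$atom1 == "O2" | edited$bonds$atom2 == "O2"))
  # the edited cif text carries no O2 row
  expect_false(grepl(" O2 ", write_component_cif(edited)))

  # empty strip: identity, same code
  expect_identical(strip_leaving_atoms(sia, character(0))$code, "SIA")

  # ring atoms are protected (O6 is the sialic ring oxygen)
  expect_error(strip_leaving_atoms(ccd_component("NAG"), "O5"), "ring atom")
  expect_error(strip_leaving_atoms(sia, "O6"), "ring atom")
  expect_error(strip_leaving_atoms(sia, "OZZ"), "not in component")
})

test_that("edited codes never collide with registry codes", {
  all_codes <- glycobap:::.all_registry_codes()
  for (code in all_codes) {
    edited <- glycobap:::.edited_code(code)
    expect_false(edited %in% all_codes)
    # and collision with an explicit reserved name falls through to X2
    edited2 <- glycobap:::.edited_code(code, reserved = edited)
    expect_false(edited2 %in% c(all_codes, edited))
  }
})

test_that("modification bonds bridge through the retained sugar oxygen", {
  p <- plan_modification_bond("GlcNAc", 6, "sulfate")
  expect_identical(p$sugar_atom, "O6")
  expect_identical(p$bond_atom_on_mod, "S")
  expect_identical(p$strip, "O4")

  p2 <- plan_modification_bond("Xyl", 2, "phosphate")
  expect_identical(p2$sugar_atom, "O2")
  expect_identical(p2$bond_atom_on_mod, "P")

  p3 <- plan_modification_bond("Man", 6, "phosphate")
  expect_identical(p3$sugar_atom, "O6")

  expect_error(plan_modification_bond("Glc", 5, "sulfate"), "not modifiable")

  # valence property: after the strip, every oxygen in the edited
  # modification component has at most 2 heavy neighbours, and the bridge
  # plan leaves the bonding atom one slot for the sugar oxygen
  po4 <- ccd_component("PO4")
  ed <- strip_leaving_atoms(po4, p2$strip)
  for (o in ed$atoms$name[ed$atoms$element == "O"]) {
    expect_lte(length(glycobap:::.component_neighbors(ed, o)), 2)
  }
})
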