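# Monosaccharide / building-block registry: CCD code mapping, anomeric and
# leaving-atom semantics, and reference substitution patterns used by the
# synthetic builder and the stereochemistry validator.

# Orientation codes refer to the reference chair (4C1 for D-pyranoses; the
# mirror build is used for L sugars).  "eq"/"ax" per stereocenter; the
# anomeric orientation is stored per anomer.

.sugar <- function(name, class = "aldose", ring = "pyranose",
                   default_config = "D",
                   codes = list(), substituents = list(),
                   anomeric_orient = c(alpha = "ax", beta = "eq"),
                   ring_atoms = NULL, notes = NULL) {
  if (is.null(ring_atoms)) {
    ring_atoms <- switch(ring,
      pyranose = c("O5", "C1", "C2", "C3", "C4", "C5"),
      furanose = c("O4", "C1", "C2", "C3", "C4"),
      open     = character(0))
  }
  # open-chain polyols link through C1 with O1 as the displaced hydroxyl,
  # mirroring the aldose convention
  anomeric_carbon <- if (class == "ketose") "C2" else "C1"
  leaving_atom <- if (class == "ketose") "O2" else "O1"
  auto_removed <- !identical(class, "ketose")
  structure(list(
    sugar = name, class = class, ring = ring,
    default_config = default_config,
    anomeric_carbon = anomeric_carbon,
    leaving_atom = leaving_atom,
    auto_removed = auto_removed,
    ring_atoms = ring_atoms,
    codes = codes,
    substituents = substituents,
    anomeric_orient = anomeric_orient,
    notes = notes
  ), class = "monosaccharide_definition")
}

# substituent helper: first exocyclic heavy atom on a ring carbon, plus an
# optional chain of further atoms.  Chain entries are c(name, element) bonded
# to the previous chain atom, or c(name, element, parent) for branches
# (carboxylate oxygens, acetyl methyls, glycerol-tail carbons).
.sub <- function(atom, element, orient = "eq", chain = NULL) {
  list(atom = atom, element = element, orient = orient, chain = chain)
}
.chain <- function(...) {
  lapply(list(...), function(x) {
    list(atom = x[[1]], element = x[[2]],
         parent = if (length(x) >= 3) x[[3]] else NULL)
  })
}

.build_sugar_registry <- function() {
  r <- list()

  r$Glc <- .sugar("Glc",
    codes = list("D:pyranose:alpha" = "GLC", "D:pyranose:beta" = "BGC"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  r$Gal <- .sugar("Gal",
    codes = list("D:pyranose:alpha" = "GLA", "D:pyranose:beta" = "GAL"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O", "ax"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  r$Man <- .sugar("Man",
    codes = list("D:pyranose:alpha" = "MAN", "D:pyranose:beta" = "BMA"),
    substituents = list(
      C2 = .sub("O2", "O", "ax"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  r$GlcNAc <- .sugar("GlcNAc",
    codes = list("D:pyranose:alpha" = "NDG", "D:pyranose:beta" = "NAG"),
    substituents = list(
      C2 = .sub("N2", "N", chain = .chain(c("C7", "C"), c("O7", "O"), c("C8", "C", "C7"))),
      C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  r$GalNAc <- .sugar("GalNAc",
    codes = list("D:pyranose:alpha" = "A2G", "D:pyranose:beta" = "NGA"),
    substituents = list(
      C2 = .sub("N2", "N", chain = .chain(c("C7", "C"), c("O7", "O"), c("C8", "C", "C7"))),
      C3 = .sub("O3", "O"), C4 = .sub("O4", "O", "ax"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  r$GlcN <- .sugar("GlcN",
    codes = list("D:pyranose:alpha" = "GCS", "D:pyranose:beta" = "PA1"),
    substituents = list(
      C2 = .sub("N2", "N"),
      C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6", "O")))))

  # 6-deoxy-L-galactose; built as the mirror image of the D reference.
  r$Fuc <- .sugar("Fuc", default_config = "L",
    codes = list("L:pyranose:alpha" = "FUC", "L:pyranose:beta" = "FUL"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O", "ax"),
      C5 = .sub("C6", "C")))

  r$Xyl <- .sugar("Xyl",
    codes = list("D:pyranose:alpha" = "XYS", "D:pyranose:beta" = "XYP"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O")))

  r$GlcA <- .sugar("GlcA",
    codes = list("D:pyranose:alpha" = "GCU", "D:pyranose:beta" = "BDP"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6A", "O"), c("O6B", "O", "C6")))))

  # C5 epimer of GlcA (carboxylate axial in the reference frame).
  r$IdoA <- .sugar("IdoA", default_config = "L",
    codes = list("L:pyranose:alpha" = "IDR"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", orient = "ax", chain = .chain(c("O6A", "O"), c("O6B", "O", "C6")))))

  r$ManA <- .sugar("ManA",
    codes = list("D:pyranose:beta" = "BEM"),
    substituents = list(
      C2 = .sub("O2", "O", "ax"), C3 = .sub("O3", "O"), C4 = .sub("O4", "O"),
      C5 = .sub("C6", "C", chain = .chain(c("O6A", "O"), c("O6B", "O", "C6")))))

  # Sialic acids: ketoses; ring O6-C2..C6, anomeric C2 carries both the
  # glycosidic O2 and the C1 carboxylate.  AF3 does not auto-remove O2.
  neu_ring <- c("O6", "C2", "C3", "C4", "C5", "C6")
  r$Neu5Ac <- .sugar("Neu5Ac", class = "ketose", ring_atoms = neu_ring,
    codes = list("D:pyranose:alpha" = "SIA", "D:pyranose:beta" = "SLB"),
    substituents = list(
      C2 = .sub("C1", "C", orient = "anomeric_partner",
                chain = .chain(c("O1A", "O"), c("O1B", "O", "C1"))),
      C4 = .sub("O4", "O"),
      C5 = .sub("N5", "N", chain = .chain(c("C10", "C"), c("O10", "O"), c("C11", "C", "C10"))),
      C6 = .sub("C7", "C", chain = .chain(c("O7", "O"), c("C8", "C", "C7"),
                                          c("O8", "O"), c("C9", "C", "C8"), c("O9", "O")))))

  r$Neu5Gc <- .sugar("Neu5Gc", class = "ketose", ring_atoms = neu_ring,
    codes = list("D:pyranose:alpha" = "NGC", "D:pyranose:beta" = "NGE"),
    substituents = list(
      C2 = .sub("C1", "C", orient = "anomeric_partner",
                chain = .chain(c("O1A", "O"), c("O1B", "O", "C1"))),
      C4 = .sub("O4", "O"),
      C5 = .sub("N5", "N", chain = .chain(c("C10", "C"), c("O10", "O"),
                                          c("C11", "C", "C10"), c("O11", "O"))),
      C6 = .sub("C7", "C", chain = .chain(c("O7", "O"), c("C8", "C", "C7"),
                                          c("O8", "O"), c("C9", "C", "C8"), c("O9", "O")))))

  r$Kdn <- .sugar("Kdn", class = "ketose", ring_atoms = neu_ring,
    codes = list("D:pyranose:alpha" = "KDN"),
    substituents = list(
      C2 = .sub("C1", "C", orient = "anomeric_partner",
                chain = .chain(c("O1A", "O"), c("O1B", "O", "C1"))),
      C4 = .sub("O4", "O"),
      C5 = .sub("O5", "O"),
      C6 = .sub("C7", "C", chain = .chain(c("O7", "O"), c("C8", "C", "C7"),
                                          c("O8", "O"), c("C9", "C", "C8"), c("O9", "O")))))

  r$Galf <- .sugar("Galf", ring = "furanose",
    codes = list("D:furanose:beta" = "GZL"),
    substituents = list(
      C2 = .sub("O2", "O"), C3 = .sub("O3", "O"),
      C4 = .sub("C5", "C", chain = .chain(c("O5", "O"), c("C6", "C", "C5"), c("O6", "O")))))

  # Open-chain polyol; participates in graphs with anomer "none" and links
  # through C1 (positional oxygens O1..O5 available as acceptor sites).
  r$`Rib-ol` <- .sugar("Rib-ol", class = "open", ring = "open",
    codes = list("D:open:none" = "RBT"),
    substituents = list(),
    anomeric_orient = c(none = "eq"),
    notes = "open-chain ribitol; pucker analysis skipped")

  r
}

# Lipid / small-molecule building blocks used by template assemblies.
# Synthetic simplified heavy-atom definitions (documented atom names); real
# CCD definitions are drop-in compatible through load_component_cif().
.build_block_registry <- function() {
  chainC <- function(n, from = 2) sprintf("C%d", seq(from, n))
  blk <- function(code, atoms, bonds, attach_atom, leaving = character(0)) {
    list(code = code, atoms = atoms, bonds = bonds,
         attach_atom = attach_atom, leaving = leaving)
  }
  # atoms: named character vector name -> element; bonds: list of c(a1, a2)
  lin <- function(names) {
    if (length(names) < 2) return(list())
    mapply(function(a, b) c(a, b), names[-length(names)], names[-1],
           SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  b <- list()
  # sphingosine: O1 head, N2 amine (amide link to fatty acid), C18 tail
  sph_c <- c("C1", "O1", "C2", "N2", "C3", "O3", chainC(18, 4))
  sph_el <- ifelse(grepl("^O", sph_c), "O", ifelse(grepl("^N", sph_c), "N", "C"))
  names(sph_el) <- sph_c
  sph_bonds <- c(list(c("C1", "O1"), c("C1", "C2"), c("C2", "N2"),
                      c("C2", "C3"), c("C3", "O3")), lin(chainC(18, 3)))
  b$SPH <- blk("SPH", sph_el, sph_bonds, attach_atom = "O1")

  # stearic acid: carboxyl C1 (O1 carbonyl, O2 hydroxyl = leaving on amide)
  ste_c <- c("C1", "O1", "O2", chainC(18))
  ste_el <- ifelse(grepl("^O", ste_c), "O", "C"); names(ste_el) <- ste_c
  b$STE <- blk("STE", ste_el,
               c(list(c("C1", "O1"), c("C1", "O2"), c("C1", "C2")), lin(chainC(18))),
               attach_atom = "C1", leaving = "O2")

  # palmityl alcohol
  pl3_c <- c("C1", "O1", chainC(16))
  pl3_el <- ifelse(grepl("^O", pl3_c), "O", "C"); names(pl3_el) <- pl3_c
  b$PL3 <- blk("PL3", pl3_el,
               c(list(c("C1", "O1"), c("C1", "C2")), lin(chainC(16))),
               attach_atom = "O1")

  gol_el <- c(C1 = "C", O1 = "O", C2 = "C", O2 = "O", C3 = "C", O3 = "O")
  b$GOL <- blk("GOL", gol_el,
               list(c("C1", "O1"), c("C1", "C2"), c("C2", "O2"),
                    c("C2", "C3"), c("C3", "O3")),
               attach_atom = "O1")

  # myo-inositol 1-phosphate: carbocycle C1..C6, hydroxyls O2..O6, P on O1
  ipd_names <- c(sprintf("C%d", 1:6), sprintf("O%d", 1:6), "P1", "O1P", "O2P", "O3P")
  ipd_el <- ifelse(grepl("^C", ipd_names), "C",
                   ifelse(ipd_names == "P1", "P", "O"))
  names(ipd_el) <- ipd_names
  ipd_bonds <- c(lin(sprintf("C%d", 1:6)), list(c("C6", "C1")),
                 lapply(1:6, function(i) c(sprintf("C%d", i), sprintf("O%d", i))),
                 list(c("O1", "P1"), c("P1", "O1P"), c("P1", "O2P"), c("P1", "O3P")))
  b$IPD <- blk("IPD", ipd_el, ipd_bonds, attach_atom = "O2", leaving = "O3P")

  eta_el <- c(C1 = "C", O1 = "O", C2 = "C", N1 = "N")
  b$ETA <- blk("ETA", eta_el,
               list(c("C1", "O1"), c("C1", "C2"), c("C2", "N1")),
               attach_atom = "N1")

  po4_el <- c(P = "P", O1 = "O", O2 = "O", O3 = "O", O4 = "O")
  b$PO4 <- blk("PO4", po4_el,
               list(c("P", "O1"), c("P", "O2"), c("P", "O3"), c("P", "O4")),
               attach_atom = "P", leaving = c("O3", "O4"))

  # dolichol-PP analog: truncated prenyl tail + pyrophosphate head.
  otp_c <- sprintf("C%d", 1:10)
  otp_names <- c(otp_c, "O1", "P1", "O2", "O3", "O4", "P2", "O5", "O6", "O7")
  otp_el <- ifelse(grepl("^C", otp_names), "C",
                   ifelse(grepl("^P", otp_names), "P", "O"))
  names(otp_el) <- otp_names
  otp_bonds <- c(lin(otp_c),
                 list(c("C1", "O1"), c("O1", "P1"), c("P1", "O2"), c("P1", "O3"),
                      c("P1", "O4"), c("O4", "P2"), c("P2", "O5"), c("P2", "O6"),
                      c("P2", "O7")))
  b$OTP <- blk("OTP", otp_el, otp_bonds, attach_atom = "O7")

  b
}

# Hydroxyl modifications attached through bondedAtomPairs.  The sugar's
# O<position> is retained as the bridging atom; a terminal oxygen on the
# modification component is the leaving atom that must be stripped manually.
.build_modification_registry <- function() {
  list(
    sulfate = list(mod_name = "sulfate", ccd_code = "SO4",
                   bond_atom_on_mod = "S",
                   leaving_atoms_on_mod = "O4",
                   atoms = c(S = "S", O1 = "O", O2 = "O", O3 = "O", O4 = "O"),
                   bonds = list(c("S", "O1"), c("S", "O2"), c("S", "O3"), c("S", "O4"))),
    phosphate = list(mod_name = "phosphate", ccd_code = "PO4",
                     bond_atom_on_mod = "P",
                     leaving_atoms_on_mod = "O4",
                     atoms = c(P = "P", O1 = "O", O2 = "O", O3 = "O", O4 = "O"),
                     bonds = list(c("P", "O1"), c("P", "O2"), c("P", "O3"), c("P", "O4"))),
    acetyl = list(mod_name = "acetyl", ccd_code = "ACE",
                  bond_atom_on_mod = "C",
                  leaving_atoms_on_mod = character(0),
                  atoms = c(C = "C", O = "O", CH3 = "C"),
                  bonds = list(c("C", "O"), c("C", "CH3"))),
    methyl = list(mod_name = "methyl", ccd_code = "MOH",
                  bond_atom_on_mod = "C",
                  leaving_atoms_on_mod = "O",
                  atoms = c(C = "C", O = "O"),
                  bonds = list(c("C", "O")))
  )
}

.registry_env <- new.env(parent = emptyenv())

#' Monosaccharide and building-block registry
#'
#' Returns the packaged registry mapping sugar names to CCD codes per
#' (configuration, ring form, anomer), together with anomeric-carbon and
#' leaving-atom semantics and the reference axial/equatorial substitution
#' pattern each sugar adopts in the \eqn{^4C_1} chair (D-pyranoses; L sugars
#' are mirror builds).
#'
#' @return A list with elements \code{sugars}, \code{blocks} (lipid and
#'   small-molecule assembly blocks), and \code{modifications} (sulfate,
#'   phosphate, acetyl, methyl attachment plans).
#' @export
#' @examples
#' reg <- ccd_registry()
#' names(reg$sugars)
ccd_registry <- function() {
  if (is.null(.registry_env$registry)) {
    .registry_env$registry <- list(
      sugars = .build_sugar_registry(),
      blocks = .build_block_registry(),
      modifications = .build_modification_registry()
    )
  }
  .registry_env$registry
}

#' Resolve a residue to its CCD code and bonding semantics
#'
#' Maps a (sugar, configuration, ring form, anomer) tuple to the CCD code
#' that encodes its anomeric configuration.  Anomericity is carried purely
#' by the code choice (e.g. MAN vs BMA), never by geometry.
#'
#' @param sugar_name Sugar token, e.g. \code{"Man"}, \code{"Neu5Ac"}.
#' @param config \code{"D"} or \code{"L"}; defaults to the sugar's SNFG
#'   default (L for Fuc and IdoA, D otherwise).
#' @param ring \code{"pyranose"}, \code{"furanose"} or \code{"open"}.
#' @param anomer \code{"alpha"}, \code{"beta"} or \code{"none"} (open chain).
#' @return List with \code{ccd_code}, \code{anomeric_carbon},
#'   \code{leaving_atom}, \code{auto_removed}, and the registry definition.
#' @export
#' @examples
#' resolve_ccd("Man", anomer = "beta")$ccd_code     # "BMA"
#' resolve_ccd("Neu5Ac", anomer = "alpha")$ccd_code # "SIA"
resolve_ccd <- function(sugar_name, config = NULL, ring = NULL, anomer = "beta") {
  reg <- ccd_registry()
  def <- reg$sugars[[sugar_name]]
  if (is.null(def)) {
    stop("unsupported sugar '", sugar_name, "'; supported: ",
         paste(names(reg$sugars), collapse = ", "), call. = FALSE)
  }
  if (is.null(config)) config <- def$default_config
  if (is.null(ring)) ring <- def$ring
  key <- paste(config, ring, anomer, sep = ":")
  code <- def$codes[[key]]
  if (is.null(code)) {
    stop("no CCD code for (", sugar_name, ", ", key, "); available: ",
         paste(names(def$codes), collapse = ", "), call. = FALSE)
  }
  list(ccd_code = code,
       anomeric_carbon = def$anomeric_carbon,
       leaving_atom = def$leaving_atom,
       auto_removed = def$auto_removed,
       definition = def)
}

# Internal: look up a sugar definition or fail with the spec'd error.
.sugar_def <- function(sugar_name) {
  def <- ccd_registry()$sugars[[sugar_name]]
  if (is.null(def)) {
    stop("unsupported sugar '", sugar_name, "'", call. = FALSE)
  }
  def
}

# Stereocenters checked by the validator: ring carbons carrying an exocyclic
# heavy substituent, plus the anomeric carbon.
.sugar_stereocenters <- function(def) {
  if (def$class %in% c("open", "block")) return(character(0))
  centers <- names(def$substituents)
  centers <- setdiff(centers, def$anomeric_carbon)
  c(def$anomeric_carbon, centers)
}

# Valid acceptor positions: positions p for which atom O<p> exists and is a
# hydroxyl (not the ring oxygen, not the anomeric oxygen).
.sugar_acceptor_positions <- function(def) {
  if (def$class == "open") return(1:5)
  pos <- integer(0)
  for (cc in names(def$substituents)) {
    s <- def$substituents[[cc]]
    atoms <- c(s$atom, vapply(s$chain, `[[`, "", "atom"))
    hydroxyls <- grep("^O[0-9]+$", atoms, value = TRUE)
    pos <- c(pos, as.integer(sub("^O", "", hydroxyls)))
  }
  sort(unique(pos))
}
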