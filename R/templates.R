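# Curated template catalog: glycan topologies and fully assembled AF3 jobs
# for the common N-glycans, O-GalNAc cores, GAG linkers, glycolipids,
# dolichol-PP and GPI assemblies, and the fully glycosylated Siglec-2 pair.
#
# Protein sequences are synthetic stand-ins (inst/extdata/
# proteins_synthetic.fasta, deterministic) with attachment sites recorded
# in attachment_sites_synthetic.tsv; real sequences keyed by the
# corresponding UniProt accessions are drop-in replacements.

.GLYCAN_CATALOG <- list(
  LNnT = "Galb1-4GlcNAcb1-3Galb1-4Glc",
  M9 = paste0("Mana1-2Mana1-6[Mana1-2Mana1-3]Mana1-6",
              "[Mana1-2Mana1-2Mana1-3]Manb1-4GlcNAcb1-4GlcNAc"),
  A1 = "Mana1-6[GlcNAcb1-2Mana1-3]Manb1-4GlcNAcb1-4GlcNAc",
  G2 = paste0("Galb1-4GlcNAcb1-2Mana1-6[Galb1-4GlcNAcb1-2Mana1-3]",
              "Manb1-4GlcNAcb1-4GlcNAc"),
  G2F = paste0("Fuca1-6[Galb1-4GlcNAcb1-2Mana1-6[Galb1-4GlcNAcb1-2Mana1-3]",
               "Manb1-4GlcNAcb1-4]GlcNAc"),
  G2S2 = paste0("Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-6",
                "[Neu5Aca2-6Galb1-4GlcNAcb1-2Mana1-3]",
                "Manb1-4GlcNAcb1-4GlcNAc"),
  `G2S2-6S` = paste0("Neu5Aca2-6Galb1-4GlcNAc6Sb1-2Mana1-6",
                     "[Neu5Aca2-6Galb1-4GlcNAc6Sb1-2Mana1-3]",
                     "Manb1-4GlcNAcb1-4GlcNAc"),
  `O-core1` = "Galb1-3GalNAca",
  `O-core2` = "GlcNAcb1-6[Galb1-3]GalNAca",
  `O-core3` = "GlcNAcb1-3GalNAca",
  `O-core4` = "GlcNAcb1-6[GlcNAcb1-3]GalNAca",
  `disialyl-core1` = "Neu5Aca2-6[Neu5Aca2-3Galb1-3]GalNAca",
  `KS-core2` = paste0("Neu5Aca2-3Galb1-4GlcNAc6Sb1-3Gal6Sb1-4GlcNAc6Sb1-6",
                      "[Galb1-3]GalNAca"),
  `HS-linker` = "GlcAb1-3Galb1-3Galb1-4Xyl2Pb",
  `CS-linker` = "GalNAcb1-4GlcAb1-3Galb1-3Galb1-4Xyl2Pb",
  coreM3 = "Rib-ol5P1-3GalNAcb1-3GlcNAcb1-4Man6Pa",
  GP1c = paste0("Neu5Aca2-8Neu5Aca2-3Galb1-3GalNAcb1-4",
                "[Neu5Aca2-8Neu5Aca2-8Neu5Aca2-3]Galb1-4Glc"),
  `Leb-lactoside` = "Fuca1-4[Fuca1-2Galb1-3]GlcNAcb1-3Galb1-4Glc",
  GloboH = "Fuca1-2Galb1-3GalNAcb1-3Gala1-4Galb1-4Glc",
  chitobiose = "GlcNAcb1-4GlcNAca",
  `GPI-core` = "Mana1-2Mana1-6Mana1-4GlcNa"
)

#' Catalog of packaged glycan topologies
#' @return Character vector of glycan template names.
#' @export
glycan_catalog <- function() names(.GLYCAN_CATALOG)

#' Retrieve a packaged glycan topology
#'
#' @param name Catalog name (see \code{\link{glycan_catalog}}), e.g.
#'   \code{"G2"}, \code{"M9"}, \code{"O-core2"}.
#' @return A canonical \code{glycan_graph}.
#' @export
#' @examples
#' length(template_glycan("M9")$residues)  # 11
template_glycan <- function(name) {
  text <- .GLYCAN_CATALOG[[name]]
  if (is.null(text)) {
    stop("unknown glycan template '", name, "'; catalog: ",
         paste(names(.GLYCAN_CATALOG), collapse = ", "), call. = FALSE)
  }
  parse_iupac_condensed(text)
}

# synthetic protein fixtures ------------------------------------------------

.read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^>", lines)
  out <- list()
  for (k in seq_along(idx)) {
    name <- sub("^>([^ ]+).*$", "\\1", lines[idx[k]])
    end <- if (k < length(idx)) idx[k + 1] - 1 else length(lines)
    out[[name]] <- paste(lines[seq(idx[k] + 1, end)], collapse = "")
  }
  out
}

.protein_env <- new.env(parent = emptyenv())

#' Packaged synthetic protein fixtures
#'
#' Deterministic stand-in sequences with annotated glycan attachment sites
#' (sequon positions for the N-glycoproteins, Ser/Thr sites for the
#' O-glycoproteins).  Labelled synthetic throughout; real UniProt sequences
#' are drop-in replacements with the corresponding site annotations.
#'
#' @return List with \code{sequences} (named list) and \code{sites}
#'   (data.frame protein/kind/position).
#' @export
protein_fixtures <- function() {
  if (is.null(.protein_env$fixtures)) {
    fa <- system.file("extdata", "proteins_synthetic.fasta",
                      package = "glycobap", mustWork = TRUE)
    tsv <- system.file("extdata", "attachment_sites_synthetic.tsv",
                       package = "glycobap", mustWork = TRUE)
    .protein_env$fixtures <- list(
      sequences = .read_fasta(fa),
      sites = utils::read.delim(tsv, stringsAsFactors = FALSE))
  }
  .protein_env$fixtures
}

.protein_seq <- function(name) {
  seqs <- protein_fixtures()$sequences
  s <- seqs[[paste0(name, "_synthetic")]]
  if (is.null(s)) stop("no packaged protein fixture '", name, "'", call. = FALSE)
  s
}

.protein_sites <- function(name, kind = NULL) {
  st <- protein_fixtures()$sites
  st <- st[st$protein == paste0(name, "_synthetic"), , drop = FALSE]
  if (!is.null(kind)) st <- st[st$kind == kind, , drop = FALSE]
  st$position
}

# lipid assembly helpers ----------------------------------------------------

# ceramide entity: SPH + STE with an amide bond (STE hydroxyl O2 stripped)
.add_ceramide <- function(job, id) {
  ste <- strip_leaving_atoms(ccd_component("STE"), "O2",
                             reserved = names(job$user_ccd))
  job$user_ccd[[ste$code]] <- write_component_cif(ste)
  job <- add_ligand_chain(job, id, c("SPH", ste$code))
  add_bond(job, id, 1L, "N2", id, 2L, "C1")
}

# glycolipid: glycan entity + ceramide entity + reducing-end bond
.add_glycolipid <- function(job, glycan_id, cer_id, glycan_name) {
  job <- .add_ceramide(job, cer_id)
  add_glycan(job, glycan_id, template_glycan(glycan_name),
             attachment = attachment_spec("lipid", cer_id, 1L, "O1"))
}

# template builders ----------------------------------------------------------

.TEMPLATE_BUILDERS <- list(
  lnnt = function() {
    job <- af3_job("lnnt-free")
    add_glycan(job, "NG", template_glycan("LNnT"))
  },
  m9 = function() {
    job <- af3_job("m9-free")
    add_glycan(job, "NG", template_glycan("M9"))
  },
  g2 = function() {
    job <- af3_job("g2-free")
    add_glycan(job, "NG", template_glycan("G2"))
  },
  g2f = function() {
    job <- af3_job("g2f-free")
    add_glycan(job, "NG", template_glycan("G2F"))
  },
  g2s2 = function() {
    job <- af3_job("g2s2-free")
    add_glycan(job, "NG", template_glycan("G2S2"))
  },
  a1 = function() {
    job <- af3_job("a1-free")
    add_glycan(job, "NG", template_glycan("A1"))
  },
  "man1a1-m9" = function() {
    job <- af3_job("man1a1-m9-ca")
    job <- add_protein(job, "A", .protein_seq("MAN1A1"))
    job <- add_ion(job, "CA", "CA")
    add_glycan(job, "NG", template_glycan("M9"))
  },
  "epo-m9" = function() {
    job <- af3_job("epo-m9")
    job <- add_protein(job, "A", .protein_seq("EPO"))
    site <- .protein_sites("EPO", "N-linked")[1]
    add_glycan(job, "NG", template_glycan("M9"),
               attachment = attachment_spec("N-linked", "A", site))
  },
  "epo-o-cores" = function() {
    job <- af3_job("epo-o-core-gallery")
    job <- add_protein(job, "A", .protein_seq("EPO"))
    site <- .protein_sites("EPO", "O-Ser")[1]
    add_glycan(job, "OG", template_glycan("O-core1"),
               attachment = attachment_spec("O-Ser", "A", site))
  },
  "ks-core2-epo" = function() {
    job <- af3_job("ks-core2-epo")
    job <- add_protein(job, "A", .protein_seq("EPO"))
    site <- .protein_sites("EPO", "O-Ser")[1]
    add_glycan(job, "OG", template_glycan("KS-core2"),
               attachment = attachment_spec("O-Ser", "A", site))
  },
  "hs-linker-gpc1" = function() {
    job <- af3_job("hs-linker-gpc1", model_seeds = 1:10)  # hard target
    job <- add_protein(job, "A", .protein_seq("GPC1"))
    site <- .protein_sites("GPC1", "O-Ser")[1]
    add_glycan(job, "OG", template_glycan("HS-linker"),
               attachment = attachment_spec("O-Ser", "A", site))
  },
  "cs-linker-bikunin" = function() {
    job <- af3_job("cs-linker-bikunin", model_seeds = 1:10)
    job <- add_protein(job, "A", .protein_seq("BIKUNIN"))
    site <- .protein_sites("BIKUNIN", "O-Ser")[1]
    add_glycan(job, "OG", template_glycan("CS-linker"),
               attachment = attachment_spec("O-Ser", "A", site))
  },
  "corem3-dag1" = function() {
    job <- af3_job("corem3-dag1")
    job <- add_protein(job, "A", .protein_seq("DAG1"))
    site <- .protein_sites("DAG1", "O-Thr")[1]
    add_glycan(job, "OG", template_glycan("coreM3"),
               attachment = attachment_spec("O-Thr", "A", site))
  },
  gp1c = function() {
    job <- af3_job("gp1c-gsl")
    .add_glycolipid(job, "GL", "CR", "GP1c")
  },
  "leb-lactoside" = function() {
    job <- af3_job("leb-lactoside-gsl")
    .add_glycolipid(job, "GL", "CR", "Leb-lactoside")
  },
  "globoh-bc2lc" = function() {
    job <- af3_job("globoh-bc2lc-trimer")
    for (ch in c("A", "B", "C")) {
      job <- add_protein(job, ch, .protein_seq("BC2LC"))
    }
    for (k in 1:3) {
      job <- .add_glycolipid(job, paste0("GL", k), paste0("CR", k), "GloboH")
    }
    job
  },
  "dolpp-chitobiose-alg1" = function() {
    job <- af3_job("dolpp-chitobiose-alg1")
    job <- add_protein(job, "A", .protein_seq("ALG1"))
    job <- add_ion(job, "MN", "MN")
    job <- add_ligand_chain(job, "GD", "GDM")  # GDP-mannose donor
    job <- add_ligand_chain(job, "LP", "OTP")  # dol-PP analog
    # alpha-linked root GlcNAc bonded to the pyrophosphate oxygen
    add_glycan(job, "NG", template_glycan("chitobiose"),
               attachment = attachment_spec("small-molecule-chain",
                                            "LP", 1L, "O7"))
  },
  "gpi-gpc1" = function() {
    job <- af3_job("gpi-gpc1", model_seeds = 1:10)  # hard target
    job <- add_protein(job, "A", .protein_seq("GPC1"))
    ser <- max(.protein_sites("GPC1", "O-Ser"))  # C-terminal serine
    # phosphoethanolamine bridge: ETA + stripped PO4
    po4 <- strip_leaving_atoms(ccd_component("PO4"), c("O3", "O4"))
    job$user_ccd[[po4$code]] <- write_component_cif(po4)
    job <- add_ligand_chain(job, "ET", "ETA")
    job <- add_ligand_chain(job, "PP", po4$code)
    job <- add_glycan(job, "NG", template_glycan("GPI-core"))
    # lipid side: inositol-1-phosphate + glycerol + acyl/alkyl tails
    ipd <- strip_leaving_atoms(ccd_component("IPD"), "O3P")
    job$user_ccd[[ipd$code]] <- write_component_cif(ipd)
    ste <- strip_leaving_atoms(ccd_component("STE"), "O2")
    job$user_ccd[[ste$code]] <- write_component_cif(ste)
    job <- add_ligand_chain(job, "IP", ipd$code)
    job <- add_ligand_chain(job, "GO", "GOL")
    job <- add_ligand_chain(job, "PL", "PL3")
    job <- add_ligand_chain(job, "ST", ste$code)
    # amide from the C-terminal serine backbone carbonyl to ethanolamine
    job <- add_bond(job, "A", ser, "C", "ET", 1L, "N1")
    job <- add_bond(job, "ET", 1L, "O1", "PP", 1L, "P")
    job <- add_bond(job, "NG", 4L, "O6", "PP", 1L, "P")   # P-6-Man (top)
    job <- add_bond(job, "IP", 1L, "O6", "NG", 1L, "C1")  # GlcN alpha1-6 Ino
    job <- add_bond(job, "IP", 1L, "O1P", "GO", 1L, "C3")
    job <- add_bond(job, "GO", 1L, "O1", "ST", 1L, "C1")
    job <- add_bond(job, "GO", 1L, "O2", "PL", 1L, "C1")
    attr(job, "provisional") <-
      "GPI sidechain sialylation omitted; linkage undetermined"
    job
  },
  "siglec2-full-pair" = function() {
    job <- af3_job("siglec2-full-pair")
    sites <- .protein_sites("SIGLEC2", "N-linked")
    seq <- .protein_seq("SIGLEC2")
    g2s2 <- template_glycan("G2S2")
    counter <- 0L
    for (ch in c("S1", "S2")) {
      job <- add_protein(job, ch, seq)
      for (site in sites) {
        counter <- counter + 1L
        gid <- if (counter == 1L) "NG" else paste0("NG", counter)
        job <- add_glycan(job, gid, g2s2,
                          attachment = attachment_spec("N-linked", ch, site))
      }
    }
    job
  },
  "siglec2-trans" = function() {
    job <- .TEMPLATE_BUILDERS[["siglec2-full-pair"]]()
    job$name <- "siglec2-trans-ligand"
    add_glycan(job, "FG", template_glycan("G2S2-6S"))
  }
)

#' Catalog of packaged job templates
#' @return Character vector of template names.
#' @export
template_catalog <- function() names(.TEMPLATE_BUILDERS)

#' Build a packaged AF3 job template
#'
#' Fully assembled, validated jobs reproducing the packaged modeling
#' scenarios: free N-glycans, enzyme/lectin complexes, O-glycans on their
#' carrier proteins, glycolipids on ceramide, the dolichol-PP and GPI
#' assemblies, and the fully N-glycosylated Siglec-2 pair.  Templates
#' flagged hard (GPI, HS/CS linkers) default to a larger seed list.
#'
#' @param name Template name (see \code{\link{template_catalog}}).
#' @return A validated \code{af3_job}.
#' @export
#' @examples
#' job <- template("g2")
#' length(job$bonded_atom_pairs)  # 8
template <- function(name) {
  b <- .TEMPLATE_BUILDERS[[name]]
  if (is.null(b)) {
    stop("unknown template '", name, "'; catalog: ",
         paste(template_catalog(), collapse = ", "), call. = FALSE)
  }
  job <- b()
  issues <- validate_job(job)
  if (length(issues)) {
    stop("template '", name, "' failed validation: ",
         issues[[1]]$message, call. = FALSE)
  }
  job
}
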