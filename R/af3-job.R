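# AlphaFold 3 input assembly: entities, bondedAtomPairs, userCCD blocks,
# and canonical JSON (input format version 2) serialization.

#' Create an empty AF3 job
#'
#' @param name Job name.
#' @param model_seeds Integer vector of model seeds (default 1).
#' @return Object of class \code{af3_job}.
#' @export
af3_job <- function(name, model_seeds = 1L) {
  structure(list(name = name,
                 model_seeds = as.integer(model_seeds),
                 entities = list(),
                 bonded_atom_pairs = list(),
                 user_ccd = list()),
            class = "af3_job")
}

.job_entity_ids <- function(job) vapply(job$entities, `[[`, "", "id")

.add_entity <- function(job, entity) {
  if (entity$id %in% .job_entity_ids(job)) {
    stop("duplicate entity id '", entity$id, "'", call. = FALSE)
  }
  job$entities[[length(job$entities) + 1L]] <- entity
  job
}

#' Add a protein entity
#'
#' @param job An \code{af3_job}.
#' @param id Entity id.
#' @param sequence One-letter amino-acid sequence.
#' @param ptms List of \code{list(ptmType =, ptmPosition =)} entries.
#' @return Updated job.
#' @export
add_protein <- function(job, id, sequence, ptms = list()) {
  .add_entity(job, list(id = id, kind = "protein",
                        sequence = toupper(gsub("[[:space:]]", "", sequence)),
                        ptms = ptms))
}

#' Add a single-component ion or small-molecule ligand entity
#' @param job An \code{af3_job}.
#' @param id Entity id.
#' @param ccd_code Component code (e.g. \code{"CA"}, \code{"MN"}).
#' @return Updated job.
#' @export
add_ion <- function(job, id, ccd_code) {
  .add_entity(job, list(id = id, kind = "ion", ccd_codes = ccd_code))
}

#' Add a multi-component ligand chain (assembly blocks)
#' @param job An \code{af3_job}.
#' @param id Entity id.
#' @param ccd_codes Ordered component codes.
#' @return Updated job.
#' @export
add_ligand_chain <- function(job, id, ccd_codes) {
  .add_entity(job, list(id = id, kind = "ligand-chain", ccd_codes = ccd_codes))
}

#' Add an explicit covalent bond
#'
#' @param job An \code{af3_job}.
#' @param entity1,residue1,atom1 First endpoint (entity id, 1-based residue
#'   index, atom name).
#' @param entity2,residue2,atom2 Second endpoint.
#' @return Updated job.
#' @export
add_bond <- function(job, entity1, residue1, atom1, entity2, residue2, atom2) {
  pair <- list(first = list(entity = entity1, residue = as.integer(residue1),
                            atom = atom1),
               second = list(entity = entity2, residue = as.integer(residue2),
                             atom = atom2))
  if (identical(pair$first, pair$second)) {
    stop("bond endpoints must differ", call. = FALSE)
  }
  job$bonded_atom_pairs[[length(job$bonded_atom_pairs) + 1L]] <- pair
  job
}

# Compile a glycan graph: ccdCodes in numbering order (modification
# components appended), intra-entity bonded pairs, and required userCCD
# blocks (edited ketose donors; stripped modification components).
.compile_glycan <- function(graph, entity) {
  graph <- .canonicalize_graph(graph)
  n <- length(graph$residues)
  codes <- character(n)
  user_ccd <- list()
  edited_for <- list()  # base code -> edited code (one block per base code)
  for (k in seq_len(n)) {
    res <- graph$residues[[k]]
    rc <- resolve_ccd(res$sugar_name, config = res$absolute_config,
                      ring = res$ring_form, anomer = res$anomer)
    codes[k] <- rc$ccd_code
    is_donor <- any(vapply(graph$linkages, function(l) l$donor_index == k, TRUE))
    if (is_donor && !rc$auto_removed) {
      # ketose donor: AF3 does not remove the leaving oxygen by default;
      # ship an edited component with O2 (and its hydroxyl H) deleted
      if (is.null(edited_for[[rc$ccd_code]])) {
        comp <- ccd_component(rc$ccd_code)
        edited <- strip_leaving_atoms(comp, rc$leaving_atom,
                                      reserved = names(user_ccd))
        edited_for[[rc$ccd_code]] <- edited$code
        user_ccd[[edited$code]] <- write_component_cif(edited)
      }
      codes[k] <- edited_for[[rc$ccd_code]]
    }
  }
  pairs <- list()
  for (l in graph$linkages) {
    don_def <- .sugar_def(graph$residues[[l$donor_index]]$sugar_name)
    pairs[[length(pairs) + 1L]] <- list(
      first = list(entity = entity, residue = l$acceptor_index,
                   atom = paste0("O", l$acceptor_position)),
      second = list(entity = entity, residue = l$donor_index,
                    atom = don_def$anomeric_carbon))
  }
  # modification components appended after the sugars, in residue order
  idx <- n
  for (k in seq_len(n)) {
    res <- graph$residues[[k]]
    mods <- res$modifications
    if (!length(mods)) next
    mods <- mods[order(vapply(mods, function(m) m$position, 0))]
    for (m in mods) {
      idx <- idx + 1L
      plan <- plan_modification_bond(res$sugar_name, m$position, m$mod_name)
      use_code <- plan$mod_code
      if (length(plan$strip)) {
        if (is.null(edited_for[[plan$mod_code]])) {
          comp <- ccd_component(plan$mod_code)
          edited <- strip_leaving_atoms(comp, plan$strip,
                                        reserved = names(user_ccd))
          edited_for[[plan$mod_code]] <- edited$code
          user_ccd[[edited$code]] <- write_component_cif(edited)
        }
        use_code <- edited_for[[plan$mod_code]]
      }
      codes <- c(codes, use_code)
      pairs[[length(pairs) + 1L]] <- list(
        first = list(entity = entity, residue = k, atom = plan$sugar_atom),
        second = list(entity = entity, residue = idx,
                      atom = plan$bond_atom_on_mod))
    }
  }
  list(graph = graph, codes = codes, pairs = pairs, user_ccd = user_ccd)
}

#' Emit the bondedAtomPairs of a glycan
#'
#' One pair per glycosidic linkage (acceptor hydroxyl oxygen first, donor
#' anomeric carbon second, indices following the canonical residue
#' numbering) plus one pair per hydroxyl modification, i.e. exactly
#' (residues - 1 + modifications) pairs.
#'
#' @param graph A valid \code{glycan_graph}.
#' @param entity Entity id used in the pairs.
#' @return List of pairs, each \code{list(first =, second =)} with
#'   \code{(entity, residue, atom)} triples.
#' @export
#' @examples
#' g2 <- template_glycan("G2")
#' emit_glycan_bonds(g2, "NG")[[2]]  # ((NG,2,O4),(NG,3,C1))
emit_glycan_bonds <- function(graph, entity = "NG") {
  .compile_glycan(graph, entity)$pairs
}

#' Add a glycan entity to a job
#'
#' Compiles the topology (codes, bonds, required userCCD edits) and, when
#' an attachment is given, either emits the aglycone bond as a
#' bondedAtomPair (default) or records a protein modification
#' (\code{strategy = "ptm"}).
#'
#' @param job An \code{af3_job}.
#' @param id Entity id for the glycan (e.g. \code{"NG"}).
#' @param glycan A \code{glycan_graph} or IUPAC-condensed text.
#' @param attachment Optional \code{\link{attachment_spec}}.
#' @param strategy \code{"bap"} (bonded pair) or \code{"ptm"}.
#' @return Updated job.
#' @export
add_glycan <- function(job, id, glycan, attachment = NULL,
                       strategy = c("bap", "ptm")) {
  strategy <- match.arg(strategy)
  if (is.character(glycan)) glycan <- parse_iupac_condensed(glycan)
  comp <- .compile_glycan(glycan, id)
  job <- .add_entity(job, list(id = id, kind = "ligand-chain",
                               ccd_codes = comp$codes, graph = comp$graph))
  job$bonded_atom_pairs <- c(job$bonded_atom_pairs, comp$pairs)
  for (nm in names(comp$user_ccd)) job$user_ccd[[nm]] <- comp$user_ccd[[nm]]
  if (!is.null(attachment)) {
    job <- attach_glycan(job, id, attachment, strategy = strategy)
  }
  job
}

#' Bond a glycan entity to its aglycone
#'
#' Emits the attachment pair ((partner, position, partner atom), (glycan,
#' 1, root anomeric carbon)); for \code{strategy = "ptm"} a protein
#' modification entry is recorded on the partner instead of a pair.
#'
#' @param job An \code{af3_job} already containing the glycan entity.
#' @param glycan_entity Glycan entity id.
#' @param attachment An \code{\link{attachment_spec}} (kind \code{"free"}
#'   is an error: nothing to attach).
#' @param strategy \code{"bap"} or \code{"ptm"}.
#' @return Updated job.
#' @export
attach_glycan <- function(job, glycan_entity, attachment,
                          strategy = c("bap", "ptm")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(attachment, "attachment_spec"))
  if (attachment$kind == "free") {
    stop("attachment kind 'free' has nothing to attach", call. = FALSE)
  }
  ids <- .job_entity_ids(job)
  gi <- match(glycan_entity, ids)
  pi_ <- match(attachment$partner_entity, ids)
  if (is.na(gi) || is.na(pi_)) {
    stop("attachment references unknown entity", call. = FALSE)
  }
  ent <- job$entities[[gi]]
  root_res <- ent$graph$residues[[ent$graph$root_index]]
  root_def <- .sugar_def(root_res$sugar_name)
  root_atom <- if (is.na(root_def$anomeric_carbon)) "C1"
               else root_def$anomeric_carbon
  if (strategy == "ptm") {
    part <- job$entities[[pi_]]
    if (part$kind != "protein") {
      stop("ptm strategy requires a protein partner", call. = FALSE)
    }
    part$ptms <- c(part$ptms, list(list(
      ptmType = paste0("CCD_", ent$ccd_codes[1]),
      ptmPosition = attachment$partner_residue)))
    job$entities[[pi_]] <- part
    return(job)
  }
  add_bond(job,
           attachment$partner_entity, attachment$partner_residue,
           attachment$partner_atom,
           glycan_entity, 1L, root_atom)
}

# atom names available in a component code, or NULL when unknown
.component_atoms_for_code <- function(job, code) {
  if (!is.null(job$user_ccd[[code]])) {
    return(load_component_cif(job$user_ccd[[code]])$atoms$name)
  }
  comp <- tryCatch(ccd_component(code), error = function(e) NULL)
  if (is.null(comp)) NULL else comp$atoms$name
}

# standard amino-acid atoms accepted in protein-side bond endpoints
.PROTEIN_ATOMS <- c("N", "CA", "C", "O", "CB", "CG", "CG1", "CG2", "CD",
                    "CD1", "CD2", "CE", "CE1", "CE2", "CZ", "ND1", "ND2",
                    "NE", "NE1", "NE2", "NZ", "OG", "OG1", "OD1", "OD2",
                    "OE1", "OE2", "OH", "SD", "SG", "OXT")

#' Validate an AF3 job
#'
#' Reporting operation: empty list iff the job invariants hold.  Issue
#' categories: \code{duplicate-id}, \code{dangling-pair},
#' \code{bad-atom-name}, \code{missing-userCCD}.
#'
#' @param job An \code{af3_job}.
#' @return List of issues, each \code{list(category =, message =)}.
#' @export
validate_job <- function(job) {
  issues <- list()
  flag <- function(category, message) {
    issues[[length(issues) + 1L]] <<- list(category = category,
                                           message = message)
  }
  ids <- .job_entity_ids(job)
  if (anyDuplicated(ids)) {
    flag("duplicate-id", paste("duplicate entity id",
                               ids[duplicated(ids)][1]))
  }
  for (p in job$bonded_atom_pairs) {
    for (endp in list(p$first, p$second)) {
      ei <- match(endp$entity, ids)
      if (is.na(ei)) {
        flag("dangling-pair", paste("pair references unknown entity",
                                    endp$entity))
        next
      }
      ent <- job$entities[[ei]]
      nres <- switch(ent$kind,
                     protein = nchar(ent$sequence),
                     `ligand-chain` = length(ent$ccd_codes),
                     ion = 1L)
      if (endp$residue < 1 || endp$residue > nres) {
        flag("dangling-pair",
             sprintf("pair references residue %d of entity %s (size %d)",
                     endp$residue, endp$entity, nres))
        next
      }
      if (ent$kind == "protein") {
        if (!endp$atom %in% .PROTEIN_ATOMS) {
          flag("bad-atom-name",
               sprintf("atom %s is not a standard amino-acid atom", endp$atom))
        }
      } else {
        code <- ent$ccd_codes[endp$residue]
        atoms <- .component_atoms_for_code(job, code)
        if (!is.null(atoms) && !endp$atom %in% atoms) {
          flag("bad-atom-name",
               sprintf("atom %s not found in component %s", endp$atom, code))
        }
      }
    }
  }
  # ketose donors must carry an edited component in userCCD
  for (ent in job$entities) {
    if (is.null(ent$graph)) next
    g <- ent$graph
    for (l in g$linkages) {
      don <- g$residues[[l$donor_index]]
      rc <- resolve_ccd(don$sugar_name, config = don$absolute_config,
                        ring = don$ring_form, anomer = don$anomer)
      if (rc$auto_removed) next
      used <- ent$ccd_codes[l$donor_index]
      if (is.null(job$user_ccd[[used]])) {
        flag("missing-userCCD",
             sprintf(paste("residue %d (%s) donates through %s but no edited",
                           "component removing %s is present in userCCD"),
                     l$donor_index, don$sugar_name, rc$ccd_code,
                     rc$leaving_atom))
      }
    }
  }
  issues
}

#' Assemble a complete job from a declarative description
#'
#' @param spec List with optional elements \code{name}, \code{seeds},
#'   \code{proteins} (each \code{list(id, sequence, ptms)}), \code{glycans}
#'   (each \code{list(id, glycan, attachment, strategy)}), \code{ions},
#'   \code{ligands} (block chains), and \code{bonds} (each a 6-element
#'   list: entity1, residue1, atom1, entity2, residue2, atom2).
#' @return A validated \code{af3_job} (errors aggregate all issues).
#' @export
build_job <- function(spec) {
  job <- af3_job(spec$name %||% "job",
                 model_seeds = spec$seeds %||% 1L)
  for (p in spec$proteins %||% list()) {
    job <- add_protein(job, p$id, p$sequence, p$ptms %||% list())
  }
  for (lg in spec$ligands %||% list()) {
    job <- add_ligand_chain(job, lg$id, lg$codes)
  }
  for (io in spec$ions %||% list()) job <- add_ion(job, io$id, io$code)
  for (g in spec$glycans %||% list()) {
    job <- add_glycan(job, g$id, g$glycan, attachment = g$attachment,
                      strategy = g$strategy %||% "bap")
  }
  for (b in spec$bonds %||% list()) {
    job <- do.call(add_bond, c(list(job), b))
  }
  issues <- validate_job(job)
  if (length(issues)) {
    stop("job validation failed:\n",
         paste(vapply(issues, function(i)
           paste0("  [", i$category, "] ", i$message), ""), collapse = "\n"),
         call. = FALSE)
  }
  job
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a job as AF3 input JSON (format version 2)
#'
#' Canonical serialization: dialect marker, stable key order, 1-based
#' residue indices, UTF-8; identical jobs serialize to identical bytes.
#'
#' @param job An \code{af3_job}.
#' @param path Optional output file.
#' @return JSON text (invisibly when written to a file).
#' @export
write_af3_json <- function(job, path = NULL) {
  seqs <- lapply(job$entities, function(ent) {
    if (ent$kind == "protein") {
      block <- list(id = ent$id, sequence = ent$sequence)
      if (length(ent$ptms)) block$modifications <- ent$ptms
      list(protein = block)
    } else {
      list(ligand = list(id = ent$id, ccdCodes = as.list(ent$ccd_codes)))
    }
  })
  doc <- list(dialect = "alphafold3", version = 2L, name = job$name,
              modelSeeds = as.list(job$model_seeds), sequences = seqs)
  if (length(job$bonded_atom_pairs)) {
    doc$bondedAtomPairs <- lapply(job$bonded_atom_pairs, function(p) {
      list(list(p$first$entity, p$first$residue, p$first$atom),
           list(p$second$entity, p$second$residue, p$second$atom))
    })
  }
  if (length(job$user_ccd)) {
    doc$userCCD <- paste(unlist(job$user_ccd[order(names(job$user_ccd))]),
                         collapse = "\n")
  }
  text <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  text <- paste0(as.character(text), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

#' @export
print.af3_job <- function(x, ...) {
  cat(sprintf("<af3_job> '%s': %d entities, %d bonded pairs, %d userCCD block%s\n",
              x$name, length(x$entities), length(x$bonded_atom_pairs),
              length(x$user_ccd), if (length(x$user_ccd) == 1) "" else "s"))
  for (e in x$entities) {
    desc <- switch(e$kind,
                   protein = sprintf("protein (%d aa)", nchar(e$sequence)),
                   `ligand-chain` = sprintf("ligand [%s]",
                                            paste(e$ccd_codes, collapse = ",")),
                   ion = sprintf("ion %s", e$ccd_codes))
    cat("  ", e$id, ": ", desc, "\n", sep = "")
  }
  invisible(x)
}
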