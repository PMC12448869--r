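# Chemical components (CCD entries): in-memory representation, mmCIF
# chem_comp dialect reader/writer, and leaving-atom remediation producing
# edited components for the AF3 userCCD field.

.new_component <- function(code, atoms, bonds) {
  stopifnot(!anyDuplicated(atoms$name))
  for (col in c("atom1", "atom2")) {
    bad <- !(bonds[[col]] %in% atoms$name)
    if (any(bad)) stop("bond references unknown atom ", bonds[[col]][bad][1],
                       call. = FALSE)
  }
  structure(list(code = code, atoms = atoms, bonds = bonds),
            class = "ccd_component")
}

#' @export
print.ccd_component <- function(x, ...) {
  cat(sprintf("<ccd_component> %s: %d atoms (%d heavy), %d bonds\n",
              x$code, nrow(x$atoms), sum(x$atoms$element != "H"), nrow(x$bonds)))
  invisible(x)
}

# heavy neighbors of an atom within a component
.component_neighbors <- function(component, atom) {
  b <- component$bonds
  c(b$atom2[b$atom1 == atom], b$atom1[b$atom2 == atom])
}

#' Build the packaged definition of a chemical component
#'
#' Components for registry sugars are generated from ideal ring geometry and
#' the registry substitution pattern (heavy atoms plus hydroxyl hydrogens);
#' lipid/assembly blocks and modification groups use the packaged synthetic
#' definitions.  Real PDBeChem chem_comp files load through
#' \code{\link{load_component_cif}} and are drop-in compatible.
#'
#' @param code CCD code, e.g. \code{"NAG"}, \code{"SIA"}, \code{"GOL"}.
#' @return A \code{ccd_component}.
#' @export
#' @examples
#' comp <- ccd_component("NAG")
#' c("C1", "O1", "O4") %in% comp$atoms$name
ccd_component <- function(code) {
  reg <- ccd_registry()
  # sugar codes: reverse lookup
  for (def in reg$sugars) {
    hit <- names(def$codes)[vapply(def$codes, identical, TRUE, code)]
    if (length(hit)) {
      parts <- strsplit(hit[1], ":", fixed = TRUE)[[1]]
      return(.component_from_sugar(def, config = parts[1], ring = parts[2],
                                   anomer = parts[3], code = code))
    }
  }
  if (!is.null(reg$blocks[[code]])) {
    return(.component_from_block(reg$blocks[[code]]))
  }
  for (m in reg$modifications) {
    if (identical(m$ccd_code, code)) return(.component_from_block(
      list(code = code, atoms = m$atoms, bonds = m$bonds)))
  }
  stop("no packaged component for code '", code, "'", call. = FALSE)
}

# sugar component: heavy atoms from the synthetic residue builder, anomeric
# hydroxyl flagged as the leaving atom, hydroxyl hydrogens added.
.component_from_sugar <- function(def, config, ring, anomer, code) {
  xyz <- build_residue(def$sugar, anomer = anomer, config = config)
  atoms <- data.frame(name = xyz$name, element = xyz$element,
                      x = xyz$x, y = xyz$y, z = xyz$z,
                      leaving = "N", stringsAsFactors = FALSE)
  atoms$leaving[atoms$name == def$leaving_atom] <- "Y"
  bonds <- attr(xyz, "bonds")
  # hydroxyl hydrogens: one H on every oxygen with a single heavy neighbor
  comp0 <- .new_component(code, atoms, bonds)
  hyd <- list()
  for (i in which(atoms$element == "O")) {
    nm <- atoms$name[i]
    if (length(.component_neighbors(comp0, nm)) == 1L) {
      hname <- paste0("H", nm)
      dirv <- c(atoms$x[i], atoms$y[i], atoms$z[i])
      nrm <- sqrt(sum(dirv^2)); if (nrm < 1e-8) { dirv <- c(1, 0, 0); nrm <- 1 }
      hyd[[length(hyd) + 1L]] <- list(
        name = hname,
        x = atoms$x[i] + 0.96 * dirv[1] / nrm,
        y = atoms$y[i] + 0.96 * dirv[2] / nrm,
        z = atoms$z[i] + 0.96 * dirv[3] / nrm,
        parent = nm)
    }
  }
  for (h in hyd) {
    atoms <- rbind(atoms, data.frame(name = h$name, element = "H",
                                     x = h$x, y = h$y, z = h$z, leaving = "N"))
    bonds <- rbind(bonds, data.frame(atom1 = h$parent, atom2 = h$name,
                                     order = "SING"))
  }
  .new_component(code, atoms, bonds)
}

# block component: registry atom/bond lists with generated spread-out
# coordinates (placeholder chain geometry; used for atom-name validation
# and userCCD emission, not for ring analysis).
.component_from_block <- function(blk) {
  nm <- names(blk$atoms)
  n <- length(nm)
  t <- seq_len(n)
  atoms <- data.frame(name = nm, element = unname(blk$atoms),
                      x = round(1.25 * t, 3),
                      y = round(0.5 * (t %% 2), 3),
                      z = rep(0, n),
                      leaving = "N", stringsAsFactors = FALSE)
  if (!is.null(blk$leaving)) atoms$leaving[atoms$name %in% blk$leaving] <- "Y"
  bonds <- do.call(rbind, lapply(blk$bonds, function(b)
    data.frame(atom1 = b[1], atom2 = b[2], order = "SING")))
  .new_component(blk$code, atoms, bonds)
}

#' Remove leaving atoms from a component
#'
#' Removes the named atoms together with any hydrogens bonded only to them,
#' prunes the affected bonds, and assigns a deterministic new code (original
#' code + \code{"X"}, then \code{"X2"}, \code{"X3"} on collision with the
#' supplied code set).  Ring atoms are protected.
#'
#' @param component A \code{ccd_component}.
#' @param atom_names Atoms to strip; empty set returns the component
#'   unchanged (same code).
#' @param reserved Codes the new code must not collide with.
#' @return The edited \code{ccd_component}; attribute \code{"removed"} lists
#'   all atoms removed (named atoms plus co-removed hydrogens).
#' @export
#' @examples
#' sia <- ccd_component("SIA")
#' edited <- strip_leaving_atoms(sia, "O2")
#' edited$code                          # "SIAX"
#' "O2" %in% edited$atoms$name          # FALSE
strip_leaving_atoms <- function(component, atom_names, reserved = character(0)) {
  stopifnot(inherits(component, "ccd_component"))
  if (!length(atom_names)) return(component)
  missing <- setdiff(atom_names, component$atoms$name)
  if (length(missing)) {
    stop("atom(s) not in component: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ring <- .component_ring_atoms(component)
  if (length(intersect(atom_names, ring))) {
    stop("refusing to strip ring atom(s): ",
         paste(intersect(atom_names, ring), collapse = ", "), call. = FALSE)
  }
  removed <- atom_names
  # co-remove hydrogens whose only bond partner is being removed
  for (h in component$atoms$name[component$atoms$element == "H"]) {
    nb <- .component_neighbors(component, h)
    if (length(nb) && all(nb %in% removed)) removed <- c(removed, h)
  }
  atoms <- component$atoms[!(component$atoms$name %in% removed), , drop = FALSE]
  bonds <- component$bonds[!(component$bonds$atom1 %in% removed |
                             component$bonds$atom2 %in% removed), , drop = FALSE]
  code <- .edited_code(component$code, reserved)
  out <- .new_component(code, atoms, bonds)
  attr(out, "removed") <- removed
  attr(out, "parent_code") <- component$code
  out
}

.edited_code <- function(code, reserved = character(0)) {
  reserved <- c(reserved, .all_registry_codes())
  cand <- paste0(code, "X")
  k <- 2L
  while (cand %in% reserved) {
    cand <- paste0(code, "X", k)
    k <- k + 1L
  }
  cand
}

.all_registry_codes <- function() {
  reg <- ccd_registry()
  codes <- unlist(lapply(reg$sugars, function(d) unlist(d$codes)), use.names = FALSE)
  c(codes, names(reg$blocks),
    vapply(reg$modifications, `[[`, "", "ccd_code"))
}

# ring atoms of a component: smallest cycle containing exactly one oxygen,
# via the bond graph; character(0) if acyclic.
.component_ring_atoms <- function(component) {
  heavy <- component$atoms$name[component$atoms$element != "H"]
  adj <- lapply(stats::setNames(heavy, heavy), function(a)
    intersect(.component_neighbors(component, a), heavy))
  # DFS cycle detection collecting one fundamental cycle set
  visited <- character(0); parent <- list(); ringset <- character(0)
  for (start in heavy) {
    if (start %in% visited) next
    stack <- list(list(node = start, from = NA))
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (top$node %in% visited) next
      visited <- c(visited, top$node)
      parent[[top$node]] <- top$from
      for (nb in adj[[top$node]]) {
        if (identical(nb, top$from)) next
        if (nb %in% visited) {
          # back edge: walk parents to recover the cycle
          path <- top$node
          cur <- top$node
          while (!is.na(parent[[cur]]) && !identical(cur, nb)) {
            cur <- parent[[cur]]
            path <- c(path, cur)
          }
          if (identical(cur, nb)) ringset <- union(ringset, path)
        } else {
          stack[[length(stack) + 1L]] <- list(node = nb, from = top$node)
        }
      }
    }
  }
  ringset
}

#' Write a component as mmCIF chem_comp text
#'
#' Emits the \code{_chem_comp_atom} (with ideal coordinates and the
#' \code{pdbx_leaving_atom_flag} column) and \code{_chem_comp_bond} loops in
#' stable field order, suitable for the AF3 \code{userCCD} field.
#' \code{load_component_cif(write_component_cif(c))} is the identity.
#'
#' @param component A \code{ccd_component}.
#' @return Single mmCIF string.
#' @export
write_component_cif <- function(component) {
  stopifnot(inherits(component, "ccd_component"))
  a <- component$atoms
  lines <- c(
    paste0("data_", component$code),
    "#",
    paste0("_chem_comp.id ", component$code),
    "_chem_comp.pdbx_type HETAIN",
    "#",
    "loop_",
    "_chem_comp_atom.comp_id",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "_chem_comp_atom.charge",
    "_chem_comp_atom.pdbx_leaving_atom_flag",
    "_chem_comp_atom.pdbx_model_Cartn_x_ideal",
    "_chem_comp_atom.pdbx_model_Cartn_y_ideal",
    "_chem_comp_atom.pdbx_model_Cartn_z_ideal",
    sprintf("%s %s %s 0 %s %.3f %.3f %.3f",
            component$code, a$name, a$element, a$leaving, a$x, a$y, a$z))
  if (nrow(component$bonds)) {
    b <- component$bonds
    lines <- c(lines,
      "#",
      "loop_",
      "_chem_comp_bond.comp_id",
      "_chem_comp_bond.atom_id_1",
      "_chem_comp_bond.atom_id_2",
      "_chem_comp_bond.value_order",
      sprintf("%s %s %s %s", component$code, b$atom1, b$atom2, b$order))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# split an mmCIF data line into fields, honoring single/double quotes
.cif_fields <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", line)[[1]]
  f <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", f)
}

#' Load a component from mmCIF chem_comp text
#'
#' Faithful reader for the chem_comp dialect used by the CCD and by
#' \code{\link{write_component_cif}}: requires \code{_chem_comp_atom} and
#' \code{_chem_comp_bond} loops; preserves leaving-atom flags.  Coordinates
#' are taken from the ideal-coordinate columns when present, otherwise from
#' the model-coordinate columns.
#'
#' @param text mmCIF text (single string or character vector of lines).
#' @return A \code{ccd_component}.
#' @export
load_component_cif <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  code <- NA_character_
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    l <- lines[i]
    if (startsWith(l, "data_")) {
      code <- sub("^data_", "", l)
      i <- i + 1L
    } else if (startsWith(l, "_chem_comp.id")) {
      f <- .cif_fields(l)
      if (length(f) >= 2) code <- f[2]
      i <- i + 1L
    } else if (identical(l, "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, lines[i])
        i <- i + 1L
      }
      if (!length(tags)) stop("malformed loop: no tags", call. = FALSE)
      rows <- list()
      while (i <= n && !startsWith(lines[i], "_") && !identical(lines[i], "loop_") &&
             !startsWith(lines[i], "data_") && !startsWith(lines[i], "#")) {
        f <- .cif_fields(lines[i])
        if (length(f) != length(tags)) {
          stop("malformed loop row: ", length(f), " fields for ",
               length(tags), " tags", call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- f
        i <- i + 1L
      }
      cat_name <- sub("\\..*$", "", tags[1])
      tbl <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
      names(tbl) <- sub("^[^.]*\\.", "", tags)
      loops[[cat_name]] <- tbl
    } else {
      i <- i + 1L
    }
  }
  at <- loops[["_chem_comp_atom"]]
  bd <- loops[["_chem_comp_bond"]]
  if (is.null(at) || is.null(bd)) {
    stop("component cif lacks _chem_comp_atom or _chem_comp_bond loop",
         call. = FALSE)
  }
  pick <- function(tbl, candidates) {
    for (c1 in candidates) if (c1 %in% names(tbl)) return(tbl[[c1]])
    rep(NA, nrow(tbl))
  }
  atoms <- data.frame(
    name = at$atom_id,
    element = at$type_symbol,
    x = as.numeric(pick(at, c("pdbx_model_Cartn_x_ideal", "model_Cartn_x"))),
    y = as.numeric(pick(at, c("pdbx_model_Cartn_y_ideal", "model_Cartn_y"))),
    z = as.numeric(pick(at, c("pdbx_model_Cartn_z_ideal", "model_Cartn_z"))),
    leaving = pick(at, "pdbx_leaving_atom_flag"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$name)) stop("duplicate atom names", call. = FALSE)
  bonds <- data.frame(atom1 = bd$atom_id_1, atom2 = bd$atom_id_2,
                      order = if ("value_order" %in% names(bd)) bd$value_order
                              else "SING",
                      stringsAsFactors = FALSE)
  .new_component(if (is.na(code)) at$comp_id[1] else code, atoms, bonds)
}

#' Plan a hydroxyl-modification bond
#'
#' For sulfation, phosphorylation, acetylation or methylation at a sugar
#' hydroxyl, the sugar's bridging oxygen O\code{<position>} is retained and
#' bonded to the modification component's bonding atom; the modification's
#' own leaving oxygen(s) must be stripped manually (same principle as the
#' glycosidic leaving atom).
#'
#' @param sugar_name Registry sugar token.
#' @param position Ring position carrying the modification.
#' @param mod_name One of \code{"sulfate"}, \code{"phosphate"},
#'   \code{"acetyl"}, \code{"methyl"}.
#' @return List with \code{sugar_atom} (bridging O), \code{mod_code},
#'   \code{bond_atom_on_mod}, \code{strip} (atoms to remove from the
#'   modification component) and \code{edited_code}.
#' @export
#' @examples
#' plan_modification_bond("GlcNAc", 6, "sulfate")
plan_modification_bond <- function(sugar_name, position, mod_name) {
  def <- .sugar_def(sugar_name)
  mod <- ccd_registry()$modifications[[mod_name]]
  if (is.null(mod)) stop("unknown modification '", mod_name, "'", call. = FALSE)
  if (!(position %in% .sugar_acceptor_positions(def))) {
    stop("position ", position, " not modifiable on ", sugar_name, call. = FALSE)
  }
  edited <- if (length(mod$leaving_atoms_on_mod))
    .edited_code(mod$ccd_code) else mod$ccd_code
  list(sugar_atom = paste0("O", position),
       mod_code = mod$ccd_code,
       bond_atom_on_mod = mod$bond_atom_on_mod,
       strip = mod$leaving_atoms_on_mod,
       edited_code = edited)
}
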