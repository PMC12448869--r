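# Stereochemistry validation of predicted glycan structures: bond
# inference, ring perception, pucker analysis, chirality checks against
# ideal reference builds, valence sanity, and glycosidic torsions.
# Hydrogens are ignored throughout.

.COV_RADII <- c(C = 0.77, N = 0.75, O = 0.73, P = 1.06, S = 1.02,
                F = 0.71, H = 0.37)

#' Infer heavy-atom bonds from coordinates
#'
#' Two heavy atoms are bonded when their distance is below the sum of their
#' covalent radii plus a 0.4 Angstrom tolerance.  Symmetric, no self-bonds;
#' hydrogens are excluded.
#'
#' @param model A \code{structure_model}.
#' @param tol Tolerance added to the covalent-radius sum (Angstrom).
#' @return data.frame with one row per bond: \code{i}, \code{j} (row indices
#'   into the heavy-atom subset returned as attribute \code{"atoms"}),
#'   entity/residue/atom identifiers for both partners, and \code{dist}.
#' @export
infer_bonds <- function(model, tol = 0.4) {
  a <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  n <- nrow(a)
  if (n < 2) {
    out <- data.frame(i = integer(0), j = integer(0))
    attr(out, "atoms") <- a
    return(out)
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .COV_RADII[a$element]
  rad[is.na(rad)] <- 0.77
  d <- as.matrix(stats::dist(xyz))
  lim <- outer(rad, rad, "+") + tol
  hit <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  out <- data.frame(
    i = hit[, 1], j = hit[, 2],
    entity1 = a$entity[hit[, 1]], residue1 = a$residue[hit[, 1]],
    atom1 = a$atom[hit[, 1]],
    entity2 = a$entity[hit[, 2]], residue2 = a$residue[hit[, 2]],
    atom2 = a$atom[hit[, 2]],
    dist = d[hit], stringsAsFactors = FALSE)
  attr(out, "atoms") <- a
  out
}

# adjacency list (atom names) within one residue, plus cross-residue
# neighbours, from an inferred bond table
.residue_adjacency <- function(bonds, entity, residue) {
  sel1 <- bonds$entity1 == entity & bonds$residue1 == residue
  sel2 <- bonds$entity2 == entity & bonds$residue2 == residue
  intra <- bonds[sel1 & sel2, , drop = FALSE]
  adj <- list()
  addp <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (k in seq_len(nrow(intra))) addp(intra$atom1[k], intra$atom2[k])
  cross <- bonds[xor(sel1, sel2), , drop = FALSE]
  adj_cross <- list()
  for (k in seq_len(nrow(cross))) {
    if (cross$entity1[k] == entity && cross$residue1[k] == residue) {
      own <- cross$atom1[k]
      other <- cross[k, c("entity2", "residue2", "atom2")]
    } else {
      own <- cross$atom2[k]
      other <- cross[k, c("entity1", "residue1", "atom1")]
    }
    adj_cross[[own]] <- c(adj_cross[[own]], list(unname(unlist(other))))
  }
  list(intra = adj, cross = adj_cross)
}

#' Perceive the sugar ring of a residue
#'
#' Finds the 5- or 6-cycle containing exactly one oxygen among the
#' residue's heavy atoms and returns it ordered ring-oxygen first,
#' proceeding toward the anomeric carbon (the ring carbon neighbouring the
#' ring oxygen that carries an additional oxygen substituent).
#'
#' @param model A \code{structure_model}.
#' @param entity,residue Residue selector.
#' @param bonds Optional precomputed \code{\link{infer_bonds}} table.
#' @return Character vector of ordered ring atom names, or \code{NULL}
#'   (indeterminate: open-chain or no unique ring).
#' @export
perceive_ring <- function(model, entity, residue, bonds = NULL) {
  if (is.null(bonds)) bonds <- infer_bonds(model)
  adj <- .residue_adjacency(bonds, entity, residue)
  atoms <- names(adj$intra)
  if (length(atoms) < 5) return(NULL)
  elem <- function(a) {
    i <- which(model$atoms$entity == entity & model$atoms$residue == residue &
               model$atoms$atom == a)
    model$atoms$element[i[1]]
  }
  # depth-limited cycle search from each oxygen
  oxy <- atoms[vapply(atoms, elem, "") == "O"]
  cycles <- list()
  for (o in oxy) {
    paths <- list(o)
    for (depth in 1:6) {
      nxt <- list()
      for (p in paths) {
        last <- p[length(p)]
        for (nb in adj$intra[[last]]) {
          if (nb == o && length(p) >= 5) {
            key <- paste(sort(p), collapse = "|")
            cycles[[key]] <- p
          } else if (!(nb %in% p)) {
            nxt[[length(nxt) + 1L]] <- c(p, nb)
          }
        }
      }
      paths <- nxt
      if (!length(paths)) break
    }
  }
  cycles <- Filter(function(cy) {
    length(cy) %in% c(5L, 6L) && sum(vapply(cy, elem, "") == "O") == 1L
  }, cycles)
  if (length(cycles) != 1L) return(NULL)
  ring <- cycles[[1]]
  o <- ring[vapply(ring, elem, "") == "O"]
  i <- match(o, ring)
  ring <- c(ring[i:length(ring)], ring[seq_len(i - 1)])
  # orient toward the anomeric carbon: the O-neighbour in the ring with an
  # extra oxygen attachment (intra leaving O or cross-residue O)
  cand <- c(ring[2], ring[length(ring)])
  has_extra_o <- vapply(cand, function(a) {
    nb_o <- any(vapply(setdiff(adj$intra[[a]], ring), function(b)
      identical(elem(b), "O"), TRUE))
    nb_o || length(adj$cross[[a]]) > 0
  }, TRUE)
  anomeric <- if (has_extra_o[1] && !has_extra_o[2]) cand[1]
              else if (has_extra_o[2] && !has_extra_o[1]) cand[2]
              else cand[which.min(cand)]  # tie-break on name
  if (anomeric == ring[length(ring)]) ring <- c(ring[1], rev(ring[-1]))
  ring
}

# ring pucker report for one residue, or NULL
.residue_pucker <- function(model, entity, residue, bonds) {
  ring <- perceive_ring(model, entity, residue, bonds)
  if (is.null(ring)) return(NULL)
  coords <- t(vapply(ring, function(a) .atom_xyz(model, entity, residue, a),
                     numeric(3)))
  cp <- cremer_pople(coords)
  cls <- classify_pucker(cp$Q, cp$theta, cp$phi, ring_size = length(ring))
  list(ring_atoms = ring, Q = cp$Q, theta = cp$theta, phi = cp$phi,
       conformer = cls$label, margin = cls$margin, ambiguous = cls$ambiguous)
}

# signed chirality volume at a center given neighbour coordinates in fixed
# order: 3 neighbours -> det of edge vectors from the center; 4 -> signed
# tetrahedron volume of the neighbours themselves
.chirality_sign <- function(center, nbrs) {
  if (nrow(nbrs) == 3) {
    m <- sweep(nbrs, 2, center)
  } else {
    m <- sweep(nbrs[1:3, , drop = FALSE], 2, nbrs[4, ])
  }
  sign(det(m))
}

# reference neighbour names (sorted) of a stereocenter in a sugar's
# construction bond table
.reference_neighbors <- function(def, center) {
  ref <- build_residue(def$sugar, anomer = names(def$anomeric_orient)[1],
                       config = def$default_config)
  b <- attr(ref, "bonds")
  nb <- sort(unique(c(b$atom1[b$atom2 == center], b$atom2[b$atom1 == center])))
  list(ref = ref, neighbors = nb)
}

.xyz_of <- function(df, name) as.numeric(df[df$name == name, c("x", "y", "z")])

#' Check glycan stereocenters against the intended topology
#'
#' For each residue of the expected glycan graph, each stereocenter's
#' chirality (sign of the signed volume over its heavy-atom neighbours in
#' canonical name order) is compared against the same sign computed on the
#' registry's ideal build of the expected residue.  The anomeric center is
#' handled identically, with the glycosidic oxygen standing in for the
#' leaving hydroxyl, and is reported as ok/flipped.  Verdicts use heavy
#' atoms only; missing atoms make a center indeterminate, not fatal.
#'
#' @param model A \code{structure_model}.
#' @param graph The expected \code{glycan_graph} (canonical numbering is
#'   assumed to match the model's residue indices).
#' @param entity Entity id of the glycan in the model.
#' @param bonds Optional precomputed bond table.
#' @return A \code{stereo_report}: per-residue entries with
#'   \code{anomeric_verdict}, \code{epimer_mismatches},
#'   \code{valence_flags}, \code{pucker}; plus a \code{findings}
#'   data.frame aggregating all defects.
#' @export
check_stereocenters <- function(model, graph, entity = "NG", bonds = NULL) {
  graph <- .canonicalize_graph(graph)
  if (is.null(bonds)) bonds <- infer_bonds(model)
  valence <- check_valence(model, bonds)
  # a single retained leaving oxygen produces several raw valence states at
  # one junction (the flagged carbon plus its crowded oxygens); report the
  # carbon-level flag and fold in oxygen flags adjacent to it
  if (nrow(valence)) {
    carbons <- valence[valence$flag == "retained-leaving-oxygen", , drop = FALSE]
    near_flagged_c <- function(vrow) {
      sel <- (bonds$entity1 == vrow$entity & bonds$residue1 == vrow$residue &
                bonds$atom1 == vrow$atom) |
             (bonds$entity2 == vrow$entity & bonds$residue2 == vrow$residue &
                bonds$atom2 == vrow$atom)
      nb <- rbind(
        data.frame(entity = bonds$entity2, residue = bonds$residue2,
                   atom = bonds$atom2)[sel & bonds$atom1 == vrow$atom &
                                         bonds$entity1 == vrow$entity &
                                         bonds$residue1 == vrow$residue, ],
        data.frame(entity = bonds$entity1, residue = bonds$residue1,
                   atom = bonds$atom1)[sel & bonds$atom2 == vrow$atom &
                                         bonds$entity2 == vrow$entity &
                                         bonds$residue2 == vrow$residue, ])
      any(paste(nb$entity, nb$residue, nb$atom) %in%
            paste(carbons$entity, carbons$residue, carbons$atom))
    }
    # a crowded retained oxygen can also sit within bonding distance of an
    # adjacent carbon (the sialic carboxylate): attribute the defect to the
    # junction carbon (the one with a cross-residue bond)
    atom_key <- function(e, r, a) paste(e, r, a)
    cross <- bonds[!(bonds$entity1 == bonds$entity2 &
                       bonds$residue1 == bonds$residue2), , drop = FALSE]
    cross_keys <- c(atom_key(cross$entity1, cross$residue1, cross$atom1),
                    atom_key(cross$entity2, cross$residue2, cross$atom2))
    bonded_keys <- function(e, r, a) {
      s1 <- bonds$entity1 == e & bonds$residue1 == r & bonds$atom1 == a
      s2 <- bonds$entity2 == e & bonds$residue2 == r & bonds$atom2 == a
      c(atom_key(bonds$entity2[s1], bonds$residue2[s1], bonds$atom2[s1]),
        atom_key(bonds$entity1[s2], bonds$residue1[s2], bonds$atom1[s2]))
    }
    if (nrow(carbons) > 1) {
      ckeys <- atom_key(carbons$entity, carbons$residue, carbons$atom)
      has_cross <- ckeys %in% cross_keys
      drop_c <- vapply(seq_len(nrow(carbons)), function(i) {
        if (has_cross[i]) return(FALSE)
        nb <- bonded_keys(carbons$entity[i], carbons$residue[i],
                          carbons$atom[i])
        any(ckeys[has_cross] %in% nb)
      }, TRUE)
      dropped <- ckeys[drop_c]
    } else {
      dropped <- character(0)
    }
    keep <- vapply(seq_len(nrow(valence)), function(i) {
      v <- valence[i, ]
      if (v$flag == "overbonded-oxygen" && near_flagged_c(v)) return(FALSE)
      if (v$flag == "retained-leaving-oxygen" &&
          atom_key(v$entity, v$residue, v$atom) %in% dropped) return(FALSE)
      TRUE
    }, TRUE)
    valence <- valence[keep, , drop = FALSE]
  }
  entries <- list()
  findings <- list()
  note <- function(residue, center, category) {
    findings[[length(findings) + 1L]] <<-
      data.frame(entity = entity, residue = residue, center = center,
                 category = category, stringsAsFactors = FALSE)
  }
  for (k in seq_along(graph$residues)) {
    res <- graph$residues[[k]]
    def <- .sugar_def(res$sugar_name)
    expected_code <- tryCatch(
      resolve_ccd(res$sugar_name, config = res$absolute_config,
                  ring = res$ring_form, anomer = res$anomer)$ccd_code,
      error = function(e) NA_character_)
    entry <- list(residue = k, sugar = res$sugar_name,
                  expected_code = expected_code,
                  anomeric_verdict = "indeterminate",
                  epimer_mismatches = character(0),
                  valence_flags = character(0), pucker = NULL)
    if (def$class %in% c("open", "block")) {
      entry$anomeric_verdict <- "not-applicable"
      entries[[k]] <- entry
      next
    }
    # reference build of the *expected* residue (expected anomer/config)
    ref <- build_residue(res$sugar_name, anomer = res$anomer,
                         config = res$absolute_config)
    refb <- attr(ref, "bonds")
    adj <- .residue_adjacency(bonds, entity, k)
    for (center in .sugar_stereocenters(def)) {
      nb_ref <- sort(unique(c(refb$atom1[refb$atom2 == center],
                              refb$atom2[refb$atom1 == center])))
      ref_sign <- .chirality_sign(.xyz_of(ref, center),
                                  t(vapply(nb_ref, function(a) .xyz_of(ref, a),
                                           numeric(3))))
      is_anomeric <- identical(center, def$anomeric_carbon)
      # model neighbour coordinates in the same name order; the leaving
      # oxygen slot may be filled by a cross-residue glycosidic oxygen
      nb_model <- lapply(nb_ref, function(a) {
        if (is_anomeric && identical(a, def$leaving_atom)) {
          # the glycosidic oxygen fills the leaving-hydroxyl slot; prefer it
          # over a (pathologically) retained intra-residue leaving oxygen
          cr <- adj$cross[[center]]
          if (length(cr)) {
            other <- cr[[1]]
            return(.atom_xyz(model, other[1], as.integer(other[2]), other[3]))
          }
        }
        .atom_xyz(model, entity, k, a)
      })
      cpos <- .atom_xyz(model, entity, k, center)
      if (is.null(cpos) || any(vapply(nb_model, is.null, TRUE))) {
        if (is_anomeric) entry$anomeric_verdict <- "indeterminate"
        next
      }
      mod_sign <- .chirality_sign(cpos, do.call(rbind, nb_model))
      ok <- isTRUE(mod_sign == ref_sign)
      if (is_anomeric) {
        entry$anomeric_verdict <- if (ok) "ok" else "flipped"
        if (!ok) note(k, center, "anomer-flip")
      } else if (!ok) {
        entry$epimer_mismatches <- c(entry$epimer_mismatches, center)
        note(k, center, "epimer-flip")
      }
    }
    vf <- valence[valence$entity == entity & valence$residue == k, , drop = FALSE]
    if (nrow(vf)) {
      entry$valence_flags <- vf$flag
      for (fi in seq_len(nrow(vf))) note(k, vf$atom[fi], vf$flag[fi])
    }
    if (def$ring != "open") {
      entry$pucker <- .residue_pucker(model, entity, k, bonds)
    }
    entries[[k]] <- entry
  }
  findings <- if (length(findings)) do.call(rbind, findings)
              else data.frame(entity = character(0), residue = integer(0),
                              center = character(0), category = character(0))
  structure(list(entity = entity, entries = entries, findings = findings),
            class = "stereo_report")
}

#' @export
print.stereo_report <- function(x, ...) {
  nf <- nrow(x$findings)
  cat(sprintf("<stereo_report> entity %s: %d residue%s, %d finding%s\n",
              x$entity, length(x$entries),
              if (length(x$entries) == 1) "" else "s",
              nf, if (nf == 1) "" else "s"))
  for (e in x$entries) {
    pk <- if (is.null(e$pucker)) "" else sprintf(" pucker=%s", e$pucker$conformer)
    cat(sprintf("  %2d %-7s anomeric=%s%s%s%s\n", e$residue, e$sugar,
                e$anomeric_verdict,
                if (length(e$epimer_mismatches))
                  paste0(" epimer![", paste(e$epimer_mismatches, collapse = ","), "]")
                else "",
                if (length(e$valence_flags))
                  paste0(" valence![", paste(unique(e$valence_flags), collapse = ","), "]")
                else "",
                pk))
  }
  invisible(x)
}

#' Flag chemically implausible valence states
#'
#' Flags oxygens with more than two heavy-atom neighbours and carbons
#' bonded to three or more oxygens (the signature of a retained leaving
#' oxygen at a glycosidic junction).
#'
#' @param model A \code{structure_model}.
#' @param bonds Optional precomputed bond table.
#' @return data.frame: entity, residue, atom, flag, detail.
#' @export
check_valence <- function(model, bonds = NULL) {
  if (is.null(bonds)) bonds <- infer_bonds(model)
  a <- attr(bonds, "atoms")
  flags <- list()
  if (!nrow(bonds)) {
    return(data.frame(entity = character(0), residue = integer(0),
                      atom = character(0), flag = character(0),
                      detail = character(0)))
  }
  deg_o <- integer(nrow(a))       # heavy neighbours of each atom
  o_nbrs <- integer(nrow(a))      # oxygen neighbours of each atom
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    deg_o[i] <- deg_o[i] + 1L; deg_o[j] <- deg_o[j] + 1L
    if (a$element[j] == "O") o_nbrs[i] <- o_nbrs[i] + 1L
    if (a$element[i] == "O") o_nbrs[j] <- o_nbrs[j] + 1L
  }
  for (i in seq_len(nrow(a))) {
    if (a$element[i] == "O" && deg_o[i] > 2L) {
      flags[[length(flags) + 1L]] <- data.frame(
        entity = a$entity[i], residue = a$residue[i], atom = a$atom[i],
        flag = "overbonded-oxygen",
        detail = sprintf("%d heavy neighbours", deg_o[i]))
    }
    if (a$element[i] == "C" && o_nbrs[i] >= 3L) {
      flags[[length(flags) + 1L]] <- data.frame(
        entity = a$entity[i], residue = a$residue[i], atom = a$atom[i],
        flag = "retained-leaving-oxygen",
        detail = sprintf("carbon bonded to %d oxygens", o_nbrs[i]))
    }
  }
  if (!length(flags)) {
    return(data.frame(entity = character(0), residue = integer(0),
                      atom = character(0), flag = character(0),
                      detail = character(0)))
  }
  do.call(rbind, flags)
}

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * .unit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Glycosidic torsion angles at a linkage
#'
#' phi = ring O - anomeric C - glycosidic O - acceptor C;
#' psi = anomeric C - glycosidic O - acceptor C - preceding acceptor C;
#' omega = glycosidic O - C6 - C5 - ring O, reported for 1->6 (and 2->6)
#' linkages only.  Degrees in (-180, 180].
#'
#' @param model A \code{structure_model} of the glycan.
#' @param graph Expected \code{glycan_graph}.
#' @param linkage A \code{glycosidic_linkage} from the graph (canonical
#'   indices).
#' @param entity Entity id.
#' @return List with \code{phi}, \code{psi} and (for 6-linkages)
#'   \code{omega}; absent atoms yield NULL components.
#' @export
glycosidic_torsions <- function(model, graph, linkage, entity = "NG") {
  graph <- .canonicalize_graph(graph)
  don <- linkage$donor_index
  acc <- linkage$acceptor_index
  pos <- linkage$acceptor_position
  don_def <- .sugar_def(graph$residues[[don]]$sugar_name)
  ring_o <- don_def$ring_atoms[1]
  ac <- don_def$anomeric_carbon
  ox <- paste0("O", pos)
  cx <- paste0("C", pos)
  cprev <- paste0("C", pos - 1)
  g <- function(res, atom, who = entity) .atom_xyz(model, who, res, atom)
  p <- list(g(don, ring_o), g(don, ac), g(acc, ox), g(acc, cx), g(acc, cprev))
  out <- list(phi = NULL, psi = NULL, omega = NULL)
  if (!any(vapply(p[1:4], is.null, TRUE))) {
    out$phi <- .dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
  }
  if (!any(vapply(p[2:5], is.null, TRUE))) {
    out$psi <- .dihedral(p[[2]], p[[3]], p[[4]], p[[5]])
  }
  if (pos == 6) {
    acc_def <- .sugar_def(graph$residues[[acc]]$sugar_name)
    q <- list(g(acc, "O6"), g(acc, "C6"), g(acc, "C5"),
              g(acc, acc_def$ring_atoms[1]))
    if (!any(vapply(q, is.null, TRUE))) {
      out$omega <- .dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    }
  }
  out
}
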