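# Glycan topology model: rooted tree of monosaccharide residues joined by
# glycosidic linkages.  The single source of truth for topology; serialized
# through the IUPAC-condensed grammar and the AF3 job emitter.

#' Construct a monosaccharide residue
#'
#' @param sugar_name Registry sugar token (e.g. \code{"GlcNAc"}, \code{"Neu5Ac"}).
#' @param anomer \code{"alpha"}, \code{"beta"}, or \code{"none"} (open-chain
#'   residues only).
#' @param config Absolute configuration \code{"D"}/\code{"L"}; default per
#'   SNFG convention (L for Fuc/IdoA, D otherwise).
#' @param ring \code{"pyranose"}, \code{"furanose"}, or \code{"open"};
#'   default per registry.
#' @param modifications List of \code{list(position =, mod_name =)} entries;
#'   \code{mod_name} one of sulfate, phosphate, acetyl, methyl.
#' @return An object of class \code{monosaccharide_residue}.
#' @export
#' @examples
#' monosaccharide_residue("Gal", "beta")
#' monosaccharide_residue("GlcNAc", "beta",
#'   modifications = list(list(position = 6, mod_name = "sulfate")))
monosaccharide_residue <- function(sugar_name, anomer = "beta", config = NULL,
                                   ring = NULL, modifications = list()) {
  def <- .sugar_def(sugar_name)
  if (is.null(config)) config <- def$default_config
  if (is.null(ring)) ring <- def$ring
  if (def$class == "open") anomer <- "none"
  if (anomer == "none" && def$class != "open") {
    stop("anomer 'none' is only valid for open-chain residues", call. = FALSE)
  }
  if (!anomer %in% c("alpha", "beta", "none")) {
    stop("anomer must be alpha, beta or none", call. = FALSE)
  }
  mods <- ccd_registry()$modifications
  valid_pos <- .sugar_acceptor_positions(def)
  for (m in modifications) {
    if (is.null(mods[[m$mod_name]])) {
      stop("unknown modification '", m$mod_name, "'", call. = FALSE)
    }
    if (!(m$position %in% valid_pos)) {
      stop("invalid modification position ", m$position, " for ", sugar_name,
           " (valid: ", paste(valid_pos, collapse = ","), ")", call. = FALSE)
    }
  }
  mod_pos <- vapply(modifications, function(m) m$position, 0)
  if (anyDuplicated(mod_pos)) {
    stop("duplicate modification position", call. = FALSE)
  }
  structure(list(sugar_name = sugar_name, absolute_config = config,
                 ring_form = ring, anomer = anomer,
                 modifications = modifications),
            class = "monosaccharide_residue")
}

#' Create an empty glycan graph
#'
#' @param attachment An \code{\link{attachment_spec}} or \code{NULL} for a
#'   free reducing end.
#' @return An object of class \code{glycan_graph}.
#' @export
glycan_graph <- function(attachment = NULL) {
  structure(list(residues = list(),
                 linkages = list(),
                 root_index = NA_integer_,
                 attachment = attachment),
            class = "glycan_graph")
}

#' Attachment specification for a glycan's reducing end
#'
#' The attachment kind determines the default partner atom on the aglycone:
#' N-linked glycans bond to Asn ND2, O-glycans to Ser OG or Thr OG1; lipid
#' and small-molecule-chain attachments name their partner atom explicitly.
#'
#' @param kind One of \code{"N-linked"}, \code{"O-Ser"}, \code{"O-Thr"},
#'   \code{"lipid"}, \code{"small-molecule-chain"}, \code{"free"}.
#' @param partner_entity Entity id of the attachment partner.
#' @param partner_residue 1-based residue position in the partner entity.
#' @param partner_atom Atom name; defaults from \code{kind} where defined.
#' @export
#' @examples
#' attachment_spec("N-linked", "A", 83)           # partner atom ND2
#' attachment_spec("lipid", "CER", 1, "O1")
attachment_spec <- function(kind, partner_entity = NULL, partner_residue = NULL,
                            partner_atom = NULL) {
  kinds <- c("N-linked", "O-Ser", "O-Thr", "lipid", "small-molecule-chain", "free")
  if (!kind %in% kinds) {
    stop("unknown attachment kind '", kind, "'", call. = FALSE)
  }
  if (is.null(partner_atom)) {
    partner_atom <- switch(kind, "N-linked" = "ND2", "O-Ser" = "OG",
                           "O-Thr" = "OG1", NA_character_)
    if (is.na(partner_atom) && kind != "free") {
      stop("attachment kind '", kind, "' requires an explicit partner_atom",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, partner_entity = partner_entity,
                 partner_residue = partner_residue,
                 partner_atom = partner_atom),
            class = "attachment_spec")
}

#' Add a residue to a glycan graph
#'
#' The first residue added becomes the root (reducing end).  Returned
#' indices are stable: residues are never renumbered by later additions.
#'
#' @param graph A \code{glycan_graph}.
#' @param residue A \code{monosaccharide_residue}, or a sugar token which is
#'   promoted via \code{monosaccharide_residue(residue, anomer)}.
#' @param anomer Used only when \code{residue} is given as a token.
#' @return The updated graph, with the new residue's index in attribute
#'   \code{"index"} (also retrievable as \code{length(graph$residues)}).
#' @export
#' @examples
#' g <- glycan_graph()
#' g <- add_residue(g, "Glc", "beta")
#' attr(g, "index")  # 1
add_residue <- function(graph, residue, anomer = "beta") {
  stopifnot(inherits(graph, "glycan_graph"))
  if (is.character(residue)) residue <- monosaccharide_residue(residue, anomer)
  stopifnot(inherits(residue, "monosaccharide_residue"))
  graph$residues[[length(graph$residues) + 1L]] <- residue
  idx <- length(graph$residues)
  if (is.na(graph$root_index)) graph$root_index <- idx
  attr(graph, "index") <- idx
  graph
}

#' Add a glycosidic linkage
#'
#' Records donor -> acceptor at the given acceptor hydroxyl position.  The
#' donor's anomeric carbon (C1 for aldoses, C2 for ketoses such as sialic
#' acid) is taken from the registry.  Tree invariants are enforced: one
#' linkage per acceptor position, each residue donor at most once, no cycles.
#'
#' @param graph A \code{glycan_graph}.
#' @param donor_index,acceptor_index Residue indices.
#' @param acceptor_position Hydroxyl position on the acceptor (2-6 typical).
#' @return The updated graph; the new linkage is in attribute \code{"linkage"}.
#' @export
add_linkage <- function(graph, donor_index, acceptor_index, acceptor_position) {
  stopifnot(inherits(graph, "glycan_graph"))
  n <- length(graph$residues)
  if (donor_index < 1 || donor_index > n || acceptor_index < 1 || acceptor_index > n) {
    stop("linkage references nonexistent residue", call. = FALSE)
  }
  if (donor_index == acceptor_index) {
    stop("residue cannot link to itself", call. = FALSE)
  }
  acc_def <- .sugar_def(graph$residues[[acceptor_index]]$sugar_name)
  if (!(acceptor_position %in% .sugar_acceptor_positions(acc_def))) {
    stop("position ", acceptor_position, " is not a valid acceptor position on ",
         acc_def$sugar, call. = FALSE)
  }
  for (l in graph$linkages) {
    if (l$acceptor_index == acceptor_index && l$acceptor_position == acceptor_position) {
      stop("acceptor position O", acceptor_position, " of residue ",
           acceptor_index, " already occupied", call. = FALSE)
    }
    if (l$donor_index == donor_index) {
      stop("residue ", donor_index, " is already a donor", call. = FALSE)
    }
  }
  acc_res <- graph$residues[[acceptor_index]]
  for (m in acc_res$modifications) {
    if (m$position == acceptor_position) {
      stop("acceptor position O", acceptor_position, " carries a ",
           m$mod_name, " modification", call. = FALSE)
    }
  }
  # cycle check: walking acceptor-ward from the acceptor must not reach donor
  cur <- acceptor_index
  repeat {
    up <- NULL
    for (l in graph$linkages) if (l$donor_index == cur) up <- l$acceptor_index
    if (is.null(up)) break
    if (up == donor_index) stop("linkage would create a cycle", call. = FALSE)
    cur <- up
  }
  don_def <- .sugar_def(graph$residues[[donor_index]]$sugar_name)
  lk <- structure(list(donor_index = as.integer(donor_index),
                       acceptor_index = as.integer(acceptor_index),
                       acceptor_position = as.integer(acceptor_position),
                       donor_anomeric_carbon = don_def$anomeric_carbon),
                  class = "glycosidic_linkage")
  graph$linkages[[length(graph$linkages) + 1L]] <- lk
  attr(graph, "linkage") <- lk
  graph
}

# children of node i: data.frame(donor, position) sorted by acceptor position
.graph_children <- function(graph, i) {
  kids <- Filter(function(l) l$acceptor_index == i, graph$linkages)
  if (!length(kids)) return(data.frame(donor = integer(0), position = integer(0)))
  d <- data.frame(donor = vapply(kids, `[[`, 0, "donor_index"),
                  position = vapply(kids, `[[`, 0, "acceptor_position"))
  d[order(d$position), , drop = FALSE]
}

#' Canonical residue numbering
#'
#' Breadth-first order from the reducing-end root; at branch points children
#' are visited in ascending acceptor position (O2 < O3 < O4 < O6).  This
#' convention reproduces the published numbering of the packaged templates:
#' the G2 N-glycan places its two terminal Gal residues at 8 and 9, and M9
#' places the 3-arm mannoses at 4, 6 and 9.
#'
#' @param graph A valid \code{glycan_graph}.
#' @return Integer vector: original residue indices in canonical order, so
#'   canonical number k corresponds to residue \code{residue_numbering(g)[k]}.
#' @export
residue_numbering <- function(graph) {
  stopifnot(inherits(graph, "glycan_graph"))
  n <- length(graph$residues)
  if (n == 0) return(integer(0))
  issues <- validate_graph(graph)
  if (length(issues)) {
    stop("graph invalid: ", issues[[1]]$message, call. = FALSE)
  }
  order <- integer(0)
  queue <- graph$root_index
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    order <- c(order, cur)
    queue <- c(queue, .graph_children(graph, cur)$donor)
  }
  as.integer(order)
}

#' Validate glycan graph invariants
#'
#' Reporting operation: returns an empty list iff all type invariants hold.
#' Each issue carries a \code{category}, a human-readable \code{message},
#' and the residue/linkage locus.
#'
#' @param graph A \code{glycan_graph}.
#' @return List of issues (possibly empty).
#' @export
validate_graph <- function(graph) {
  issues <- list()
  flag <- function(category, message, locus = NA) {
    issues[[length(issues) + 1L]] <<- list(category = category,
                                           message = message, locus = locus)
  }
  n <- length(graph$residues)
  if (n == 0) return(issues)
  if (is.na(graph$root_index) || graph$root_index < 1 || graph$root_index > n) {
    flag("no-root", "graph has no valid root residue")
    return(issues)
  }
  donors <- vapply(graph$linkages, `[[`, 0, "donor_index")
  for (l in graph$linkages) {
    if (l$donor_index > n || l$acceptor_index > n) {
      flag("dangling-linkage", "linkage references nonexistent residue", l)
    }
    don_def <- .sugar_def(graph$residues[[l$donor_index]]$sugar_name)
    if (!identical(l$donor_anomeric_carbon, don_def$anomeric_carbon)) {
      flag("anomeric-carbon-mismatch",
           sprintf("linkage records donor anomeric carbon %s but registry says %s for %s",
                   l$donor_anomeric_carbon, don_def$anomeric_carbon, don_def$sugar),
           l)
    }
  }
  if (anyDuplicated(donors)) {
    flag("donor-reuse", "a residue is donor of more than one linkage")
  }
  acc_keys <- vapply(graph$linkages, function(l)
    paste(l$acceptor_index, l$acceptor_position), "")
  if (anyDuplicated(acc_keys)) {
    flag("occupied-position", "two linkages share an acceptor position")
  }
  # connectivity: every non-root residue must be donor of exactly one linkage
  for (i in seq_len(n)) {
    if (i == graph$root_index) next
    cnt <- sum(donors == i)
    if (cnt == 0) flag("orphan-residue",
                       sprintf("residue %d is not the root and donates no linkage", i), i)
  }
  if (sum(donors == graph$root_index) > 0) {
    flag("root-is-donor", "root residue acts as a donor")
  }
  issues
}

#' @export
print.glycan_graph <- function(x, ...) {
  n <- length(x$residues)
  cat(sprintf("<glycan_graph> %d residue%s, %d linkage%s\n",
              n, if (n == 1) "" else "s",
              length(x$linkages), if (length(x$linkages) == 1) "" else "s"))
  if (n > 0 && !length(validate_graph(x))) {
    ord <- residue_numbering(x)
    for (k in seq_along(ord)) {
      r <- x$residues[[ord[k]]]
      cat(sprintf("  %2d %s%s (%s)\n", k,
                  r$sugar_name,
                  if (r$anomer == "none") "" else paste0("-", substr(r$anomer, 1, 1)),
                  r$ring_form))
    }
    cat("  notation:", tryCatch(write_iupac_condensed(x),
                                error = function(e) "<unserializable>"), "\n")
  }
  invisible(x)
}

# number of modifications across all residues
.graph_mod_count <- function(graph) {
  sum(vapply(graph$residues, function(r) length(r$modifications), 0))
}
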