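# Structure models: atoms with entity/residue/name/element/coordinates/
# confidence, read and written in mmCIF and PDB formats.

#' Construct a structure model
#'
#' @param atoms data.frame with columns \code{entity}, \code{residue}
#'   (integer), \code{code} (residue/component code), \code{atom},
#'   \code{element}, \code{x}, \code{y}, \code{z}, and optionally
#'   \code{confidence} (pLDDT/B-factor column).
#' @return Object of class \code{structure_model}.
#' @export
structure_model <- function(atoms) {
  req <- c("entity", "residue", "code", "atom", "element", "x", "y", "z")
  missing <- setdiff(req, names(atoms))
  if (length(missing)) {
    stop("atoms lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"confidence" %in% names(atoms)) atoms$confidence <- NA_real_
  key <- paste(atoms$entity, atoms$residue, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate (entity, residue, atom) triple: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d residues, entities: %s\n",
              nrow(a), length(unique(paste(a$entity, a$residue))),
              paste(unique(a$entity), collapse = ", ")))
  invisible(x)
}

# coordinates of one atom as numeric(3), or NULL
.atom_xyz <- function(model, entity, residue, atom) {
  a <- model$atoms
  i <- which(a$entity == entity & a$residue == residue & a$atom == atom)
  if (!length(i)) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

#' Write a structure model as mmCIF
#'
#' Minimal atom_site representation with the confidence value in the
#' B-factor-equivalent column (the AF3 convention stores pLDDT there).
#'
#' @param model A \code{structure_model}.
#' @param path Optional file path; when NULL the text is returned.
#' @return mmCIF text (invisibly when written to a file).
#' @export
write_structure_mmcif <- function(model, path = NULL) {
  a <- model$atoms
  conf <- ifelse(is.na(a$confidence), 0, a$confidence)
  lines <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    sprintf("HETATM %d %s %s %s %s %d %.3f %.3f %.3f 1.00 %.2f",
            seq_len(nrow(a)), a$element, a$atom, a$code, a$entity, a$residue,
            a$x, a$y, a$z, conf),
    "#")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Write a structure model as PDB
#'
#' @inheritParams write_structure_mmcif
#' @export
write_structure_pdb <- function(model, path = NULL) {
  a <- model$atoms
  conf <- ifelse(is.na(a$confidence), 0, a$confidence)
  chain <- substr(a$entity, 1, 1)
  recs <- sprintf(
    "HETATM%5d %-4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)),
    ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom),
    substr(a$code, 1, 3), chain, a$residue,
    a$x, a$y, a$z, 1.0, conf, a$element)
  text <- paste0(paste(c(recs, "END"), collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

.read_structure_mmcif <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  i <- 1L
  while (i <= n && !identical(lines[i], "loop_")) i <- i + 1L
  at <- NULL
  while (i <= n) {
    if (identical(lines[i], "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, lines[i]); i <- i + 1L
      }
      rows <- list()
      while (i <= n && !startsWith(lines[i], "_") && !identical(lines[i], "loop_") &&
             !startsWith(lines[i], "#") && !startsWith(lines[i], "data_")) {
        f <- .cif_fields(lines[i])
        if (length(f) == length(tags)) rows[[length(rows) + 1L]] <- f
        i <- i + 1L
      }
      if (startsWith(tags[1], "_atom_site.")) {
        tbl <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tbl) <- sub("^_atom_site\\.", "", tags)
        at <- tbl
      }
    } else {
      i <- i + 1L
    }
  }
  if (is.null(at)) stop("no _atom_site loop found", call. = FALSE)
  get <- function(cands, default = NA) {
    for (c1 in cands) if (c1 %in% names(at)) return(at[[c1]])
    rep(default, nrow(at))
  }
  seqid <- get(c("label_seq_id", "auth_seq_id"))
  atoms <- data.frame(
    entity = get(c("label_asym_id", "auth_asym_id"), "A"),
    residue = suppressWarnings(as.integer(seqid)),
    code = get("label_comp_id", "UNK"),
    atom = get(c("label_atom_id", "auth_atom_id")),
    element = get("type_symbol"),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    confidence = suppressWarnings(as.numeric(get("B_iso_or_equiv"))),
    stringsAsFactors = FALSE)
  atoms
}

.read_structure_pdb <- function(lines) {
  recs <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(recs)) stop("no ATOM/HETATM records", call. = FALSE)
  sub_ <- function(a, b) trimws(substr(recs, a, b))
  el <- sub_(77, 78)
  atom <- sub_(13, 16)
  el[!nzchar(el)] <- substr(gsub("[0-9]", "", atom[!nzchar(el)]), 1, 1)
  data.frame(
    entity = sub_(21, 22),
    residue = as.integer(sub_(23, 26)),
    code = sub_(18, 20),
    atom = atom,
    element = el,
    x = as.numeric(sub_(31, 38)),
    y = as.numeric(sub_(39, 46)),
    z = as.numeric(sub_(47, 54)),
    confidence = as.numeric(sub_(61, 66)),
    stringsAsFactors = FALSE)
}

#' Read a predicted structure
#'
#' Reads mmCIF or PDB text into a \code{structure_model}.  The
#' B-factor-equivalent column is stored as per-atom \code{confidence}
#' (pLDDT for AF3 outputs).
#'
#' @param text File path, single string, or character vector of lines.
#' @param format \code{"mmcif"}, \code{"pdb"}, or \code{"auto"} (detected
#'   from content).
#' @return A \code{structure_model}.
#' @export
read_structure <- function(text, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  if (format == "auto") {
    format <- if (any(startsWith(text, "loop_") | startsWith(text, "data_")))
      "mmcif" else "pdb"
  }
  atoms <- if (format == "mmcif") .read_structure_mmcif(text)
           else .read_structure_pdb(text)
  structure_model(atoms)
}

#' Extract per-atom confidence values
#'
#' Passes stored confidence values (the mmCIF B-factor-equivalent column,
#' treated as pLDDT for AF3 outputs) through unchanged, with summary
#' statistics over the selection.
#'
#' @param model A \code{structure_model}.
#' @param entity Optional entity filter.
#' @param residues Optional residue-index filter.
#' @return List with \code{values} (data.frame entity/residue/atom/
#'   confidence), \code{mean}, \code{min}; empty with a warning when no
#'   confidence column is present.
#' @export
extract_confidence <- function(model, entity = NULL, residues = NULL) {
  a <- model$atoms
  if (!is.null(entity)) a <- a[a$entity %in% entity, , drop = FALSE]
  if (!is.null(residues)) a <- a[a$residue %in% residues, , drop = FALSE]
  if (!nrow(a) || all(is.na(a$confidence))) {
    if (nrow(a)) warning("no confidence column present in selection")
    return(list(values = a[0, c("entity", "residue", "atom", "confidence")],
                mean = NA_real_, min = NA_real_))
  }
  vals <- a[, c("entity", "residue", "atom", "confidence")]
  list(values = vals,
       mean = mean(vals$confidence, na.rm = TRUE),
       min = min(vals$confidence, na.rm = TRUE))
}
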