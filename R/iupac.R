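# IUPAC-condensed text grammar for glycan topologies.
#
# Residue token:  [D-|L-] SugarName [p|f] [<pos><mod>]* [a|b] [<d>-<a>]
# where <mod> is S (sulfate), P (phosphate), Ac (acetyl), Me (methyl); the
# trailing "<d>-<a>" linkage joins the residue (donor, anomeric carbon d) to
# the residue on its right (acceptor hydroxyl position a).  Branches are
# carried in square brackets immediately before their acceptor.  The root
# (reducing end) is the rightmost residue.  Whitespace is ignored.

.mod_codes <- c(S = "sulfate", P = "phosphate", Ac = "acetyl", Me = "methyl")

.sugar_tokens <- function() {
  toks <- names(ccd_registry()$sugars)
  toks[order(-nchar(toks))]
}

# Tokenize into residue records and bracket markers.
.iupac_tokenize <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  toks <- list()
  i <- 1L
  n <- nchar(text)
  sugars <- .sugar_tokens()
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[" || ch == "]") {
      toks[[length(toks) + 1L]] <- ch
      i <- i + 1L
      next
    }
    rest <- substr(text, i, n)
    config <- NULL
    m <- regmatches(rest, regexec("^([DL])-", rest))[[1]]
    if (length(m)) {
      cand <- substr(rest, nchar(m[1]) + 1, nchar(rest))
      if (any(startsWith(cand, sugars))) {
        config <- m[2]
        i <- i + nchar(m[1])
        rest <- cand
      }
    }
    hit <- sugars[startsWith(rest, sugars)]
    if (!length(hit)) {
      stop("syntax error at character ", i, ": no sugar token matches '",
           substr(rest, 1, 12), "'", call. = FALSE)
    }
    sugar <- hit[1]
    i <- i + nchar(sugar)
    rest <- substr(text, i, n)
    ring <- NULL
    if (grepl("^[pf]", rest)) {
      # ring marker must not swallow an anomer-less linkage or mod; only
      # accept when followed by a mod, anomer, linkage, bracket or end
      nxt <- substr(rest, 2, nchar(rest))
      if (nxt == "" || grepl("^([ab]|[0-9]+(S|P|Ac|Me)|[0-9]+-[0-9]|\\[|\\])", nxt)) {
        ring <- c(p = "pyranose", f = "furanose")[[substr(rest, 1, 1)]]
        i <- i + 1L
        rest <- nxt
      }
    }
    mods <- list()
    repeat {
      m <- regmatches(rest, regexec("^([0-9]+)(Ac|Me|S|P)", rest))[[1]]
      if (!length(m)) break
      mods[[length(mods) + 1L]] <- list(position = as.integer(m[2]),
                                        mod_name = .mod_codes[[m[3]]])
      i <- i + nchar(m[1])
      rest <- substr(text, i, n)
    }
    anomer <- NULL
    if (grepl("^[ab]", rest)) {
      anomer <- c(a = "alpha", b = "beta")[[substr(rest, 1, 1)]]
      i <- i + 1L
      rest <- substr(text, i, n)
    }
    link <- NULL
    m <- regmatches(rest, regexec("^([0-9]+)-([0-9]+)", rest))[[1]]
    if (length(m)) {
      link <- c(as.integer(m[2]), as.integer(m[3]))
      i <- i + nchar(m[1])
    }
    toks[[length(toks) + 1L]] <- list(sugar = sugar, config = config,
                                      ring = ring, mods = mods,
                                      anomer = anomer, link = link)
  }
  toks
}

# Recursive right-to-left parse of a token stream into a nested tree:
# list(residue_token, children = list(subtree, ...)).
.iupac_parse_level <- function(toks) {
  if (!length(toks)) stop("empty residue group", call. = FALSE)
  last <- toks[[length(toks)]]
  if (is.character(last)) stop("expected residue before bracket/end", call. = FALSE)
  rest <- toks[-length(toks)]
  children <- list()
  while (length(rest)) {
    tail_tok <- rest[[length(rest)]]
    if (identical(tail_tok, "]")) {
      depth <- 1L
      j <- length(rest) - 1L
      while (j >= 1L) {
        if (identical(rest[[j]], "]")) depth <- depth + 1L
        if (identical(rest[[j]], "[")) depth <- depth - 1L
        if (depth == 0L) break
        j <- j - 1L
      }
      if (depth != 0L) stop("unbalanced brackets", call. = FALSE)
      inner <- rest[seq.int(j + 1L, length(rest) - 1L)]
      children[[length(children) + 1L]] <- .iupac_parse_level(inner)
      rest <- if (j > 1L) rest[seq_len(j - 1L)] else list()
    } else {
      children[[length(children) + 1L]] <- .iupac_parse_level(rest)
      rest <- list()
    }
  }
  list(token = last, children = children)
}

.token_to_residue <- function(tok) {
  monosaccharide_residue(tok$sugar,
                         anomer = if (is.null(tok$anomer)) {
                           if (.sugar_def(tok$sugar)$class == "open") "none" else "beta"
                         } else tok$anomer,
                         config = tok$config, ring = tok$ring,
                         modifications = tok$mods)
}

# insert a parsed subtree into graph, returning updated graph; parent_index
# NULL for the root.
.iupac_build <- function(graph, node, parent_index = NULL) {
  graph <- add_residue(graph, .token_to_residue(node$token))
  idx <- attr(graph, "index")
  if (!is.null(parent_index)) {
    link <- node$token$link
    if (is.null(link)) stop("non-root residue lacks a linkage", call. = FALSE)
    graph <- add_linkage(graph, donor_index = idx, acceptor_index = parent_index,
                         acceptor_position = link[2])
  } else if (!is.null(node$token$link)) {
    stop("root residue must not carry a linkage", call. = FALSE)
  }
  for (ch in node$children) graph <- .iupac_build(graph, ch, idx)
  graph
}

# Reorder graph residues so index == canonical residue number.
.canonicalize_graph <- function(graph) {
  if (!length(graph$residues)) return(graph)
  ord <- residue_numbering(graph)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  g2 <- glycan_graph(attachment = graph$attachment)
  g2$residues <- graph$residues[ord]
  g2$root_index <- 1L
  g2$linkages <- lapply(graph$linkages, function(l) {
    l$donor_index <- rank[l$donor_index]
    l$acceptor_index <- rank[l$acceptor_index]
    l
  })
  ord2 <- order(vapply(g2$linkages, `[[`, 0, "donor_index"))
  g2$linkages <- g2$linkages[ord2]
  g2
}

#' Parse IUPAC-condensed glycan text
#'
#' @param text Glycan in the condensed grammar, e.g.
#'   \code{"Galb1-4GlcNAcb1-3Galb1-4Glc"} (LNnT).  Whitespace is ignored.
#' @param attachment Optional \code{\link{attachment_spec}} for the root.
#' @return A \code{\link{glycan_graph}} whose residue indices follow the
#'   canonical \code{\link{residue_numbering}} order.
#' @export
#' @examples
#' g <- parse_iupac_condensed("Galb1-4GlcNAcb1-3Galb1-4Glc")
#' length(g$residues)  # 4
parse_iupac_condensed <- function(text, attachment = NULL) {
  toks <- .iupac_tokenize(text)
  depth <- 0L
  for (t in toks) {
    if (identical(t, "[")) depth <- depth + 1L
    if (identical(t, "]")) depth <- depth - 1L
    if (depth < 0L) break
  }
  if (depth != 0L) stop("unbalanced brackets", call. = FALSE)
  tree <- .iupac_parse_level(toks)
  graph <- .iupac_build(glycan_graph(attachment = attachment), tree)
  issues <- validate_graph(graph)
  if (length(issues)) {
    stop("parsed graph invalid: ", issues[[1]]$message, call. = FALSE)
  }
  .canonicalize_graph(graph)
}

.mod_suffix <- function(mods) {
  if (!length(mods)) return("")
  mods <- mods[order(vapply(mods, function(m) m$position, 0))]
  paste(vapply(mods, function(m) {
    paste0(m$position, names(.mod_codes)[match(m$mod_name, .mod_codes)])
  }, ""), collapse = "")
}

.residue_token_text <- function(res, link_text = "", is_root = FALSE) {
  def <- .sugar_def(res$sugar_name)
  cfg <- if (!identical(res$absolute_config, def$default_config))
    paste0(res$absolute_config, "-") else ""
  ring <- if (!identical(res$ring_form, def$ring) && res$ring_form != "open")
    substr(res$ring_form, 1, 1) else ""
  ano <- switch(res$anomer, alpha = "a", beta = "b", none = "")
  # the free reducing end omits the default beta anomer ("...Galb1-4Glc")
  if (is_root && identical(res$anomer, "beta")) ano <- ""
  paste0(cfg, res$sugar_name, ring, .mod_suffix(res$modifications), ano, link_text)
}

#' Serialize a glycan graph to IUPAC-condensed text
#'
#' Canonical form: at each branch point the child at the highest acceptor
#' position continues the unbracketed chain (matching the conventional
#' condensed rendering of, e.g., biantennary N-glycans); remaining branches
#' are emitted in brackets in ascending acceptor-position order.  The output
#' contains no whitespace and satisfies
#' \code{parse_iupac_condensed(write_iupac_condensed(g)) == g}.
#'
#' @param graph A valid \code{glycan_graph}.
#' @return Single string.
#' @export
write_iupac_condensed <- function(graph) {
  issues <- validate_graph(graph)
  if (length(issues)) {
    stop("cannot serialize invalid graph: ", issues[[1]]$message, call. = FALSE)
  }
  ser <- function(i, link_text) {
    res <- graph$residues[[i]]
    kids <- .graph_children(graph, i)
    me <- .residue_token_text(res, link_text,
                              is_root = identical(i, graph$root_index))
    if (!nrow(kids)) return(me)
    link_of <- function(k) {
      don <- graph$residues[[kids$donor[k]]]
      don_def <- .sugar_def(don$sugar_name)
      d <- if (identical(don_def$anomeric_carbon, "C2")) 2 else 1
      paste0(d, "-", kids$position[k])
    }
    main_k <- nrow(kids)  # highest acceptor position
    branches <- ""
    if (nrow(kids) > 1) {
      branches <- paste(vapply(seq_len(nrow(kids) - 1), function(k) {
        paste0("[", ser(kids$donor[k], link_of(k)), "]")
      }, ""), collapse = "")
    }
    paste0(ser(kids$donor[main_k], link_of(main_k)), branches, me)
  }
  ser(graph$root_index, "")
}
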