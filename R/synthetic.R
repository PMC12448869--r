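# Synthetic coordinate builder: ideal rings at specified pucker (inverse
# Cremer-Pople), full monosaccharides from registry substitution patterns,
# assembled glycans, and stereochemically corrupted variants for detector
# tests.

.BOND_LEN <- c(O = 1.43, N = 1.45, C = 1.53, P = 1.62, S = 1.58)

.vnorm <- function(v) sqrt(sum(v^2))
.unit <- function(v) v / .vnorm(v)
.cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# rotation matrix about unit axis by angle (radians), Rodrigues form
.rotmat <- function(axis, angle) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# proper rotation mapping unit vector a onto unit vector b
.align_rot <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- .cross(a, b)
  s <- .vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(.rotmat(.cross(a, p), pi))
  }
  .rotmat(v, atan2(s, c_))
}

#' Build an ideal ring at a specified Cremer-Pople pucker
#'
#' Inverse of the puckering transform: in-plane positions on a circle plus
#' out-of-plane displacements synthesized from the target (Q, theta, phi)
#' Fourier amplitudes.  The m = 1 component is zero by construction, so
#' forward analysis with \code{\link{cremer_pople}} recovers the target
#' exactly (to machine precision).
#'
#' @param n Ring size, 5 or 6.
#' @param Q Total puckering amplitude (Angstrom), >= 0.
#' @param theta Polar angle in degrees (6-rings only; ignored for 5-rings).
#' @param phi Phase angle in degrees.
#' @param radius In-plane ring radius (Angstrom).
#' @return n x 3 coordinate matrix, rows in ring order.
#' @export
#' @examples
#' cp <- cremer_pople(build_ring(6, 0.57, 0, 0))
#' abs(cp$Q - 0.57) < 1e-9
build_ring <- function(n = 6L, Q = 0.57, theta = 0, phi = 0, radius = 1.45) {
  if (Q < 0) stop("Q must be >= 0", call. = FALSE)
  if (Q > radius) stop("infeasible amplitude: Q exceeds the ring radius",
                       call. = FALSE)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rad <- pi / 180
  if (n == 6L) {
    q2 <- Q * sin(theta * rad)
    q3 <- Q * cos(theta * rad)
    z <- sqrt(2 / n) * q2 * cos(phi * rad + 2 * ang) +
      sqrt(1 / n) * q3 * (-1)^(seq_len(n) - 1)
  } else if (n == 5L) {
    z <- sqrt(2 / n) * Q * cos(phi * rad + 2 * ang)
  } else {
    stop("ring size must be 5 or 6", call. = FALSE)
  }
  cbind(x = radius * cos(ang), y = -radius * sin(ang), z = z)
}

# tetrahedral exocyclic slots at ring atom j given its two ring neighbours:
# returns list(ax =, eq =) unit directions.  "ax" is the slot more aligned
# with the local ring axis.
.exocyclic_slots <- function(pos, prev, nxt, ring_normal) {
  b1 <- .unit(prev - pos)
  b2 <- .unit(nxt - pos)
  m <- .unit(b1 + b2)
  w <- .unit(.cross(b1, b2))
  d1 <- .unit(-m + w)
  d2 <- .unit(-m - w)
  if (abs(sum(d1 * ring_normal)) >= abs(sum(d2 * ring_normal))) {
    list(ax = d1, eq = d2)
  } else {
    list(ax = d2, eq = d1)
  }
}

# candidate positions for a chain atom given its parent and grandparent; k
# indexes the zig-zag alternation, later candidates fan out for clash
# avoidance
.chain_candidates <- function(parent, grand, element, k) {
  dirv <- .unit(parent - grand)
  ref <- if (abs(dirv[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  lat <- .unit(.cross(dirv, ref))
  bl <- .BOND_LEN[[element]]
  mixes <- list(c(0.55 * (-1)^k, 0.2), c(-0.55 * (-1)^k, 0.2))
  for (t in c(-1, -0.5, 0, 0.5, 1)) {
    for (s in c(-1, -0.5, 0, 0.5, 1)) mixes[[length(mixes) + 1L]] <- c(t, s)
  }
  lapply(mixes, function(m)
    parent + bl * .unit(dirv + m[1] * lat + m[2] * ref))
}

#' Build ideal coordinates for a single monosaccharide residue
#'
#' Constructs the full heavy-atom residue from the registry definition:
#' ideal ring at the requested conformer, exocyclic substituents placed
#' axial/equatorial per the reference substitution pattern, anomeric
#' hydroxyl per the anomer, side chains extended clash-free.  L sugars are
#' built as the mirror image of the D reference.
#'
#' @param sugar_name Registry sugar token.
#' @param anomer \code{"alpha"}, \code{"beta"} or \code{"none"}.
#' @param config \code{"D"} or \code{"L"} (default per registry).
#' @param conformer \code{"4C1"} (default), \code{"1C4"}, or a numeric
#'   \code{c(Q, theta, phi)} pucker target.  Pyranoses only.
#' @param flip_center Optional ring-carbon name whose substituent is placed
#'   in the opposite (epimeric) slot — used to synthesize epimer defects.
#' @param flip_anomer If TRUE the anomeric substituent(s) are placed in the
#'   opposite slot(s) — used to synthesize anomer defects.
#' @return data.frame(name, element, x, y, z) with attribute \code{"bonds"}
#'   (data.frame atom1, atom2, order) describing construction connectivity.
#' @export
build_residue <- function(sugar_name, anomer = "beta", config = NULL,
                          conformer = "4C1", flip_center = NULL,
                          flip_anomer = FALSE) {
  def <- .sugar_def(sugar_name)
  if (is.null(config)) config <- def$default_config
  if (def$class == "open") return(.build_open_chain(def, config))

  nring <- length(def$ring_atoms)
  pucker <- if (is.numeric(conformer)) conformer
            else switch(conformer,
                        "4C1" = c(0.57, 0, 0),
                        "1C4" = c(0.57, 180, 0),
                        planar = c(0, 0, 0),
                        stop("unsupported conformer '", conformer, "'",
                             call. = FALSE))
  if (nring == 5L && is.character(conformer) && conformer %in% c("4C1", "1C4")) {
    pucker <- c(0.38, NA, 90)  # furanose envelope default
  }
  ring <- build_ring(nring, Q = pucker[1],
                     theta = if (is.na(pucker[2])) 0 else pucker[2],
                     phi = pucker[3])
  rownames(ring) <- def$ring_atoms
  normal <- c(0, 0, 1)

  pos <- list()
  for (i in seq_len(nring)) pos[[def$ring_atoms[i]]] <- ring[i, ]
  bonds <- data.frame(atom1 = def$ring_atoms,
                      atom2 = def$ring_atoms[c(2:nring, 1)],
                      order = "SING", stringsAsFactors = FALSE)
  elements <- stats::setNames(ifelse(grepl("^O", def$ring_atoms), "O", "C"),
                              def$ring_atoms)

  slot_at <- function(atom) {
    i <- match(atom, def$ring_atoms)
    prev <- def$ring_atoms[if (i == 1) nring else i - 1]
    nxt <- def$ring_atoms[if (i == nring) 1 else i + 1]
    .exocyclic_slots(pos[[atom]], pos[[prev]], pos[[nxt]], normal)
  }
  place <- function(atom, name, element, orient) {
    s <- slot_at(atom)
    dirv <- if (orient == "ax") s$ax else s$eq
    pos[[name]] <<- pos[[atom]] + .BOND_LEN[[element]] * dirv
    elements[[name]] <<- element
    bonds <<- rbind(bonds, data.frame(atom1 = atom, atom2 = name, order = "SING"))
  }
  opposite <- function(o) if (o == "ax") "eq" else "ax"

  # anomeric substituent(s)
  ac <- def$anomeric_carbon
  ao <- def$anomeric_orient[[anomer]]
  if (is.null(ao) || is.na(ao)) {
    stop("anomer '", anomer, "' undefined for ", sugar_name, call. = FALSE)
  }
  if (flip_anomer) ao <- opposite(ao)
  place(ac, def$leaving_atom, "O", ao)

  chain_counter <- 0L
  place_chain <- function(first_name, first_parent, chain) {
    prev <- first_name
    grand <- first_parent
    for (el in chain) {
      par <- if (is.null(el$parent)) prev else el$parent
      gp <- if (is.null(el$parent)) grand else {
        # grandparent = the atom the parent itself hangs on
        b <- bonds[bonds$atom2 == par, , drop = FALSE]
        if (nrow(b)) b$atom1[1] else first_parent
      }
      chain_counter <<- chain_counter + 1L
      cands <- .chain_candidates(pos[[par]], pos[[gp]], el$element,
                                 chain_counter)
      # clash-aware pick: keep the first candidate at least 2.2 A from every
      # placed atom other than the bonded parent, else the best available
      existing <- do.call(rbind, pos[setdiff(names(pos), par)])
      score <- vapply(cands, function(p)
        min(sqrt(rowSums(sweep(existing, 2, p)^2))), 0)
      ok <- which(score >= 2.2)
      pick <- if (length(ok)) ok[1] else which.max(score)
      pos[[el$atom]] <<- cands[[pick]]
      elements[[el$atom]] <<- el$element
      bonds <<- rbind(bonds, data.frame(atom1 = par, atom2 = el$atom,
                                        order = "SING"))
      prev <- el$atom
      grand <- par
    }
  }

  for (cc in names(def$substituents)) {
    s <- def$substituents[[cc]]
    if (identical(s$orient, "anomeric_partner")) {
      # second substituent on the anomeric carbon (sialic C1 carboxylate):
      # occupies the slot the glycosidic oxygen does not
      orient <- opposite(ao)
    } else {
      orient <- s$orient
    }
    place(cc, s$atom, s$element, orient)
    if (!is.null(s$chain)) place_chain(s$atom, cc, s$chain)
    if (identical(cc, flip_center) && !identical(s$orient, "anomeric_partner")) {
      # epimeric defect: rigidly rotate the whole substituent subtree from
      # its reference slot into the opposite one, preserving its internal
      # geometry
      slots <- slot_at(cc)
      d_old <- if (orient == "ax") slots$ax else slots$eq
      d_new <- if (orient == "ax") slots$eq else slots$ax
      R <- .align_rot(d_old, d_new)
      subtree <- c(s$atom, vapply(s$chain %||% list(), `[[`, "", "atom"))
      ctr <- pos[[cc]]
      moved <- lapply(subtree, function(a) as.numeric(ctr + R %*% (pos[[a]] - ctr)))
      names(moved) <- subtree
      # spin the subtree about the new slot axis to maximize clearance
      rest <- do.call(rbind, pos[setdiff(names(pos), subtree)])
      best <- NULL
      for (spin in seq(0, 330, by = 30) * pi / 180) {
        Rs <- .rotmat(d_new, spin)
        cand <- lapply(moved, function(p) as.numeric(ctr + Rs %*% (p - ctr)))
        dmin <- min(vapply(cand, function(p) {
          d <- sqrt(rowSums(sweep(rest, 2, p)^2))
          min(d[d > 1e-6])
        }, 0))
        if (is.null(best) || dmin > best$dmin) best <- list(dmin = dmin,
                                                            cand = cand)
      }
      for (a in subtree) pos[[a]] <- best$cand[[a]]
    }
  }

  nm <- names(pos)
  out <- data.frame(name = nm,
                    element = unname(elements[nm]),
                    x = vapply(pos, `[[`, 0, 1),
                    y = vapply(pos, `[[`, 0, 2),
                    z = vapply(pos, `[[`, 0, 3),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (identical(config, "L")) out$x <- -out$x  # mirror build
  attr(out, "bonds") <- bonds
  attr(out, "ring_atoms") <- def$ring_atoms
  out
}

# extended zig-zag for open-chain polyols (ribitol): C1..C5 backbone with a
# hydroxyl on each carbon
.build_open_chain <- function(def, config) {
  n <- 5L
  cx <- 1.25 * (seq_len(n) - 1)
  cy <- 0.45 * (seq_len(n) %% 2)
  atoms <- data.frame(name = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  bonds <- data.frame(atom1 = character(0), atom2 = character(0),
                      order = character(0))
  for (i in seq_len(n)) {
    atoms <- rbind(atoms, data.frame(name = sprintf("C%d", i), element = "C",
                                     x = cx[i], y = cy[i], z = 0))
    atoms <- rbind(atoms, data.frame(name = sprintf("O%d", i), element = "O",
                                     x = cx[i], y = cy[i] + 0.45,
                                     z = 1.36 * (-1)^i))
    bonds <- rbind(bonds, data.frame(atom1 = sprintf("C%d", i),
                                     atom2 = sprintf("O%d", i), order = "SING"))
    if (i > 1) bonds <- rbind(bonds, data.frame(atom1 = sprintf("C%d", i - 1),
                                                atom2 = sprintf("C%d", i),
                                                order = "SING"))
  }
  attr(atoms, "bonds") <- bonds
  attr(atoms, "ring_atoms") <- character(0)
  atoms
}

#' Build a clean (or deliberately corrupted) glycan coordinate model
#'
#' Residues are built by \code{\link{build_residue}} and placed one linkage
#' at a time: the donor is rigidly rotated so its anomeric-carbon -> leaving
#' oxygen direction continues the acceptor's C-O bond, the leaving oxygen is
#' dropped, and the donor is spun about the new glycosidic bond to avoid
#' clashes (retrying a grid of spin angles; inter-atom distances below 1.0
#' Angstrom after all retries are an error).
#'
#' @param graph A valid \code{glycan_graph} (canonicalized internally).
#' @param entity Entity id recorded on the atoms (default \code{"NG"}).
#' @param confidence Either a single number stored as per-atom confidence,
#'   or \code{"gradient"} for values decreasing with residue number.
#' @param overrides List of defect specs, each
#'   \code{list(residue =, class =, center =)} with class one of
#'   \code{"epimer-flip"}, \code{"anomer-flip"},
#'   \code{"retain-leaving-oxygen"}, \code{"ring-flatten"}.
#' @return A \code{\link{structure_model}} carrying attributes
#'   \code{"bonds"} (construction connectivity) and \code{"graph"}.
#' @export
build_glycan_coords <- function(graph, entity = "NG", confidence = 90,
                                overrides = list()) {
  graph <- .canonicalize_graph(graph)
  n <- length(graph$residues)
  ov_for <- function(k) Filter(function(o) o$residue == k, overrides)

  placed <- list()   # per residue: data.frame with positions + bonds attr
  all_atoms <- NULL
  all_bonds <- NULL
  add_bond <- function(r1, a1, r2, a2) {
    all_bonds <<- rbind(all_bonds,
                        data.frame(res1 = r1, atom1 = a1, res2 = r2, atom2 = a2))
  }

  for (k in seq_len(n)) {
    res <- graph$residues[[k]]
    def <- .sugar_def(res$sugar_name)
    ovs <- ov_for(k)
    flip_center <- NULL; flip_anomer <- FALSE
    retain_leaving <- FALSE; conformer <- "4C1"
    for (o in ovs) {
      if (o$class == "epimer-flip") flip_center <- o$center
      if (o$class == "anomer-flip") flip_anomer <- TRUE
      if (o$class == "retain-leaving-oxygen") retain_leaving <- TRUE
      if (o$class == "ring-flatten") conformer <- "planar"
    }
    xyz <- build_residue(res$sugar_name, anomer = res$anomer,
                         config = res$absolute_config, conformer = conformer,
                         flip_center = flip_center, flip_anomer = flip_anomer)
    rb <- attr(xyz, "bonds")

    if (k == 1L) {
      placed[[k]] <- xyz
    } else {
      lk <- NULL
      for (l in graph$linkages) if (l$donor_index == k) lk <- l
      acc <- placed[[lk$acceptor_index]]
      o_name <- paste0("O", lk$acceptor_position)
      o_row <- which(acc$name == o_name)
      if (!length(o_row)) stop("acceptor lacks atom ", o_name, call. = FALSE)
      o_pos <- as.numeric(acc[o_row, c("x", "y", "z")])
      # parent carbon of the acceptor oxygen
      ab <- attr(acc, "bonds")
      pc <- c(ab$atom1[ab$atom2 == o_name], ab$atom2[ab$atom1 == o_name])
      pc <- pc[1]
      c_pos <- as.numeric(acc[acc$name == pc, c("x", "y", "z")])
      u <- .unit(o_pos - c_pos)  # direction the new bond extends along

      a_name <- def$anomeric_carbon
      l_name <- def$leaving_atom
      a_pos <- as.numeric(xyz[xyz$name == a_name, c("x", "y", "z")])
      l_pos <- as.numeric(xyz[xyz$name == l_name, c("x", "y", "z")])
      R0 <- .align_rot(l_pos - a_pos, -u)
      target <- o_pos + 1.43 * u

      coords <- as.matrix(xyz[, c("x", "y", "z")])
      others <- do.call(rbind, lapply(placed, function(p)
        as.matrix(p[, c("x", "y", "z")])))
      spin_score <- function(spin) {
        R <- .rotmat(u, spin) %*% R0
        moved <- sweep(coords, 2, a_pos) %*% t(R)
        moved <- sweep(moved, 2, target, "+")
        keep <- xyz$name != l_name
        dmin <- min(vapply(which(keep), function(i) {
          d2 <- rowSums(sweep(others, 2, moved[i, ])^2)
          # ignore the covalent contact of the anomeric carbon with O_x
          if (xyz$name[i] == a_name) {
            d2 <- d2[-which.min(rowSums(sweep(others, 2, o_pos)^2))]
          }
          sqrt(min(d2))
        }, 0))
        list(dmin = dmin, moved = moved)
      }
      best <- NULL
      for (spin in seq(0, 345, by = 15) * pi / 180) {
        sc <- spin_score(spin)
        if (is.null(best) || sc$dmin > best$dmin) best <- sc
        if (sc$dmin >= 1.95) break  # above every bond-inference limit
      }
      if (best$dmin < 1.0) {
        stop("steric collapse while placing residue ", k,
             " (min distance ", round(best$dmin, 2), " A)", call. = FALSE)
      }
      xyz$x <- best$moved[, 1]; xyz$y <- best$moved[, 2]; xyz$z <- best$moved[, 3]
      if (retain_leaving) {
        # keep the leaving oxygen, relocated off the new glycosidic bond so
        # the junction carbon carries an extra oxygen: choose the direction
        # from the anomeric carbon maximizing the clearance to every other
        # atom (a clean free slot for aldoses; the least-clashing position
        # for the crowded sialic anomeric carbon)
        a_new <- as.numeric(xyz[xyz$name == a_name, c("x", "y", "z")])
        env_atoms <- rbind(
          as.matrix(xyz[xyz$name != l_name, c("x", "y", "z")]),
          others)
        env_atoms <- env_atoms[sqrt(rowSums(sweep(env_atoms, 2, a_new)^2)) < 6,
                               , drop = FALSE]
        gold <- pi * (3 - sqrt(5))
        iidx <- seq_len(256)
        zz <- 1 - 2 * (iidx - 0.5) / 256
        rr <- sqrt(1 - zz^2)
        th <- gold * iidx
        dirs <- cbind(rr * cos(th), rr * sin(th), zz)
        cand <- sweep(1.43 * dirs, 2, a_new, "+")
        clearance <- apply(cand, 1, function(p) {
          d <- sqrt(rowSums(sweep(env_atoms, 2, p)^2))
          min(d[d > 1e-6])
        })
        xyz[xyz$name == l_name, c("x", "y", "z")] <-
          as.list(cand[which.max(clearance), ])
      } else {
        drop_row <- xyz$name == l_name
        xyz <- xyz[!drop_row, , drop = FALSE]
        rb <- rb[!(rb$atom1 == l_name | rb$atom2 == l_name), , drop = FALSE]
        attr(xyz, "bonds") <- rb
      }
      placed[[k]] <- xyz
      add_bond(lk$acceptor_index, o_name, k, a_name)
    }
    for (bi in seq_len(nrow(attr(placed[[k]], "bonds")))) {
      b <- attr(placed[[k]], "bonds")[bi, ]
      add_bond(k, b$atom1, k, b$atom2)
    }
  }

  rows <- list()
  for (k in seq_len(n)) {
    p <- placed[[k]]
    code <- tryCatch(resolve_ccd(graph$residues[[k]]$sugar_name,
                                 config = graph$residues[[k]]$absolute_config,
                                 ring = graph$residues[[k]]$ring_form,
                                 anomer = graph$residues[[k]]$anomer)$ccd_code,
                     error = function(e) graph$residues[[k]]$sugar_name)
    rows[[k]] <- data.frame(entity = entity, residue = k, code = code,
                            atom = p$name, element = p$element,
                            x = p$x, y = p$y, z = p$z,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$confidence <- if (identical(confidence, "gradient")) {
    round(95 - 60 * (atoms$residue - 1) / max(1, n - 1), 2)
  } else as.numeric(confidence)
  model <- structure_model(atoms)
  attr(model, "bonds") <- all_bonds
  attr(model, "graph") <- graph
  model
}

#' Inject a single stereochemical defect into a synthetic glycan model
#'
#' Rebuilds the model from its recorded topology with exactly the requested
#' defect (epimer flip, anomer flip, retained leaving oxygen, or flattened
#' ring) introduced at the target residue; all construction parameters are
#' otherwise identical, so the validator should report that defect and
#' nothing else.
#'
#' @param model A model produced by \code{\link{build_glycan_coords}}.
#' @param spec \code{list(residue =, class =, center =)}; \code{center}
#'   (ring-carbon name) is required for \code{"epimer-flip"}.
#' @return The corrupted \code{structure_model}.
#' @export
corrupt <- function(model, spec) {
  graph <- attr(model, "graph")
  if (is.null(graph)) {
    stop("corrupt() requires a model built by build_glycan_coords()",
         call. = FALSE)
  }
  classes <- c("epimer-flip", "anomer-flip", "retain-leaving-oxygen",
               "ring-flatten")
  if (!spec$class %in% classes) {
    stop("unknown corruption class '", spec$class, "'", call. = FALSE)
  }
  if (spec$residue < 1 || spec$residue > length(graph$residues)) {
    stop("corruption target residue does not exist", call. = FALSE)
  }
  if (spec$class == "retain-leaving-oxygen" && spec$residue == graph$root_index) {
    stop("the root residue keeps its anomeric hydroxyl; nothing to retain",
         call. = FALSE)
  }
  if (spec$class == "epimer-flip") {
    def <- .sugar_def(graph$residues[[spec$residue]]$sugar_name)
    if (is.null(spec$center) || !spec$center %in% names(def$substituents)) {
      stop("epimer-flip requires a substituted ring-carbon center",
           call. = FALSE)
    }
  }
  ent <- unique(model$atoms$entity)[1]
  conf <- model$atoms$confidence[1]
  build_glycan_coords(graph, entity = ent, confidence = conf,
                      overrides = list(spec))
}
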