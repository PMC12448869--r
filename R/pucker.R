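# Cremer-Pople ring puckering: forward analysis (coordinates -> Q, theta,
# phi), canonical conformer table, and nearest-vertex classification.

#' Cremer-Pople puckering parameters
#'
#' Computes the puckering amplitude and phase of a 5- or 6-membered ring
#' from ordered ring coordinates: atoms are centered, the unique mean plane
#' is defined through the two in-plane Fourier sums, per-atom displacements
#' z_j are projected onto its normal, and the puckering coordinates are the
#' discrete Fourier amplitudes of z.  For 6-rings \eqn{Q = \sqrt{q_2^2 +
#' q_3^2}}, \eqn{\cos\theta = q_3/Q}; for 5-rings there is a single pair
#' (q_2, phi_2) and theta is undefined.
#'
#' Ring atoms must be ordered ring-oxygen first, then the anomeric carbon,
#' then ascending carbons (O5, C1, ..., C5 for aldopyranoses).  Under this
#' convention the 4C1 chair of D-pyranoses sits at theta = 0.
#'
#' @param coords Numeric matrix (5 or 6) x 3 of ordered ring coordinates.
#' @return List with \code{Q} (Angstrom), \code{theta} (degrees, [0, 180];
#'   \code{NA} for 5-rings), \code{phi} (degrees, [0, 360)), and the raw
#'   displacements \code{z}.
#' @references Cremer & Pople (1975) J Am Chem Soc 97:1354-1358.
#' @export
cremer_pople <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (!(n %in% c(5L, 6L)) || ncol(coords) != 3) {
    stop("coords must be a 5x3 or 6x3 matrix of ordered ring atoms",
         call. = FALSE)
  }
  ctr <- colMeans(coords)
  r <- sweep(coords, 2, ctr)
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rp <- colSums(r * sin(ang))
  rpp <- colSums(r * cos(ang))
  nvec <- c(rp[2] * rpp[3] - rp[3] * rpp[2],
            rp[3] * rpp[1] - rp[1] * rpp[3],
            rp[1] * rpp[2] - rp[2] * rpp[1])
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-12) stop("degenerate (collinear) ring coordinates", call. = FALSE)
  nvec <- nvec / nn
  z <- as.numeric(r %*% nvec)
  Q <- sqrt(sum(z^2))
  deg <- function(x) {
    d <- (x * 180 / pi) %% 360
    if (d >= 360 - 1e-9) 0 else d
  }
  ang2 <- 2 * ang  # m = 2 Fourier angle
  qc <- sqrt(2 / n) * sum(z * cos(ang2))
  qs <- -sqrt(2 / n) * sum(z * sin(ang2))
  q2 <- sqrt(qc^2 + qs^2)
  phi <- if (q2 > 1e-12) deg(atan2(qs, qc)) else 0
  if (n == 6L) {
    q3 <- sqrt(1 / n) * sum(z * (-1)^(seq_len(n) - 1))
    theta <- if (Q > 1e-12) acos(max(-1, min(1, q3 / Q))) * 180 / pi else 0
    list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3, z = z)
  } else {
    list(Q = Q, theta = NA_real_, phi = phi, q2 = q2, q3 = NA_real_, z = z)
  }
}

# ---- canonical conformer table ---------------------------------------------
# Vertices are derived from ideal out-of-plane patterns (atom k above /
# below the best plane), projected onto the (theta, phi) sphere, so labels
# and angles stay mutually consistent by construction.  Ring positions
# j = 1..6 are (O, C1, C2, C3, C4, C5); labels use "O" for the ring oxygen.

.conformer_vertex <- function(pattern, n = 6L) {
  # pattern: numeric z-weight per ring position; project out mean and m=1,
  # then read (theta, phi) of the remainder
  ang <- 2 * pi * (seq_len(n) - 1) / n
  z <- pattern - mean(pattern)
  # remove m = 1 component
  c1 <- sum(z * cos(ang)) * 2 / n
  s1 <- sum(z * sin(ang)) * 2 / n
  z <- z - c1 * cos(ang) - s1 * sin(ang)
  z <- z / sqrt(sum(z^2))
  cp <- cremer_pople(cbind(1.45 * cos(ang), -1.45 * sin(ang), 0.6 * z))
  c(theta = cp$theta, phi = cp$phi)
}

.pyranose_conformers <- function() {
  labs <- c("O", "1", "2", "3", "4", "5")
  out <- list()
  addv <- function(name, pattern) {
    v <- .conformer_vertex(pattern)
    out[[length(out) + 1L]] <<- data.frame(label = name, theta = v["theta"],
                                           phi = v["phi"])
  }
  e <- function(k) { p <- numeric(6); p[k] <- 1; p }
  # chairs
  addv("4C1", rep(c(1, -1), 3))
  addv("1C4", rep(c(-1, 1), 3))
  # boats: para pair (k, k+3) displaced to one side; in the conventional
  # labels numbered atoms precede the ring oxygen ("3,OB", "B3,O")
  pair_label <- function(up) {
    l <- labs[up]
    paste(c(sort(l[l != "O"]), l[l == "O"]), collapse = ",")
  }
  for (k in 1:3) {
    up <- c(k, k + 3)
    p <- rep(-0.5, 6); p[up] <- 1
    addv(paste0(pair_label(up), "B"), p)
    addv(paste0("B", pair_label(up)), -p)
  }
  # twist-boats (skews): two para pairs displaced to opposite sides; the
  # canonical six names follow the standard pyranose wheel
  skew <- function(up1, down1) {
    p <- numeric(6)
    p[c(up1, (up1 + 2) %% 6 + 1)] <- 1
    p[c(down1, (down1 + 2) %% 6 + 1)] <- -1
    p
  }
  addv("3S1", skew(1, 2))   # up O,C3 / down C1,C4
  addv("1S3", -skew(1, 2))
  addv("OS2", skew(1, 3))   # up O,C3 / down C2,C5
  addv("2SO", -skew(1, 3))
  addv("5S1", skew(3, 2))   # up C2,C5 / down C1,C4
  addv("1S5", -skew(3, 2))
  # envelopes: single atom out of plane
  for (k in 1:6) {
    addv(paste0(labs[k], "E"), e(k))
    addv(paste0("E", labs[k]), -e(k))
  }
  # half-chairs: adjacent pair, opposite sides
  for (k in 1:6) {
    l <- k %% 6 + 1
    addv(paste0(labs[k], "H", labs[l]), e(k) - e(l))
    addv(paste0(labs[l], "H", labs[k]), e(l) - e(k))
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  tbl
}

.furanose_conformers <- function() {
  labs <- c("O", "1", "2", "3", "4")
  out <- list()
  addv <- function(name, pattern) {
    ang <- 2 * pi * (0:4) / 5
    z <- pattern - mean(pattern)
    c1 <- sum(z * cos(ang)) * 2 / 5
    s1 <- sum(z * sin(ang)) * 2 / 5
    z <- z - c1 * cos(ang) - s1 * sin(ang)
    z <- z / sqrt(sum(z^2))
    cp <- cremer_pople(cbind(1.4 * cos(ang), -1.4 * sin(ang), 0.45 * z))
    out[[length(out) + 1L]] <<- data.frame(label = name, theta = NA_real_,
                                           phi = cp$phi)
  }
  e <- function(k) { p <- numeric(5); p[k] <- 1; p }
  for (k in 1:5) {
    addv(paste0(labs[k], "E"), e(k))
    addv(paste0("E", labs[k]), -e(k))
    l <- k %% 5 + 1
    addv(paste0(labs[k], "T", labs[l]), e(k) - e(l))
    addv(paste0(labs[l], "T", labs[k]), e(l) - e(k))
  }
  tbl <- do.call(rbind, out)
  rownames(tbl) <- NULL
  tbl
}

.conformer_env <- new.env(parent = emptyenv())

#' Canonical ring conformer table
#'
#' The 38 canonical pyranose conformers (2 chairs, 6 boats, 6 twist-boats,
#' 12 envelopes, 12 half-chairs) with their (theta, phi) vertices, or the
#' furanose envelope/twist wheel (20 entries, phi only).  Vertices are
#' derived from ideal displacement patterns, so e.g. 3,OB sits at
#' theta = 90, phi = 0 under the packaged atom-ordering convention.
#'
#' @param ring_size 5 or 6.
#' @return data.frame with columns \code{label}, \code{theta}, \code{phi}.
#' @export
conformer_table <- function(ring_size = 6L) {
  key <- as.character(ring_size)
  if (is.null(.conformer_env[[key]])) {
    .conformer_env[[key]] <- if (ring_size == 6L) .pyranose_conformers()
                             else if (ring_size == 5L) .furanose_conformers()
                             else stop("ring_size must be 5 or 6", call. = FALSE)
  }
  .conformer_env[[key]]
}

#' Classify a ring pucker as its nearest canonical conformer
#'
#' Nearest vertex on the (theta, phi) sphere by angular distance (6-rings),
#' or nearest phase on the pseudorotation wheel (5-rings).  Amplitudes below
#' \code{flat_Q} are reported as \code{"planar"}.  When the angular margin
#' between the best and second-best vertex is under 10 degrees the label is
#' flagged ambiguous.
#'
#' @param Q,theta,phi Puckering parameters as from \code{\link{cremer_pople}}.
#' @param ring_size 5 or 6.
#' @param flat_Q Flatness threshold in Angstrom (default 0.1).
#' @return List: \code{label}, \code{margin} (degrees), \code{ambiguous}.
#' @export
#' @examples
#' classify_pucker(0.57, 2, 0)$label    # "4C1"
#' classify_pucker(0.76, 90, 0)$label   # "3,OB"
classify_pucker <- function(Q, theta, phi, ring_size = 6L, flat_Q = 0.1) {
  if (Q < flat_Q) {
    return(list(label = "planar", margin = NA_real_, ambiguous = FALSE))
  }
  tbl <- conformer_table(ring_size)
  rad <- pi / 180
  if (ring_size == 6L) {
    u <- c(sin(theta * rad) * cos(phi * rad),
           sin(theta * rad) * sin(phi * rad),
           cos(theta * rad))
    vth <- tbl$theta * rad; vph <- tbl$phi * rad
    d <- acos(pmin(1, pmax(-1,
      sin(vth) * cos(vph) * u[1] + sin(vth) * sin(vph) * u[2] + cos(vth) * u[3]
    ))) / rad
  } else {
    d <- abs(((tbl$phi - phi + 180) %% 360) - 180)
  }
  o <- order(d)
  margin <- d[o[2]] - d[o[1]]
  list(label = tbl$label[o[1]], margin = margin, ambiguous = margin < 10)
}
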