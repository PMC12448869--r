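# shared fixture builders for the test suite

# disaccharide with the given sugar as donor onto a Gal acceptor at O3
junction_graph <- function(sugar, anomer) {
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue("Gal", "beta"))
  g <- add_residue(g, monosaccharide_residue(sugar, anomer))
  add_linkage(g, 2, 1, 3)
}

# random glycan tree over common sugars, for round-trip property tests
random_glycan <- function(n_residues, rng) {
  sugars <- c("Glc", "Gal", "Man", "GlcNAc", "GalNAc", "Fuc", "Xyl")
  anomers <- c("alpha", "beta")
  g <- glycan_graph()
  g <- add_residue(g, monosaccharide_residue(sample(sugars, 1), sample(anomers, 1)))
  for (k in seq_len(n_residues - 1)) {
    repeat {
      acc <- sample(seq_len(length(g$residues)), 1)
      acc_def <- glycobap::ccd_registry()$sugars[[g$residues[[acc]]$sugar_name]]
      taken <- vapply(Filter(function(l) l$acceptor_index == acc, g$linkages),
                      function(l) l$acceptor_position, 0)
      free <- setdiff(c(2, 3, 4, 6), taken)
      free <- intersect(free, glycobap:::.sugar_acceptor_positions(acc_def))
      if (length(free)) break
    }
    g <- add_residue(g, monosaccharide_residue(sample(sugars, 1),
                                               sample(anomers, 1)))
    g <- add_linkage(g, length(g$residues), acc,
                     free[sample.int(length(free), 1)])
  }
  glycobap:::.canonicalize_graph(g)
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y - w*z), 2*(x*z + w*y),
           2*(x*y + w*z), 1 - 2*(x^2+z^2), 2*(y*z - w*x),
           2*(x*z - w*y), 2*(y*z + w*x), 1 - 2*(x^2+y^2)), 3, 3)
}

# batch of uniform random rotation matrices, returned as an n x 9 matrix of
# column-major 3x3 entries (quaternion construction)
random_rotation_batch <- function(n, sd_angle = NULL) {
  if (is.null(sd_angle)) {
    q <- matrix(rnorm(4 * n), n, 4)
  } else {
    # small rotations around identity: angle ~ N(0, sd_angle)
    ax <- matrix(rnorm(3 * n), n, 3)
    ax <- ax / sqrt(rowSums(ax^2))
    ang <- rnorm(n, sd = sd_angle)
    q <- cbind(cos(ang / 2), sin(ang / 2) * ax)
  }
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

# best achievable superposition rmsd over sampled rotations, via the trace
# identity rmsd^2 = (|P0|^2 + |Q0|^2 - 2 tr(R'H)) / n.  A global random
# sweep is followed by shrinking local perturbations composed onto the
# incumbent; tr((dR B)' H) = sum(dR * (H B')) keeps every stage one matrix
# product.  Independent of the closed-form SVD solution path.
sampled_rotation_rmsd <- function(P, Q, n_global = 50000, n_local = 4000,
                                  rounds = 30) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  H <- t(P0) %*% Q0
  const <- sum(P0^2) + sum(Q0^2)
  n <- nrow(P)
  glob <- random_rotation_batch(n_global)
  scores <- glob %*% as.vector(H)
  besti <- which.max(scores)
  B <- matrix(glob[besti, ], 3, 3)
  best <- scores[besti]
  scale <- 0.5
  for (r in seq_len(rounds)) {
    M <- as.vector(H %*% t(B))
    loc <- random_rotation_batch(n_local, sd_angle = scale)
    s <- loc %*% M
    i <- which.max(s)
    if (s[i] > best) {
      best <- s[i]
      B <- matrix(loc[i, ], 3, 3) %*% B
    }
    scale <- scale * 0.65
  }
  sqrt(max(0, (const - 2 * best) / n))
}
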