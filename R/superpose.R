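# Rigid superposition: closed-form least-squares (Kabsch) RMSD with
# optional iterative outlier rejection, and atom-matched glycan comparison.

#' Closed-form least-squares superposition
#'
#' Computes the proper rotation and translation minimizing the RMSD between
#' two matched point sets via singular value decomposition of the
#' covariance matrix (determinant-corrected so the rotation is never a
#' reflection).
#'
#' @param P,Q n x 3 matrices of matched coordinates (n >= 3,
#'   non-degenerate).
#' @return List: \code{rmsd}, \code{rotation} (3 x 3, applied to centered
#'   P), \code{translation}, \code{residuals} (per-pair distances after
#'   superposition).
#' @export
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' kabsch(P, P)$rmsd  # 0
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3 || nrow(P) < 3) {
    stop("P and Q must be matched n x 3 matrices with n >= 3", call. = FALSE)
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  s <- svd(H)
  if (s$d[2] < 1e-12) stop("degenerate point set (rank < 2)", call. = FALSE)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)    # P0 %*% R approximates Q0
  res <- sqrt(rowSums((P0 %*% R - Q0)^2))
  list(rmsd = sqrt(mean(res^2)), rotation = R,
       translation = cq - as.numeric(cp %*% R), residuals = res)
}

#' Superposition with iterative outlier rejection
#'
#' Mirrors refined-alignment behaviour: after each fit, pairs whose
#' residual exceeds \code{reject_sigma} standard deviations of the current
#' residuals are removed and the remaining pairs are re-fit, for up to
#' \code{cycles} cycles or until no pair is rejected.  \code{cycles = 0}
#' is exactly \code{\link{kabsch}}.
#'
#' @param P,Q Matched n x 3 coordinate matrices.
#' @param cycles Maximum refinement cycles (default 5).
#' @param reject_sigma Rejection threshold in residual standard deviations
#'   (default 2.0).
#' @return List: \code{rmsd} (refined), \code{rmsd_all} (all-pair rmsd of
#'   the initial fit), \code{n_retained}, \code{retained} (logical mask),
#'   \code{fit} (final \code{kabsch} result).
#' @export
align_refine <- function(P, Q, cycles = 5L, reject_sigma = 2.0) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  fit <- kabsch(P, Q)
  keep <- rep(TRUE, nrow(P))
  rmsd_all <- fit$rmsd
  if (cycles >= 1L) {
    for (cy in seq_len(cycles)) {
      res <- fit$residuals
      s <- stats::sd(res)
      if (!is.finite(s) || s < 1e-12) break
      drop <- res > reject_sigma * s
      if (!any(drop)) break
      cand <- which(keep)[!drop]
      if (length(cand) < 3) break
      keep[] <- FALSE
      keep[cand] <- TRUE
      fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    }
  }
  list(rmsd = fit$rmsd, rmsd_all = rmsd_all, n_retained = sum(keep),
       retained = keep, fit = fit)
}

#' Atom-matched comparison of two glycan structures
#'
#' Pairs atoms by (mapped residue index, atom name) after an explicit
#' residue mapping, filters to heavy atoms by default, and reports both the
#' all-atom and the outlier-rejected superposition RMSD together with
#' per-residue mean residuals.
#'
#' @param model_a,model_b \code{structure_model}s.
#' @param entity_a,entity_b Entity selectors.
#' @param residue_map Named mapping of model-a residue indices to model-b
#'   residue indices, e.g. \code{c("3" = 3, "4" = 4)}; NULL maps
#'   identically over shared residue indices.
#' @param atoms Optional atom-name filter (e.g. ring atoms only).
#' @param cycles,reject_sigma Refinement settings (see
#'   \code{\link{align_refine}}).
#' @return List: \code{n_pairs}, \code{rmsd_all}, \code{rmsd_refined},
#'   \code{n_retained}, \code{per_residue} (data.frame), \code{pairs}.
#' @export
compare_glycans <- function(model_a, model_b, entity_a = "NG", entity_b = "NG",
                            residue_map = NULL, atoms = NULL,
                            cycles = 5L, reject_sigma = 2.0) {
  a <- model_a$atoms[model_a$atoms$entity == entity_a &
                     model_a$atoms$element != "H", , drop = FALSE]
  b <- model_b$atoms[model_b$atoms$entity == entity_b &
                     model_b$atoms$element != "H", , drop = FALSE]
  if (!is.null(atoms)) {
    a <- a[a$atom %in% atoms, , drop = FALSE]
    b <- b[b$atom %in% atoms, , drop = FALSE]
  }
  if (is.null(residue_map)) {
    shared <- intersect(unique(a$residue), unique(b$residue))
    residue_map <- stats::setNames(shared, shared)
  }
  pairs <- list()
  for (ra in names(residue_map)) {
    ra_i <- as.integer(ra); rb_i <- residue_map[[ra]]
    aa <- a[a$residue == ra_i, , drop = FALSE]
    bb <- b[b$residue == rb_i, , drop = FALSE]
    common <- intersect(aa$atom, bb$atom)
    for (at in common) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        residue_a = ra_i, residue_b = rb_i, atom = at,
        xa = aa$x[aa$atom == at], ya = aa$y[aa$atom == at],
        za = aa$z[aa$atom == at],
        xb = bb$x[bb$atom == at], yb = bb$y[bb$atom == at],
        zb = bb$z[bb$atom == at])
    }
  }
  if (!length(pairs)) stop("empty atom pairing", call. = FALSE)
  pr <- do.call(rbind, pairs)
  if (nrow(pr) < 3) stop("fewer than 3 atom pairs", call. = FALSE)
  P <- as.matrix(pr[, c("xa", "ya", "za")])
  Q <- as.matrix(pr[, c("xb", "yb", "zb")])
  fit0 <- kabsch(P, Q)
  ref <- align_refine(P, Q, cycles = cycles, reject_sigma = reject_sigma)
  pr$residual <- fit0$residuals
  per_res <- stats::aggregate(residual ~ residue_a, data = pr, FUN = mean)
  list(n_pairs = nrow(pr), rmsd_all = fit0$rmsd, rmsd_refined = ref$rmsd,
       n_retained = ref$n_retained, per_residue = per_res, pairs = pr)
}
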