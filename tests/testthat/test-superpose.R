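test_that("closed-form superposition nulls rigid transformations", {
  set.seed(101)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch(P, P)$rmsd, 0, tolerance = 1e-12)

  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, c(3, -7, 2), "+")
  expect_lt(kabsch(P, Q)$rmsd, 1e-9)
  # rotation is proper
  expect_equal(det(kabsch(P, Q)$rotation), 1, tolerance = 1e-9)

  # rmsd invariant under pre-rotation of either argument, symmetric
  N <- P + matrix(rnorm(30, sd = 0.3), 10, 3)
  r0 <- kabsch(P, N)$rmsd
  expect_equal(kabsch(P %*% t(random_rotation()), N)$rmsd, r0,
               tolerance = 1e-9)
  expect_equal(kabsch(N, P)$rmsd, r0, tolerance = 1e-9)

  expect_error(kabsch(P[1:2, ], P[1:2, ]), "n >= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "degenerate")
})

test_that("closed form beats (and matches) sampled-rotation brute force", {
  set.seed(202)
  for (i in 1:6) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    exact <- kabsch(P, Q)$rmsd
    sampled <- sampled_rotation_rmsd(P, Q, n_global = 5000, n_local = 800,
                                     rounds = 18)
    expect_lte(exact, sampled + 1e-12)
    expect_lt(sampled - exact, 1e-3)
  }
})

test_that("iterative refinement rejects outliers and reduces to Kabsch", {
  set.seed(303)
  P <- matrix(rnorm(45), 15, 3)
  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, c(1, 2, 3), "+")

  clean <- align_refine(P, Q)
  expect_identical(clean$n_retained, 15L)
  expect_equal(clean$rmsd, clean$rmsd_all, tolerance = 1e-12)

  Qo <- Q
  Qo[7, ] <- Qo[7, ] + c(10, 0, 0)
  ref <- align_refine(P, Qo)
  expect_identical(ref$n_retained, 14L)
  expect_false(ref$retained[7])
  expect_lt(ref$rmsd, 1e-9)          # back to the clean fit
  expect_gt(ref$rmsd_all, 1)         # the contaminated all-pair fit

  # cycles = 0 is exactly plain Kabsch
  r0 <- align_refine(P, Qo, cycles = 0)
  k <- kabsch(P, Qo)
  expect_identical(r0$rmsd, k$rmsd)
  expect_identical(r0$n_retained, 15L)
  expect_identical(r0$fit$rotation, k$rotation)
})

test_that("glycan comparison pairs atoms and reports residuals", {
  m <- build_glycan_coords(template_glycan("M9"))
  self <- compare_glycans(m, m)
  expect_equal(self$rmsd_all, 0, tolerance = 1e-12)
  expect_equal(self$rmsd_refined, 0, tolerance = 1e-12)

  # a rigid copy with one residue translated: after re-fit the rmsd of the
  # full pairing reflects the known displacement
  m2 <- m
  sel <- m2$atoms$residue == 9
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 2
  cmp <- compare_glycans(m, m2)
  expect_gt(cmp$rmsd_all, 0.1)
  res9 <- cmp$per_residue$residual[cmp$per_residue$residue_a == 9]
  expect_gt(res9, max(cmp$per_residue$residual[cmp$per_residue$residue_a != 9]))
  # refinement rejects the moved residue and recovers the clean fit
  expect_lt(cmp$rmsd_refined, 0.05)

  # explicit residue mapping and atom filters
  sub <- compare_glycans(m, m, residue_map = c("3" = 3, "4" = 4, "6" = 6),
                         atoms = c("C1", "C2", "C3", "C4", "C5", "O5"))
  expect_identical(sub$n_pairs, 18L)
  expect_error(compare_glycans(m, m, residue_map = c("99" = 99)),
               "empty|fewer")
})
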