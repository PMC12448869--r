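test_that("inverse-built rings recover their puckering parameters exactly", {
  for (Q in c(0.3, 0.57, 0.76)) {
    for (theta in c(10, 54.7, 90, 125.3, 170)) {
      for (phi in c(0, 75, 210, 330)) {
        cp <- cremer_pople(build_ring(6, Q, theta, phi))
        expect_equal(cp$Q, Q, tolerance = 1e-9)
        expect_equal(cp$theta, theta, tolerance = 1e-7)
        expect_equal(cp$phi, phi, tolerance = 1e-7)
      }
    }
  }
  # poles: theta and Q recovered; phi undefined there
  cp0 <- cremer_pople(build_ring(6, 0.57, 0, 0))
  expect_equal(cp0$theta, 0, tolerance = 1e-9)
  cp180 <- cremer_pople(build_ring(6, 0.57, 180, 0))
  expect_equal(cp180$theta, 180, tolerance = 1e-9)
  # furanose: single (Q, phi) pair
  cp5 <- cremer_pople(build_ring(5, 0.35, phi = 90))
  expect_equal(cp5$Q, 0.35, tolerance = 1e-9)
  expect_equal(cp5$phi, 90, tolerance = 1e-7)
  expect_true(is.na(cp5$theta))

  expect_error(build_ring(6, 2.0), "infeasible")
  expect_error(cremer_pople(matrix(0, 6, 3)), "degenerate")
})

test_that("displacements satisfy the mean-plane conditions", {
  set.seed(11)
  for (i in 1:20) {
    cp <- cremer_pople(build_ring(6, runif(1, 0.2, 0.9), runif(1, 5, 175),
                                  runif(1, 0, 360)))
    expect_lt(abs(sum(cp$z)), 1e-10)
    # m=1 Fourier components vanish (mean-plane orthogonality)
    ang <- 2 * pi * (0:5) / 6
    expect_lt(abs(sum(cp$z * cos(ang))), 1e-10)
    expect_lt(abs(sum(cp$z * sin(ang))), 1e-10)
  }
})

test_that("puckering parameters are invariant under rigid motion", {
  set.seed(23)
  base <- build_ring(6, 0.64, 112, 47)
  ref <- cremer_pople(base)
  for (i in 1:15) {
    R <- random_rotation()
    moved <- sweep(base %*% t(R), 2, rnorm(3, sd = 10), "+")
    cp <- cremer_pople(moved)
    expect_equal(cp$Q, ref$Q, tolerance = 1e-9)
    expect_equal(cp$theta, ref$theta, tolerance = 1e-9)
    expect_equal(cp$phi, ref$phi, tolerance = 1e-9)
  }
})

test_that("classification covers chairs, boats, skews, and the flat ring", {
  expect_identical(classify_pucker(0.57, 2, 0)$label, "4C1")
  expect_identical(classify_pucker(0.57, 2, 271)$label, "4C1")
  expect_identical(classify_pucker(0.57, 178, 45)$label, "1C4")
  expect_identical(classify_pucker(0.76, 90, 0)$label, "3,OB")
  expect_identical(classify_pucker(0.76, 90, 180)$label, "B3,O")
  expect_identical(classify_pucker(0.76, 90, 30)$label, "3S1")
  expect_identical(classify_pucker(0.76, 90, 330)$label, "OS2")
  expect_identical(classify_pucker(0.02, 90, 0)$label, "planar")
  # near-boundary labels are flagged ambiguous
  expect_true(classify_pucker(0.76, 90, 14.9)$ambiguous)

  tbl <- conformer_table(6)
  expect_identical(nrow(tbl), 38L)
  expect_identical(sum(grepl("C", tbl$label)), 2L)
  expect_identical(sum(grepl("B", tbl$label)), 6L)
  expect_identical(sum(grepl("S", tbl$label)), 6L)
  expect_identical(sum(grepl("E", tbl$label)), 12L)
  expect_identical(sum(grepl("H", tbl$label)), 12L)
  expect_identical(nrow(conformer_table(5)), 20L)
})

test_that("the 3,OB vertex agrees with the label-from-geometry oracle", {
  ring <- build_ring(6, 0.76, 90, 0)
  # geometry oracle: fit a plane through the four atoms that are not C3/O5
  # (ring order O, C1, C2, C3, C4, C5 -> rows 1 and 4 are O and C3) and
  # check both displaced atoms sit on the same (positive) side
  out_idx <- c(1, 4)
  plane <- ring[-out_idx, ]
  ctr <- colMeans(plane)
  sv <- svd(sweep(plane, 2, ctr))
  normal <- sv$v[, 3]
  d_out <- as.numeric(sweep(ring[out_idx, ], 2, ctr) %*% normal)
  d_in <- as.numeric(sweep(plane, 2, ctr) %*% normal)
  expect_lt(max(abs(d_in)), 0.15)         # four-atom plane is a real plane
  expect_true(all(d_out > 0.4) || all(d_out < -0.4))  # prow and stern together
  expect_identical(classify_pucker(0.76, 90, 0)$label, "3,OB")

  # the inverted boat gets the inverted label
  expect_identical(classify_pucker(0.76, 90, 180)$label, "B3,O")
})
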