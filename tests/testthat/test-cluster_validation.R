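test_that("cluster strain reproduces analytic values for affine marker motion", {
  # simple shear gamma = 0.2: every constant-strain tet sees the field
  # tensor, so cluster MPS equals the analytic eigenvalue
  spec <- deformation_spec("simple_shear", peak = 0.2, duration = 0.01)
  fx <- make_cluster_fixture(spec)
  cs <- cluster_strain(fx$cluster, fx$times, fx$marker_disp)
  expect_equal(max(cs$mps), shear_mps(0.2), tolerance = 1e-12)
  # per-tet values identical under the affine field
  t_pk <- which.max(cs$mps)
  expect_lt(diff(range(cs$tet_mps[t_pk, ])), 1e-12)
  # analytic max shear (E1 - E3) / 2
  E <- green_lagrange(matrix(c(1, 0, 0, 0.2, 1, 0, 0, 0, 1), 3L))
  ev <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(max(cs$max_shear), (ev[1] - ev[3]) / 2, tolerance = 1e-12)
})

test_that("cluster strain is connectivity-independent for affine fields and zero for rigid motion", {
  set.seed(61)
  A <- random_affine_matrix()
  spec <- deformation_spec("affine", peak = 1, duration = 0.01, matrix = A)
  fx <- make_cluster_fixture(spec)
  cs <- cluster_strain(fx$cluster, fx$times, fx$marker_disp)
  # alternative connectivity over the same markers
  alt_tets <- fx$cluster$tets[c(2, 4, 6, 8, 1, 3, 5, 7), ]
  alt <- cluster_definition(fx$cluster$marker_coords, alt_tets)
  cs2 <- cluster_strain(alt, fx$times, fx$marker_disp)
  expect_equal(cs2$mps, cs$mps, tolerance = 1e-12)
  ev <- principal_strains(green_lagrange(A))
  expect_equal(max(cs$mps), ev[1], tolerance = 1e-10)
  # rigid motion: identically zero strain
  rspec <- deformation_spec("rigid_rotation", peak = 1.1, duration = 0.01,
                            axis = c(1, 2, 0.5), translation = c(4, -2, 1))
  rfx <- make_cluster_fixture(rspec)
  rcs <- cluster_strain(rfx$cluster, rfx$times, rfx$marker_disp)
  expect_lt(max(abs(rcs$mps)), 1e-9)
  expect_lt(max(abs(rcs$max_shear)), 1e-9)
})

test_that("tet exclusion restricts the cluster average and errors are raised", {
  spec <- deformation_spec("simple_shear", peak = 0.2, duration = 0.01)
  fx <- make_cluster_fixture(spec, exclude = 5:8)
  cs <- cluster_strain(fx$cluster, fx$times, fx$marker_disp)
  expect_identical(ncol(cs$tet_mps), 4L)
  expect_identical(cs$included, 1:4)
  # excluding everything is an error
  fx_all <- make_cluster_fixture(spec)
  all_ex <- cluster_definition(fx_all$cluster$marker_coords,
                               fx_all$cluster$tets, exclude = 1:8)
  expect_error(cluster_strain(all_ex, fx_all$times, fx_all$marker_disp),
               "excluded")
  # degenerate reference tet named in the error
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))
  expect_error(cluster_definition(bad, matrix(1:4, 1L)),
               "tetrahedron 1")
})

test_that("CORA sub-ratings behave per the configured formulas", {
  p <- make_cora_pair("identical")
  r <- cora_score(p$reference, p$test, p$times)
  expect_equal(r$total, 1.0)
  expect_equal(c(r$shape, r$size, r$phase), c(1, 1, 1))
  expect_identical(r$label, "Excellent")
  # doubled magnitude: shape and phase stay 1, size = 1/2 by the
  # min/max L2-norm ratio, total the weighted mean
  p2 <- make_cora_pair("scaled", scale = 2)
  r2 <- cora_score(p2$reference, p2$test, p2$times)
  expect_equal(r2$shape, 1, tolerance = 1e-12)
  expect_equal(r2$phase, 1)
  expect_equal(r2$size, 0.5, tolerance = 1e-12)
  cfg <- cora_config()
  expect_equal(r2$total,
               (cfg$w_shape * 1 + cfg$w_size * 0.5 + cfg$w_phase * 1) /
                 (cfg$w_shape + cfg$w_size + cfg$w_phase),
               tolerance = 1e-12)
  expect_lt(r2$total, 1)
  # shift at the maximum allowed window: phase rating 0
  n <- 201L
  m_max <- floor(cora_config()$max_shift_frac * n)
  p3 <- make_cora_pair("shifted", n = n, shift_frac = m_max / n)
  r3 <- cora_score(p3$reference, p3$test, p3$times)
  expect_equal(r3$phase, 0)
  # invariance to a common rescale of both curves
  r4 <- cora_score(3.7 * p2$reference, 3.7 * p2$test, p2$times)
  expect_equal(r4$total, r2$total, tolerance = 1e-12)
  expect_error(cora_score(numeric(201), p$test, p$times), "all-zero")
})

test_that("CORA totals degrade monotonically with phase shift", {
  n <- 201L
  shifts <- c(0, 5, 10, 20, 30, 40)
  totals <- vapply(shifts, function(m) {
    p <- make_cora_pair("shifted", n = n, shift_frac = m / n)
    cora_score(p$reference, p$test, p$times)$total
  }, numeric(1))
  expect_true(all(diff(totals) < 1e-12))
  # detected shift agrees with an independent brute-force correlation scan
  p <- make_cora_pair("shifted", n = n, shift_frac = 20 / n)
  r <- cora_score(p$reference, p$test, p$times)
  scan <- vapply(-40:40, function(m) {
    ref <- p$reference; tst <- p$test
    if (m >= 0) { a <- ref[1:(n - m)]; b <- tst[(1 + m):n] }
    else { a <- ref[(1 - m):n]; b <- tst[1:(n + m)] }
    s <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    if (is.finite(s)) s else 0
  }, numeric(1))
  expect_identical(r$shift, (-40:40)[which.max(scan)])
})

test_that("rating bands partition [0, 1] with upper-edge assignment", {
  expect_identical(cora_rating(0.894), "Excellent")
  expect_identical(cora_rating(0.766), "Good")
  expect_identical(cora_rating(0.516), "Fair")
  expect_identical(cora_rating(0.65), "Good")
  expect_identical(cora_rating(0.26), "Marginal")
  expect_error(cora_rating(1.2), "\\[0, 1\\]")
  # every score maps to exactly one band, boundaries to the upper band
  edges <- c(0, 0.26, 0.44, 0.65, 0.86, 1)
  eps <- 1e-9
  grid <- sort(unique(pmin(1, pmax(0, c(edges, edges - eps, edges + eps,
                                        seq(0, 1, 0.01))))))
  labs <- cora_rating(grid)
  expect_false(anyNA(labs))
  expect_identical(cora_rating(edges),
                   c("Unacceptable", "Marginal", "Fair", "Good", "Excellent",
                     "Excellent"))
})

test_that("validation reports average channels onto the sliding scale", {
  p1 <- make_cora_pair("identical")
  p2 <- make_cora_pair("scaled", scale = 2)
  rep <- validation_report(list(mps = list(reference = p1$reference,
                                           test = p1$test),
                                shear = list(reference = p2$reference,
                                             test = p2$test)),
                           times = p1$times)
  expect_identical(nrow(rep$table), 2L)
  expect_equal(rep$mean_total, mean(rep$table$total))
  expect_identical(rep$mean_label, cora_rating(rep$mean_total))
})

test_that("mixed-grid curves are resampled onto a common base", {
  t1 <- seq(0, 0.05, length.out = 101)
  t2 <- seq(0, 0.05, length.out = 51)
  y <- function(t) haversine_pulse(t, 1, 0.025)
  r <- cora_score(cbind(t1, y(t1)), cbind(t2, y(t2)))
  expect_gt(r$total, 0.99)
})
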