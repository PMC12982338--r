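test_that("arc-length resampling follows the step and remainder rules", {
  # straight 10 mm line, step 1.0 -> 11 nodes / 10 beams
  sl <- cbind(seq(0, 10, length.out = 41), 0, 0)
  f <- resample_streamline(sl, 1.0)
  expect_identical(nrow(f), 11L)
  expect_equal(diff(f[, 1]), rep(1, 10), tolerance = 1e-12)
  # 10.4 mm: remainder 0.4 < step/2 merged into the last beam -> 10 beams
  sl2 <- cbind(seq(0, 10.4, length.out = 41), 0, 0)
  f2 <- resample_streamline(sl2, 1.0)
  expect_identical(nrow(f2), 11L)
  expect_equal(f2[11, 1], 10.4, tolerance = 1e-12)
  expect_equal(f2[11, 1] - f2[10, 1], 1.4, tolerance = 1e-12)
  # 10.6 mm: remainder kept as a short final beam -> 11 beams
  sl3 <- cbind(seq(0, 10.6, length.out = 41), 0, 0)
  f3 <- resample_streamline(sl3, 1.0)
  expect_identical(nrow(f3), 12L)
  expect_equal(f3[12, 1] - f3[11, 1], 0.6, tolerance = 1e-12)
  # shorter than the step: single beam between the endpoints
  f4 <- resample_streamline(rbind(c(0, 0, 0), c(0.4, 0, 0)), 1.0)
  expect_identical(nrow(f4), 2L)
  # semicircle of radius 10: resampled length within 0.5% of pi * r
  th <- seq(0, pi, length.out = 400)
  semi <- cbind(10 * cos(th), 10 * sin(th), 0)
  f5 <- resample_streamline(semi, 1.0)
  L <- sum(sqrt(rowSums(diff(f5)^2)))
  expect_lt(abs(L - pi * 10) / (pi * 10), 0.005)
})

test_that("direction canonicalization flips on negative component product", {
  expect_equal(canonicalize_direction(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(canonicalize_direction(c(-1, 2, 3)), c(1, -2, -3))
  # zero product: strict mode keeps, robust applies first-nonzero-positive
  expect_equal(canonicalize_direction(c(1, 0, 0), mode = "strict"), c(1, 0, 0))
  expect_equal(canonicalize_direction(c(1, 0, 0), mode = "robust"), c(1, 0, 0))
  expect_equal(canonicalize_direction(c(-1, 0, 0), mode = "strict"), c(-1, 0, 0))
  expect_equal(canonicalize_direction(c(-1, 0, 0), mode = "robust"), c(1, 0, 0))
  expect_error(canonicalize_direction(c(0, 0, 0)), "zero")
  # idempotence and antipodal collapse on random vectors (both modes for
  # nonzero product; robust also for zero-product vectors)
  set.seed(21)
  v <- matrix(rnorm(300), ncol = 3L)
  for (mode in c("strict", "robust")) {
    cv <- canonicalize_direction(v, mode = mode)
    expect_equal(canonicalize_direction(cv, mode = mode), cv)
    expect_equal(canonicalize_direction(-v, mode = mode), cv)
  }
})

test_that("tract sets conserve fiber counts through resampling and transforms", {
  set.seed(22)
  tr <- make_bundle("arc", n_fibers = 7, label = "TR_P_L", radius = 8,
                    angle = pi / 2, seed = 3)
  cnt <- tract_counts(tr)
  expect_identical(cnt$n_fibers, 7L)
  M <- diag(c(2, 2, 2, 1))
  tr2 <- affine_transform_tracts(tr, M)
  expect_identical(tract_counts(tr2)$n_fibers, 7L)
  # uniform scale 2 doubles every beam reference length
  for (i in seq_along(tr$TR_P_L)) {
    l1 <- sqrt(rowSums(diff(tr$TR_P_L[[i]])^2))
    l2 <- sqrt(rowSums(diff(tr2$TR_P_L[[i]])^2))
    expect_equal(l2, 2 * l1, tolerance = 1e-12)
  }
  # identity transform is exact
  tr3 <- affine_transform_tracts(tr, diag(4))
  expect_identical(tr3$TR_P_L, tr$TR_P_L)
})

test_that("material axes average canonicalized beam directions per element", {
  m <- make_box_mesh(1, 1, 1, 2.0)
  # one straight fiber along +x through the single element
  tr <- tract_set(list(CST = list(cbind(c(0.2, 1.0, 1.8), 1, 1))))
  ax <- assign_material_axes(m, tr)
  expect_equal(ax$axes[1, ], c(1, 0, 0), tolerance = 1e-12)
  # two antipodal diagonal fibers collapse to one representative
  f1 <- cbind(c(0.2, 1.8), c(0.2, 1.8), c(1, 1))       # along (1, 1, 0)
  f2 <- cbind(c(1.8, 0.2), c(1.8, 0.2), c(1.2, 1.2))   # along (-1, -1, 0)
  ax2 <- assign_material_axes(m, tract_set(list(CC_B = list(f1, f2))))
  expect_equal(ax2$axes[1, ], c(1, 1, 0) / sqrt(2), tolerance = 1e-12)
  # element traversed by no fiber is absent
  m2 <- make_box_mesh(2, 1, 1, 2.0)
  ax3 <- assign_material_axes(m2, tr)
  expect_false(ax3$present[2])
  expect_true(all(is.na(ax3$axes[2, ])))
  # axis-aligned opposite fibers cancel in strict mode (degenerate, warned)
  g1 <- cbind(c(0.2, 1.8), 1, 1)
  g2 <- cbind(c(1.8, 0.2), 1.2, 1.2)
  expect_warning(
    ax4 <- assign_material_axes(m, tract_set(list(ML = list(g1, g2))),
                                mode = "strict"),
    "degenerate")
  expect_true(ax4$degenerate[1])
  # robust mode resolves them
  ax5 <- assign_material_axes(m, tract_set(list(ML = list(g1, g2))))
  expect_equal(ax5$axes[1, ], c(1, 0, 0), tolerance = 1e-12)
})

test_that("material axes are invariant to reversing fiber node order", {
  set.seed(23)
  m <- make_box_mesh(4, 4, 4, 2.5)
  for (rep in 1:3) {
    tr <- make_bundle("helix", n_fibers = 4, label = "AF", radius = 3,
                      pitch = 3, turns = 1,
                      start = c(5, 5, 2), seed = rep)
    rev_tr <- tract_set(list(AF = lapply(tr$AF, function(f)
      f[rev(seq_len(nrow(f))), ])))
    a1 <- assign_material_axes(m, tr)
    a2 <- assign_material_axes(m, rev_tr)
    expect_equal(a2$axes, a1$axes, tolerance = 1e-10)
    expect_identical(a2$present, a1$present)
  }
})

test_that("keyword export round-trips the material axis and skips absent elements", {
  m <- make_box_mesh(2, 1, 1, 2.0)
  tr <- tract_set(list(CST = list(cbind(c(0.2, 1.0, 1.8), 1, 1))))
  ax <- assign_material_axes(m, tr)
  path <- withr::local_tempfile(fileext = ".k")
  info <- export_solid_ortho(ax, m, path)
  expect_identical(info$n_written, 1L)
  expect_identical(info$n_skipped, 1L)
  back <- read_solid_ortho(path)
  expect_identical(nrow(back), 1L)
  expect_identical(as.integer(back$element), 1L)
  expect_lt(max(abs(as.numeric(back[1, c("a1", "a2", "a3")]) - ax$axes[1, ])),
            1e-6)
  # the completion vector is orthonormal to the axis
  d <- as.numeric(back[1, c("d1", "d2", "d3")])
  expect_lt(abs(sum(d * ax$axes[1, ])), 1e-6)
  expect_equal(sum(d^2), 1, tolerance = 1e-6)
})
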