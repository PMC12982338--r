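test_that("fibers embed with ordered hosts and natural coordinates on a box row", {
  m <- make_box_mesh(10, 1, 1, 1.0)
  # straight fiber along the row axis, nodes at x = 0.5, 1.5, ..., 9.5
  fiber <- cbind(seq(0.5, 9.5, 1), 0.5, 0.5)
  emb <- embed_fibers(m, tract_set(list(CST = list(fiber))))
  expect_identical(emb$summary$n_fibers, 1L)
  expect_identical(emb$summary$n_beams, 9L)
  expect_identical(emb$nodes$element, 1:10)
  expect_equal(emb$nodes$xi1, rep(0, 10), tolerance = 1e-9)
  # node exactly on the face shared by elements 3 and 4 goes to element 3
  emb2 <- embed_fibers(m, tract_set(list(A = list(rbind(c(3, 0.5, 0.5),
                                                        c(3.4, 0.5, 0.5))))))
  expect_identical(emb2$nodes$element[1], 3L)
})

test_that("out-of-mesh fibers are dropped and near-boundary nodes snapped", {
  m <- make_box_mesh(3, 3, 3, 1.0)
  inside <- cbind(c(0.5, 2.5), 1.5, 1.5)
  outside <- cbind(c(10, 12), 1.5, 1.5)
  near <- cbind(c(0.5, 2.5), 3.2, 1.5)  # 0.2 mm above the top face
  emb <- embed_fibers(m, tract_set(list(T1 = list(inside, outside, near))),
                      snap_tol = 0.5)
  expect_identical(emb$summary$n_dropped, 1L)
  expect_identical(emb$summary$n_fibers, 2L)
  expect_identical(emb$summary$n_snapped, 2L)
  # the snapped nodes sit on the boundary surface
  snapped <- which(emb$nodes$element %in% locate_points(m, near)$element |
                     abs(emb$nodes$xi2 - 1) < 1e-9)
  expect_true(length(snapped) >= 2L)
  # everything outside tolerance: error
  far <- tract_set(list(T2 = list(outside)))
  expect_error(embed_fibers(m, far), "outside the mesh")
})

test_that("dynamic axonal strain matches closed forms per measure", {
  m <- make_box_mesh(4, 4, 4, 1.0)
  # fiber along x under uniform stretch diag(1.2, 1, 1)
  fib_x <- cbind(seq(0.5, 3.5, 0.5), 2, 2)
  tr <- tract_set(list(CC_B = list(fib_x)))
  emb <- embed_fibers(m, tr)
  A <- diag(c(1.2, 1, 1))
  set.seed(41)
  disp <- affine_history(m, A)
  expect_equal(max(axonal_strain_dynamic(emb, disp, "green")$peaks), 0.22,
               tolerance = 1e-12)
  expect_equal(max(axonal_strain_dynamic(emb, disp, "engineering")$peaks),
               0.2, tolerance = 1e-12)
  expect_equal(max(axonal_strain_dynamic(emb, disp, "logarithmic")$peaks),
               log(1.2), tolerance = 1e-12)
  # diagonal fiber: lambda^2 = a' F'F a = (1.44 + 1) / 2 = 1.22
  fib_d <- cbind(seq(0.5, 3.3, 0.4), seq(0.5, 3.3, 0.4), 2)
  emb_d <- embed_fibers(m, tract_set(list(SLF = list(fib_d))))
  eng <- axonal_strain_dynamic(emb_d, disp, "engineering")
  expect_equal(max(eng$peaks), sqrt(1.22) - 1, tolerance = 1e-10)
})

test_that("axonal strain vanishes under rigid motion and ignores node order", {
  m <- make_box_mesh(3, 3, 3, 2.0)
  set.seed(42)
  tr <- make_bundle("arc", n_fibers = 5, label = "ARC", radius = 2,
                    start = c(3, 3, 3), angle = pi, seed = 2)
  emb <- embed_fibers(m, tr)
  disp <- rigid_history(m)
  ax <- axonal_strain_dynamic(emb, disp)
  expect_lt(max(abs(ax$strain)), 1e-10)
  # node-order reversal leaves per-fiber strain sets unchanged
  rev_tr <- tract_set(list(ARC = lapply(tr$ARC, function(f)
    f[rev(seq_len(nrow(f))), ])))
  emb_r <- embed_fibers(m, rev_tr)
  A <- random_affine_matrix()
  disp_a <- affine_history(m, A)
  p1 <- sort(axonal_strain_dynamic(emb, disp_a)$peaks)
  p2 <- sort(axonal_strain_dynamic(emb_r, disp_a)$peaks)
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("static projection equals dynamic tracking for homogeneous fields", {
  m <- make_box_mesh(4, 4, 4, 1.0)
  set.seed(43)
  tr <- make_bundle("straight", n_fibers = 8, label = "B",
                    start = c(0.5, 0.6, 0.7),
                    direction = c(2, 1, 0.5), length = 3.5, spread = 0.4,
                    seed = 5)
  emb <- embed_fibers(m, tr)
  A <- random_affine_matrix()
  disp <- affine_history(m, A)
  dyn <- axonal_strain_dynamic(emb, disp, "green")
  E <- green_lagrange(A)
  d0 <- emb$ref_positions[emb$beams$node1, ] - emb$ref_positions[emb$beams$node0, ]
  axes <- d0 / sqrt(rowSums(d0^2))
  stat <- vapply(seq_len(nrow(axes)), function(b)
    axonal_strain_static(E, axes[b, ], "green"), numeric(1))
  expect_lt(max(abs(dyn$strain[nrow(dyn$strain), ] - stat)), 1e-10)
})

test_that("dynamic and static axonal strain differ under an inhomogeneous twist", {
  sc <- synth_scenario("twist_box", peak = 0.15, n = 4L, n_fibers = 10L)
  emb <- embed_fibers(sc$mesh, sc$tracts)
  dyn <- axonal_strain_dynamic(emb, sc$history, "green")
  solid <- element_strain_history(sc$mesh, sc$history)
  t_pk <- which.max(apply(solid$mps, 1L, max))
  d0 <- emb$ref_positions[emb$beams$node1, ] - emb$ref_positions[emb$beams$node0, ]
  axes <- d0 / sqrt(rowSums(d0^2))
  host <- emb$nodes$element[emb$beams$node0]
  stat <- vapply(seq_len(nrow(axes)), function(b)
    axonal_strain_static(solid$E[t_pk, host[b], , ], axes[b, ], "green"),
    numeric(1))
  diff_tw <- max(abs(dyn$strain[t_pk, ] - stat))
  expect_gt(diff_tw, 1e-4)  # genuinely different, unlike the affine case
})

test_that("static projection validates input and covers all measures", {
  E <- diag(c(0.22, 0, 0))
  expect_equal(axonal_strain_static(E, c(1, 0, 0)), 0.22)
  expect_equal(axonal_strain_static(matrix(0, 3, 3), c(0, 1, 0)), 0)
  expect_equal(axonal_strain_static(E, c(1, 0, 0), "engineering"), 0.2,
               tolerance = 1e-12)
  expect_error(axonal_strain_static(E, c(2, 0, 0)), "unit")
  expect_error(axonal_strain_static(diag(c(-0.51, 0, 0)), c(1, 0, 0),
                                    "engineering"), "non-positive")
})

test_that("peak over time is monotone as the history extends", {
  m <- make_box_mesh(3, 3, 3, 1.0)
  fib <- cbind(seq(0.5, 2.5, 0.5), 1.5, 1.5)
  emb <- embed_fibers(m, tract_set(list(F1 = list(fib))))
  spec <- deformation_spec("affine", peak = 1, duration = 0.01,
                           matrix = diag(c(1.3, 1, 1)))
  mh <- make_history(m, spec, seq(0, 0.01, length.out = 21))
  peaks_prefix <- vapply(2:21, function(k) {
    d <- displacement_history(mh$history$times[1:k],
                              mh$history$displacements[1:k, , , drop = FALSE])
    max(axonal_strain_dynamic(emb, d)$peaks)
  }, numeric(1))
  expect_true(all(diff(peaks_prefix) >= -1e-15))
})

test_that("embedding tables round-trip through CSV", {
  m <- make_box_mesh(3, 3, 3, 1.0)
  tr <- make_bundle("straight", n_fibers = 3, start = c(0.3, 1.2, 1.4),
                    direction = c(1, 0.2, 0), length = 2, spread = 0.3,
                    seed = 9)
  emb <- embed_fibers(m, tr)
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding_csv(emb, path)
  back <- read_embedding_csv(path)
  expect_identical(back$element, emb$nodes$element)
  expect_equal(back$xi1, emb$nodes$xi1, tolerance = 1e-12)
  expect_equal(as.matrix(back[, c("x", "y", "z")]), emb$ref_positions,
               tolerance = 1e-12, ignore_attr = TRUE)
})
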