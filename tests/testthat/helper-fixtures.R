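# Shared fixture helpers for the test suite. Oracles here are written
# independently of the package internals they check.

# random rotation matrix via QR of a Gaussian matrix (det corrected to +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# random invertible matrix near identity (moderate strains, positive det)
random_affine_matrix <- function(max_dev = 0.3) {
  repeat {
    A <- diag(3) + matrix(stats::runif(9, -max_dev, max_dev), 3L)
    if (det(A) > 0.3) return(A)
  }
}

# analytic peak MPS of a simple shear with parameter g:
# eigenvalues of E = [[0, g/2, 0], [g/2, g^2/2, 0], [0, 0, 0]]
shear_mps <- function(g) g^2 / 4 + sqrt((g^2 / 4)^2 + g^2 / 4)

# brute-force trilinear weights straight from the product formula
brute_trilinear_weights <- function(xi) {
  signs <- expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1))
  # reorder to the standard corner ordering used by the package
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7)
  w <- (1 + signs$sx * xi[1]) * (1 + signs$sy * xi[2]) *
    (1 + signs$sz * xi[3]) / 8
  w[ord]
}

# rigid displacement history (rotation + translation ramp) on a mesh
rigid_history <- function(mesh, n_times = 5L, angle = pi / 3) {
  R <- random_rotation()
  ctr <- colMeans(mesh$node_coords)
  trans <- stats::rnorm(3)
  times <- seq(0, 0.01, length.out = n_times)
  U <- array(0, c(n_times, nrow(mesh$node_coords), 3L))
  for (t in seq_len(n_times)) {
    a <- (t - 1) / (n_times - 1)
    # interpolate the rotation by scaling the angle about a fixed axis:
    # use matrix power via eigen of the full rotation is overkill; simply
    # blend with a second random rotation ramp by applying R^a through
    # axis-angle extraction
    th <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2)))
    if (th < 1e-12) {
      Ra <- diag(3)
    } else {
      ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
        (2 * sin(th))
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L)
      Ra <- diag(3) + sin(a * th) * K + (1 - cos(a * th)) * (K %*% K)
    }
    Xc <- sweep(mesh$node_coords, 2L, ctr)
    U[t, , ] <- Xc %*% t(Ra) - Xc +
      matrix(a * trans, nrow(mesh$node_coords), 3L, byrow = TRUE)
  }
  displacement_history(times, U, mesh)
}

# affine displacement history u = a(t) (A - I) X with a linear ramp
affine_history <- function(mesh, A, n_times = 3L) {
  times <- seq(0, 0.01, length.out = n_times)
  U <- array(0, c(n_times, nrow(mesh$node_coords), 3L))
  for (t in seq_len(n_times)) {
    a <- (t - 1) / (n_times - 1)
    U[t, , ] <- mesh$node_coords %*% t(diag(3) + a * (A - diag(3))) -
      mesh$node_coords
  }
  displacement_history(times, U, mesh)
}
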