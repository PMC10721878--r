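#' @keywords internal
"_PACKAGE"

# ---- quaternions and rotations ------------------------------------------

#' Normalize a quaternion
#'
#' @param q numeric vector of length 4 `(w, x, y, z)`.
#' @return unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) rlang::abort("cannot normalize zero quaternion")
  q / n
}

#' Quaternion product
#' @param a,b quaternions `(w, x, y, z)`.
#' @return the product `a * b`.
#' @keywords internal
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rotation matrix of a unit quaternion
#'
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from axis-angle
#' @param axis 3-vector (normalized internally); @param angle radians.
#' @keywords internal
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Skew-symmetric (cross-product) matrix
#' @keywords internal
skew <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
         nrow = 3, byrow = TRUE)
}

#' Rotation matrix from a rotation vector (exponential map)
#' @keywords internal
rotvec_to_rotmat <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3) + skew(w))
  K <- skew(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Sample orientations uniformly on the rotation group
#'
#' Draws Haar-uniform unit quaternions by normalizing 4D standard Gaussians.
#' The double cover is irrelevant for orientation averages; either sign of a
#' sampled quaternion represents the same rotation.
#'
#' @param n number of samples (>= 0).
#' @param seed integer seed; sampling is reproducible for a fixed seed.
#' @return an `n x 4` matrix of unit quaternions (rows `(w, x, y, z)`).
#' @export
sample_uniform_orientations <- function(n, seed) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    rlang::abort("`n` must be a nonnegative count")
  }
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), ncol = 4))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  g <- matrix(stats::rnorm(4L * n), ncol = 4)
  g / sqrt(rowSums(g^2))
}

#' Euler angles (fixed-axis x, y, z convention) from a unit quaternion
#'
#' Returns `(phi, theta, psi)` such that the rotation factorizes as
#' `Rz(psi) %*% Ry(theta) %*% Rx(phi)` (rotations about the fixed x, then y,
#' then z axes). Near gimbal lock (`|theta| ~ pi/2`) the canonical branch
#' `phi = 0` is returned; no error is raised.
#'
#' @param q unit quaternion.
#' @return named numeric vector `c(phi, theta, psi)` in radians.
#' @export
quat_to_euler_xyz <- function(q) {
  R <- quat_to_rotmat(q)
  # R = Rz(psi) Ry(theta) Rx(phi): R[3,1] = -sin(theta)
  st <- -R[3, 1]
  st <- max(-1, min(1, st))
  if (abs(abs(st) - 1) < 1e-9) {
    # gimbal lock: only phi +/- psi is determined; canonical branch phi = 0
    theta <- asin(st)
    phi <- 0
    psi <- atan2(-R[1, 2], R[2, 2])
  } else {
    theta <- asin(st)
    phi <- atan2(R[3, 2], R[3, 3])
    psi <- atan2(R[2, 1], R[1, 1])
  }
  c(phi = phi, theta = theta, psi = psi)
}

#' Rotation matrix from fixed-axis x,y,z Euler angles
#' @param e named vector `(phi, theta, psi)` as from [quat_to_euler_xyz()].
#' @export
euler_xyz_to_rotmat <- function(e) {
  cx <- cos(e[[1]]); sx <- sin(e[[1]])
  cy <- cos(e[[2]]); sy <- sin(e[[2]])
  cz <- cos(e[[3]]); sz <- sin(e[[3]])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# ---- building blocks and cluster structures ------------------------------

#' Create a rigid building block
#'
#' A building block is a rigid body given in its own body frame: one or more
#' spheres (the excluded-volume body) and zero or more typed point patches
#' (the specific interaction sites). Isotropic blocks (single spheres with no
#' orientation-dependent interactions) carry no rotational degrees of freedom.
#'
#' @param species_id character label for the species.
#' @param spheres matrix (n x 3) of sphere centers in the body frame, or a
#'   3-vector for a single sphere.
#' @param sphere_diameters numeric vector of sphere diameters (recycled).
#' @param patches matrix (m x 3) of patch positions in the body frame
#'   (or `NULL`).
#' @param patch_types character vector of patch type labels, one per patch.
#' @param isotropic logical; `TRUE` for blocks with no orientational degrees
#'   of freedom (they must carry no patches).
#' @return an object of class `building_block`.
#' @export
building_block <- function(species_id, spheres, sphere_diameters = 1,
                           patches = NULL, patch_types = character(),
                           isotropic = FALSE) {
  if (is.null(dim(spheres))) spheres <- matrix(spheres, ncol = 3)
  spheres <- as.matrix(spheres)
  if (nrow(spheres) < 1) rlang::abort("a building block needs at least one sphere")
  if (!all(is.finite(spheres))) rlang::abort("sphere centers must be finite")
  if (is.null(patches)) patches <- matrix(numeric(0), ncol = 3)
  if (is.null(dim(patches))) patches <- matrix(patches, ncol = 3)
  patches <- as.matrix(patches)
  if (!all(is.finite(patches))) rlang::abort("patch positions must be finite")
  if (nrow(patches) != length(patch_types)) {
    rlang::abort("`patch_types` must have one label per patch")
  }
  if (isotropic && nrow(patches) > 0 && any(abs(patches) > 1e-9)) {
    rlang::abort("isotropic blocks may only carry orientation-free (central) patches")
  }
  structure(
    list(
      species_id = as.character(species_id),
      spheres = spheres,
      sphere_diameters = rep_len(sphere_diameters, nrow(spheres)),
      patches = patches,
      patch_types = as.character(patch_types),
      isotropic = isTRUE(isotropic)
    ),
    class = "building_block"
  )
}

#' @export
print.building_block <- function(x, ...) {
  cat(sprintf("<building_block> species '%s': %d sphere(s), %d patch(es)%s\n",
              x$species_id, nrow(x$spheres), nrow(x$patches),
              if (x$isotropic) ", isotropic" else ""))
  invisible(x)
}

#' Create a pose (rigid placement)
#'
#' @param position 3-vector.
#' @param orientation unit quaternion `(w, x, y, z)`; normalized on input.
#' @return object of class `pose`.
#' @export
pose <- function(position = c(0, 0, 0), orientation = c(1, 0, 0, 0)) {
  if (!all(is.finite(position)) || length(position) != 3) {
    rlang::abort("`position` must be a finite 3-vector")
  }
  structure(list(position = as.numeric(position),
                 orientation = quat_normalize(as.numeric(orientation))),
            class = "pose")
}

#' Create a cluster structure
#'
#' A candidate assembly: a list of blocks placed at the ground-state energy
#' minimum, with the species composition and the symmetry number counting
#' rotation/permutation combinations that map the cluster onto itself.
#'
#' @param blocks named list: each element a list with fields `block`
#'   (a [building_block()]) and `pose` (a [pose()]).
#' @param symmetry_number positive integer.
#' @param label string identifying the structure.
#' @return object of class `cluster_structure`.
#' @export
cluster_structure <- function(blocks, symmetry_number = 1, label = "") {
  stopifnot(length(blocks) >= 1)
  for (b in blocks) {
    if (!inherits(b$block, "building_block") || !inherits(b$pose, "pose")) {
      rlang::abort("each element of `blocks` needs a building_block and a pose")
    }
  }
  if (symmetry_number < 1) rlang::abort("symmetry_number must be >= 1")
  comp <- table(vapply(blocks, function(b) b$block$species_id, character(1)))
  structure(
    list(blocks = blocks,
         composition = stats::setNames(as.integer(comp), names(comp)),
         symmetry_number = as.integer(symmetry_number),
         label = label),
    class = "cluster_structure"
  )
}

#' @export
print.cluster_structure <- function(x, ...) {
  comp <- paste(sprintf("%s:%d", names(x$composition), x$composition),
                collapse = ", ")
  cat(sprintf("<cluster_structure> '%s': %d block(s) [%s], sigma = %d\n",
              x$label, length(x$blocks), comp, x$symmetry_number))
  invisible(x)
}

#' Number of blocks in a structure
#' @keywords internal
n_blocks <- function(structure) length(structure$blocks)

#' Block positions of a cluster structure
#' @return n x 3 matrix of block (body-origin) positions.
#' @keywords internal
block_positions <- function(structure) {
  t(vapply(structure$blocks, function(b) b$pose$position, numeric(3)))
}

#' Center of mass of a cluster structure
#'
#' Unit masses throughout: the center of mass is the unweighted mean of the
#' block positions.
#'
#' @param structure a [cluster_structure()].
#' @return 3-vector.
#' @export
center_of_mass <- function(structure) {
  colMeans(block_positions(structure))
}

#' Inertia tensor of a cluster structure
#'
#' Unit-mass inertia tensor `I_jk = sum_i (|r_i|^2 d_jk - r_ij r_ik)` with
#' positions taken relative to the center of mass.
#'
#' @param structure a [cluster_structure()].
#' @return symmetric positive semidefinite 3x3 matrix.
#' @export
inertia_tensor <- function(structure) {
  p <- block_positions(structure)
  p <- sweep(p, 2, colMeans(p))
  r2 <- rowSums(p^2)
  sum(r2) * diag(3) - t(p) %*% p
}

#' Apply a global rigid motion to a cluster structure
#'
#' Rotates every block position and orientation by `q` (about the origin) and
#' then translates by `t`. Used to test equivariance and chart invariance.
#'
#' @param structure a [cluster_structure()].
#' @param q unit quaternion for the rotation.
#' @param t translation 3-vector.
#' @return the transformed `cluster_structure`.
#' @export
transform_structure <- function(structure, q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  R <- quat_to_rotmat(q)
  structure$blocks <- lapply(structure$blocks, function(b) {
    b$pose$position <- as.numeric(R %*% b$pose$position + t)
    b$pose$orientation <- quat_normalize(quat_multiply(q, b$pose$orientation))
    b
  })
  structure
}
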