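# Per-cluster configurational partition functions:
#   Z_s = exp(-beta E0) * V * (Jtilde / sigma) * prod_i sqrt(2 pi / (beta w_i^2))
# with w_i^2 the nonzero Hessian eigenvalues at the minimum and Jtilde the
# orientation integral of the coordinate-change Jacobian. Orientation
# integrals use the rotation-invariant (Haar) measure, total volume 8 pi^2
# per rigid body; the Jacobian is evaluated in exponential-map charts centered
# at the evaluation point, where the Haar density is exactly 1, making all
# results chart-invariant.

#' Monte Carlo settings for orientation integrals
#' @param n_samples number of Haar-uniform orientation samples.
#' @param seed integer seed (mandatory: results must be reproducible).
#' @export
mc_config <- function(n_samples = 1e5, seed) {
  if (n_samples < 1) rlang::abort("n_samples must be >= 1")
  if (missing(seed)) rlang::abort("an integer `seed` is required")
  list(n_samples = as.integer(n_samples), seed = as.integer(seed))
}

#' Rigid-motion generators of a structure in its chart
#'
#' Columns 1:3 are global translations, columns 4:6 global rotations about
#' the center of mass (acting on positions and, for oriented blocks, on
#' orientations).
#'
#' @keywords internal
rigid_mode_basis <- function(structure) {
  dof <- block_dof(structure)
  off <- dof_offsets(dof)
  ndof <- sum(dof)
  com <- center_of_mass(structure)
  B <- matrix(0, ndof, 6)
  for (k in seq_along(structure$blocks)) {
    B[(off[k] + 1L):(off[k] + 3L), 1:3] <- diag(3)
    r <- structure$blocks[[k]]$pose$position - com
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- 1
      B[(off[k] + 1L):(off[k] + 3L), 3 + ax] <- c(
        e[2] * r[3] - e[3] * r[2],
        e[3] * r[1] - e[1] * r[3],
        e[1] * r[2] - e[2] * r[1])
    }
    if (dof[k] == 6L) B[(off[k] + 4L):(off[k] + 6L), 4:6] <- diag(3)
  }
  B
}

#' Rank of the global-rotation action (3 nonlinear, 2 linear, 0 point-like)
#' @keywords internal
rotation_rank <- function(structure, tol = 1e-8) {
  W <- rigid_mode_basis(structure)[, 4:6, drop = FALSE]
  s <- svd(W)$d
  sum(s > tol * max(s, 1))
}

#' Hessian spectrum of a cluster at its energy minimum
#'
#' Diagonalizes the exact Hessian of the cluster energy. For a rigid
#' nonlinear cluster the spectrum contains exactly `3 + rank(rotations)` zero
#' modes (6 in the generic case); additional numerical zeros indicate a
#' floppy cluster and raise an error of class
#' `assemblyyield_floppy_cluster`; a negative eigenvalue beyond tolerance
#' raises `assemblyyield_not_at_minimum`.
#'
#' The default chart (`"block"`) uses per-block translation/rotation
#' increments with orthonormal eigenvectors. For two-body systems the
#' `"relative"` chart diagonalizes the energy in the relative-displacement
#' coordinate (unit-Jacobian center-of-mass split), the convention in which
#' the overlapping isotropic dimer has all three eigenvalues `2 E0 alpha^2`.
#'
#' @param structure a [cluster_structure()] at (or very near) a minimum.
#' @param interactions an [interaction_table()].
#' @param repulsion a [repulsion_params()] or `NULL`.
#' @param zero_tol relative zero-mode threshold (|w^2| < zero_tol * max|w^2|).
#' @param chart `"block"` or `"relative"` (two isotropic blocks only).
#' @param grad_tol maximum allowed gradient norm at the input configuration.
#' @param soft_modes `"error"` (default: extra zero modes raise
#'   `assemblyyield_floppy_cluster`) or `"integrate"`: extra zero modes are
#'   retained as *soft modes* — quartically confined shell flexes or bounded
#'   mechanisms — whose phase-space volume is later integrated explicitly
#'   over the bond-topology-preserving region (see [soft_mode_volumes()]).
#'   An orthonormal basis of the soft subspace (orthogonal to the global
#'   rigid motions) is stored in `soft_basis`.
#' @return object of class `hessian_spectrum` with fields `eigenvalues`
#'   (ascending), `eigenvectors`, `zero_mode_count`, `zero_tol`,
#'   `expected_zero_modes`, `soft_mode_count`, `soft_basis`, `chart`.
#' @export
hessian_spectrum <- function(structure, interactions, repulsion = NULL,
                             zero_tol = 1e-8, chart = c("block", "relative"),
                             grad_tol = 1e-6,
                             soft_modes = c("error", "integrate")) {
  chart <- match.arg(chart)
  soft_modes <- match.arg(soft_modes)
  if (chart == "relative") {
    if (n_blocks(structure) != 2 || !all(block_dof(structure) == 3L)) {
      rlang::abort("the relative chart applies to pairs of isotropic blocks")
    }
    H <- cluster_hessian(structure, interactions, repulsion)
    Hrel <- (H[1:3, 1:3] + H[4:6, 4:6] - H[1:3, 4:6] - H[4:6, 1:3]) / 4
    sep <- sqrt(sum((structure$blocks[[1]]$pose$position -
                       structure$blocks[[2]]$pose$position)^2))
    expected_zero <- if (sep < 1e-8) 0L else 2L
    eg <- eigen(Hrel, symmetric = TRUE)
    ndof <- 3L
  } else {
    g <- cluster_gradient(structure, interactions, repulsion)
    H <- cluster_hessian(structure, interactions, repulsion)
    scale <- max(abs(H), 1)
    if (sqrt(sum(g^2)) > grad_tol * max(1, scale)) {
      rlang::abort("configuration is not at a stationary point (gradient too large); run minimize_and_check() first",
                   class = "assemblyyield_not_at_minimum")
    }
    expected_zero <- 3L + rotation_rank(structure)
    eg <- eigen(H, symmetric = TRUE)
    ndof <- sum(block_dof(structure))
  }
  ev <- sort(eg$values)
  vmax <- max(abs(ev))
  if (vmax == 0) {
    zero_count <- length(ev)
  } else {
    zero_count <- sum(abs(ev) < zero_tol * vmax)
    if (any(ev < -zero_tol * vmax)) {
      rlang::abort("negative Hessian eigenvalue: configuration is not a minimum",
                   class = "assemblyyield_not_at_minimum")
    }
  }
  single_body <- (chart == "block") && n_blocks(structure) == 1
  soft_basis <- NULL
  soft_count <- 0L
  if (!single_body && zero_count > expected_zero) {
    if (soft_modes == "error") {
      rlang::abort(sprintf(
        "floppy cluster: %d zero modes where %d (global motions) were expected",
        zero_count, expected_zero), class = "assemblyyield_floppy_cluster")
    }
    # soft subspace: numerical kernel orthogonal to the rigid motions
    ordz <- order(eg$values)[seq_len(zero_count)]
    Z <- eg$vectors[, ordz, drop = FALSE]
    Q <- qr.Q(qr(rigid_mode_basis(structure)))
    proj <- Z - Q %*% (t(Q) %*% Z)
    sv <- svd(proj)
    soft_count <- zero_count - expected_zero
    soft_basis <- sv$u[, seq_len(soft_count), drop = FALSE]
    if (sv$d[soft_count] < 0.5) {
      rlang::abort("soft-mode basis extraction failed (ill-separated kernel)")
    }
  }
  ord <- order(eg$values)
  structure(list(eigenvalues = eg$values[ord],
                 eigenvectors = eg$vectors[, ord, drop = FALSE],
                 zero_mode_count = as.integer(zero_count),
                 zero_tol = zero_tol,
                 expected_zero_modes = as.integer(expected_zero),
                 soft_mode_count = soft_count,
                 soft_basis = soft_basis,
                 chart = chart, ndof = ndof),
            class = "hessian_spectrum")
}

#' Soft-mode phase-space volumes over the bond-topology window
#'
#' A soft mode is a Hessian kernel direction beyond the global rigid
#' motions: a quartically confined shell flex or a bounded hinge mechanism.
#' Its harmonic factor diverges, but the cluster region itself is bounded:
#' the configuration belongs to the cluster only while its bond topology is
#' unchanged. For each soft mode `v` this routine finds the interval
#' `(t_lo, t_hi)` of displacements `t * v` over which no pair distance
#' crosses the interaction cutoff (pair distances are exact quadratics in
#' `t`), and returns the explicit one-dimensional integral
#' `log int_{t_lo}^{t_hi} exp(-beta dE(t)) dt` per mode, evaluated on a
#' profile grid (with `dE >= 0` inside the window, clamped against
#' rounding). Modes are treated independently in the stored basis; the
#' couplings between soft modes are neglected (documented approximation).
#'
#' @param structure all-isotropic [cluster_structure()] at its minimum.
#' @param interactions the [interaction_table()] (its `r0 + r_cut` defines
#'   the bond cutoff).
#' @param spectrum a [hessian_spectrum()] with `soft_modes = "integrate"`.
#' @param beta inverse temperature.
#' @param n_grid profile points per mode.
#' @param t_cap hard cap on the half-window (guards unbounded mechanisms;
#'   the quartic energy rise makes the integrand negligible well before).
#' @return numeric vector of per-mode log volumes (length
#'   `spectrum$soft_mode_count`; zero-length when none).
#' @export
soft_mode_volumes <- function(structure, interactions, spectrum, beta = 1,
                              n_grid = 15, t_cap = 2) {
  if (spectrum$soft_mode_count == 0L) return(numeric(0))
  if (!all(block_dof(structure) == 3L)) {
    rlang::abort("soft-mode integration is implemented for isotropic-block clusters")
  }
  cutoff <- interactions$r0 + interactions$r_cut
  E0 <- cluster_energy(structure, interactions, NULL)
  P <- block_positions(structure)
  vapply(seq_len(spectrum$soft_mode_count), function(m) {
    v <- spectrum$soft_basis[, m]
    w <- soft_window(P, v, cutoff, t_cap)
    ts <- seq(w[1], w[2], length.out = n_grid)
    dE <- vapply(ts, function(t) {
      max(cluster_energy(displace_structure(structure, t * v),
                         interactions, NULL) - E0, 0)
    }, numeric(1))
    f <- exp(-beta * dE)
    log(sum((f[-1] + f[-n_grid]) / 2 * diff(ts)))
  }, numeric(1))
}

#' Bond-topology-preserving window along a mode
#' @keywords internal
soft_window <- function(P, v, cutoff, t_cap = 2) {
  V <- matrix(v, ncol = 3, byrow = TRUE)
  n <- nrow(P)
  tlo <- -t_cap; thi <- t_cap
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dp <- P[i, ] - P[j, ]; dv <- V[i, ] - V[j, ]
    a <- sum(dv^2)
    if (a < 1e-14) next
    b <- 2 * sum(dp * dv); cc <- sum(dp^2) - cutoff^2
    disc <- b^2 - 4 * a * cc
    if (disc <= 0) next
    r1 <- (-b - sqrt(disc)) / (2 * a); r2 <- (-b + sqrt(disc)) / (2 * a)
    if (cc < 0) {            # bonded pair: window ends where it leaves
      tlo <- max(tlo, r1); thi <- min(thi, r2)
    } else {                 # unbonded pair: window ends where it enters
      if (r1 > 0) thi <- min(thi, r1)
      if (r2 < 0) tlo <- max(tlo, r2)
    }
  }
  c(tlo, thi)
}

#' @export
print.hessian_spectrum <- function(x, ...) {
  cat(sprintf("<hessian_spectrum> %d dof, %d zero mode(s), chart '%s'\n",
              x$ndof, x$zero_mode_count, x$chart))
  invisible(x)
}

#' Log vibrational partition function
#'
#' `ln prod sqrt(2 pi / (beta w_i^2))` over the nonzero modes of a validated
#' spectrum (the zero modes are the global motions and are integrated
#' elsewhere).
#'
#' @param spectrum a [hessian_spectrum()].
#' @param beta inverse temperature.
#' @return log of the vibrational factor (0 for no internal modes).
#' @export
vibrational_Z <- function(spectrum, beta) {
  ev <- spectrum$eigenvalues
  keep <- ev[seq_len(length(ev)) > spectrum$zero_mode_count]
  if (length(keep) == 0) return(0)
  if (any(keep <= 0)) rlang::abort("retained eigenvalue not positive")
  sum(0.5 * log(2 * pi / (beta * keep)))
}

#' Differentiable map from cluster coordinates to per-block poses
#'
#' Packages the data of the coordinate change `f = T o R o f_tilde`: internal
#' vibrations (the orthonormal eigenvectors of the nonzero modes) followed by
#' a global rotation about the center of mass and a global translation.
#'
#' @param structure structure at the minimum (defines the reference poses).
#' @param spectrum the matching [hessian_spectrum()] in the `"block"` chart.
#' @return object of class `com_map`.
#' @export
build_com_map <- function(structure, spectrum) {
  if (spectrum$chart != "block") rlang::abort("need a block-chart spectrum")
  if (spectrum$ndof != sum(block_dof(structure))) {
    rlang::abort("spectrum frame does not match the structure")
  }
  nz <- spectrum$ndof - spectrum$zero_mode_count
  Vt <- spectrum$eigenvectors[, spectrum$zero_mode_count + seq_len(nz),
                              drop = FALSE]
  structure(list(structure = structure, V_internal = Vt,
                 com = center_of_mass(structure),
                 dof = block_dof(structure),
                 off = dof_offsets(block_dof(structure)),
                 rot_rank = rotation_rank(structure)),
            class = "com_map")
}

#' Evaluate a center-of-mass map
#'
#' @param map a [build_com_map()] result.
#' @param q_c global translation 3-vector.
#' @param q_quat global orientation quaternion (rotation about the COM).
#' @param xi internal vibration coordinates (length = number of nonzero
#'   modes).
#' @return the displaced [cluster_structure()].
#' @export
com_map_apply <- function(map, q_c = c(0, 0, 0), q_quat = c(1, 0, 0, 0),
                          xi = NULL) {
  s <- map$structure
  if (!is.null(xi) && any(xi != 0)) {
    s <- displace_structure(s, as.numeric(map$V_internal %*% xi))
  }
  Rg <- quat_to_rotmat(q_quat)
  for (k in seq_along(s$blocks)) {
    p <- s$blocks[[k]]$pose$position
    s$blocks[[k]]$pose$position <- as.numeric(map$com + Rg %*% (p - map$com) + q_c)
    if (map$dof[k] == 6L) {
      s$blocks[[k]]$pose$orientation <- quat_normalize(
        quat_multiply(q_quat, s$blocks[[k]]$pose$orientation))
    }
  }
  s
}

#' Jacobian determinant of the coordinate change at xi = 0
#'
#' Absolute determinant of the matrix of partial derivatives of the per-block
#' coordinates with respect to (global translation, global rotation, internal
#' vibrations), evaluated at the given global orientation in
#' exponential-map (Haar-density-1) charts. Independent of the global
#' translation by construction; includes the center-of-mass transform factor
#' (`N^{3/2}` for N unit-mass blocks).
#'
#' @param map a [build_com_map()] result.
#' @param q_quat global orientation at which to evaluate.
#' @return |det J|.
#' @export
jacobian_det <- function(map, q_quat = c(1, 0, 0, 0)) {
  if (map$rot_rank != 3L) {
    rlang::abort("jacobian_det requires a nonlinear cluster (use the inertia route for linear/point clusters)")
  }
  Rg <- quat_to_rotmat(q_quat)
  ndof <- sum(map$dof)
  nint <- ncol(map$V_internal)
  M <- matrix(0, ndof, 6 + nint)
  # internal columns: block-diagonal rotation of the eigenvectors
  Vrot <- map$V_internal
  for (k in seq_along(map$dof)) {
    rows <- (map$off[k] + 1L):(map$off[k] + 3L)
    Vrot[rows, ] <- Rg %*% Vrot[rows, , drop = FALSE]
    if (map$dof[k] == 6L) {
      wrows <- (map$off[k] + 4L):(map$off[k] + 6L)
      Vrot[wrows, ] <- Rg %*% Vrot[wrows, , drop = FALSE]
    }
  }
  for (k in seq_along(map$dof)) {
    rows <- (map$off[k] + 1L):(map$off[k] + 3L)
    r <- as.numeric(Rg %*% (map$structure$blocks[[k]]$pose$position - map$com))
    M[rows, 1:3] <- diag(3)
    M[rows, 4:6] <- -skew(r)
    if (map$dof[k] == 6L) {
      wrows <- (map$off[k] + 4L):(map$off[k] + 6L)
      M[wrows, 4:6] <- diag(3)
    }
  }
  M[, 7:(6 + nint)] <- Vrot
  abs(det(M))
}

#' Monte Carlo rotational integral of the Jacobian
#'
#' `Jtilde = int dphi_c J(phi_c)` over the Haar measure (total volume
#' 8 pi^2): estimated as `8 pi^2 * mean(J)` over Haar-uniform orientations,
#' with the Monte Carlo standard error from the sample variance.
#'
#' @param map a [build_com_map()] result.
#' @param mc an [mc_config()].
#' @return list with `Jtilde`, `stderr`, `n_samples`, `seed`.
#' @export
rotational_Z_mc <- function(map, mc) {
  qs <- sample_uniform_orientations(mc$n_samples, mc$seed)
  J <- vapply(seq_len(nrow(qs)), function(i) jacobian_det(map, qs[i, ]),
              numeric(1))
  bad <- !is.finite(J)
  if (mean(bad) > 0.001) {
    rlang::abort("non-finite Jacobian at more than 0.1% of sampled orientations")
  }
  J <- J[!bad]
  vol <- 8 * pi^2
  list(Jtilde = vol * mean(J),
       stderr = vol * stats::sd(J) / sqrt(length(J)),
       n_samples = mc$n_samples, seed = mc$seed)
}

#' Rotational factor from moments of inertia (isotropic blocks)
#'
#' For clusters of isotropic (orientation-free) blocks the Jacobian is
#' independent of the global orientation and the orientation integral has the
#' closed form `8 pi^2 sqrt(det I) N^{3/2}` (nonlinear clusters; unit-mass
#' inertia tensor in the COM frame), `4 pi I_perp N^{3/2}` for linear
#' clusters, and `N^{3/2}` for point-like clusters (all positions
#' coincident). The factor does not include the per-block free-spin volumes
#' (handled by [compute_partition_function()]) nor `1/sigma`.
#'
#' @param structure a [cluster_structure()] of isotropic blocks.
#' @return log of the positional rotational factor.
#' @export
rotational_Z_inertia <- function(structure) {
  if (!all(block_dof(structure) == 3L)) {
    rlang::abort("mixed isotropic/oriented blocks: use the Monte Carlo route")
  }
  N <- n_blocks(structure)
  rr <- rotation_rank(structure)
  base <- 1.5 * log(N)
  if (N == 1 || rr == 0L) return(base)
  if (rr == 2L) {
    I <- inertia_tensor(structure)
    I_perp <- sum(eigen(I, symmetric = TRUE, only.values = TRUE)$values[1:2]) / 2
    return(base + log(4 * pi) + log(I_perp))
  }
  I <- inertia_tensor(structure)
  base + log(8 * pi^2) + 0.5 * determinant(I, logarithm = TRUE)$modulus[1]
}

# ---- symmetry numbers ----------------------------------------------------

#' Symmetry number of a cluster
#'
#' Counts the combinations of proper rotations and species-preserving
#' permutations that map the cluster onto itself. Computed by brute force for
#' clusters of isotropic blocks (candidate rotations are built from images of
#' a reference point pair and verified on the whole coordinate set). For
#' clusters with oriented blocks the user-supplied value stored in the
#' structure is returned (default 1, with a warning).
#'
#' @param structure a [cluster_structure()].
#' @param tol matching tolerance for distances (absolute).
#' @return integer symmetry number.
#' @export
symmetry_number <- function(structure, tol = 1e-6) {
  if (!all(block_dof(structure) == 3L)) {
    if (structure$symmetry_number == 1L) {
      rlang::warn("oriented blocks: using the user-supplied symmetry number (1)")
    }
    return(structure$symmetry_number)
  }
  p <- block_positions(structure)
  sp <- vapply(structure$blocks, function(b) b$block$species_id, character(1))
  n <- nrow(p)
  if (n == 1) return(1L)
  p <- sweep(p, 2, colMeans(p))
  rad <- sqrt(rowSums(p^2))
  if (max(rad) < tol) {
    # all blocks coincident: any permutation of identical species "fits", but
    # none corresponds to a distinct rotation; conventionally sigma = product
    # of factorials of identical-species counts
    return(as.integer(prod(factorial(table(sp)))))
  }
  # linear case
  W <- svd(p)$d
  if (sum(W > tol * max(W)) <= 1L) {
    axis_order <- order(p %*% (p[which.max(rad), ] / max(rad)))
    rev_map <- vapply(seq_len(n), function(i) {
      target <- -p[i, ]
      j <- which.min(rowSums(sweep(p, 2, target)^2))
      if (sqrt(sum((p[j, ] - target)^2)) < tol && sp[j] == sp[i]) j else NA_integer_
    }, integer(1))
    return(if (!anyNA(rev_map)) 2L else 1L)
  }
  i1 <- which.max(rad)
  cross_norm <- apply(p, 1, function(x) {
    cx <- c(p[i1, 2] * x[3] - p[i1, 3] * x[2],
            p[i1, 3] * x[1] - p[i1, 1] * x[3],
            p[i1, 1] * x[2] - p[i1, 2] * x[1])
    sqrt(sum(cx^2))
  })
  i2 <- which.max(cross_norm)
  frame_of <- function(u, v) {
    e1 <- u / sqrt(sum(u^2))
    w <- v - sum(v * e1) * e1
    e2 <- w / sqrt(sum(w^2))
    cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                    e1[3] * e2[1] - e1[1] * e2[3],
                    e1[1] * e2[2] - e1[2] * e2[1]))
  }
  F1 <- frame_of(p[i1, ], p[i2, ])
  d12 <- sqrt(sum((p[i1, ] - p[i2, ])^2))
  count <- 0L
  for (a in seq_len(n)) {
    if (sp[a] != sp[i1] || abs(rad[a] - rad[i1]) > tol) next
    for (b in seq_len(n)) {
      if (b == a || sp[b] != sp[i2] || abs(rad[b] - rad[i2]) > tol) next
      if (abs(sqrt(sum((p[a, ] - p[b, ])^2)) - d12) > tol) next
      R <- frame_of(p[a, ], p[b, ]) %*% t(F1)
      q <- p %*% t(R)
      # nearest original point for every rotated point, vectorized
      d2 <- outer(rowSums(q^2), rowSums(p^2), "+") - 2 * (q %*% t(p))
      j <- max.col(-d2)
      ok <- all(d2[cbind(seq_len(n), j)] < tol^2) && all(sp[j] == sp) &&
        !anyDuplicated(j)
      if (ok) count <- count + 1L
    }
  }
  max(count, 1L)
}

# ---- assembly ------------------------------------------------------------

#' Assemble a partition function from its factors
#'
#' `ln Z = -beta E0 + ln V + ln Jtilde - ln sigma + ln_Zvib`. `Jtilde` is the
#' total orientation-volume factor: the integrated coordinate-change Jacobian
#' (which includes the `N^{3/2}` center-of-mass factor) times the free-spin
#' volumes (8 pi^2 each) of isotropic blocks.
#'
#' @param E0 ground-state energy (kB*T).
#' @param ln_Zvib log vibrational factor ([vibrational_Z()]).
#' @param Jtilde orientation-volume factor (or use `ln_Jtilde`).
#' @param sigma symmetry number.
#' @param V system volume.
#' @param beta inverse temperature.
#' @param mc_stderr Monte Carlo standard error of `Jtilde` (0 for closed
#'   forms).
#' @param ln_Jtilde optional log-domain alternative to `Jtilde`.
#' @param n_samples,seed,label bookkeeping carried into the result.
#' @return object of class `partition_function`.
#' @export
assemble_Z <- function(E0, ln_Zvib, Jtilde = NULL, sigma = 1, V = 1, beta = 1,
                       mc_stderr = 0, ln_Jtilde = NULL,
                       n_samples = NA_integer_, seed = NA_integer_,
                       label = "") {
  if (is.null(ln_Jtilde)) ln_Jtilde <- log(Jtilde)
  if (is.null(Jtilde)) Jtilde <- exp(ln_Jtilde)
  ln_Zrot <- ln_Jtilde - log(sigma)
  ln_Z <- -beta * E0 + log(V) + ln_Zrot + ln_Zvib
  structure(list(E0 = E0, beta = beta, ln_Zvib = ln_Zvib, ln_Zrot = ln_Zrot,
                 ln_Ztrans_per_V = 0, Jtilde = Jtilde, mc_stderr = mc_stderr,
                 sigma = sigma, V = V, ln_Z = ln_Z,
                 ln_Z_per_V = ln_Z - log(V),
                 n_samples = n_samples, seed = seed, label = label),
            class = "partition_function")
}

#' @export
print.partition_function <- function(x, ...) {
  cat(sprintf("<partition_function> '%s': E0 = %.6g, ln Z = %.6g (V = %g, beta = %g)\n",
              x$label, x$E0, x$ln_Z, x$V, x$beta))
  cat(sprintf("  ln_Zvib = %.6g, ln_Zrot = %.6g, Jtilde = %.6g (+/- %.2g), sigma = %d\n",
              x$ln_Zvib, x$ln_Zrot, x$Jtilde, x$mc_stderr, as.integer(x$sigma)))
  invisible(x)
}

#' Compute the partition function of a cluster structure
#'
#' End-to-end driver: validates the minimum, diagonalizes the Hessian,
#' evaluates the rotational factor (Monte Carlo Jacobian integral when any
#' block is oriented; inertia closed form when all blocks are isotropic),
#' determines the symmetry number, and assembles the factors.
#'
#' @param structure a [cluster_structure()] at its energy minimum.
#' @param interactions an [interaction_table()].
#' @param repulsion a [repulsion_params()] or `NULL`.
#' @param beta inverse temperature (kB*T units; default 1).
#' @param V system volume (cancels out of all yields).
#' @param mc an [mc_config()]; required when any block is oriented and the
#'   cluster has more than one block.
#' @param sigma symmetry number override; `NULL` computes it (brute force for
#'   isotropic clusters, user-supplied field otherwise).
#' @param zero_tol zero-mode threshold passed to [hessian_spectrum()].
#' @param soft_modes passed to [hessian_spectrum()]; with `"integrate"`,
#'   soft-mode volumes from [soft_mode_volumes()] multiply the vibrational
#'   factor.
#' @return a `partition_function`.
#' @export
compute_partition_function <- function(structure, interactions = NULL,
                                       repulsion = NULL, beta = 1, V = 1,
                                       mc = NULL, sigma = NULL,
                                       zero_tol = 1e-8,
                                       soft_modes = c("error", "integrate")) {
  soft_modes <- match.arg(soft_modes)
  dof <- block_dof(structure)
  N <- n_blocks(structure)
  n_iso <- sum(dof == 3L)
  ln_spin <- n_iso * log(8 * pi^2)
  if (N == 1) {
    if (is.null(sigma)) sigma <- structure$symmetry_number
    ln_J <- if (dof == 6L) log(8 * pi^2) else ln_spin
    return(assemble_Z(0, 0, ln_Jtilde = ln_J, sigma = sigma, V = V,
                      beta = beta, label = structure$label))
  }
  E0 <- cluster_energy(structure, interactions, repulsion)
  H <- cluster_hessian(structure, interactions, repulsion)
  if (max(abs(H)) < 1e-14) {
    # no binding at all (e.g. a zero energy scale): the bound state has
    # vanishing statistical weight
    rlang::warn(sprintf("structure '%s' has no binding interactions; Z = 0",
                        structure$label))
    return(assemble_Z(0, 0, ln_Jtilde = -Inf, sigma = 1, V = V, beta = beta,
                      label = structure$label))
  }
  if (is.null(sigma)) sigma <- symmetry_number(structure)
  spec <- hessian_spectrum(structure, interactions, repulsion,
                           zero_tol = zero_tol, soft_modes = soft_modes)
  ln_vib <- vibrational_Z(spec, beta)
  if (spec$soft_mode_count > 0) {
    ln_vib <- ln_vib + sum(soft_mode_volumes(structure, interactions, spec,
                                             beta = beta))
  }
  if (all(dof == 3L)) {
    ln_J <- rotational_Z_inertia(structure) + ln_spin
    return(assemble_Z(E0, ln_vib, ln_Jtilde = ln_J, sigma = sigma, V = V,
                      beta = beta, label = structure$label))
  }
  if (is.null(mc)) rlang::abort("oriented blocks: an mc_config() is required")
  map <- build_com_map(structure, spec)
  rot <- rotational_Z_mc(map, mc)
  assemble_Z(E0, ln_vib, Jtilde = rot$Jtilde * exp(ln_spin), sigma = sigma,
             V = V, beta = beta,
             mc_stderr = rot$stderr * exp(ln_spin),
             n_samples = rot$n_samples, seed = rot$seed,
             label = structure$label)
}

# ---- minimization --------------------------------------------------------

#' Verify and locally refine an energy minimum
#'
#' Damped Newton refinement in the block chart with retraction after each
#' step. Succeeds when the gradient norm falls below `tol`; raises
#' `assemblyyield_not_at_minimum` if the refinement does not converge, drifts
#' outside the starting basin, or lands on a configuration with a vanishing
#' Hessian (no binding).
#'
#' @param structure starting [cluster_structure()] (near a minimum).
#' @param interactions an [interaction_table()].
#' @param repulsion a [repulsion_params()] or `NULL`.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @param basin_radius maximum allowed total per-coordinate displacement.
#' @return list with `structure` (refined), `E0`, `grad_norm`,
#'   `displacement` (max abs coordinate shift), `iterations`.
#' @export
minimize_and_check <- function(structure, interactions, repulsion = NULL,
                               tol = 1e-8, max_iter = 100,
                               basin_radius = 0.5) {
  total_shift <- 0
  for (it in seq_len(max_iter)) {
    g <- cluster_gradient(structure, interactions, repulsion)
    gn <- sqrt(sum(g^2))
    if (gn < tol) {
      H <- cluster_hessian(structure, interactions, repulsion)
      if (max(abs(H)) < 1e-12) {
        rlang::abort("configuration has no binding interactions (zero Hessian); not a cluster minimum",
                     class = "assemblyyield_not_at_minimum")
      }
      return(list(structure = structure,
                  E0 = cluster_energy(structure, interactions, repulsion),
                  grad_norm = gn, displacement = total_shift,
                  iterations = it - 1L))
    }
    H <- cluster_hessian(structure, interactions, repulsion)
    lam <- 1e-6 * max(abs(H), 1)
    step <- NULL
    e_old <- cluster_energy(structure, interactions, repulsion)
    for (k in 1:40) {
      step <- tryCatch(-solve(H + lam * diag(nrow(H)), g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- displace_structure(structure, step)
        if (cluster_energy(cand, interactions, repulsion) <= e_old + 1e-12) break
      }
      lam <- lam * 10
      step <- NULL
    }
    if (is.null(step)) {
      rlang::abort("refinement failed to find a descent step",
                   class = "assemblyyield_not_at_minimum")
    }
    total_shift <- total_shift + max(abs(step))
    if (total_shift > basin_radius) {
      rlang::abort("refinement escaped the starting basin",
                   class = "assemblyyield_not_at_minimum")
    }
    structure <- displace_structure(structure, step)
  }
  rlang::abort("refinement did not converge", class = "assemblyyield_not_at_minimum")
}

# ---- radial quartic Laplace correction ----------------------------------

#' Fourth-order radial Laplace dimer ratio
#'
#' Z-ratio of the radially symmetric dimer using the quartic Taylor
#' expansion of the smoothed Morse well about its minimum:
#' `4 pi int_0^{r_cut} r^2 exp(-beta U4(r)) dr / V` with
#' `U4 = E_b (c0 + c2 r^2 + c3 r^3 + c4 r^4)` from [radial_taylor()]. The
#' quartic coefficient is recomputed for whatever `r_cut` the parameters
#' carry (it reduces to the rational 7177/12288 alpha^4 at
#' `r_cut = 8/alpha`).
#'
#' @param p a [morse_params()] with `r0 = 0`, `r_on = 0`.
#' @param beta inverse temperature.
#' @param V system volume.
#' @param rel_tol quadrature relative tolerance.
#' @param log return the log of the ratio (avoids overflow at large
#'   `beta * E0`).
#' @return the dimensionless ratio `Z_dimer / (Z_1 Z_2)` (or its log).
#' @export
laplace4_radial_Z <- function(p, beta, V = 1, rel_tol = 1e-10, log = FALSE) {
  if (p$r0 != 0) rlang::abort("the radial expansion assumes r0 = 0")
  co <- radial_taylor(p, 4)
  # integrate with the well depth factored out: exp(-beta (U4 + E_b)) <= 1
  dU <- function(r) p$E_b * (co[3] * r^2 + co[4] * r^3 + co[5] * r^4)
  f <- function(r) 4 * pi * r^2 * exp(-beta * dU(r))
  val <- stats::integrate(f, 0, p$r_cut, rel.tol = rel_tol,
                          subdivisions = 500L)$value
  ln <- beta * p$E_b + base::log(val) - base::log(V)
  if (log) ln else exp(ln)
}
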