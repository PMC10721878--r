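# Total cluster energy and its exact derivatives.
#
# Coordinates ("chart"): each oriented block contributes 3 translational
# increments dq and 3 rotational increments dw (rotation vector applied on the
# left of the block's reference orientation: R = exp([dw]) R0). Isotropic
# blocks contribute only dq. Derivatives are evaluated at the chart origin of
# the supplied structure; optimization proceeds by retraction (update the
# poses, re-center the chart). All derivatives are closed-form: for a pair
# term f(|u|), u = x_a - x_b with x = q + R b,
#   d x / d dq = I,   d x / d dw_k = e_k x r      (r = R0 b, world frame)
#   d2 x / d dw_j d dw_k . g = 1/2 (g_k r_j + g_j r_k) - (g . r) delta_jk.

#' Degrees of freedom of each block
#' @keywords internal
block_dof <- function(structure) {
  vapply(structure$blocks, function(b) if (b$block$isotropic) 3L else 6L,
         integer(1))
}

#' Chart offsets (0-based) per block
#' @keywords internal
dof_offsets <- function(dof) cumsum(c(0L, dof[-length(dof)]))

#' Enumerate interacting pair terms of a structure
#'
#' @return list of terms, each with `i`, `j` (block indices), `ba`, `bb`
#'   (body-frame site offsets), `kind` ("morse"/"rep") and `params`.
#' @keywords internal
pair_terms <- function(structure, interactions, repulsion = NULL) {
  blocks <- structure$blocks
  n <- length(blocks)
  terms <- list()
  missing_pairs <- character()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bi <- blocks[[i]]$block; bj <- blocks[[j]]$block
    if (!is.null(interactions) && nrow(bi$patches) && nrow(bj$patches)) {
      for (a in seq_len(nrow(bi$patches))) for (b in seq_len(nrow(bj$patches))) {
        depth <- pair_depth(interactions, bi$patch_types[a], bj$patch_types[b])
        if (is.na(depth)) {
          if (interactions$unknown_pairs == "error") {
            missing_pairs <- c(missing_pairs,
                               paste(bi$patch_types[a], bj$patch_types[b], sep = "~"))
          }
          next
        }
        if (depth == 0) next
        terms[[length(terms) + 1L]] <- list(
          i = i, j = j, ba = bi$patches[a, ], bb = bj$patches[b, ],
          kind = "morse",
          params = morse_params(depth, interactions$alpha, interactions$r0,
                                interactions$r_on, interactions$r_cut))
      }
    }
    if (!is.null(repulsion) && repulsion$A > 0) {
      for (a in seq_len(nrow(bi$spheres))) for (b in seq_len(nrow(bj$spheres))) {
        d_ab <- (bi$sphere_diameters[a] + bj$sphere_diameters[b]) / 2
        terms[[length(terms) + 1L]] <- list(
          i = i, j = j, ba = bi$spheres[a, ], bb = bj$spheres[b, ],
          kind = "rep", params = repulsion_params(repulsion$A, d_ab))
      }
    }
  }
  if (length(missing_pairs)) {
    rlang::abort(paste0("unknown patch type pair(s): ",
                        paste(unique(missing_pairs), collapse = ", ")),
                 class = "assemblyyield_unknown_pair")
  }
  terms
}

#' @keywords internal
pair_value <- function(term, r, deriv = 0) {
  if (term$kind == "morse") morse_smoothed(r, term$params, deriv)
  else soft_repulsion(r, term$params, deriv)
}

#' World-frame block rotations and positions
#' @keywords internal
block_frames <- function(structure) {
  list(
    R = lapply(structure$blocks, function(b) quat_to_rotmat(b$pose$orientation)),
    p = lapply(structure$blocks, function(b) b$pose$position)
  )
}

#' Total energy of a cluster
#'
#' Sum over matching patch pairs on different blocks of the smoothed Morse
#' attraction on the patch-patch distance, plus soft-sphere repulsion between
#' inter-block sphere centers (contact distance: mean of the two diameters).
#' Invariant under global rigid motions; smooth wherever the Laplace
#' machinery needs Hessians. Intra-block terms are excluded (blocks are
#' rigid).
#'
#' @param structure a [cluster_structure()].
#' @param interactions an [interaction_table()] (or `NULL` for none).
#' @param repulsion a [repulsion_params()] (or `NULL` for none).
#' @return energy in kB*T units (at unit `epsilon` scaling it is whatever the
#'   table's strengths imply).
#' @export
cluster_energy <- function(structure, interactions, repulsion = NULL) {
  fr <- block_frames(structure)
  terms <- pair_terms(structure, interactions, repulsion)
  e <- 0
  for (tm in terms) {
    xa <- fr$p[[tm$i]] + fr$R[[tm$i]] %*% tm$ba
    xb <- fr$p[[tm$j]] + fr$R[[tm$j]] %*% tm$bb
    e <- e + pair_value(tm, sqrt(sum((xa - xb)^2)))
  }
  e
}

#' Gradient and Hessian of the cluster energy at the chart origin
#'
#' Closed-form first and second derivatives of [cluster_energy()] with
#' respect to the per-block increment coordinates, evaluated at the poses
#' stored in `structure`.
#'
#' @inheritParams cluster_energy
#' @return `cluster_gradient`: numeric vector (length = total dof).
#'   `cluster_hessian`: symmetric matrix.
#' @export
cluster_gradient <- function(structure, interactions, repulsion = NULL) {
  derivs_impl(structure, interactions, repulsion, want_hessian = FALSE)$grad
}

#' @rdname cluster_gradient
#' @export
cluster_hessian <- function(structure, interactions, repulsion = NULL) {
  derivs_impl(structure, interactions, repulsion, want_hessian = TRUE)$hess
}

#' @keywords internal
derivs_impl <- function(structure, interactions, repulsion, want_hessian) {
  fr <- block_frames(structure)
  terms <- pair_terms(structure, interactions, repulsion)
  dof <- block_dof(structure)
  off <- dof_offsets(dof)
  ndof <- sum(dof)
  grad <- numeric(ndof)
  hess <- if (want_hessian) matrix(0, ndof, ndof) else NULL
  idx <- function(k) (off[k] + 1L):(off[k] + dof[k])
  rtol <- 1e-10
  for (tm in terms) {
    ra <- as.numeric(fr$R[[tm$i]] %*% tm$ba)
    rb <- as.numeric(fr$R[[tm$j]] %*% tm$bb)
    xa <- fr$p[[tm$i]] + ra
    xb <- fr$p[[tm$j]] + rb
    u <- xa - xb
    r <- sqrt(sum(u^2))
    Da <- if (dof[tm$i] == 6L) cbind(diag(3), -skew(ra)) else diag(3)
    Db <- if (dof[tm$j] == 6L) cbind(diag(3), -skew(rb)) else diag(3)
    if (r > rtol) {
      f1 <- pair_value(tm, r, 1)
      uh <- u / r
      g_u <- f1 * uh
    } else {
      f1 <- 0
      g_u <- c(0, 0, 0)
    }
    grad[idx(tm$i)] <- grad[idx(tm$i)] + as.numeric(t(Da) %*% g_u)
    grad[idx(tm$j)] <- grad[idx(tm$j)] - as.numeric(t(Db) %*% g_u)
    if (want_hessian) {
      f2 <- pair_value(tm, r, 2)
      Hu <- if (r > rtol) {
        f2 * (uh %o% uh) + (f1 / r) * (diag(3) - uh %o% uh)
      } else {
        f2 * diag(3)
      }
      ii <- idx(tm$i); jj <- idx(tm$j)
      hess[ii, ii] <- hess[ii, ii] + t(Da) %*% Hu %*% Da + curvature_term(g_u, ra, dof[tm$i])
      hess[jj, jj] <- hess[jj, jj] + t(Db) %*% Hu %*% Db + curvature_term(-g_u, rb, dof[tm$j])
      cross <- -t(Da) %*% Hu %*% Db
      hess[ii, jj] <- hess[ii, jj] + cross
      hess[jj, ii] <- hess[jj, ii] + t(cross)
    }
  }
  list(grad = grad, hess = hess)
}

#' Second-derivative (chart curvature) contribution of one site
#' @keywords internal
curvature_term <- function(g, r, dof) {
  out <- matrix(0, dof, dof)
  if (dof == 6L) {
    T <- 0.5 * (g %o% r + r %o% g) - sum(g * r) * diag(3)
    out[4:6, 4:6] <- T
  }
  out
}

#' Apply chart increments to a structure (retraction)
#'
#' @param structure a [cluster_structure()].
#' @param xi increment vector in the structure's chart.
#' @return the displaced `cluster_structure`.
#' @export
displace_structure <- function(structure, xi) {
  dof <- block_dof(structure)
  off <- dof_offsets(dof)
  for (k in seq_along(structure$blocks)) {
    dq <- xi[(off[k] + 1L):(off[k] + 3L)]
    structure$blocks[[k]]$pose$position <-
      structure$blocks[[k]]$pose$position + dq
    if (dof[k] == 6L) {
      dw <- xi[(off[k] + 4L):(off[k] + 6L)]
      th <- sqrt(sum(dw^2))
      qrot <- if (th < 1e-300) c(1, 0, 0, 0) else c(cos(th / 2), sin(th / 2) * dw / th)
      structure$blocks[[k]]$pose$orientation <-
        quat_normalize(quat_multiply(qrot, structure$blocks[[k]]$pose$orientation))
    }
  }
  structure
}
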