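# From per-structure partition functions to concentrations and yields.
#
# Grand-canonical mode: solve, in log free-monomer-concentration variables,
#   c_s / prod_a c_a^{N_{s,a}} = (Z_s/V) / prod_a (Z_a/V)^{N_{s,a}}
# subject to sum_s N_{s,a} c_s = c_a^tot (one conservation law per species).
# Canonical mode: exact enumeration over cluster configurations for small
# closed systems. Factors of V (and any per-length normalization of the
# partition functions) cancel identically.

#' Ensemble specification
#'
#' @param beta inverse temperature.
#' @param volume system volume (cancels out of grand-canonical yields; sets
#'   the canonical box).
#' @param concentrations named vector of total concentrations per species
#'   (grand-canonical mode).
#' @param counts named integer vector of particle numbers per species
#'   (canonical mode).
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(beta = 1, volume = 1, concentrations = NULL,
                          counts = NULL) {
  if (is.null(concentrations) == is.null(counts)) {
    rlang::abort("give exactly one of `concentrations` (grand-canonical) or `counts` (canonical)")
  }
  if (volume <= 0) rlang::abort("volume must be positive")
  if (!is.null(concentrations) && any(concentrations <= 0)) {
    rlang::abort("total concentrations must be positive")
  }
  if (!is.null(counts) && any(counts < 1)) rlang::abort("counts must be >= 1")
  structure(list(beta = beta, volume = volume,
                 concentrations = concentrations, counts = counts,
                 mode = if (is.null(counts)) "grand-canonical" else "canonical"),
            class = "ensemble_spec")
}

#' @keywords internal
structure_entry <- function(x) {
  # normalize a (structure, Z) pair into label/composition/ln_Z_per_V
  s <- x$structure; z <- x$Z
  list(label = if (nzchar(s$label)) s$label else z$label,
       composition = s$composition,
       ln_Z_per_V = z$ln_Z_per_V,
       N_total = sum(s$composition))
}

#' Grand-canonical self-consistent yield solve
#'
#' Damped Newton iteration in log free-monomer concentrations, initialized
#' at the total concentrations. The structure list must contain every
#' monomer species as a structure (the unbound monomer is a valid
#' equilibrium structure).
#'
#' @param structures list of pairs `list(structure = <cluster_structure>,
#'   Z = <partition_function>)`, all with mutually consistent conventions.
#' @param spec an [ensemble_spec()] in grand-canonical mode.
#' @param tol convergence tolerance on the conservation residuals
#'   (relative).
#' @param max_iter Newton iteration cap.
#' @return a `yield_solution`: a tibble with one row per structure (columns
#'   `structure`, `n_blocks`, `concentration`, `yield`) carrying the free
#'   monomer concentrations, normalized concentrations, conservation
#'   residuals and solver diagnostics as attributes.
#' @export
gc_solve <- function(structures, spec, tol = 1e-12, max_iter = 500) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$mode != "grand-canonical") rlang::abort("spec must be grand-canonical")
  entries <- lapply(structures, structure_entry)
  species <- names(spec$concentrations)
  if (is.null(species)) rlang::abort("concentrations must be named by species")
  comp <- t(vapply(entries, function(e) {
    v <- stats::setNames(numeric(length(species)), species)
    miss <- setdiff(names(e$composition), species)
    if (length(miss)) rlang::abort(paste("structure uses unknown species:",
                                         paste(miss, collapse = ", ")))
    v[names(e$composition)] <- e$composition
    v
  }, numeric(length(species))))
  if (is.null(dim(comp))) comp <- matrix(comp, ncol = 1,
                                         dimnames = list(NULL, species))
  monomer_idx <- vapply(species, function(a) {
    i <- which(comp[, a] == 1 & rowSums(comp) == 1)
    if (length(i) < 1) rlang::abort(sprintf("monomer structure for species '%s' is missing", a))
    i[1]
  }, integer(1))
  lnZv <- vapply(entries, function(e) e$ln_Z_per_V, numeric(1))
  ln_K <- lnZv - as.numeric(comp %*% lnZv[monomer_idx])
  ln_ctot <- log(spec$concentrations[species])
  x <- ln_ctot                       # x = ln c_alpha (free monomers)
  ln_cs <- function(x) ln_K + as.numeric(comp %*% x)
  residual <- function(x) {
    lc <- ln_cs(x)
    vapply(seq_along(species), function(a) {
      idx <- which(comp[, a] > 0)
      m <- max(lc[idx])
      log(sum(comp[idx, a] * exp(lc[idx] - m))) + m - ln_ctot[a]
    }, numeric(1))
  }
  FF <- residual(x)
  it <- 0L
  while (max(abs(FF)) > tol && it < max_iter) {
    it <- it + 1L
    lc <- ln_cs(x)
    m <- max(lc)
    w <- exp(lc - m)
    J <- matrix(0, length(species), length(species))
    for (a in seq_along(species)) {
      den <- sum(comp[, a] * w)
      for (b in seq_along(species)) {
        J[a, b] <- sum(comp[, a] * comp[, b] * w) / den
      }
    }
    # Levenberg-regularized Newton: the Jacobian degenerates when one
    # structure dominates every conservation law
    lam <- 1e-12 * max(abs(J), 1)
    step <- NULL
    for (k in 1:30) {
      step <- tryCatch(
        -solve(crossprod(J) + lam * diag(ncol(J)), crossprod(J, FF)),
        error = function(e) NULL)
      if (!is.null(step)) break
      lam <- lam * 100
    }
    if (is.null(step)) step <- -FF
    step <- pmax(pmin(as.numeric(step), 50), -50)  # log-domain trust region
    tau <- 1
    repeat {
      Fn <- residual(x + tau * step)
      if (sum(Fn^2) <= sum(FF^2) * (1 - 1e-4 * tau) || tau < 1e-10) break
      tau <- tau / 2
    }
    if (sum(Fn^2) >= sum(FF^2) && lam < 1) {
      # stalled: retry with a heavily damped (gradient-like) step
      step2 <- pmax(pmin(-FF, 1), -1)
      Fn2 <- residual(x + step2)
      if (sum(Fn2^2) < sum(Fn^2)) { Fn <- Fn2; tau <- 1; step <- step2 }
    }
    x <- x + tau * step
    FF <- Fn
  }
  if (max(abs(FF)) > 1e-8) {
    rlang::abort(sprintf("mass-action solver did not converge (max residual %.3g)",
                         max(abs(FF))), class = "assemblyyield_solver_error")
  }
  lc <- ln_cs(x)
  cs <- exp(lc)
  yields <- cs / sum(cs)
  out <- tibble::tibble(
    structure = vapply(entries, function(e) e$label, character(1)),
    n_blocks = vapply(entries, function(e) e$N_total, numeric(1)),
    concentration = cs,
    yield = yields
  )
  free <- stats::setNames(exp(x), species)
  attr(out, "free_monomers") <- free
  attr(out, "normalized_concentrations") <-
    stats::setNames(free / exp(lnZv[monomer_idx]), species)
  attr(out, "residuals") <- stats::setNames(FF, species)
  attr(out, "iterations") <- it
  attr(out, "beta") <- spec$beta
  class(out) <- c("yield_solution", class(out))
  out
}

#' Closed-form grand-canonical dimer yield
#'
#' For the two-species dimerizing system with internal bound volume
#' `V_int = 4 pi int r^2 exp(-beta U(r)) dr` the mass-action system has the
#' closed form
#' `Y_d = (q - sqrt(q^2 - 4 V_int^2 cb cw)) / (q - 2 + sqrt(q^2 - 4 V_int^2 cb cw))`
#' with `q = V_int (cb + cw) + 1`.
#'
#' @param V_int bound-state internal volume (>= 0).
#' @param cb_tot,cw_tot total concentrations of the two monomer species.
#' @return dimer yield in [0, 1].
#' @export
gc_dimer_closed_form <- function(V_int, cb_tot, cw_tot) {
  if (V_int < 0) rlang::abort("V_int must be >= 0")
  if (V_int == 0) return(0)
  q <- V_int * (cb_tot + cw_tot) + 1
  disc <- sqrt(pmax(q^2 - 4 * V_int^2 * cb_tot * cw_tot, 0))
  (q - disc) / (q - 2 + disc)
}

# ---- canonical ensemble --------------------------------------------------

#' Enumerate canonical cluster configurations
#'
#' All multisets of clusters consistent with the per-species particle
#' counts: nonnegative integers `N_a` with
#' `sum_a N_a N_{a,i} = n_i` for every species `i`.
#'
#' @param counts named integer vector of per-species particle numbers.
#' @param compositions list of named integer vectors, one per cluster type
#'   (must include the monomers).
#' @param guard maximum total particle number for exhaustive enumeration.
#' @return list of integer vectors (one count per cluster type, named by
#'   `names(compositions)` or index).
#' @export
canonical_enumerate <- function(counts, compositions, guard = 30) {
  if (sum(counts) > guard) {
    rlang::abort(sprintf(
      "total particle count %d exceeds the enumeration guard (%d); use the grand-canonical solver",
      sum(counts), guard))
  }
  species <- names(counts)
  A <- t(vapply(compositions, function(co) {
    v <- stats::setNames(numeric(length(species)), species)
    v[names(co)] <- co
    v
  }, numeric(length(species))))
  nm <- names(compositions)
  if (is.null(nm)) nm <- paste0("cluster", seq_along(compositions))
  out <- list()
  rec <- function(a, remaining, acc) {
    if (a > nrow(A)) {
      if (all(remaining == 0)) out[[length(out) + 1L]] <<- stats::setNames(acc, nm)
      return(invisible())
    }
    uses <- A[a, ]
    maxn <- if (all(uses == 0)) 0L else floor(min(remaining[uses > 0] / uses[uses > 0]))
    # feasibility prune: later rows must be able to consume the rest
    for (n in 0:maxn) {
      rem <- remaining - n * uses
      if (a == nrow(A) && !all(rem == 0)) next
      rec(a + 1L, rem, c(acc, n))
    }
  }
  rec(1L, as.numeric(counts[species]), integer(0))
  out
}

#' Canonical multiplicity of a configuration
#'
#' Number of ways of assigning the labeled building blocks to the clusters
#' of a configuration:
#' `M = prod_i n_i! / ( prod_a N_a! prod_{a,i} (N_{a,i}!)^{N_a} )`.
#' For the monomer/dimer system this reduces to the familiar
#' `choose(Nb, Nd) choose(Nw, Nd) Nd!`.
#'
#' @param config integer vector of cluster counts `N_a`.
#' @param counts named per-species totals `n_i`.
#' @param compositions list of named integer vectors `N_{a,i}`.
#' @return the multiplicity as a numeric (exact for moderate sizes), with
#'   attribute `"log"` carrying `ln M`.
#' @export
canonical_M <- function(config, counts, compositions) {
  ln <- sum(lfactorial(counts))
  for (a in seq_along(config)) {
    ln <- ln - lfactorial(config[a]) -
      config[a] * sum(lfactorial(compositions[[a]]))
  }
  out <- exp(ln)
  if (sum(counts) <= 18) out <- round(out)   # exact in double precision
  attr(out, "log") <- ln
  out
}

#' Exact canonical yields for a small closed system
#'
#' Enumerates every configuration, weights it by
#' `p = M * prod_a Z_a^{N_a}` (computed in the log domain), normalizes, and
#' averages cluster fractions:
#' `Y_s = sum_c (N_s^c / sum_s' N_s'^c) P_c`.
#'
#' @param structures list of `list(structure = , Z = )` pairs (cluster
#'   types, including monomers) with partition functions evaluated at the
#'   ensemble volume.
#' @param spec an [ensemble_spec()] in canonical mode.
#' @param guard enumeration guard on the total particle number.
#' @return a `canonical_solution`: tibble of per-structure yields with the
#'   configuration table as attribute `configurations`.
#' @export
canonical_yield <- function(structures, spec, guard = 30) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$mode != "canonical") rlang::abort("spec must be canonical")
  entries <- lapply(structures, structure_entry)
  compositions <- lapply(entries, function(e) e$composition)
  names(compositions) <- vapply(entries, function(e) e$label, character(1))
  lnZ <- vapply(entries, function(e) e$ln_Z_per_V, numeric(1)) +
    log(spec$volume)
  configs <- canonical_enumerate(spec$counts, compositions, guard = guard)
  if (length(configs) == 0) rlang::abort("no feasible configuration")
  lnp <- vapply(configs, function(cf) {
    attr(canonical_M(cf, spec$counts, compositions), "log") + sum(cf * lnZ)
  }, numeric(1))
  m <- max(lnp)
  P <- exp(lnp - m); P <- P / sum(P)
  nclus <- vapply(configs, sum, numeric(1))
  yields <- vapply(seq_along(entries), function(a) {
    sum(P * vapply(configs, function(cf) cf[a], numeric(1)) / nclus)
  }, numeric(1))
  out <- tibble::tibble(
    structure = names(compositions),
    n_blocks = vapply(entries, function(e) e$N_total, numeric(1)),
    yield = yields
  )
  cfg <- do.call(rbind, configs)
  attr(out, "configurations") <- tibble::as_tibble(as.data.frame(cfg)) |>
    dplyr::mutate(probability = P)
  attr(out, "beta") <- spec$beta
  class(out) <- c("canonical_solution", class(out))
  out
}

# ---- exactly solvable spherical dimer ------------------------------------

#' Exact Z-ratio of the overlapping spherical dimer
#'
#' `Z_dimer / (Z_1 Z_2) = 4 pi int_0^{r0 + r_cut} r^2 exp(-beta U(r)) dr / V`
#' with `U` the smoothed Morse attraction on the center-center distance. The
#' integral is restricted to the bound region `[0, r0 + r_cut]` (beyond the
#' cutoff the pair is not a cluster).
#'
#' @param p a [morse_params()].
#' @param beta inverse temperature.
#' @param V system volume.
#' @param rel_tol quadrature tolerance.
#' @param log return the log of the ratio.
#' @export
spherical_dimer_exact_ratio <- function(p, beta, V = 1, rel_tol = 1e-10,
                                        log = FALSE) {
  # well depth factored out for numerical range
  f <- function(r) 4 * pi * r^2 * exp(-beta * (morse_smoothed(r, p) + p$E_b))
  upper <- p$r0 + p$r_cut
  val <- stats::integrate(f, 0, upper, rel.tol = rel_tol,
                          subdivisions = 1000L)$value
  ln <- beta * p$E_b + base::log(val) - base::log(V)
  if (log) ln else exp(ln)
}

#' Finite-size gap between grand-canonical and canonical dimer yields
#'
#' For the exactly solvable spherical dimer the grand-canonical yield has
#' the closed form of [gc_dimer_closed_form()] while the canonical yield is
#' an exact finite sum; their difference quantifies the grand-canonical
#' error for finite systems and decays with particle number.
#'
#' @param N_m monomers of each color.
#' @param p a [morse_params()] describing the attraction.
#' @param beta inverse temperature.
#' @param volume box volume; with `density` given, `volume = 2 N_m /
#'   density` instead (constant-density scaling).
#' @param density optional total number density (both species).
#' @return tibble with `N_m`, `Y_gc`, `Y_canonical`, `gap`.
#' @export
dimer_ensemble_gap <- function(N_m, p, beta = 1, volume = 18000,
                               density = NULL) {
  V_int <- spherical_dimer_exact_ratio(p, beta, V = 1)
  rows <- lapply(N_m, function(n) {
    V <- if (is.null(density)) volume else 2 * n / density
    Ygc <- gc_dimer_closed_form(V_int, n / V, n / V)
    # canonical: configurations indexed by the dimer count
    Nd <- 0:n
    lnp <- lfactorial(n) * 2 - lfactorial(n - Nd) * 2 - lfactorial(Nd) +
      Nd * log(V_int / V)
    P <- exp(lnp - max(lnp)); P <- P / sum(P)
    Yc <- sum(P * Nd / (2 * n - Nd))
    tibble::tibble(N_m = n, Y_gc = Ygc, Y_canonical = Yc,
                   gap = abs(Ygc - Yc))
  })
  dplyr::bind_rows(rows)
}

#' Second-order Laplace Z-ratio of the overlapping spherical dimer
#'
#' Closed form `exp(beta E0) pi^{3/2} / ((beta E0)^{3/2} alpha^3 V)`,
#' computed in logs.
#'
#' @inheritParams spherical_dimer_exact_ratio
#' @export
spherical_dimer_laplace_ratio <- function(p, beta, V = 1, log = FALSE) {
  bE <- beta * p$E_b
  if (bE <= 0) rlang::abort("beta * E0 must be positive")
  ln <- bE + 1.5 * base::log(pi) - 1.5 * base::log(bE) -
    3 * base::log(p$alpha) - base::log(V)
  if (log) ln else exp(ln)
}
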