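make_dimer_pairs <- function(E_b = 8, alpha = 5, V = 18000, beta = 1) {
  sd <- spherical_dimer_system(E_b = E_b, alpha = alpha)
  list(
    pairs = list(
      list(structure = sd$monomer_b,
           Z = compute_partition_function(sd$monomer_b, V = V, beta = beta)),
      list(structure = sd$monomer_w,
           Z = compute_partition_function(sd$monomer_w, V = V, beta = beta)),
      list(structure = sd$dimer,
           Z = compute_partition_function(sd$dimer, sd$interactions, V = V,
                                          beta = beta))),
    sd = sd, V = V)
}

test_that("the closed-form dimer yield matches its printed special values", {
  expect_equal(gc_dimer_closed_form(0, 1e-3, 1e-3), 0)
  # V_int * c = 1 for both species: q = 3, Y = (3 - sqrt(5)) / (1 + sqrt(5))
  expect_equal(gc_dimer_closed_form(1, 1, 1), (3 - sqrt(5)) / (1 + sqrt(5)))
  expect_equal(gc_dimer_closed_form(1, 1, 1), 0.2360679, tolerance = 1e-6)
  # strong binding saturates at 1 (rate ~ 1/sqrt(V_int c))
  expect_equal(gc_dimer_closed_form(1e14, 1e-3, 1e-3), 1, tolerance = 1e-5)
  expect_error(gc_dimer_closed_form(-1, 1, 1), "V_int")
})

test_that("gc_solve reproduces the closed-form dimer solution to 1e-10", {
  mk <- make_dimer_pairs(E_b = 8)
  cb <- 9 / mk$V; cw <- 7 / mk$V
  sol <- gc_solve(mk$pairs, ensemble_spec(concentrations = c(black = cb,
                                                             white = cw)))
  zs <- lapply(mk$pairs, function(p) p$Z$ln_Z)
  V_int <- exp(zs[[3]] - zs[[1]] - zs[[2]] + log(mk$V))
  expect_equal(sol$yield[3], gc_dimer_closed_form(V_int, cb, cw),
               tolerance = 1e-10)
  expect_equal(sum(sol$yield), 1, tolerance = 1e-12)
  expect_lt(max(abs(attr(sol, "residuals"))), 1e-8)
})

test_that("gc_solve yields are volume-independent and respect edge cases", {
  cb <- 5e-4; cw <- 5e-4
  y <- lapply(c(9000, 18000, 90000), function(V) {
    mk <- make_dimer_pairs(E_b = 8, V = V)
    gc_solve(mk$pairs, ensemble_spec(volume = V,
                                     concentrations = c(black = cb,
                                                        white = cw)))$yield
  })
  expect_equal(y[[1]], y[[2]], tolerance = 1e-10)
  expect_equal(y[[2]], y[[3]], tolerance = 1e-10)

  # monomer-only input: free concentrations equal the totals
  mk <- make_dimer_pairs()
  mono <- mk$pairs[1:2]
  sol <- gc_solve(mono, ensemble_spec(concentrations = c(black = 2e-4,
                                                         white = 6e-4)))
  expect_equal(unname(attr(sol, "free_monomers")), c(2e-4, 6e-4),
               tolerance = 1e-12)
  expect_equal(sol$yield, c(0.25, 0.75), tolerance = 1e-12)

  # a missing monomer structure is an error
  expect_error(gc_solve(mk$pairs[c(1, 3)],
                        ensemble_spec(concentrations = c(black = 1e-4,
                                                         white = 1e-4))),
               "monomer")
})

test_that("per-length normalizations cancel from the yields identically", {
  mk <- make_dimer_pairs(E_b = 8)
  spec <- ensemble_spec(concentrations = c(black = 5e-4, white = 5e-4))
  sol0 <- gc_solve(mk$pairs, spec)
  # multiply every Z by kappa^(3 N_s): the lambda bookkeeping of the
  # configurational partition function
  kap3 <- log(7.3)
  scaled <- lapply(mk$pairs, function(p) {
    N <- sum(p$structure$composition)
    p$Z$ln_Z_per_V <- p$Z$ln_Z_per_V + N * kap3
    p
  })
  sol1 <- gc_solve(scaled, spec)
  expect_identical(sol0$yield, sol1$yield)
})

test_that("canonical enumeration lists exactly the feasible configurations", {
  comps <- list(b = c(b = 1), w = c(w = 1), d = c(b = 1, w = 1))
  cfg <- canonical_enumerate(c(b = 2, w = 2), comps)
  expect_length(cfg, 3)              # Nd = 0, 1, 2
  expect_setequal(vapply(cfg, function(x) x[["d"]], numeric(1)), 0:2)
  for (x in cfg) {
    expect_equal(x[["b"]] + x[["d"]], 2)
    expect_equal(x[["w"]] + x[["d"]], 2)
  }

  expect_length(canonical_enumerate(c(b = 1), list(b = c(b = 1))), 1)
  expect_length(canonical_enumerate(c(b = 9, w = 9), comps), 10)
  expect_error(canonical_enumerate(c(b = 20, w = 20), comps), "guard")
})

test_that("canonical multiplicities match the dimer formula and brute force", {
  comps <- list(b = c(b = 1), w = c(w = 1), d = c(b = 1, w = 1))
  M <- function(Nb, Nw, Nd) {
    as.numeric(canonical_M(c(b = Nb - Nd, w = Nw - Nd, d = Nd),
                           c(b = Nb, w = Nw), comps))
  }
  expect_equal(M(1, 1, 1), 1)
  expect_equal(M(2, 2, 1), 4)
  expect_equal(M(9, 9, 9), factorial(9))

  for (Nb in 1:9) for (Nw in 1:9) for (Nd in 0:min(Nb, Nw)) {
    expect_equal(M(Nb, Nw, Nd), choose(Nb, Nd) * choose(Nw, Nd) * factorial(Nd))
  }

  # labeled brute-force enumeration for small systems
  for (Nb in 1:3) for (Nw in 1:3) for (Nd in 0:min(Nb, Nw)) {
    expect_equal(M(Nb, Nw, Nd), brute_dimer_assignments(Nb, Nw, Nd))
  }
})

test_that("canonical yields agree with a hand enumeration and are symmetric", {
  mk <- make_dimer_pairs(E_b = 8)
  spec2 <- ensemble_spec(volume = mk$V, counts = c(black = 1, white = 1))
  sol <- canonical_yield(mk$pairs, spec2)
  # two configurations: {b, w} and {d}
  zs <- lapply(mk$pairs, function(p) p$Z$ln_Z)
  p_free <- exp(zs[[1]] + zs[[2]]); p_dimer <- exp(zs[[3]])
  P_d <- p_dimer / (p_dimer + p_free)
  expect_equal(sol$yield[sol$structure == "bw"], P_d, tolerance = 1e-12)
  expect_equal(sol$yield[sol$structure == "b"], (1 - P_d) / 2,
               tolerance = 1e-12)
  expect_equal(sum(attr(sol, "configurations")$probability), 1,
               tolerance = 1e-12)

  solN <- canonical_yield(mk$pairs, ensemble_spec(volume = mk$V,
                                                  counts = c(black = 6,
                                                             white = 6)))
  expect_equal(solN$yield[solN$structure == "b"],
               solN$yield[solN$structure == "w"], tolerance = 1e-12)
})

test_that("exact and Laplace spherical-dimer ratios behave as derived", {
  # beta = 0: the bound-region volume (4 pi / 3) r_cut^3 / V
  p <- morse_params(5, 5)
  expect_equal(spherical_dimer_exact_ratio(p, 0, 100),
               4 * pi / 3 * 1.6^3 / 100, tolerance = 1e-9)

  # ~40% relative deviation at beta E0 = 30
  p30 <- morse_params(30, 5)
  ex <- spherical_dimer_exact_ratio(p30, 1, 1)
  la <- spherical_dimer_laplace_ratio(p30, 1, 1)
  expect_equal(abs(ex - la) / ex, 0.39, tolerance = 0.04)

  # deviation vanishes in the deep-well limit
  devs <- vapply(c(30, 300, 3000), function(bE) {
    pp <- morse_params(bE, 5)
    abs(1 - exp(spherical_dimer_laplace_ratio(pp, 1, 1, log = TRUE) -
                  spherical_dimer_exact_ratio(pp, 1, 1, log = TRUE)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 0.05)

  # V scaling
  expect_equal(spherical_dimer_laplace_ratio(p30, 1, 2) * 2,
               spherical_dimer_laplace_ratio(p30, 1, 1))
})

test_that("the Laplace error in E_half shrinks with the interaction range", {
  c_tot <- 5e-4
  E_half <- function(alpha, method) {
    f <- function(E0) {
      p <- morse_params(E0, alpha)
      Vint <- if (method == "exact") spherical_dimer_exact_ratio(p, 1, 1)
      else spherical_dimer_laplace_ratio(p, 1, 1)
      gc_dimer_closed_form(Vint, c_tot, c_tot) - 0.5
    }
    stats::uniroot(f, c(0.5, 60), tol = 1e-9)$root
  }
  rel_err <- vapply(c(20, 10, 5, 2.5), function(al) {
    ee <- E_half(al, "exact")
    abs(E_half(al, "laplace") - ee) / ee
  }, numeric(1))
  # ranges 0.4, 0.8, 1.6, 3.2 d: the error grows with the range
  expect_true(all(diff(rel_err) > 0))
})

test_that("the grand-canonical error decays as a power law in system size", {
  p <- morse_params(16, 5)
  for (mode in c("volume", "density")) {
    g <- if (mode == "volume") {
      dimer_ensemble_gap(c(3, 6, 12, 24), p, volume = 18000)
    } else {
      dimer_ensemble_gap(c(3, 6, 12, 24), p, density = 1e-3)
    }
    expect_true(all(diff(g$gap) < 0))
    fit <- stats::lm(log(gap) ~ log(N_m), data = g)
    expect_lt(stats::coef(fit)[2], 0)
    expect_gt(summary(fit)$r.squared, 0.95)
  }
})

test_that("entropy shifts the toy dimer yield curve away from the energy-only one", {
  tc <- toy_dimer_yield_curves(c(5, 7, 9), mc_config(2000, 13))
  expect_true(all(tc$yield_dimer >= 0 & tc$yield_dimer <= 1))
  expect_true(all(diff(tc$yield_dimer) > 0))   # monotone in E_b
  # the energy-only curve saturates immediately; the full curve does not
  expect_true(all(tc$yield_dimer_energy_only > 0.999999))
  expect_true(all(tc$yield_dimer < 0.9))
  expect_gt(max(abs(tc$yield_dimer - tc$yield_dimer_energy_only)), 0.1)
})
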