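# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a partition function into its exportable record
#'
#' One row: label, E0, log factors, Jacobian integral with its Monte Carlo
#' error, symmetry number and sampling bookkeeping.
#'
#' @param x a `partition_function`; @param ... unused.
#' @exportS3Method generics::tidy
tidy.partition_function <- function(x, ...) {
  tibble::tibble(label = x$label, E0 = x$E0, ln_Zvib = x$ln_Zvib,
                 ln_Zrot = x$ln_Zrot, Jtilde = x$Jtilde,
                 mc_stderr = x$mc_stderr, sigma = x$sigma,
                 n_samples = x$n_samples, seed = x$seed)
}

#' @rdname tidy.partition_function
#' @exportS3Method generics::glance
glance.partition_function <- function(x, ...) {
  tibble::tibble(ln_Z = x$ln_Z, ln_Z_per_V = x$ln_Z_per_V, beta = x$beta,
                 V = x$V)
}

#' Tidy yield solutions
#'
#' `tidy()` returns the per-structure table; `glance()` the solver
#' diagnostics (iterations, worst conservation residual, yield sum).
#'
#' @param x a `yield_solution`; @param ... unused.
#' @exportS3Method generics::tidy
tidy.yield_solution <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("structure", "n_blocks", "concentration",
                                 "yield")])
}

#' @rdname tidy.yield_solution
#' @exportS3Method generics::glance
glance.yield_solution <- function(x, ...) {
  tibble::tibble(n_structures = nrow(x),
                 iterations = attr(x, "iterations"),
                 max_residual = max(abs(attr(x, "residuals"))),
                 yield_sum = sum(x$yield))
}

#' @rdname tidy.yield_solution
#' @exportS3Method generics::tidy
tidy.canonical_solution <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("structure", "n_blocks", "yield")])
}

#' @rdname tidy.yield_solution
#' @exportS3Method generics::glance
glance.canonical_solution <- function(x, ...) {
  cfg <- attr(x, "configurations")
  tibble::tibble(n_structures = nrow(x), n_configurations = nrow(cfg),
                 yield_sum = sum(x$yield))
}

#' Plot a yield solution
#'
#' Bars of equilibrium yield per structure.
#'
#' @param object a `yield_solution` or `canonical_solution`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.yield_solution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = stats::reorder(.data$structure,
                                                  .data$n_blocks),
                               y = .data$yield)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "structure", y = "equilibrium yield") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.yield_solution
#' @exportS3Method ggplot2::autoplot
autoplot.canonical_solution <- autoplot.yield_solution

#' Plot a yield scan
#'
#' Yield curves against the interaction energy scale, one line per
#' structure, faceted by totals grid point.
#'
#' @param object a `yield_scan` from [run_scan()].
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.yield_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$epsilon, y = .data$yield,
                               colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~totals) +
    ggplot2::labs(x = "energy scale (kT)", y = "yield") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
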