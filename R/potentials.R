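# Pair potentials: smoothed Morse attraction between matching patches and a
# soft-sphere repulsion between block bodies. All energies in kB*T units
# (beta multiplies them downstream), lengths in units of the sphere diameter.

#' Morse parameters
#'
#' @param E_b well depth (> 0, in kB*T).
#' @param alpha inverse interaction length (1/d); the interaction range is
#'   `8/alpha`.
#' @param r0 location of the minimum (the potential is evaluated at `r - r0`).
#' @param r_on smoothing onset; 0 throughout the reference systems.
#' @param r_cut smoothing cutoff; defaults to `8/alpha`.
#' @return object of class `morse_params`.
#' @export
morse_params <- function(E_b, alpha, r0 = 0, r_on = 0, r_cut = 8 / alpha) {
  if (E_b <= 0) rlang::abort("E_b must be positive")
  if (!(r_on >= 0 && r_on < r_cut)) rlang::abort("need 0 <= r_on < r_cut")
  structure(list(E_b = E_b, alpha = alpha, r0 = r0, r_on = r_on, r_cut = r_cut),
            class = "morse_params")
}

#' Repulsion parameters
#'
#' Soft sphere-sphere repulsion `H(r) = A/(2.5 d) (d - r)^{2.5}` for `r < d`.
#'
#' @param A stiffness (energy/length^1.5), default 500.
#' @param d sphere contact diameter.
#' @export
repulsion_params <- function(A = 500, d = 1) {
  if (A < 0) rlang::abort("A must be >= 0")
  if (d <= 0) rlang::abort("d must be > 0")
  structure(list(A = A, d = d), class = "repulsion_params")
}

#' Smoothing factor S(r)
#'
#' Polynomial switching function: 1 below `r_on`, 0 above `r_cut`,
#' continuously differentiable at both junctions and monotone in between:
#' `S(r) = (r_cut^2 - r^2)^2 (r_cut^2 + 2 r^2 - 3 r_on^2) /
#'         (r_cut^2 - r_on^2)^3`.
#'
#' @param r distance (>= 0); vectorized.
#' @param r_on,r_cut onset and cutoff, `0 <= r_on < r_cut`.
#' @param deriv 0, 1 or 2: return S, S' or S''.
#' @export
smoothing_S <- function(r, r_on, r_cut, deriv = 0) {
  if (!(r_on >= 0 && r_on < r_cut)) rlang::abort("need 0 <= r_on < r_cut")
  den <- (r_cut^2 - r_on^2)^3
  mid <- r > r_on & r < r_cut
  out <- numeric(length(r))
  if (deriv == 0) {
    out[r <= r_on] <- 1
    rm <- r[mid]
    out[mid] <- (r_cut^2 - rm^2)^2 * (r_cut^2 + 2 * rm^2 - 3 * r_on^2) / den
  } else if (deriv == 1) {
    rm <- r[mid]
    out[mid] <- (-4 * rm * (r_cut^2 - rm^2) * (r_cut^2 + 2 * rm^2 - 3 * r_on^2) +
                   4 * rm * (r_cut^2 - rm^2)^2) / den
  } else if (deriv == 2) {
    # S = P(x)/den with x = r^2, P(x) = (c2 - x)^2 (c2 + 2x - 3 o2):
    # S'' = (2 P'(x) + 4 x P''(x)) / den
    x <- r[mid]^2
    c2 <- r_cut^2; o2 <- r_on^2
    P1 <- -2 * (c2 - x) * (c2 + 2 * x - 3 * o2) + 2 * (c2 - x)^2
    P2 <- 2 * (c2 + 2 * x - 3 * o2) - 8 * (c2 - x)
    out[mid] <- (2 * P1 + 4 * x * P2) / den
  } else rlang::abort("deriv must be 0, 1 or 2")
  out
}

#' Smoothed Morse pair potential
#'
#' `E(r) = E_b (exp(-2 a (r - r0)) - 2 exp(-a (r - r0))) S(r - r0)` with the
#' smoothing of [smoothing_S()]. The minimum value is `-E_b`, attained at
#' `r = r0`; the potential vanishes for `r >= r0 + r_cut`.
#'
#' @param r distance (vectorized, >= 0).
#' @param p a [morse_params()].
#' @param deriv 0, 1 or 2 for the value and radial derivatives.
#' @export
morse_smoothed <- function(r, p, deriv = 0) {
  x <- r - p$r0
  m <- exp(-2 * p$alpha * x) - 2 * exp(-p$alpha * x)
  mid <- x > p$r_on & x < p$r_cut
  S <- numeric(length(x))
  S[x <= p$r_on] <- 1
  S[mid] <- smoothing_S(x[mid], p$r_on, p$r_cut)
  if (deriv == 0) return(p$E_b * m * S)
  m1 <- -2 * p$alpha * exp(-2 * p$alpha * x) + 2 * p$alpha * exp(-p$alpha * x)
  S1 <- numeric(length(x))
  S1[mid] <- smoothing_S(x[mid], p$r_on, p$r_cut, deriv = 1)
  if (deriv == 1) return(p$E_b * (m1 * S + m * S1))
  m2 <- 4 * p$alpha^2 * exp(-2 * p$alpha * x) - 2 * p$alpha^2 * exp(-p$alpha * x)
  S2 <- numeric(length(x))
  S2[mid] <- smoothing_S(x[mid], p$r_on, p$r_cut, deriv = 2)
  if (deriv == 2) return(p$E_b * (m2 * S + 2 * m1 * S1 + m * S2))
  rlang::abort("deriv must be 0, 1 or 2")
}

#' Soft-sphere repulsion
#'
#' `H(r) = A/(2.5 d) (d - r)^{2.5}` for `r < d`, zero otherwise. Value and
#' first derivative are continuous at contact (`r = d`).
#'
#' @param r center-center distance (vectorized).
#' @param p a [repulsion_params()].
#' @param deriv 0, 1 or 2.
#' @export
soft_repulsion <- function(r, p, deriv = 0) {
  out <- numeric(length(r))
  inside <- r < p$d
  ri <- r[inside]
  if (deriv == 0) out[inside] <- p$A / (2.5 * p$d) * (p$d - ri)^2.5
  else if (deriv == 1) out[inside] <- -p$A / p$d * (p$d - ri)^1.5
  else if (deriv == 2) out[inside] <- 1.5 * p$A / p$d * (p$d - ri)^0.5
  else rlang::abort("deriv must be 0, 1 or 2")
  out
}

#' Interaction table for typed patches
#'
#' Maps unordered pairs of patch types to Morse parameters. Per-contact well
#' depths follow `E = epsilon * p_contact`, with `epsilon` a global scale in
#' kB*T and `p_contact` the contact probability/score supplied per pair.
#'
#' @param pairs data frame with columns `type_a`, `type_b`, `p_contact`.
#' @param epsilon global energy scale (kB*T per unit of `p_contact`).
#' @param alpha,r0,r_on,r_cut shared Morse shape parameters.
#' @param unknown_pairs `"zero"` (default: unlisted pairs do not interact) or
#'   `"error"`.
#' @return object of class `interaction_table`.
#' @export
interaction_table <- function(pairs, epsilon = 1, alpha = 5, r0 = 0,
                              r_on = 0, r_cut = 8 / alpha,
                              unknown_pairs = c("zero", "error")) {
  unknown_pairs <- match.arg(unknown_pairs)
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("type_a", "type_b", "p_contact") %in% names(pairs)))
  if (!all(is.finite(pairs$p_contact))) rlang::abort("contact strengths must be finite")
  key <- pair_key(pairs$type_a, pairs$type_b)
  if (anyDuplicated(key)) rlang::abort("duplicate patch type pair in table")
  structure(
    list(pairs = pairs, key = key, epsilon = epsilon, alpha = alpha, r0 = r0,
         r_on = r_on, r_cut = r_cut, unknown_pairs = unknown_pairs),
    class = "interaction_table"
  )
}

#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "\r")
}

#' Well depth for a patch type pair (epsilon * p_contact), NA if unlisted
#' @keywords internal
pair_depth <- function(tbl, type_a, type_b) {
  i <- match(pair_key(type_a, type_b), tbl$key)
  ifelse(is.na(i), NA_real_, tbl$epsilon * tbl$pairs$p_contact[i])
}

#' Rescale the global energy scale of an interaction table
#' @param tbl an [interaction_table()]; @param epsilon new scale.
#' @export
set_epsilon <- function(tbl, epsilon) {
  tbl$epsilon <- epsilon
  tbl
}

#' Write / read an interaction table as tabular text
#'
#' Tab-separated columns `type_a`, `type_b`, `p_contact`, with the shared
#' parameters (`epsilon`, `alpha`, `r0`, `r_on`, `r_cut`) in `#`-prefixed
#' header lines.
#'
#' @param tbl an [interaction_table()]; @param path file path.
#' @export
write_interaction_table <- function(tbl, path) {
  hdr <- sprintf("# %s=%.17g", c("epsilon", "alpha", "r0", "r_on", "r_cut"),
                 c(tbl$epsilon, tbl$alpha, tbl$r0, tbl$r_on, tbl$r_cut))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tbl$pairs[, c("type_a", "type_b", "p_contact")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, regmatches(hdr, regexec("# *([a-z_0-9]+)=([-0-9.eE+]+)", hdr)))
  vals <- stats::setNames(as.numeric(kv[, 3]), kv[, 2])
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  interaction_table(body, epsilon = vals[["epsilon"]], alpha = vals[["alpha"]],
                    r0 = vals[["r0"]], r_on = vals[["r_on"]],
                    r_cut = vals[["r_cut"]])
}

# ---- radial Taylor expansion --------------------------------------------

#' Taylor expansion of the smoothed Morse well about its minimum
#'
#' Expands `U(r)/E_b` about `r = r0` for the `r > r0` branch with
#' `r_on = 0`, returning the coefficients of `1, x, x^2, x^3, x^4`
#' (`x = r - r0`) in units of powers of `alpha`. The degree-4 coefficient is
#' `(7/12 + 3/k^4) alpha^4` with `k = alpha * r_cut`: the bare Morse quartic
#' `7/12` plus the switching-function contribution `3/k^4`. For integer `k`
#' the coefficient is also reported as an exact reduced fraction.
#'
#' @param p a [morse_params()] with `r_on = 0`.
#' @param order 2, 3 or 4.
#' @return numeric vector of coefficients `c0..c_order` (units `alpha^k`),
#'   with attribute `fraction` (integer `c(numerator, denominator)` of the
#'   quartic coefficient in units of `alpha^4`) when `order = 4` and
#'   `alpha * r_cut` is an integer.
#' @export
radial_taylor <- function(p, order) {
  if (p$r_on != 0) rlang::abort("the printed expansion assumes r_on = 0")
  if (!order %in% 2:4) rlang::abort("unsupported order (use 2, 3 or 4)")
  a <- p$alpha
  co <- c(-1, 0, a^2, -a^3, NA)[seq_len(order + 1)]
  if (order == 4) {
    k <- a * p$r_cut
    if (is.finite(k)) {
      co[5] <- (7 / 12 + 3 / k^4) * a^4
      if (abs(k - round(k)) < 1e-12) {
        k <- round(k)
        num <- 7 * k^4 + 36
        den <- 12 * k^4
        g <- gcd_int(num, den)
        attr(co, "fraction") <- c(numerator = num / g, denominator = den / g)
      }
    } else {
      co[5] <- 7 / 12 * a^4
      attr(co, "fraction") <- c(numerator = 7, denominator = 12)
    }
  }
  co
}

#' @keywords internal
gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
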