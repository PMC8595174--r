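#' Gibson-Ashby scaling law
#'
#' Cellular-solid scaling of relative modulus with volume fraction,
#' `E*(rho) = C1 * rho^n + E0`. The constants are specific to a lattice type
#' and to the boundary conditions of the compression test they were fitted
#' from; the law is intended for the fit range `rho in [0.2, 0.9]`.
#'
#' @param C1 Prefactor (> 0).
#' @param n_exp Exponent (> 1, cellular-solid regime).
#' @param E0 Offset (may be negative).
#' @param tpms_type Optional lattice type label.
#' @return Object of class `scaling_law`.
#' @export
scaling_law <- function(C1, n_exp, E0, tpms_type = NA_character_) {
  if (C1 <= 0) stop("C1 must be > 0")
  if (n_exp <= 1) stop("n_exp must be > 1 (cellular-solid regime)")
  structure(list(C1 = C1, n_exp = n_exp, E0 = E0, tpms_type = tpms_type),
            class = "scaling_law")
}

#' @export
print.scaling_law <- function(x, ...) {
  cat(sprintf("scaling_law (%s): E* = %.4g * vf^%.4g %+.4g\n",
              x$tpms_type, x$C1, x$n_exp, x$E0))
  invisible(x)
}

#' Default Gibson-Ashby constants
#'
#' Scaling constants for the four lattice types that survive the pore
#' constraints, obtained from uniaxial-compression finite-element
#' homogenisation over volume fractions 0.2-0.9. These ship as fixed defaults;
#' [sweep_and_fit()] can regenerate comparable constants but never silently
#' replaces them.
#'
#' @return Named list of [scaling_law()] objects.
#' @export
default_scaling_laws <- function() {
  list(
    split_p  = scaling_law(1.33, 2.04, -0.078, "split_p"),
    gyroid   = scaling_law(1.33, 2.68, -0.002, "gyroid"),
    diamond  = scaling_law(1.26, 2.74,  0.039, "diamond"),
    lidinoid = scaling_law(1.38, 2.59, -0.050, "lidinoid"))
}

#' Macroscopic stiffness envelope
#'
#' Material and geometry constants converting relative modulus to axial
#' scaffold stiffness, plus the admissible stiffness window. The defaults
#' describe a cylindrical scaffold bridging a 30 mm critical femoral defect:
#' additively manufactured Nylon (E = 1.8 GPa), diameter and length 30 mm, and
#' an axial stiffness window of 1000-2700 N/mm (stiff enough to avoid
#' refracture, compliant enough to preserve the interfragmentary movement that
#' drives bone formation and to limit stress shielding).
#'
#' @param E Material modulus in Pa (default 1.8e9).
#' @param D Scaffold diameter, mm (default 30).
#' @param L Scaffold length, mm (default 30).
#' @param k_lo,k_hi Stiffness limits, N/mm (defaults 1000 and 2700).
#' @return Object of class `stiffness_envelope`.
#' @export
stiffness_envelope <- function(E = 1.8e9, D = 30, L = 30,
                               k_lo = 1000, k_hi = 2700) {
  vals <- c(E = E, D = D, L = L, k_lo = k_lo, k_hi = k_hi)
  if (any(c(E, D, L) <= 0)) stop("E, D and L must be positive")
  if (k_lo < 0) stop("k_lo must be >= 0")
  if (k_lo >= k_hi) stop("need k_lo < k_hi")
  structure(as.list(vals), class = "stiffness_envelope")
}

.vf_fit_range <- c(0.2, 0.9)

#' Relative modulus from a scaling law
#'
#' Evaluates `E* = C1 * vf^n + E0`, clipped below at zero with a warning
#' (negative offsets can push the law below zero near the bottom of the fit
#' range).
#'
#' @param law A [scaling_law()].
#' @param vf Volume fraction(s) in `[0.2, 0.9]`.
#' @return Relative modulus values.
#' @export
relative_modulus <- function(law, vf) {
  stopifnot(inherits(law, "scaling_law"))
  if (any(vf < .vf_fit_range[1] - 1e-9 | vf > .vf_fit_range[2] + 1e-9))
    stop("vf outside the Gibson-Ashby fit range [0.2, 0.9]")
  e <- law$C1 * vf^law$n_exp + law$E0
  if (any(e < 0)) {
    warning("relative modulus clipped at 0 for some volume fractions")
    e <- pmax(e, 0)
  }
  e
}

#' Axial stiffness of a cylindrical scaffold
#'
#' `k_scaff = E* . E . pi D^2 / (4 L)`, with the material modulus converted
#' from Pa to N/mm^2 so that, with D and L in mm, the result is in N/mm.
#'
#' @param E_star Relative modulus (>= 0).
#' @param env A [stiffness_envelope()].
#' @return Stiffness in N/mm.
#' @export
axial_stiffness <- function(E_star, env = stiffness_envelope()) {
  stopifnot(inherits(env, "stiffness_envelope"))
  if (any(E_star < 0)) stop("E_star must be >= 0")
  E_mm <- env$E * 1e-6  # Pa -> N/mm^2
  E_star * E_mm * pi * env$D^2 / (4 * env$L)
}

#' Volume-fraction window satisfying the stiffness constraint
#'
#' Inverts the scaling law in closed form, `vf = ((E* - E0)/C1)^(1/n)`, at the
#' relative moduli corresponding to `k_lo` and `k_hi`, and intersects the
#' result with the fit range `[0.2, 0.9]`.
#'
#' @param law A [scaling_law()].
#' @param env A [stiffness_envelope()].
#' @return A `vf_window` list (`lo`, `hi`, `empty`, `reason`).
#' @export
stiffness_window <- function(law, env = stiffness_envelope()) {
  stopifnot(inherits(law, "scaling_law"))
  k_unit <- axial_stiffness(1, env)  # N/mm per unit relative modulus
  estar_bounds <- c(env$k_lo, env$k_hi) / k_unit
  invert <- function(es) {
    if (!is.finite(es)) return(.vf_fit_range[2])   # unbounded above
    if (es <= 0) return(.vf_fit_range[1])          # every vf qualifies
    if (es <= law$E0) return(NA_real_)  # the law exceeds this bound everywhere
    ((es - law$E0) / law$C1)^(1 / law$n_exp)
  }
  lo <- invert(estar_bounds[1])
  hi <- invert(estar_bounds[2])
  if (is.na(lo)) {
    warning("required E* at k_lo is below the law offset; lower edge clamped to 0.2")
    lo <- .vf_fit_range[1]
  }
  if (is.na(hi)) hi <- .vf_fit_range[2]
  lo <- max(lo, .vf_fit_range[1])
  hi <- min(hi, .vf_fit_range[2])
  if (lo > hi)
    return(structure(list(lo = NA_real_, hi = NA_real_, empty = TRUE,
                          reason = sprintf("no VF in [0.2, 0.9] gives %g-%g N/mm",
                                           env$k_lo, env$k_hi)),
                     class = "vf_window"))
  structure(list(lo = lo, hi = hi, empty = FALSE, reason = NA_character_),
            class = "vf_window")
}

#' Fit a Gibson-Ashby law to modulus data
#'
#' Nonlinear least squares of `E* = C1 * vf^n + E0` (Levenberg-Marquardt,
#' started at `C1 = 1, n = 2, E0 = 0`, with `n` bounded in (1, 5), the range
#' observed for sheet-TPMS lattices).
#'
#' @param vf_values Volume fractions (>= 4 points spanning the fit range).
#' @param E_star_values Relative moduli.
#' @param tpms_type Optional label for the fitted law.
#' @return A [scaling_law()] with attributes `r_squared` and `residuals`.
#' @export
fit_scaling_law <- function(vf_values, E_star_values, tpms_type = NA_character_) {
  if (length(vf_values) != length(E_star_values))
    stop("vf_values and E_star_values must have equal length")
  if (length(vf_values) < 4)
    stop("fit error: need at least 4 data points, got ", length(vf_values))
  df <- data.frame(vf = vf_values, es = E_star_values)
  fit <- tryCatch(
    minpack.lm::nlsLM(es ~ C1 * vf^n + E0, data = df,
                      start = list(C1 = 1, n = 2, E0 = 0),
                      lower = c(C1 = 1e-8, n = 1 + 1e-6, E0 = -Inf),
                      upper = c(C1 = Inf, n = 5, E0 = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit error: ", conditionMessage(e), "; data: vf = ",
           paste(signif(vf_values, 4), collapse = ", "), "; E* = ",
           paste(signif(E_star_values, 4), collapse = ", ")))
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  ss_tot <- sum((df$es - mean(df$es))^2)
  law <- scaling_law(cf[["C1"]], cf[["n"]], cf[["E0"]], tpms_type)
  attr(law, "r_squared") <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  attr(law, "residuals") <- as.numeric(res)
  law
}
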