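# Deterministic two-deme model and next-generation-matrix R0.
#
# The two-deme ODE system is
#   dS1/dt = (l1*S1 + a21*S2) - (m1*S1 + a12*S1)
#   dS2/dt = (l2*S2 + a12*S1) - (m2*S2 + a21*S2)
# with disease-free equilibrium (0, 0). Linearising the new-infection and
# transition terms there gives F = diag(l1, l2) and
# V = [[a12 + m1, -a21], [-a12, a21 + m2]]; R0 is the dominant eigenvalue of
# F V^-1, for which a closed form with discriminant Delta exists.

#' Per-deme birth-death-migration rates
#'
#' @param birth per-lineage birth (transmission) rate, 1/time; must be > 0.
#' @param death per-lineage death (removal) rate, 1/time.
#' @param migration per-lineage emigration rate to the other deme, 1/time.
#' @return a `deme_params` list with components `birth`, `death`, `migration`.
#' @export
deme_params <- function(birth, death = 0, migration = 0) {
  if (!is.numeric(birth) || birth <= 0) stop("'birth' must be a positive rate")
  if (death < 0 || migration < 0) stop("rates must be nonnegative")
  structure(list(birth = birth, death = death, migration = migration),
            class = "deme_params")
}

#' Right-hand side of the two-deme ODE system
#'
#' @param state numeric length-2 vector `(S1, S2)` of deme sizes.
#' @param deme1,deme2 [deme_params()] for each deme.
#' @return numeric length-2 vector of time derivatives `(dS1/dt, dS2/dt)`.
#' @export
ode_rhs <- function(state, deme1, deme2) {
  stopifnot(length(state) == 2L, is.finite(state))
  s1 <- state[1]; s2 <- state[2]
  c((deme1$birth * s1 + deme2$migration * s2) -
      (deme1$death * s1 + deme1$migration * s1),
    (deme2$birth * s2 + deme1$migration * s1) -
      (deme2$death * s2 + deme2$migration * s2))
}

#' Basic reproduction number of the two-deme model
#'
#' Computes R0 as the dominant eigenvalue of the next-generation matrix
#' F V^-1 evaluated at the disease-free equilibrium, either through the
#' closed form (with its discriminant Delta) or numerically from the
#' matrices themselves.
#'
#' @inheritParams ode_rhs
#' @param method `"closed_form"` (default) or `"eigen"` for the numeric
#'   eigenvalue of F V^-1.
#' @return a list of class `r0_result`: `value`, `delta` (closed-form
#'   discriminant, `NA` for the numeric route) and `method`.
#' @export
r0_general <- function(deme1, deme2, method = c("closed_form", "eigen")) {
  method <- match.arg(method)
  l1 <- deme1$birth; m1 <- deme1$death; a12 <- deme1$migration
  l2 <- deme2$birth; m2 <- deme2$death; a21 <- deme2$migration
  den <- a21 * m1 + (a12 + m1) * m2
  if (den <= 0)
    stop("degenerate model: a21*m1 + (a12 + m1)*m2 must be positive")
  if (method == "eigen") {
    F <- diag(c(l1, l2))
    V <- matrix(c(a12 + m1, -a21, -a12, a21 + m2), 2L, 2L, byrow = TRUE)
    val <- max(Re(eigen(F %*% solve(V), only.values = TRUE)$values))
    return(structure(list(value = val, delta = NA_real_, method = "eigen"),
                     class = "r0_result"))
  }
  delta <- a21^2 * l1^2 + 2 * a12 * a21 * l1 * l2 + a12^2 * l2^2 +
    l2^2 * m1^2 + l1^2 * m2^2 -
    2 * (a21 * l1 * l2 - a12 * l2^2) * m1 +
    2 * (a21 * l1^2 - a12 * l1 * l2 - l1 * l2 * m1) * m2
  if (delta < 0) stop("negative discriminant: parameters outside model domain")
  val <- (a21 * l1 + a12 * l2 + l2 * m1 + l1 * m2 + sqrt(delta)) / (2 * den)
  structure(list(value = val, delta = delta, method = "closed_form"),
            class = "r0_result")
}

#' @export
print.r0_result <- function(x, ...) {
  cat("R0 =", format(x$value, digits = 6), "(", x$method, ")\n")
  invisible(x)
}

#' R0 of a single unstructured population
#'
#' For a birth-death process without migration, R0 = birth / death.
#'
#' @param birth,death per-lineage rates; `death` must be positive.
#' @return numeric R0 value.
#' @export
r0_unstructured <- function(birth, death) {
  if (death <= 0) stop("R0 is undefined for death rate <= 0")
  birth / death
}

#' Deme-level R0 of a structured population
#'
#' The deme-level reproduction number convention used to parameterise the
#' structured simulations: emigration acts as an additional removal channel,
#' entering the denominator with weight two, so `R0 = birth / (2*migration +
#' death)`. The result does not depend on the scaling factor `k` relating
#' the two demes' rates. With `migration = 0` it reduces to the unstructured
#' `birth / death`.
#'
#' @param birth,death,migration per-deme rates.
#' @param k positive scale factor relating the other deme's rates; accepted
#'   for interface completeness, the value does not enter the formula.
#' @return numeric deme-level R0.
#' @export
r0_structured_deme <- function(birth, death, migration, k = 1) {
  if (k <= 0) stop("'k' must be positive")
  den <- 2 * migration + death
  if (den <= 0) stop("2*migration + death must be positive")
  birth / den
}

#' Birth rate achieving a target R0
#'
#' Inverse of the R0 conventions used for simulation: with migration,
#' `birth = R0 * (2*migration + death)`; without, `birth = R0 * death`.
#'
#' @param r0 target basic reproduction number (> 0).
#' @param death per-lineage death rate.
#' @param migration per-lineage emigration rate (0 for an unstructured
#'   population).
#' @return the birth rate.
#' @export
birth_rate_for_r0 <- function(r0, death, migration = 0) {
  if (r0 <= 0) stop("'r0' must be positive")
  if (death < 0 || migration < 0) stop("rates must be nonnegative")
  r0 * (2 * migration + death)
}
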