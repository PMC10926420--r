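#' Specify a true quadratic nutrient-response surface
#'
#' The generating model for synthetic data: a trait's expected value at a
#' daily intake of `P` mg protein and `C` mg carbohydrate is
#' `intercept + beta_P*P + beta_C*C + gamma_PP*P^2 + gamma_CC*C^2 + gamma_PC*P*C`.
#' Negative quadratic coefficients give a peak, positive ones a trough;
#' `gamma_PC` is the correlational (nutrient interaction) effect.
#'
#' @param intercept Trait value at zero intake.
#' @param beta_P,beta_C Linear nutritional gradients, trait units per mg/day.
#' @param gamma_PP,gamma_CC Quadratic coefficients.
#' @param gamma_PC Correlational coefficient.
#' @param noise_sd Residual standard deviation of the trait around the
#'   surface, trait units; must be >= 0. Zero gives the deterministic limit.
#' @return An object of class `"true_surface"`.
#' @examples
#' s <- true_surface(25, 0.15, 2.16, 0, -0.045, -0.01, noise_sd = 6)
#' surface_value(s, P = 1, C = 24)
#' surface_optimum(s)
#' @export
true_surface <- function(intercept = 0, beta_P = 0, beta_C = 0,
                         gamma_PP = 0, gamma_CC = 0, gamma_PC = 0,
                         noise_sd = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(intercept = intercept, beta_P = beta_P, beta_C = beta_C,
                 gamma_PP = gamma_PP, gamma_CC = gamma_CC,
                 gamma_PC = gamma_PC, noise_sd = noise_sd),
            class = "true_surface")
}

#' Evaluate a true surface at daily intakes
#' @param s A [true_surface()].
#' @param P,C Daily protein and carbohydrate intakes, mg/day (vectorised).
#' @return Expected trait values.
#' @export
surface_value <- function(s, P, C) {
  stopifnot(inherits(s, "true_surface"))
  s$intercept + s$beta_P * P + s$beta_C * C +
    s$gamma_PP * P^2 + s$gamma_CC * C^2 + s$gamma_PC * P * C
}

#' Closed-form stationary point of a true surface
#'
#' Solves the gradient system; the stationary point is a maximum only when the
#' quadratic form is negative definite (`gamma_PP < 0`, `gamma_CC < 0`,
#' `4*gamma_PP*gamma_CC > gamma_PC^2`).
#'
#' @param s A [true_surface()].
#' @return Named vector `c(P, C, value)`, or `NULL` when the quadratic part is
#'   singular (no finite stationary point).
#' @export
surface_optimum <- function(s) {
  stopifnot(inherits(s, "true_surface"))
  H <- matrix(c(2 * s$gamma_PP, s$gamma_PC, s$gamma_PC, 2 * s$gamma_CC), 2, 2)
  if (abs(det(H)) < 1e-12) return(NULL)
  xy <- solve(H, -c(s$beta_P, s$beta_C))
  c(P = xy[1], C = xy[2], value = surface_value(s, xy[1], xy[2]))
}

#' Default generating surfaces for the no-choice experiment
#'
#' One surface per (line, sex) for lifespan (days) and one per line for
#' female daily egg production (eggs/day). The shapes emulate the qualitative
#' structure reported for marula-fly selection lines: lifespan in every group
#' is carbohydrate-dominated and peaks at low P:C with a carbohydrate intake
#' in the low-to-mid 20s mg/day; control-line daily egg production peaks at a
#' markedly more protein-biased intake (about 1.6 mg/day protein, 17 mg/day
#' carbohydrate); upward-selected daily egg production rises with protein
#' only, with no interior peak.
#'
#' @return Nested list: `surfaces$LS[[line]][[sex]]` and
#'   `surfaces$DEP[[line]]`, each a [true_surface()].
#' @export
default_surfaces <- function() {
  list(
    LS = list(
      CT = list(
        F = true_surface(25, 0.15, 2.16, 0.000, -0.045, -0.010, noise_sd = 6),
        M = true_surface(25, 0.05, 2.16, -0.002, -0.040, -0.008, noise_sd = 6)),
      US = list(
        F = true_surface(22, 0.08, 1.68, 0.000, -0.035, -0.006, noise_sd = 6),
        M = true_surface(22, 0.00, 2.17, 0.000, -0.035, -0.007, noise_sd = 6))),
    DEP = list(
      CT = true_surface(1.5, 1.60, 0.50, -0.50, -0.015, 0, noise_sd = 1),
      US = true_surface(1.5, 0.80, 0.00, 0.00, 0.000, 0, noise_sd = 1))
  )
}
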