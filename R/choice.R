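#' Expected nutrient intake under random feeding from a diet pair
#'
#' The random-feeding null assigns half the fly's total consumed volume to
#' each tube of the pair ("equal amounts of each food", measured as equal
#' volumes of the two liquids) and converts via each diet's nutrient
#' densities. Regulation is detected as departure of observed intake from
#' this expectation.
#'
#' @param total_volume_uL Total volume the fly consumed across both tubes.
#' @param pair List of two [diet()] objects.
#' @return Named vector `c(protein_mg, carb_mg)`; zero consumption returns
#'   `c(0, 0)`.
#' @examples
#' expected_random_intake(100, list(diet(1, 1, 180), diet(0, 1, 180)))
#' # 4.5 mg P, 13.5 mg C: a 1:3 blend
#' @export
expected_random_intake <- function(total_volume_uL, pair) {
  stopifnot(length(pair) == 2, inherits(pair[[1]], "diet"),
            inherits(pair[[2]], "diet"))
  v <- total_volume_uL / 2
  c(protein_mg = v * (pair[[1]]$protein_mg_per_uL + pair[[2]]$protein_mg_per_uL),
    carb_mg = v * (pair[[1]]$carb_mg_per_uL + pair[[2]]$carb_mg_per_uL))
}

#' Test whether flies feed at random from a diet pair
#'
#' For each fly, the observed cumulative intake of a nutrient is compared
#' with its random-feeding expectation; the differences are tested against
#' zero with a two-sided one-sample t-test, per nutrient. A non-significant
#' result is consistent with random feeding; significant departures are
#' classified as a protein or carbohydrate preference by the sign of the
#' mean difference.
#'
#' @param observed_P,observed_C Observed cumulative intakes, mg, one per fly.
#' @param expected_P,expected_C Random-feeding expectations, mg.
#' @return Data frame with one row per nutrient: mean difference, `t`, `df`,
#'   `p`, and a `preference` label (`"protein"`, `"carbohydrate"` or
#'   `"random"` at p >= 0.05).
#' @export
random_feeding_test <- function(observed_P, expected_P,
                                observed_C, expected_C) {
  one <- function(obs, exp, nutrient) {
    d <- obs - exp
    d <- d[!is.na(d)]
    if (length(d) < 3)
      stop("random-feeding test needs at least 3 flies", call. = FALSE)
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(nutrient = nutrient, mean_diff = 0, t = 0,
                          df = length(d) - 1, p = 1, preference = "random"))
      stop("zero variance in nonzero differences; t-test undefined",
           call. = FALSE)
    }
    tt <- stats::t.test(d, mu = 0)
    pref <- if (tt$p.value >= 0.05) "random"
    else if (mean(d) > 0) {
      if (nutrient == "protein") "protein" else "carbohydrate"
    } else {
      if (nutrient == "protein") "carbohydrate" else "protein"
    }
    data.frame(nutrient = nutrient, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, preference = pref)
  }
  rbind(one(observed_P, expected_P, "protein"),
        one(observed_C, expected_C, "carbohydrate"))
}

#' Attach random-feeding expectations to choice records
#'
#' @param exp2 A `"nutri_exp2"` object from [generate_experiment2()], or a
#'   list with `flies` and `tubes` in the same format plus the design pairs.
#' @return The fly table with `expected_P_mg` and `expected_C_mg` columns.
#' @export
choice_expectations <- function(exp2) {
  flies <- exp2$flies
  vol <- tapply(exp2$tubes$volume_uL, exp2$tubes$fly_id, sum)
  pairs <- exp2$design$pairs
  ep <- ec <- numeric(nrow(flies))
  for (i in seq_len(nrow(flies))) {
    pr <- pairs[[flies$pair[i]]]
    e <- expected_random_intake(unname(vol[as.character(flies$fly_id[i])]), pr)
    ep[i] <- e["protein_mg"]; ec[i] <- e["carb_mg"]
  }
  flies$expected_P_mg <- ep
  flies$expected_C_mg <- ec
  flies
}

#' Regulated intake point of a group of flies
#'
#' The mean cumulative protein and carbohydrate intake across flies pooled
#' over all diet pairs, with its C:P ratio reported as "1:x".
#'
#' @param protein_mg,carb_mg Cumulative intakes, mg, one per fly.
#' @return Object of class `"regulated_intake"`: `mean_P`, `mean_C`, `n`,
#'   `C_to_P_ratio` (`Inf` with a flag on a pure-carbohydrate rail).
#' @examples
#' regulated_intake_point(c(10, 20), c(30, 62))
#' @export
regulated_intake_point <- function(protein_mg, carb_mg) {
  ok <- !is.na(protein_mg) & !is.na(carb_mg)
  protein_mg <- protein_mg[ok]; carb_mg <- carb_mg[ok]
  if (!length(protein_mg)) stop("no flies supplied", call. = FALSE)
  mp <- mean(protein_mg); mc <- mean(carb_mg)
  structure(list(mean_P = mp, mean_C = mc, n = length(protein_mg),
                 C_to_P_ratio = if (mp == 0) Inf else mc / mp,
                 pure_carbohydrate = mp == 0),
            class = "regulated_intake")
}

#' @export
print.regulated_intake <- function(x, ...) {
  cat(sprintf("Regulated intake point (n = %d): P = %.2f mg, C = %.2f mg",
              x$n, x$mean_P, x$mean_C))
  if (is.finite(x$C_to_P_ratio))
    cat(sprintf("  [1:%.1f P:C]\n", x$C_to_P_ratio))
  else cat("  [pure carbohydrate rail]\n")
  invisible(x)
}

#' Compare nutrient regulation between two groups
#'
#' Fits cumulative carbohydrate intake against protein intake, a grouping
#' factor (selection line or sex) and their interaction, with replicate as
#' a random intercept (maximum likelihood). A significant
#' protein-by-group interaction indicates that the regulated intake point
#' differs between the groups. Each term is tested with a likelihood-ratio
#' chi-square (df 1).
#'
#' @param flies Choice-experiment fly table (`protein_mg`, `carb_mg`,
#'   `replicate`, and the grouping column).
#' @param group Name of the grouping column (`"line"` or `"sex"`).
#' @return Object of class `"regulation_fit"`: coefficients and a
#'   three-row test table (covariate, factor, interaction).
#' @export
compare_regulation <- function(flies, group = "line") {
  if (!group %in% names(flies))
    stop("grouping column not found: ", group, call. = FALSE)
  g <- factor(flies[[group]])
  if (nlevels(g) != 2)
    stop("regulation comparison needs exactly two groups", call. = FALSE)
  d <- data.frame(C = flies$carb_mg, P = flies$protein_mg, G = g,
                  .g = factor(flies$replicate))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fml <- function(rhs) stats::as.formula(paste("C ~", rhs, "+ (1 | .g)"))
  m_full <- suppressMessages(lme4::lmer(fml("P * G"), d, REML = FALSE,
                                        control = ctrl))
  m_noint <- suppressMessages(lme4::lmer(fml("P + G"), d, REML = FALSE,
                                         control = ctrl))
  m_nog <- suppressMessages(lme4::lmer(fml("P"), d, REML = FALSE,
                                       control = ctrl))
  m_nop <- suppressMessages(lme4::lmer(fml("G"), d, REML = FALSE,
                                       control = ctrl))
  ll <- function(m) as.numeric(stats::logLik(m))
  lr <- function(m1, m0) {
    chi2 <- max(0, 2 * (ll(m1) - ll(m0)))
    c(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
  }
  rows <- rbind(protein = lr(m_noint, m_nop),
                group = lr(m_noint, m_nog),
                interaction = lr(m_full, m_noint))
  tests <- data.frame(term = c("protein", group,
                               paste(group, "x protein")),
                      chi2 = rows[, "chi2"], df = 1, p = rows[, "p"])
  structure(list(coefficients = lme4::fixef(m_full), tests = tests,
                 group = group, n = nrow(d),
                 interaction_p = rows["interaction", "p"]),
            class = "regulation_fit")
}

#' @export
print.regulation_fit <- function(x, ...) {
  cat(sprintf("Regulation comparison by %s (n = %d)\n", x$group, x$n))
  tab <- x$tests
  tab$chi2 <- round(tab$chi2, 2); tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(if (x$interaction_p < 0.05)
    "Regulated intake point differs between groups.\n"
    else "No evidence the regulated intake point differs.\n")
  invisible(x)
}
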