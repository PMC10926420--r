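#' Fit a nutrient response surface to a life-history trait
#'
#' Estimates the linear, quadratic and correlational effects of daily
#' protein and carbohydrate intake on a trait, in the response-surface
#' (selection-gradient) tradition: a linear-only model gives the nutritional
#' gradients, the full second-order model adds the P x P and C x C quadratic
#' terms and the P x C correlational term. Trait and intakes are
#' z-standardized (mean 0, sd 1, denominator n - 1) within the supplied
#' dataset before fitting, and replicate enters as a random intercept. All
#' models are fitted by maximum likelihood so nested models can be compared
#' with likelihood-ratio chi-square tests (see [term_tests()]).
#'
#' When the replicate variance estimate hits the zero boundary (a singular
#' fit) the model falls back to ordinary least squares with replicate as a
#' fixed factor, which keeps likelihood-ratio tests between nested fits well
#' defined.
#'
#' @param records Data frame with the trait column, `P_day_mg`, `C_day_mg`
#'   and (unless `random = NULL`) `replicate`.
#' @param trait Name of the trait column (e.g. `"LS"`, `"LEP"`, `"DEP"`).
#' @param type `"full"` (5 nutrient terms) or `"linear"` (2 terms).
#' @param standardize Z-standardize trait and intakes first (default TRUE,
#'   as in the analysis the class implements); set FALSE to fit on raw
#'   mg/day and trait units, e.g. for parameter-recovery checks against a
#'   generating [true_surface()].
#' @param random Name of the random-intercept grouping column, or `NULL`
#'   for a fixed-effects-only fit.
#' @return An object of class `"surface_fit"` with components
#'   `coefficients` (named vector: the nutrient terms), `se`, `vcov`,
#'   `logLik`, `n`, `type`, `engine` (`"lmer"` or `"ols"`),
#'   `ranef_variance`, and the scaling used. Methods: `print`, `summary`,
#'   `coef`, `predict`, `logLik`.
#' @examples
#' x <- generate_experiment1(design_exp1(seed = 2))
#' rec <- prepare_analysis(x$flies)$records
#' f <- surface_fit(subset(rec, line == "CT" & sex == "F"), "LS")
#' coef(f)
#' @export
surface_fit <- function(records, trait, type = c("full", "linear"),
                        standardize = TRUE, random = "replicate") {
  type <- match.arg(type)
  terms <- if (type == "full") c("P", "C", "PxP", "CxC", "PxC") else c("P", "C")
  .fit_surface(records, trait, terms, standardize, random, type)
}

# term labels -> model-matrix column expressions on (zP, zC)
.term_cols <- function(zP, zC, terms) {
  all_cols <- cbind(P = zP, C = zC, PxP = zP^2, CxC = zC^2, PxC = zP * zC)
  all_cols[, terms, drop = FALSE]
}

.fit_surface <- function(records, trait, terms, standardize, random, type) {
  if (!trait %in% names(records))
    stop("trait column not found: ", trait, call. = FALSE)
  d <- records[stats::complete.cases(records[, c(trait, "P_day_mg",
                                                 "C_day_mg")]), , drop = FALSE]
  n <- nrow(d)
  if (n < 10) stop("need at least 10 records to fit a surface", call. = FALSE)
  scaling <- list(standardize = standardize)
  if (standardize) {
    scaling$P <- c(mean = mean(d$P_day_mg), sd = stats::sd(d$P_day_mg))
    scaling$C <- c(mean = mean(d$C_day_mg), sd = stats::sd(d$C_day_mg))
    scaling$trait <- c(mean = mean(d[[trait]]), sd = stats::sd(d[[trait]]))
    if (any(c(scaling$P["sd"], scaling$C["sd"], scaling$trait["sd"]) == 0))
      stop("constant trait or intake column; cannot standardize", call. = FALSE)
    zP <- (d$P_day_mg - scaling$P["mean"]) / scaling$P["sd"]
    zC <- (d$C_day_mg - scaling$C["mean"]) / scaling$C["sd"]
    y <- (d[[trait]] - scaling$trait["mean"]) / scaling$trait["sd"]
  } else {
    zP <- d$P_day_mg; zC <- d$C_day_mg; y <- d[[trait]]
  }
  X <- .term_cols(zP, zC, terms)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1)
    stop("rank-deficient nutrient design (e.g. all flies on one rail); ",
         "cannot identify ", length(terms), " surface terms", call. = FALSE)
  mf <- data.frame(y = y, X, check.names = FALSE)
  use_lmer <- !is.null(random)
  if (use_lmer) {
    if (!random %in% names(records))
      stop("random-effect column not found: ", random, call. = FALSE)
    if (length(unique(d[[random]])) < 2)
      stop("need >= 2 levels of '", random, "' for a random intercept",
           call. = FALSE)
    mf$.g <- factor(d[[random]])
  }
  fit <- .fit_engine(mf, terms, use_lmer)
  structure(c(fit, list(trait = trait, type = type, terms = terms, n = n,
                        scaling = scaling, random = random,
                        model_frame = mf)),
            class = "surface_fit")
}

# Fit y ~ terms (+ random intercept .g) by ML; returns coefficients for the
# nutrient terms, their SEs, logLik and the engine used.
.fit_engine <- function(mf, terms, use_lmer) {
  rhs <- paste(c(terms, if (use_lmer) "(1 | .g)"),
               collapse = " + ")
  if (use_lmer) {
    m <- suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", rhs)), data = mf, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    if (lme4::isSingular(m, tol = 1e-5)) {
      # replicate variance at the zero boundary: OLS + replicate dummies
      m2 <- stats::lm(stats::as.formula(
        paste("y ~", paste(terms, collapse = " + "), "+ .g")),
        data = mf)
      b <- stats::coef(m2)[terms]
      names(b) <- terms
      V <- suppressWarnings(stats::vcov(m2))[terms, terms,
                           drop = FALSE]
      dimnames(V) <- list(terms, terms)
      return(list(coefficients = b, se = sqrt(diag(V)), vcov = V,
                  logLik = as.numeric(stats::logLik(m2)),
                  df = length(stats::coef(m2)) + 1,
                  engine = "ols", ranef_variance = 0))
    }
    b <- lme4::fixef(m)[terms]
    names(b) <- terms
    V <- as.matrix(stats::vcov(m))[terms,
                                   terms, drop = FALSE]
    dimnames(V) <- list(terms, terms)
    vc <- as.data.frame(lme4::VarCorr(m))
    list(coefficients = b, se = sqrt(diag(V)), vcov = V,
         logLik = as.numeric(stats::logLik(m)),
         df = attr(stats::logLik(m), "df"),
         engine = "lmer",
         ranef_variance = vc$vcov[vc$grp == ".g"][1])
  } else {
    m <- stats::lm(stats::as.formula(
      paste("y ~", paste(terms, collapse = " + "))), data = mf)
    b <- stats::coef(m)[terms]
    names(b) <- terms
    V <- suppressWarnings(stats::vcov(m))[terms, terms,
                        drop = FALSE]
    dimnames(V) <- list(terms, terms)
    list(coefficients = b, se = sqrt(diag(V)), vcov = V,
         logLik = as.numeric(stats::logLik(m)),
         df = length(stats::coef(m)) + 1,
         engine = "ols", ranef_variance = NA_real_)
  }
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("Nutrient response surface for %s (%s model, n = %d, %s)\n",
              x$trait, x$type, x$n,
              if (x$engine == "lmer") "replicate random intercept"
              else "fixed effects"))
  print(round(rbind(coefficient = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.surface_fit <- function(object, ...) object$coefficients

#' @export
logLik.surface_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
summary.surface_fit <- function(object, ...) {
  tt <- term_tests(object)
  tab <- data.frame(coefficient = object$coefficients, se = object$se,
                    chi2 = tt$chi2, p = tt$p)
  structure(list(fit = object, table = tab), class = "summary.surface_fit")
}

#' @export
print.summary.surface_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLikelihood-ratio term tests (df = 1):\n")
  print(round(x$table[, c("chi2", "p")], 4))
  invisible(x)
}

#' Predict trait values from a fitted surface
#' @param object A [surface_fit()].
#' @param newdata Data frame with `P_day_mg` and `C_day_mg` (mg/day).
#' @param ... Unused.
#' @return Predicted trait values on the original trait scale (population
#'   level, random effects at zero).
#' @export
predict.surface_fit <- function(object, newdata, ...) {
  s <- object$scaling
  if (s$standardize) {
    zP <- (newdata$P_day_mg - s$P["mean"]) / s$P["sd"]
    zC <- (newdata$C_day_mg - s$C["mean"]) / s$C["sd"]
  } else {
    zP <- newdata$P_day_mg; zC <- newdata$C_day_mg
  }
  X <- .term_cols(zP, zC, object$terms)
  # population-level intercept: mean residual offset of the stored fit
  Xf <- as.matrix(object$model_frame[, object$terms, drop = FALSE])
  b0 <- mean(object$model_frame$y - drop(Xf %*% object$coefficients))
  yz <- b0 + drop(X %*% object$coefficients)
  if (s$standardize) yz * s$trait["sd"] + s$trait["mean"] else yz
}

#' Likelihood-ratio tests for each nutrient term of a surface fit
#'
#' Refits the model without each term in turn (same engine, maximum
#' likelihood) and reports the chi-square statistic
#' `2 * (logLik_full - logLik_reduced)` on 1 degree of freedom.
#'
#' @param fit A [surface_fit()].
#' @return Data frame with rows per term: `chi2`, `df`, `p`.
#' @export
term_tests <- function(fit) {
  stopifnot(inherits(fit, "surface_fit"))
  use_lmer <- fit$engine == "lmer"
  chi2 <- p <- numeric(length(fit$terms))
  for (i in seq_along(fit$terms)) {
    red <- .fit_engine(fit$model_frame, fit$terms[-i], use_lmer)
    chi2[i] <- max(0, 2 * (fit$logLik - red$logLik))
    p[i] <- stats::pchisq(chi2[i], df = 1, lower.tail = FALSE)
  }
  data.frame(term = fit$terms, chi2 = chi2, df = 1, p = p,
             row.names = fit$terms)
}
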