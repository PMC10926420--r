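#' Partial F-test from residual sums of squares of nested models
#'
#' @param SSr Residual sum of squares of the reduced model.
#' @param SSc Residual sum of squares of the complete (larger) model;
#'   must satisfy `SSr >= SSc > 0`.
#' @param DF1 Number of parameters added by the complete model.
#' @param DF2 Residual degrees of freedom of the complete model.
#' @return Named vector `c(F, p)`; `p` is the upper tail of F(DF1, DF2).
#' @examples
#' partial_f(195.573, 194.732, 2, 592)  # F = 1.28
#' @export
partial_f <- function(SSr, SSc, DF1, DF2) {
  if (any(DF1 < 1) || any(DF2 < 1) || DF1 != round(DF1) || DF2 != round(DF2))
    stop("DF1 and DF2 must be positive integers", call. = FALSE)
  if (SSc <= 0) stop("complete-model residual SS must be > 0", call. = FALSE)
  if (SSc > SSr)
    stop("complete model has larger residual SS than reduced model; ",
         "models are misordered", call. = FALSE)
  F <- unname(((SSr - SSc) / DF1) / (SSc / DF2))
  c(F = F, p = unname(stats::pf(F, DF1, DF2, lower.tail = FALSE)))
}

# Pooled, standardized two-group dataset for landscape comparison.
# Intakes are always standardized on the pooled set (both groups share the
# same intake space); the trait is standardized pooled (default) or within
# group, the latter for comparisons of different traits measured in
# different units.
.pool_groups <- function(records_a, records_b, trait_a, trait_b, labels,
                         standardize) {
  pick <- function(r, tr) data.frame(
    y = r[[tr]], P = r$P_day_mg, C = r$C_day_mg,
    repl = as.character(r$replicate), stringsAsFactors = FALSE)
  a <- pick(records_a, trait_a); b <- pick(records_b, trait_b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both comparison groups must be nonempty", call. = FALSE)
  d <- rbind(a, b)
  d$G <- factor(rep(labels, c(nrow(a), nrow(b))), levels = labels)
  d <- d[stats::complete.cases(d[, c("y", "P", "C")]), , drop = FALSE]
  d$P <- z_transform(d$P)
  d$C <- z_transform(d$C)
  d$y <- if (standardize == "pooled") z_transform(d$y)
  else z_transform(d$y, d$G)
  d
}

#' Compare two nutritional landscapes by sequential model building
#'
#' Tests whether the linear, quadratic and correlational nutrient effects on
#' a trait differ between two groups (selection lines, sexes, or two traits
#' of the same flies via a dummy "trait type" factor). Six nested
#' fixed-effects models are built on the pooled standardized data: (1)
#' linear effects; (2) plus their interaction with the group dummy; (3)
#' model 2 plus the quadratic effects P x P and C x C; (4) plus their group
#' interactions; (5) model 4 plus the correlational effect P x C; (6) plus
#' its group interaction. Each block is tested with a partial F-test on the
#' residual sums of squares of the model pair (1 vs 2, 3 vs 4, 5 vs 6).
#' Residual SS come from fixed-effects fits (replicate as a fixed covariate
#' by default), since residual SS is not well defined under a mixed model.
#' When a linear or quadratic block is significant, univariate follow-ups
#' identify the contributing nutrient.
#'
#' @param records_a,records_b Analysis records of the two groups (may be the
#'   same data frame when comparing two traits).
#' @param trait_a Trait column for group A.
#' @param trait_b Trait column for group B; defaults to `trait_a`.
#' @param labels Length-2 group labels for the dummy factor.
#' @param standardize `"pooled"` (trait z-scored on the pooled set) or
#'   `"by_group"` (z-scored within each group; required when the two traits
#'   are measured in different units).
#' @param replicate_fixed Include replicate as a fixed covariate in all six
#'   models (default TRUE).
#' @param group_main Include the group main effect from model 1 onward
#'   (default TRUE).
#' @param alpha Significance threshold that triggers univariate follow-ups.
#' @return Object of class `"landscape_comparison"`: `table` (one row per
#'   block with `SSr`, `SSc`, `DF1`, `DF2`, `F`, `p`), `followups` (named
#'   list of per-nutrient chi-square follow-ups for significant blocks),
#'   `n`, labels and settings.
#' @examples
#' x <- generate_experiment1(design_exp1(seed = 5))
#' rec <- prepare_analysis(x$flies)$records
#' f <- subset(rec, sex == "F")
#' cmp <- sequential_compare(subset(f, line == "CT"), subset(f, line == "US"),
#'                           trait_a = "LS", labels = c("CT", "US"))
#' cmp$table
#' @export
sequential_compare <- function(records_a, records_b, trait_a,
                               trait_b = trait_a,
                               labels = c("A", "B"),
                               standardize = c("pooled", "by_group"),
                               replicate_fixed = TRUE,
                               group_main = TRUE,
                               alpha = 0.05) {
  standardize <- match.arg(standardize)
  d <- .pool_groups(records_a, records_b, trait_a, trait_b, labels,
                    standardize)
  d$PxP <- d$P^2; d$CxC <- d$C^2; d$PxC <- d$P * d$C
  base <- c(if (group_main) "G", if (replicate_fixed) "repl")
  f <- function(terms) stats::lm(stats::reformulate(c(base, terms), "y"),
                                 data = d)
  models <- list(
    m1 = f(c("P", "C")),
    m2 = f(c("P", "C", "P:G", "C:G")),
    m3 = f(c("P", "C", "P:G", "C:G", "PxP", "CxC")),
    m4 = f(c("P", "C", "P:G", "C:G", "PxP", "CxC", "PxP:G", "CxC:G")),
    m5 = f(c("P", "C", "P:G", "C:G", "PxP", "CxC", "PxP:G", "CxC:G", "PxC")),
    m6 = f(c("P", "C", "P:G", "C:G", "PxP", "CxC", "PxP:G", "CxC:G",
             "PxC", "PxC:G")))
  rss <- vapply(models, stats::deviance, numeric(1))
  pars <- vapply(models, function(m) m$rank, numeric(1))
  n <- nrow(d)
  blocks <- list(linear = c(1, 2), quadratic = c(3, 4), correlational = c(5, 6))
  tab <- do.call(rbind, lapply(names(blocks), function(bk) {
    ij <- blocks[[bk]]
    df1 <- pars[ij[2]] - pars[ij[1]]
    df2 <- n - pars[ij[2]]
    fp <- partial_f(rss[ij[1]], rss[ij[2]], df1, df2)
    data.frame(block = bk, SSr = rss[ij[1]], SSc = rss[ij[2]],
               DF1 = df1, DF2 = df2, F = fp["F"], p = fp["p"],
               row.names = bk)
  }))
  followups <- list()
  for (bk in c("linear", "quadratic"))
    if (tab[bk, "p"] < alpha)
      followups[[bk]] <- univariate_followup(d, block = bk, quiet = TRUE)
  structure(list(table = tab, followups = followups, n = n,
                 labels = labels, standardize = standardize,
                 replicate_fixed = replicate_fixed, alpha = alpha,
                 pooled = d),
            class = "landscape_comparison")
}

#' @export
print.landscape_comparison <- function(x, ...) {
  cat(sprintf("Nutritional landscape comparison: %s vs %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  tab <- x$table
  tab$F <- round(tab$F, 2); tab$p <- signif(tab$p, 3)
  tab$SSr <- round(tab$SSr, 3); tab$SSc <- round(tab$SSc, 3)
  print(tab[, c("SSr", "SSc", "DF1", "DF2", "F", "p")])
  for (bk in names(x$followups)) {
    cat(sprintf("\nUnivariate follow-up (%s block):\n", bk))
    print(round(x$followups[[bk]][, c("chi2", "p")], 4))
  }
  invisible(x)
}

#' Univariate follow-up: which nutrient drives a significant block
#'
#' For each nutrient, tests that nutrient's group-interaction term of the
#' given block by a likelihood-ratio chi-square (df 1) on the pooled data,
#' keeping the other nutrient's interaction in the model.
#'
#' @param pooled Pooled data frame as built by [sequential_compare()]
#'   (columns `y`, `P`, `C`, `PxP`, `CxC`, `PxC`, `G`, `repl`), or a
#'   `landscape_comparison` object.
#' @param block `"linear"` or `"quadratic"`.
#' @param replicate_fixed,group_main As in [sequential_compare()].
#' @param quiet Suppress the warning issued when the block was not
#'   significant in the comparison object.
#' @return Data frame with one row per nutrient: `chi2`, `df`, `p`.
#' @export
univariate_followup <- function(pooled, block = c("linear", "quadratic"),
                                replicate_fixed = TRUE, group_main = TRUE,
                                quiet = FALSE) {
  block <- match.arg(block)
  if (inherits(pooled, "landscape_comparison")) {
    if (!quiet && pooled$table[block, "p"] >= pooled$alpha)
      warning("follow-up requested for a non-significant block; ",
              "computing anyway", call. = FALSE)
    replicate_fixed <- pooled$replicate_fixed
    pooled <- pooled$pooled
  }
  if (length(unique(pooled$G)) < 2)
    stop("follow-up needs two groups", call. = FALSE)
  base <- c(if (group_main) "G", if (replicate_fixed) "repl")
  pair <- if (block == "linear") c(P = "P", C = "C")
  else c(P = "PxP", C = "CxC")
  shared <- if (block == "linear") c("P", "C")
  else c("P", "C", "P:G", "C:G", "PxP", "CxC")
  out <- lapply(names(pair), function(nu) {
    t_int <- paste0(pair[[nu]], ":G")
    other <- setdiff(paste0(pair, ":G"), t_int)
    full <- stats::lm(stats::reformulate(c(base, shared, other, t_int), "y"),
                      data = pooled)
    red <- stats::lm(stats::reformulate(c(base, shared, other), "y"),
                     data = pooled)
    chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                          as.numeric(stats::logLik(red))))
    data.frame(nutrient = nu, chi2 = chi2, df = 1,
               p = stats::pchisq(chi2, 1, lower.tail = FALSE),
               row.names = nu)
  })
  do.call(rbind, out)
}
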