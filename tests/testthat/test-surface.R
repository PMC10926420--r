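test_that("a noiseless paraboloid is recovered to machine precision", {
  rec <- paraboloid_records(n = 150, gPP = -0.5, gCC = -0.05)
  f <- surface_fit(rec, "LS", standardize = FALSE, random = NULL)
  b <- coef(f)
  # y = 50 - .5 (P-2)^2 - .05 (C-20)^2 expands to these polynomial terms
  expect_equal(unname(b["P"]), 2, tolerance = 1e-8)
  expect_equal(unname(b["C"]), 2, tolerance = 1e-8)
  expect_equal(unname(b["PxP"]), -0.5, tolerance = 1e-8)
  expect_equal(unname(b["CxC"]), -0.05, tolerance = 1e-8)
  expect_equal(unname(b["PxC"]), 0, tolerance = 1e-8)
})

test_that("a trait equal to zC gives beta_C = 1, beta_P = 0", {
  rec <- paraboloid_records(n = 80)
  rec$LS <- z_transform(rec$C_day_mg)
  f <- surface_fit(rec, "LS", type = "linear", random = NULL)
  expect_equal(unname(coef(f)["C"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(f)["P"]), 0, tolerance = 1e-8)
})

test_that("predictions return to the trait scale", {
  rec <- paraboloid_records(n = 150, p_peak = 2, c_peak = 20,
                            gPP = -0.5, gCC = -0.05)
  f <- surface_fit(rec, "LS", random = NULL)  # standardized fit
  pr <- predict(f, data.frame(P_day_mg = c(2, 0), C_day_mg = c(20, 0)))
  expect_equal(pr[1], 50, tolerance = 1e-6)     # peak value, trait units
  expect_equal(pr[2], 50 - 0.5 * 4 - 0.05 * 400, tolerance = 1e-6)
})

test_that("row order does not change the fit", {
  rec <- paraboloid_records(n = 90, noise_sd = 2, seed = 6)
  f1 <- surface_fit(rec, "LS")
  f2 <- surface_fit(rec[sample(nrow(rec)), ], "LS")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("without a random effect the fit equals ordinary least squares", {
  rec <- paraboloid_records(n = 100, noise_sd = 3, seed = 2)
  f <- surface_fit(rec, "LS", standardize = FALSE, random = NULL)
  zz <- data.frame(P = rec$P_day_mg, C = rec$C_day_mg, y = rec$LS)
  ols <- lm(y ~ P + C + I(P^2) + I(C^2) + I(P * C), zz)
  expect_equal(unname(coef(f)),
               unname(coef(ols)[-1]), tolerance = 1e-8)
})

test_that("the full model never has smaller log-likelihood than the linear", {
  for (seed in 1:5) {
    rec <- paraboloid_records(n = 100, noise_sd = 4, seed = seed)
    fl <- surface_fit(rec, "LS", type = "linear")
    ff <- surface_fit(rec, "LS", type = "full")
    expect_gte(ff$logLik, fl$logLik - 1e-6)
  }
})

test_that("all flies on one rail is a rank-deficiency error", {
  rec <- paraboloid_records(n = 60)
  rec$P_day_mg <- rec$C_day_mg  # everything on the 1:1 rail
  expect_error(surface_fit(rec, "LS", random = NULL), "rank-deficient")
})

test_that("term tests equal a likelihood-ratio oracle and are monotone in
           effect size", {
  rec <- paraboloid_records(n = 120, seed = 9)
  set.seed(9)
  rec$LS <- 2 * rec$C_day_mg - 0.04 * rec$C_day_mg^2 + rnorm(120, 0, 1)
  f <- surface_fit(rec, "LS", standardize = FALSE, random = NULL)
  tt <- term_tests(f)
  # oracle: explicit lm fits of the full and per-term-reduced polynomials
  d <- data.frame(P = rec$P_day_mg, C = rec$C_day_mg, y = rec$LS)
  cols <- c(P = "P", C = "C", PxP = "I(P^2)", CxC = "I(C^2)",
            PxC = "I(P * C)")
  ll_full <- as.numeric(logLik(lm(reformulate(cols, "y"), d)))
  for (term in names(cols)) {
    ll_red <- as.numeric(logLik(lm(reformulate(cols[names(cols) != term],
                                               "y"), d)))
    expect_equal(tt[term, "chi2"], 2 * (ll_full - ll_red), tolerance = 1e-6)
  }
  # irrelevant interaction stays at null size, the real C terms dominate
  expect_lt(tt["PxC", "chi2"], qchisq(0.9999, 1))
  expect_gt(tt["C", "chi2"], 100)
  expect_true(all(tt$p >= 0 & tt$p <= 1))
  # chi2 for the correlational term grows with the true interaction
  chis <- vapply(c(0.005, 0.02, 0.08), function(g) {
    r2 <- paraboloid_records(n = 120, seed = 9)
    r2$LS <- 2 * r2$C_day_mg + g * r2$P_day_mg * r2$C_day_mg +
      rnorm(120, 0, 0.5)
    term_tests(surface_fit(r2, "LS", standardize = FALSE,
                           random = NULL))["PxC", "chi2"]
  }, 1)
  expect_true(all(diff(chis) > 0))
})

test_that("surface coefficients are recovered within 3 SE at study scale", {
  # one line x sex landscape: 15 diets x 4 replicates x 5 flies = 300
  truth <- default_surfaces()$LS$CT$F
  hits <- matrix(NA, 12, 5)
  for (s in 1:12) {
    x <- generate_experiment1(
      design_exp1(lines = "CT", replicates = c(CT = 4), sexes = "F",
                  flies_per_cell = 5, seed = 100 + s),
      nonnatural_frac = 0)
    rec <- prepare_analysis(x$flies)$records
    f <- surface_fit(rec, "LS", standardize = FALSE)
    tr <- c(truth$beta_P, truth$beta_C, truth$gamma_PP, truth$gamma_CC,
            truth$gamma_PC)
    hits[s, ] <- abs(coef(f) - tr) <= 3 * f$se
  }
  expect_gte(mean(rowMeans(hits) == 1), 0.9)
})

test_that("total-consumption model recovers the line difference direction", {
  x <- generate_experiment1(design_exp1(flies_per_cell = 2, seed = 31),
                            line_volume_mult = c(CT = 0.85, US = 1.15))
  rec <- prepare_analysis(x$flies)$records
  tc <- fit_total_consumption(rec)
  # US consumes more: the US-vs-CT contrast is positive, i.e. CT negative
  expect_gt(unname(tc$coefficients["lineUS"]), 0)
  expect_lt(tc$tests["line", "p"], 0.05)
  expect_error(fit_total_consumption(rec[rec$line == "CT", ]),
               "both lines")
})

test_that("sqrt-transformed all-zero consumption stays finite", {
  rec <- data.frame(
    P_day_mg = 0, C_day_mg = 0,
    line = rep(c("CT", "US"), each = 20), sex = rep(c("F", "M"), 20),
    replicate = rep(paste0("r", 1:4), 10),
    diet_label = diet_grid()$label[1])
  tc <- fit_total_consumption(rec)
  expect_true(all(is.finite(tc$tests$chi2)))
})
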